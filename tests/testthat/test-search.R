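test_that("candidate_pairs enumerates within-bucket and mutant cross pairs once", {
  # all buckets of size <= 1: no pairs
  db <- est_database(c(s1 = "ACGT", s2 = "GGCC"))
  p <- derive_params(4, 0, "exact", q = 2)   # k=1 blocks of the 4-mer? k=d+1=1
  idx <- build_index(db, 2)
  expect_identical(nrow(candidate_pairs(build_index(est_database(
    c(s1 = "ACGTA")), 5), derive_params(5, 0, "exact"))), 0L)

  # one bucket with three occurrences: C(3,2) pairs
  idx <- build_index(est_database(c(s1 = "AAAA")), 2)
  pr <- candidate_pairs(idx, derive_params(4, 1, "exact", q = 2))
  expect_identical(nrow(pr), 3L)

  # 1-mutant cross pass pairs AAAA with AACA exactly once (k=1, q=l here)
  db <- est_database(c(s1 = "AAAA", s2 = "AACA"))
  pr <- candidate_pairs(build_index(db, 4), derive_params(4, 1, "one-mismatch"))
  cross <- pr[pr$seq1 != pr$seq2, ]
  expect_identical(nrow(cross), 1L)
  expect_identical(c(cross$seq1, cross$start1, cross$seq2, cross$start2),
                   c(1L, 0L, 2L, 0L))
})

test_that("extension is block-aligned and verification is exact", {
  set.seed(31)
  x <- rand_dna(28)
  params <- derive_params(28, 6, "one-mismatch")

  # identical l-mers: the (0,0) candidate verifies with HD 0
  db <- est_database(c(s1 = x, s2 = x))
  kept <- extend_and_verify(list(seq1 = 1, start1 = 0, seq2 = 2, start2 = 0),
                            db, params)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$hd, 0L)

  # HD 7 pair sharing an exact block-0 seed: candidate generated, rejected
  y <- substitute_at(x, c(9, 12, 15, 18, 21, 24, 27))
  expect_identical(hamming(x, y), 7L)
  db <- est_database(c(s1 = x, s2 = y))
  kept <- extend_and_verify(list(seq1 = 1, start1 = 0, seq2 = 2, start2 = 0),
                            db, params)
  expect_identical(nrow(kept), 0L)

  # 6 substitutions, none inside block 2 (offsets 14..20): the block-2 seed
  # pass recovers the pair and verification accepts at HD 6
  z <- substitute_at(x, c(1, 4, 8, 23, 26, 28))
  expect_identical(hamming(x, z), 6L)
  expect_identical(substr(x, 15, 21), substr(z, 15, 21))
  db <- est_database(c(s1 = x, s2 = z))
  kept <- extend_and_verify(list(seq1 = 1, start1 = 14, seq2 = 2, start2 = 14),
                            db, params)
  expect_identical(nrow(kept), 1L)
  expect_identical(c(kept$start1, kept$start2), c(0L, 0L))
  expect_identical(kept$hd, 6L)
  res <- find_nonunique(db, params)
  expect_identical(res$nonunique, list(0L, 0L))
})

test_that("uniqueness follows the cross-EST definition", {
  # a lone EST has no other EST to collide with
  db1 <- est_database(c(s1 = strrep("AC", 20)))
  r <- find_nonunique(db1, derive_params(8, 2, "exact"))
  expect_identical(r$n_nonunique, 0L)
  expect_identical(r$n_unique, r$n_clean)

  # two identical ESTs share every l-mer
  db2 <- est_database(c(s1 = "ACGTACGTACGT", s2 = "ACGTACGTACGT"))
  r <- find_nonunique(db2, derive_params(8, 1, "one-mismatch"))
  expect_identical(r$n_unique, 0L)
  expect_identical(lengths(r$nonunique), lengths(r$clean_windows))
})

test_that("unique and non-unique partition the clean windows", {
  db <- generate_est_db(6, c(40, 80), seed = 13)
  for (s in all_schemes) {
    r <- find_nonunique(db, derive_params(10, 2, s))
    for (i in seq_along(db$sequences)) {
      u <- r$unique_oligos$start[r$unique_oligos$seq_index == i]
      expect_identical(sort(c(u, r$nonunique[[i]])), r$clean_windows[[i]])
      expect_length(intersect(u, r$nonunique[[i]]), 0L)
    }
    expect_true(all(nchar(r$unique_oligos$oligo) == 10L))
    expect_false(any(grepl("[^ACGT]", r$unique_oligos$oligo)))
  }
})

test_that("engine marks equal the composition of the exported R operations", {
  for (seed in 1:4) {
    db <- generate_est_db(4, c(25, 45), seed = 200 + seed)
    for (s in all_schemes) {
      p <- derive_params(9, 3, s)
      expect_identical(marks_of(find_nonunique(db, p)),
                       reference_marks(db, p))
      expect_identical(marks_of(find_nonunique(db, p, within_est = TRUE)),
                       reference_marks(db, p, within_est = TRUE))
    }
  }
})

test_that("increasing d never shrinks the non-unique set", {
  db <- generate_est_db(8, c(50, 100), seed = 17)
  prev <- NULL
  for (d in 0:6) {
    r <- find_nonunique(db, derive_params(12, d, "one-mismatch"))
    if (!is.null(prev)) {
      for (i in seq_along(db$sequences))
        expect_true(all(prev[[i]] %in% r$nonunique[[i]]))
    }
    prev <- r$nonunique
  }
})

test_that("results are invariant under record reordering", {
  db <- generate_est_db(5, c(40, 70), seed = 23)
  perm <- c(4L, 2L, 5L, 1L, 3L)
  db2 <- est_database(db$sequences[perm], db$ids[perm])
  p <- derive_params(10, 2, "two-mismatch")
  r1 <- find_nonunique(db, p)
  r2 <- find_nonunique(db2, p)
  for (i in seq_along(perm))
    expect_identical(r2$nonunique[[i]], r1$nonunique[[perm[i]]])
})

test_that("within-EST repeats disqualify only under the stricter policy", {
  # one EST carrying an internal exact repeat, plus an unrelated EST
  set.seed(41)
  core <- rand_dna(10)
  db <- est_database(c(s1 = paste0(core, "GGGGG", core),
                       s2 = rand_dna(30)))
  p <- derive_params(10, 1, "exact")
  r_default <- find_nonunique(db, p)
  r_within <- find_nonunique(db, p, within_est = TRUE)
  expect_false(0 %in% r_default$nonunique[[1]])
  expect_true(0 %in% r_within$nonunique[[1]])
  expect_true(15 %in% r_within$nonunique[[1]])
})

test_that("reverse-complement shadow matching maps back to forward coordinates", {
  set.seed(43)
  x <- rand_dna(60)
  rc20 <- revcomp_string(substr(x, 1, 20))
  y <- paste0(rand_dna(15), rc20, rand_dna(15))
  db <- est_database(c(s1 = x, s2 = y))
  p <- derive_params(20, 2, "one-mismatch")
  r_off <- find_nonunique(db, p)
  r_on <- find_nonunique(db, p, revcomp = TRUE)
  expect_false(0 %in% r_off$nonunique[[1]])
  expect_true(0 %in% r_on$nonunique[[1]])
  expect_true(15 %in% r_on$nonunique[[2]])
  # the oracle agrees under the same strand policy
  expect_identical(r_on$nonunique, brute_force(db, 20, 2, revcomp = TRUE)$nonunique)
})

test_that("l longer than every sequence yields an empty result with a warning", {
  db <- est_database(c(s1 = "ACGTACGT"))
  expect_warning(r <- find_nonunique(db, derive_params(20, 2, "exact")),
                 "exceeds every sequence")
  expect_identical(r$n_clean, 0L)
  expect_identical(r$n_unique, 0L)
})
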