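test_that("hamming counts mismatching positions and rejects unequal lengths", {
  expect_identical(hamming("ACGT", "ACGT"), 0L)
  expect_identical(hamming("AAAA", "TTTT"), 4L)
  expect_identical(hamming("ACGTACG", "ACCTACG"), 1L)
  expect_error(hamming("ACG", "ACGT"), "equal-length")
})

test_that("hamming is a metric on random string triples", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    x <- rand_dna(n); y <- rand_dna(n); z <- rand_dna(n)
    expect_identical(hamming(x, y), hamming(y, x))
    expect_identical(hamming(x, x), 0L)
    expect_lte(hamming(x, z), hamming(x, y) + hamming(y, z))
  }
})

test_that("derive_params reproduces the published (l, d, scheme) -> q triples", {
  p1 <- derive_params(28, 6, "one-mismatch")
  expect_identical(c(p1$q, p1$k, p1$m), c(7L, 4L, 1L))
  p2 <- derive_params(28, 6, "exact")
  expect_identical(c(p2$q, p2$k, p2$m), c(4L, 7L, 0L))
  p3 <- derive_params(27, 6, "two-mismatch")
  expect_identical(c(p3$q, p3$k, p3$m), c(9L, 3L, 2L))
})

test_that("derive_params validates inputs and q overrides", {
  expect_error(derive_params(5, 6, "exact"), "too short")
  expect_error(derive_params(0, 3, "exact"), "l")
  expect_error(derive_params(10, -1, "exact"), "d")
  expect_error(derive_params(10, 2, "no-such-scheme"), "unknown scheme")
  expect_error(derive_params(28, 6, "one-mismatch", q = 8), "q override")
  expect_identical(derive_params(28, 6, "one-mismatch", q = 5)$q, 5L)
  # scheme aliases with underscores are accepted
  expect_identical(derive_params(28, 6, "ONE_MISMATCH")$scheme, "one-mismatch")
})

test_that("degenerate small-d schemes stay within the representable seed range", {
  # one-mismatch with d <= 1 collapses to a single block; the seed is capped
  # so its code space stays exact, which keeps the filter a superset and the
  # HD verification exact
  p <- derive_params(28, 0, "one-mismatch")
  expect_identical(p$k, 1L)
  expect_lte(p$q, 25L)
  expect_lte(p$k * p$q, p$l)
})

test_that("block seed offsets tile the l-mer without overlap", {
  expect_identical(block_starts(derive_params(28, 6, "one-mismatch")),
                   c(0L, 7L, 14L, 21L))
  expect_identical(block_starts(derive_params(27, 6, "two-mismatch")),
                   c(0L, 9L, 18L))
  expect_identical(block_starts(derive_params(5, 0, "exact")), 0L)
  for (l in c(12L, 20L, 28L)) for (d in 0:6) for (s in all_schemes) {
    p <- derive_params(l, d, s)
    starts <- block_starts(p)
    expect_length(starts, p$k)
    # blocks [i*q, (i+1)*q) for i < k-1 plus [(k-1)*q, l) tile [0, l)
    ends <- c(starts[-1], p$l)
    expect_identical(starts[1], 0L)
    expect_true(all(ends - starts >= p$q))
    expect_identical(sum(ends - starts), p$l)
  }
})

test_that("pigeonhole guarantee: some block's seeds match within m for HD <= d", {
  # the property depends only on the mismatch position set, so enumerate all
  # position subsets of size <= d instead of sequence pairs
  l <- 12L
  for (d in 0:6) for (s in all_schemes) {
    p <- derive_params(l, d, s)
    seeds_lo <- block_starts(p)
    for (j in 0:d) {
      sets <- utils::combn(l, j)
      for (col in seq_len(ncol(sets))) {
        mm <- sets[, col] - 1L     # 0-based mismatch positions
        per_seed <- vapply(seeds_lo, function(o)
          sum(mm >= o & mm < o + p$q), integer(1))
        expect_lte(min(per_seed), p$m)
      }
    }
  }
})
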