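all_schemes <- c("exact", "one-mismatch", "two-mismatch")

# exhaustive string-space Hamming ball: all q-mers with 1 <= HD <= m from s.
# Independent oracle for mutant_codes (works in string space, not code space).
string_mutants <- function(s, m) {
  q <- nchar(s)
  bases <- c("A", "C", "G", "T")
  grids <- rep(list(bases), q)
  all_mers <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  keep <- vapply(all_mers, function(t) {
    h <- hamming(s, t)
    h >= 1L && h <= m
  }, logical(1))
  sort(all_mers[keep])
}

# random DNA string helper (uses the session RNG; callers set the seed)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute the given 1-based positions of s with a different base each
substitute_at <- function(s, positions) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# marked-position lists of a result, for compact equality assertions
marks_of <- function(result) result$nonunique

# reference phase two assembled from the exported R operations:
# candidate generation -> block-aligned extension -> HD verification
reference_marks <- function(db, params, within_est = FALSE) {
  idx <- build_index(db, params$q)
  pairs <- candidate_pairs(idx, params)
  marks <- rep(list(integer(0)), length(db$sequences))
  for (r in seq_len(nrow(pairs))) {
    pair <- pairs[r, ]
    if (!within_est && pair$seq1 == pair$seq2) next
    kept <- extend_and_verify(pair, db, params)
    for (j in seq_len(nrow(kept))) {
      marks[[kept$seq1[j]]] <- union(marks[[kept$seq1[j]]], kept$start1[j])
      marks[[kept$seq2[j]]] <- union(marks[[kept$seq2[j]]], kept$start2[j])
    }
  }
  lapply(marks, function(v) sort(as.integer(v)))
}
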