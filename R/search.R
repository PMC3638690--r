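fmt_code <- function(code) sprintf("%.0f", code)

# shared result assembly: clean window scan + complement of the mark sets.
# `marks` is a per-sequence list of 0-based marked starts (forward strand).
new_uniqueness_result <- function(db, l, d, marks, params = NULL,
                                  within_est = FALSE, revcomp = FALSE) {
  clean <- cpp_clean_windows(db$sequences, as.integer(l))
  nonunique <- lapply(marks, function(v) sort(unique(as.integer(v))))
  uo <- vector("list", length(db$sequences))
  for (i in seq_along(db$sequences)) {
    u <- setdiff(clean[[i]], nonunique[[i]])
    if (length(u)) {
      uo[[i]] <- data.frame(
        seq_index = i, seq_id = db$ids[i], start = u, end = u + as.integer(l),
        oligo = substring(db$sequences[i], u + 1L, u + as.integer(l)),
        stringsAsFactors = FALSE)
    }
  }
  uo <- do.call(rbind, uo)
  if (is.null(uo))
    uo <- data.frame(seq_index = integer(0), seq_id = character(0),
                     start = integer(0), end = integer(0),
                     oligo = character(0), stringsAsFactors = FALSE)
  rownames(uo) <- NULL
  structure(
    list(l = as.integer(l), d = as.integer(d), params = params,
         within_est = within_est, revcomp = revcomp,
         seq_ids = db$ids, clean_windows = clean, nonunique = nonunique,
         unique_oligos = uo,
         n_clean = sum(lengths(clean)),
         n_nonunique = sum(lengths(nonunique)),
         n_unique = nrow(uo)),
    class = "uniqueness_result"
  )
}

#' @export
print.uniqueness_result <- function(x, ...) {
  meth <- if (is.null(x$params)) "brute force"
          else sprintf("scheme %s (q=%d, k=%d, m=%d)",
                       x$params$scheme, x$params$q, x$params$k, x$params$m)
  cat(sprintf("unique-oligo search: l=%d d=%d, %s\n", x$l, x$d, meth))
  cat(sprintf("  %d clean l-window(s): %d non-unique, %d unique\n",
              x$n_clean, x$n_nonunique, x$n_unique))
  invisible(x)
}

# sequences + EST identities presented to the engine; with revcomp, each
# sequence contributes a shadow reverse complement carrying the same EST id
engine_view <- function(db, revcomp) {
  if (!revcomp)
    return(list(seqs = db$sequences, est = seq_along(db$sequences)))
  list(seqs = c(db$sequences, vapply(db$sequences, revcomp_string, "")),
       est = rep(seq_along(db$sequences), 2L))
}

# fold marks on shadow reverse-complement slots back to forward coordinates
fold_marks <- function(raw_marks, db, l, revcomp) {
  ns <- length(db$sequences)
  marks <- raw_marks[seq_len(ns)]
  if (revcomp) {
    for (i in seq_len(ns)) {
      shadow <- raw_marks[[ns + i]]
      if (length(shadow)) {
        fwd <- nchar(db$sequences[i]) - l - shadow
        marks[[i]] <- union(marks[[i]], fwd)
      }
    }
  }
  marks
}

#' Find all non-unique and unique oligos of an EST database
#'
#' Runs the two-phase filtration search: phase one files every clean length-q
#' window into the seed index; phase two pairs occurrences within each bucket
#' (plus across m-mutant buckets for schemes with `m >= 1`), extends each
#' seed pair to l-mers at every block-aligned offset, and verifies each
#' candidate pair by exact Hamming distance. Both members of every verified
#' pair from different ESTs are marked non-unique; the unique oligos are the
#' clean l-windows never marked. The filter generates a superset of the true
#' pairs (the pigeonhole theorems guarantee no pair is missed) and the
#' verification step discards false candidates, so the result equals the
#' brute-force answer for every scheme.
#'
#' @param db An [est_database()].
#' @param params An [derive_params()] object (or `l`/`d`/`scheme` via `...`).
#' @param within_est If `TRUE`, approximate repeats within the same EST also
#'   disqualify an oligo. Default `FALSE`: only occurrences in a *different*
#'   EST make an oligo non-unique.
#' @param revcomp If `TRUE`, each sequence's reverse complement is searched as
#'   a shadow of the same EST and matches are mapped back to forward
#'   coordinates. Default `FALSE`.
#' @return A `uniqueness_result`: per-sequence 0-based `nonunique` start sets,
#'   the `unique_oligos` table (`seq_index`, `seq_id`, `start`, `end`,
#'   `oligo`; 0-based half-open), the clean-window lists and summary counts.
#' @examples
#' db <- est_database(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"))
#' find_nonunique(db, derive_params(8, 1, "exact"))$n_unique  # 0
#' @export
find_nonunique <- function(db, params, within_est = FALSE, revcomp = FALSE) {
  stopifnot(inherits(db, "est_db"), inherits(params, "oligo_params"))
  if (params$l > max(nchar(db$sequences))) {
    warning("l = ", params$l, " exceeds every sequence length; no windows",
            call. = FALSE)
    return(new_uniqueness_result(db, params$l, params$d,
                                 rep(list(integer(0)), length(db$sequences)),
                                 params, within_est, revcomp))
  }
  v <- engine_view(db, revcomp)
  raw <- cpp_find_nonunique(v$seqs, v$est, params$l, params$d,
                            params$q, params$k, params$m,
                            within_est, NULL)
  marks <- fold_marks(raw, db, params$l, revcomp)
  new_uniqueness_result(db, params$l, params$d, marks, params,
                        within_est, revcomp)
}

#' Candidate seed-occurrence pairs of an index
#'
#' Enumerates phase two's candidate pairs without extension or verification:
#' all unordered pairs of distinct occurrences within each bucket, plus (for
#' schemes with `m >= 1`) all occurrence pairs between a bucket `c` and each
#' occupied m-mutant bucket `c' > c`, so every unordered bucket pair is
#' visited exactly once. Intended for inspection and testing at small scale;
#' [find_nonunique()] performs the same enumeration in compiled code.
#'
#' @param index A [build_index()] result with `index$q == params$q`.
#' @param params An [derive_params()] object.
#' @return data.frame with columns `seq1`, `start1`, `seq2`, `start2`
#'   (0-based q-mer occurrences), one row per candidate pair.
#' @export
candidate_pairs <- function(index, params) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "oligo_params"))
  if (index$q != params$q)
    stop("index seed length (", index$q, ") does not match params q (",
         params$q, ")", call. = FALSE)
  occ <- index$occurrences
  keys <- fmt_code(index$codes)
  buckets <- split(occ[c("seq_index", "start")], factor(fmt_code(occ$code), keys))
  out <- list()
  add_pairs <- function(b1, b2 = NULL) {
    if (is.null(b2)) {                       # within-bucket, i < j
      n1 <- nrow(b1)
      if (n1 < 2L) return()
      ij <- utils::combn(n1, 2L)
      out[[length(out) + 1L]] <<- data.frame(
        seq1 = b1$seq_index[ij[1L, ]], start1 = b1$start[ij[1L, ]],
        seq2 = b1$seq_index[ij[2L, ]], start2 = b1$start[ij[2L, ]])
    } else {                                 # cross-bucket, all pairs
      g <- expand.grid(i = seq_len(nrow(b1)), j = seq_len(nrow(b2)))
      out[[length(out) + 1L]] <<- data.frame(
        seq1 = b1$seq_index[g$i], start1 = b1$start[g$i],
        seq2 = b2$seq_index[g$j], start2 = b2$start[g$j])
    }
  }
  for (ci in seq_along(index$codes)) {
    c0 <- index$codes[ci]
    b1 <- buckets[[keys[ci]]]
    add_pairs(b1)
    if (params$m >= 1L) {
      for (c2 in mutant_codes(c0, params$q, params$m)) {
        if (c2 <= c0) next
        b2 <- buckets[[fmt_code(c2)]]
        if (!is.null(b2) && nrow(b2)) add_pairs(b1, b2)
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seq1 = integer(0), start1 = integer(0),
                      seq2 = integer(0), start2 = integer(0))
  rownames(out) <- NULL
  out
}

#' Extend a seed-occurrence pair to verified l-mer pairs
#'
#' For each block index `j`, the candidate l-mer starts are
#' `start1 - j*q` and `start2 - j*q` (the matched seeds must occupy the same
#' block in both l-mers). A candidate is kept when both windows are in
#' bounds, clean, and at Hamming distance at most `d`.
#'
#' @param pair List or one-row data.frame with `seq1`, `start1`, `seq2`,
#'   `start2` (0-based q-mer occurrences).
#' @param db The [est_database()].
#' @param params An [derive_params()] object.
#' @return data.frame of verified aligned l-mer pairs with columns `seq1`,
#'   `start1`, `seq2`, `start2`, `hd`.
#' @export
extend_and_verify <- function(pair, db, params) {
  stopifnot(inherits(db, "est_db"), inherits(params, "oligo_params"))
  l <- params$l; d <- params$d; q <- params$q
  s1 <- as.integer(pair$seq1[1L]); p1 <- as.integer(pair$start1[1L])
  s2 <- as.integer(pair$seq2[1L]); p2 <- as.integer(pair$start2[1L])
  len1 <- nchar(db$sequences[s1]); len2 <- nchar(db$sequences[s2])
  kept <- list()
  for (j in block_starts(params)) {
    a <- p1 - j; b <- p2 - j
    if (a < 0L || b < 0L || a + l > len1 || b + l > len2) next
    if (s1 == s2 && a == b) next
    x <- substring(db$sequences[s1], a + 1L, a + l)
    y <- substring(db$sequences[s2], b + 1L, b + l)
    if (grepl("[^ACGT]", x) || grepl("[^ACGT]", y)) next
    h <- hamming(x, y)
    if (h <= d)
      kept[[length(kept) + 1L]] <- data.frame(seq1 = s1, start1 = a,
                                              seq2 = s2, start2 = b, hd = h)
  }
  kept <- do.call(rbind, kept)
  if (is.null(kept))
    kept <- data.frame(seq1 = integer(0), start1 = integer(0),
                       seq2 = integer(0), start2 = integer(0),
                       hd = integer(0))
  rownames(kept) <- NULL
  kept
}
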