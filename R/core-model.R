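#' Construct an EST database
#'
#' An EST database is an ordered collection of named DNA sequences. Sequences
#' are uppercased on construction; characters outside `{A,C,G,T}` (for example
#' `N`) are retained in the stored sequence but every k-mer window containing
#' one is excluded from indexing, search and reporting.
#'
#' @param sequences Character vector of DNA sequences. Names, if present, are
#'   used as record ids.
#' @param ids Optional character vector of record ids; must be unique. Defaults
#'   to the names of `sequences`, or `seq1, seq2, ...` when unnamed.
#' @return An object of class `est_db`: a list with elements `ids` (character),
#'   `sequences` (uppercase character) and `n` (total symbol count).
#' @examples
#' db <- est_database(c(s1 = "ACGTACGT", s2 = "ttttgggg"))
#' db$n
#' @export
est_database <- function(sequences, ids = NULL) {
  if (!is.character(sequences) || length(sequences) < 1L)
    stop("`sequences` must be a non-empty character vector", call. = FALSE)
  if (is.null(ids)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  }
  if (length(ids) != length(sequences))
    stop("`ids` and `sequences` must have equal length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(sequences)
  names(seqs) <- NULL
  structure(
    list(ids = as.character(ids), sequences = seqs,
         n = sum(nchar(seqs))),
    class = "est_db"
  )
}

#' @export
print.est_db <- function(x, ...) {
  cat(sprintf("EST database: %d record(s), %d symbols total\n",
              length(x$ids), x$n))
  k <- min(length(x$ids), 5L)
  for (i in seq_len(k)) {
    cat(sprintf("  %s  (%d bp)\n", x$ids[i], nchar(x$sequences[i])))
  }
  if (length(x$ids) > k) cat(sprintf("  ... and %d more\n", length(x$ids) - k))
  invisible(x)
}

#' @export
length.est_db <- function(x) length(x$sequences)

#' Hamming distance between two equal-length strings
#'
#' @param x,y Strings of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming("ACGTACG", "ACCTACG")  # 1
#' @export
hamming <- function(x, y) {
  if (length(x) != 1L || length(y) != 1L)
    stop("`x` and `y` must be single strings", call. = FALSE)
  if (nchar(x) != nchar(y))
    stop("hamming distance requires equal-length strings (",
         nchar(x), " vs ", nchar(y), ")", call. = FALSE)
  sum(utf8ToInt(x) != utf8ToInt(y))
}

scheme_names <- c("exact", "one-mismatch", "two-mismatch")

normalize_scheme <- function(scheme) {
  s <- tolower(gsub("_", "-", as.character(scheme)[1L]))
  hit <- match(s, scheme_names)
  if (is.na(hit))
    stop("unknown scheme '", scheme, "'; expected one of: ",
         paste(scheme_names, collapse = ", "), call. = FALSE)
  scheme_names[hit]
}

#' Derive search parameters for a partition scheme
#'
#' Each scheme cuts an l-mer into `k` blocks and indexes a length-`q` seed per
#' block; two l-mers within Hamming distance `d` must then share a block whose
#' seeds differ in at most `m` positions:
#' * `"exact"`: `k = d + 1`, `m = 0` (seed pairs must match exactly);
#' * `"one-mismatch"`: `k = floor(d/2) + 1`, `m = 1`;
#' * `"two-mismatch"`: `k = floor(d/3) + 1`, `m = 2`.
#'
#' The seed length is `q = floor(l/k)` unless overridden, additionally capped
#' at 25 so seed codes stay exact in the `4^q` integer key space. The floor
#' guarantees every block, including the final (possibly longer) one,
#' contains a full length-q seed, which is what makes seed indexing a
#' complete filter; the same argument holds for any shorter seed, so the cap
#' (and any override with `k * q <= l`) preserves completeness.
#'
#' @param l Oligo length in bases (`l >= 1`).
#' @param d Maximum Hamming distance for an approximate occurrence (`d >= 0`).
#' @param scheme One of `"exact"`, `"one-mismatch"`, `"two-mismatch"`.
#' @param q Optional seed-length override; default `floor(l/k)`.
#' @return An object of class `oligo_params`: list with `l`, `d`, `scheme`,
#'   `q`, `k` (block count) and `m` (per-block mismatch budget).
#' @examples
#' derive_params(28, 6, "one-mismatch")$q  # 7
#' derive_params(28, 6, "exact")$q         # 4
#' derive_params(27, 6, "two-mismatch")$q  # 9
#' @export
derive_params <- function(l, d, scheme, q = NULL) {
  l <- as.integer(l); d <- as.integer(d)
  if (is.na(l) || l < 1L) stop("`l` must be >= 1", call. = FALSE)
  if (is.na(d) || d < 0L) stop("`d` must be >= 0", call. = FALSE)
  scheme <- normalize_scheme(scheme)
  k <- switch(scheme,
    "exact"        = d + 1L,
    "one-mismatch" = d %/% 2L + 1L,
    "two-mismatch" = d %/% 3L + 1L)
  m <- switch(scheme, "exact" = 0L, "one-mismatch" = 1L, "two-mismatch" = 2L)
  if (l < k)
    stop("l = ", l, " is too short for ", k,
         " blocks (scheme '", scheme, "', d = ", d, ")", call. = FALSE)
  if (is.null(q)) {
    q <- min(l %/% k, 25L)   # codes must stay exact in the 4^q key space
  } else {
    q <- as.integer(q)
    if (is.na(q) || q < 1L || k * q > l || q > 25L)
      stop("invalid q override: need 1 <= q <= 25 and k*q <= l (k = ", k,
           ", l = ", l, ")", call. = FALSE)
  }
  structure(list(l = l, d = d, scheme = scheme, q = q, k = k, m = m),
            class = "oligo_params")
}

#' @export
print.oligo_params <- function(x, ...) {
  cat(sprintf("oligo search parameters: l=%d d=%d scheme=%s q=%d k=%d m=%d\n",
              x$l, x$d, x$scheme, x$q, x$k, x$m))
  invisible(x)
}

#' Seed start offsets of each block within an l-mer
#'
#' Block `i` (0-based) of an l-mer spans `[i*q, (i+1)*q)` for `i < k - 1`; the
#' final block spans `[(k-1)*q, l)` and is at least `q` long. The indexed seed
#' of every block is its length-q prefix, so the seed starts are the multiples
#' of `q` below `k*q`.
#'
#' @param params An `oligo_params` object from [derive_params()].
#' @return Integer vector of `k` 0-based offsets.
#' @examples
#' block_starts(derive_params(28, 6, "one-mismatch"))  # 0 7 14 21
#' @export
block_starts <- function(params) {
  stopifnot(inherits(params, "oligo_params"))
  params$q * (seq_len(params$k) - 1L)
}

#' Reverse complement of a DNA string
#'
#' Ambiguous characters are preserved as-is after complementing A/C/G/T.
#' @param s A DNA string.
#' @return The reverse complement string.
#' @keywords internal
revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                               collapse = ""))
}
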