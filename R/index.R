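#' Build the q-mer occurrence index of an EST database
#'
#' Phase one of the search: every clean length-q window of every sequence is
#' filed under its 2-bit code. The table is stored sparsely (only occupied
#' keys), keyed on the `[0, 4^q)` code space; occurrences within a bucket are
#' sorted by `(seq_index, start)`. Windows containing a character outside
#' `{A,C,G,T}` are skipped.
#'
#' @param db An [est_database()].
#' @param q Seed length (`q >= 1`).
#' @return An object of class `kmer_index`: list with `q`, `codes` (sorted
#'   numeric vector of occupied keys), `sizes` (bucket occupancy, parallel to
#'   `codes`), `occurrences` (data.frame `code`, `seq_index`, `start`, 0-based
#'   starts, sorted by code then seq then start) and `total_occurrences`.
#' @examples
#' idx <- build_index(est_database(c(s1 = "ACGTACGT")), 4)
#' idx$total_occurrences
#' @export
build_index <- function(db, q) {
  stopifnot(inherits(db, "est_db"))
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("`q` must be >= 1", call. = FALSE)

  per_seq <- vector("list", length(db$sequences))
  for (i in seq_along(db$sequences)) {
    s <- db$sequences[i]
    L <- nchar(s)
    if (L < q) next
    digits <- kmer_digits(s)
    nw <- L - q + 1L
    codes <- numeric(nw)
    valid <- rep(TRUE, nw)
    for (j in 0:(q - 1L)) {
      dj <- digits[(1L + j):(nw + j)]
      valid <- valid & !is.na(dj)
      dj[is.na(dj)] <- 0L
      codes <- codes * 4 + dj
    }
    if (!any(valid)) next
    per_seq[[i]] <- data.frame(code = codes[valid],
                               seq_index = i,
                               start = which(valid) - 1L)
  }
  occ <- do.call(rbind, per_seq)
  if (is.null(occ)) {
    warning("no sequence has a clean window of length q = ", q,
            "; index is empty", call. = FALSE)
    occ <- data.frame(code = numeric(0), seq_index = integer(0),
                      start = integer(0))
  }
  occ <- occ[order(occ$code, occ$seq_index, occ$start), , drop = FALSE]
  rownames(occ) <- NULL
  sizes <- if (nrow(occ)) as.integer(table(factor(occ$code))) else integer(0)
  codes <- if (nrow(occ)) sort(unique(occ$code)) else numeric(0)
  structure(
    list(q = q, codes = codes, sizes = sizes, occurrences = occ,
         total_occurrences = nrow(occ)),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "q-mer index: q=%d, %d occurrence(s) in %d occupied bucket(s) (key space 4^%d = %s)\n",
    x$q, x$total_occurrences, length(x$codes), x$q,
    format(4^x$q, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Occurrence list of one bucket
#'
#' @param index A `kmer_index`.
#' @param code A q-mer code.
#' @return data.frame with columns `seq_index`, `start` (possibly 0 rows).
#' @export
index_bucket <- function(index, code) {
  stopifnot(inherits(index, "kmer_index"))
  occ <- index$occurrences
  occ[occ$code == code, c("seq_index", "start"), drop = FALSE]
}

#' Bucket occupancy summary of a q-mer index
#'
#' Occupancy statistics over the full `4^q` key space: unoccupied keys count
#' as empty buckets, so `mean = total_occurrences / 4^q`, the expected bucket
#' load n/4^q under uniform base composition.
#'
#' @param index A `kmer_index`.
#' @return List with `key_space`, `occupied`, `total_occurrences`, `min`,
#'   `max`, `mean` occupancy.
#' @export
bucket_load_stats <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  key_space <- 4^index$q
  occupied <- length(index$codes)
  list(
    key_space = key_space,
    occupied = occupied,
    total_occurrences = index$total_occurrences,
    min = if (occupied < key_space) 0L
          else if (occupied) min(index$sizes) else 0L,
    max = if (occupied) max(index$sizes) else 0L,
    mean = index$total_occurrences / key_space
  )
}
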