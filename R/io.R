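#' Read an EST database from FASTA
#'
#' Records are kept in file order; ids are the first whitespace-delimited
#' token of each header and must be unique; sequences are uppercased.
#' Ambiguous bases (e.g. `N`) are loaded intact and excluded from k-mer
#' windows downstream.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return An [est_database()].
#' @export
read_est_fasta <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  est_database(as.character(x), ids = ids)
}

#' Write an EST database to FASTA
#'
#' @param db An [est_database()].
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_est_fasta <- function(db, path, width = 70L) {
  stopifnot(inherits(db, "est_db"))
  x <- Biostrings::DNAStringSet(db$sequences)
  names(x) <- db$ids
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Write search results to TSV (and optionally BED)
#'
#' Writes `<prefix>.unique.tsv` (one row per unique oligo: `seq_id`, `start`,
#' `end`, `oligo`; 0-based half-open coordinates), `<prefix>.summary.tsv`
#' (per-sequence clean-window / non-unique / unique counts plus a `TOTAL`
#' row, with the run parameters in `#`-comment header lines) and, when
#' `bed = TRUE`, `<prefix>.unique.bed` with the unique oligo intervals.
#' Non-unique totals count marked window positions summed over sequences.
#'
#' @param result A `uniqueness_result`.
#' @param db The [est_database()] that was searched.
#' @param prefix Output path prefix.
#' @param bed Also write a BED file of unique oligo intervals.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, db, prefix, bed = FALSE) {
  stopifnot(inherits(result, "uniqueness_result"), inherits(db, "est_db"))
  files <- character(0)

  upath <- paste0(prefix, ".unique.tsv")
  uo <- result$unique_oligos[c("seq_id", "start", "end", "oligo")]
  utils::write.table(uo, upath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, upath)

  spath <- paste0(prefix, ".summary.tsv")
  per_seq <- data.frame(
    seq_id = db$ids,
    clean_windows = lengths(result$clean_windows),
    nonunique = lengths(result$nonunique),
    unique = lengths(result$clean_windows) - lengths(result$nonunique),
    stringsAsFactors = FALSE)
  totals <- data.frame(seq_id = "TOTAL",
                       clean_windows = result$n_clean,
                       nonunique = result$n_nonunique,
                       unique = result$n_unique,
                       stringsAsFactors = FALSE)
  con <- file(spath, "w")
  on.exit(close(con))
  scheme <- if (is.null(result$params)) "brute-force" else result$params$scheme
  writeLines(c(
    sprintf("# l=%d d=%d scheme=%s", result$l, result$d, scheme),
    if (!is.null(result$params))
      sprintf("# q=%d k=%d m=%d", result$params$q, result$params$k,
              result$params$m),
    sprintf("# within_est=%s revcomp=%s", result$within_est,
            result$revcomp)), con)
  utils::write.table(rbind(per_seq, totals), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, spath)

  if (bed) {
    bpath <- paste0(prefix, ".unique.bed")
    bed_df <- data.frame(chrom = result$unique_oligos$seq_id,
                         chromStart = result$unique_oligos$start,
                         chromEnd = result$unique_oligos$end,
                         name = result$unique_oligos$oligo)
    utils::write.table(bed_df, bpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, bpath)
  }
  invisible(files)
}
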