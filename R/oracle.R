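#' Brute-force reference solver
#'
#' Compares every pair of clean l-windows directly by Hamming distance and
#' marks both members of each pair at distance at most `d` (cross-EST always;
#' same-EST distinct starts only when `within_est = TRUE`). This is the
#' ground-truth oracle the filtration schemes are tested against; it shares
#' no candidate-generation logic with the engine, so agreement between the
#' two is evidence of correctness rather than tautology. Quadratic in the
#' window count and guarded accordingly.
#'
#' @inheritParams find_nonunique
#' @param l Oligo length.
#' @param d Maximum Hamming distance.
#' @param max_windows Refuse inputs with more clean l-windows than this
#'   (default 20000) to keep runtimes bounded.
#' @return A `uniqueness_result`, directly comparable with
#'   [find_nonunique()] output.
#' @examples
#' db <- est_database(c(a = "AAAAAAAA", b = "AAATTAAA"))
#' brute_force(db, l = 8, d = 2)$n_nonunique  # 2
#' @export
brute_force <- function(db, l, d, within_est = FALSE, revcomp = FALSE,
                        max_windows = 20000L) {
  stopifnot(inherits(db, "est_db"))
  l <- as.integer(l); d <- as.integer(d)
  if (l < 1L || d < 0L) stop("need l >= 1 and d >= 0", call. = FALSE)
  v <- engine_view(db, revcomp)
  nwin <- sum(lengths(cpp_clean_windows(v$seqs, l)))
  if (nwin > max_windows)
    stop("input has ", nwin, " clean l-windows, above the brute-force guard ",
         "of ", max_windows, call. = FALSE)
  raw <- cpp_brute_force(v$seqs, v$est, l, d, within_est)
  marks <- fold_marks(raw, db, l, revcomp)
  new_uniqueness_result(db, l, d, marks, params = NULL,
                        within_est = within_est, revcomp = revcomp)
}
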