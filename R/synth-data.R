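# evaluate `expr` under a fixed RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic EST database
#'
#' Draws i.i.d. uniform `{A,C,G,T}` sequences with lengths sampled uniformly
#' from `length_range`, emulating the scale of EST collections (records of a
#' few hundred bases). Output is fully determined by `seed`; the global RNG
#' state is left untouched.
#'
#' @param num_seqs Number of records (`>= 1`).
#' @param length_range Length bounds `c(min, max)` in bases; default
#'   `c(200, 800)`, the typical EST length range.
#' @param seed Integer seed driving all randomness.
#' @return An [est_database()] with ids `est1, est2, ...`.
#' @examples
#' db <- generate_est_db(5, c(50, 100), seed = 1)
#' range(nchar(db$sequences))
#' @export
generate_est_db <- function(num_seqs, length_range = c(200L, 800L), seed) {
  num_seqs <- as.integer(num_seqs)
  if (is.na(num_seqs) || num_seqs < 1L)
    stop("`num_seqs` must be >= 1", call. = FALSE)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1L] > length_range[2L] || length_range[1L] < 1L)
    stop("`length_range` must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    # sample.int avoids sample()'s length-1 expansion when min == max
    lens <- length_range[1L] - 1L +
      sample.int(length_range[2L] - length_range[1L] + 1L, num_seqs,
                 replace = TRUE)
    seqs <- vapply(lens, function(n)
      paste(sample(bases, n, replace = TRUE), collapse = ""), "")
    est_database(seqs, ids = paste0("est", seq_len(num_seqs)))
  })
}

#' Specify a planted approximate repeat
#'
#' A plant copies the donor l-mer into the recipient window after applying an
#' exact number of base substitutions, so the Hamming distance between the
#' two windows is known by construction.
#'
#' @param donor `c(seq_index, start)` of the source l-mer (0-based start).
#' @param recipient `c(seq_index, start)` where the mutated copy is written.
#' @param substitutions Exact number of substituted positions in `[0, l]`.
#' @param positions Optional distinct 0-based offsets within the l-mer to
#'   substitute; sampled when `NULL`.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(donor, recipient, substitutions, positions = NULL) {
  stopifnot(length(donor) == 2L, length(recipient) == 2L)
  substitutions <- as.integer(substitutions)
  if (is.na(substitutions) || substitutions < 0L)
    stop("`substitutions` must be >= 0", call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (anyDuplicated(positions) || length(positions) != substitutions)
      stop("`positions` must be ", substitutions, " distinct offsets",
           call. = FALSE)
  }
  structure(list(donor = as.integer(donor), recipient = as.integer(recipient),
                 substitutions = substitutions, positions = positions),
            class = "plant_spec")
}

plant_window <- function(p, l, role) {
  idx <- if (role == "donor") p$donor else p$recipient
  c(seq = idx[1L], lo = idx[2L], hi = idx[2L] + l)   # half-open
}

#' Plant approximate repeats into an EST database
#'
#' Overwrites each recipient window with a copy of its donor l-mer carrying
#' exactly the requested number of substitutions (a substituted base is
#' always changed, never resampled to itself). Recipient windows must not
#' overlap any donor or other recipient window, so the planted Hamming
#' distances are unambiguous ground truth: a plant with
#' `substitutions <= d` between different ESTs is guaranteed non-unique at
#' threshold `d`. The random background may add further approximate matches,
#' so the truth set is a subset of, not equal to, the engine's mark set.
#'
#' @param db An [est_database()].
#' @param plants List of [plant_spec()] objects.
#' @param l Oligo length of the planted windows.
#' @param seed Integer seed for substitution placement and substituted bases.
#' @return List with `db` (the modified database) and `truth`, a data.frame
#'   of the planted windows (`seq_index`, `start`, `role`, `plant`,
#'   `substitutions`).
#' @export
plant_repeats <- function(db, plants, l, seed) {
  stopifnot(inherits(db, "est_db"))
  l <- as.integer(l)
  if (inherits(plants, "plant_spec")) plants <- list(plants)

  wins <- list()
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    for (role in c("donor", "recipient")) {
      w <- plant_window(p, l, role)
      if (w["lo"] < 0L || w["hi"] > nchar(db$sequences[w["seq"]]))
        stop("plant ", pi, " ", role, " window out of bounds", call. = FALSE)
      wins[[length(wins) + 1L]] <- c(w, plant = pi,
                                     role = if (role == "donor") 0L else 1L)
    }
  }
  wins <- do.call(rbind, wins)
  # recipients are written; forbid overlap with anything else
  for (i in which(wins[, "role"] == 1L)) {
    for (j in seq_len(nrow(wins))) {
      if (i == j) next
      if (wins[i, "seq"] == wins[j, "seq"] &&
          wins[i, "lo"] < wins[j, "hi"] && wins[j, "lo"] < wins[i, "hi"])
        stop("overlapping plant windows (plant ", wins[i, "plant"],
             " and plant ", wins[j, "plant"], ")", call. = FALSE)
    }
  }

  bases <- c("A", "C", "G", "T")
  seqs <- db$sequences
  truth <- list()
  with_seed(seed, {
    for (pi in seq_along(plants)) {
      p <- plants[[pi]]
      donor_mer <- substring(seqs[p$donor[1L]], p$donor[2L] + 1L,
                             p$donor[2L] + l)
      if (grepl("[^ACGT]", donor_mer))
        stop("plant ", pi, " donor window is not a clean {A,C,G,T} l-mer",
             call. = FALSE)
      pos <- p$positions
      if (is.null(pos))
        pos <- sort(sample.int(l, p$substitutions) - 1L)
      if (length(pos) && (min(pos) < 0L || max(pos) >= l))
        stop("plant ", pi, " substitution offsets out of [0, l)",
             call. = FALSE)
      mer <- strsplit(donor_mer, "", fixed = TRUE)[[1L]]
      for (o in pos)
        mer[o + 1L] <- sample(setdiff(bases, mer[o + 1L]), 1L)
      mutated <- paste(mer, collapse = "")
      s <- p$recipient[1L]
      seqs[s] <- paste0(substring(seqs[s], 1L, p$recipient[2L]), mutated,
                        substring(seqs[s], p$recipient[2L] + l + 1L))
      truth[[length(truth) + 1L]] <- data.frame(
        seq_index = c(p$donor[1L], p$recipient[1L]),
        start = c(p$donor[2L], p$recipient[2L]),
        role = c("donor", "recipient"), plant = pi,
        substitutions = p$substitutions, stringsAsFactors = FALSE)
    }
  })
  out_db <- est_database(seqs, ids = db$ids)
  for (pi in seq_along(plants)) {   # planted distance must be exact
    p <- plants[[pi]]
    got <- hamming(
      substring(out_db$sequences[p$donor[1L]], p$donor[2L] + 1L,
                p$donor[2L] + l),
      substring(out_db$sequences[p$recipient[1L]], p$recipient[2L] + 1L,
                p$recipient[2L] + l))
    if (got != p$substitutions)
      stop("internal error: plant ", pi, " realised HD ", got,
           " != requested ", p$substitutions, call. = FALSE)
  }
  list(db = out_db, truth = do.call(rbind, truth))
}
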