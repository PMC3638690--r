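#' Partition the occupied seed-key space across workers
#'
#' Splits the sorted occupied keys of an index into `workers` contiguous
#' chunks balanced by estimated candidate-pair work (the sum of squared
#' bucket sizes per chunk), not by key count, so a single giant bucket does
#' not serialise the run.
#'
#' @param index A [build_index()] result.
#' @param workers Number of workers (`>= 1`).
#' @return An object of class `work_partition`: list with `chunks` (list of
#'   numeric key vectors, pairwise disjoint, union = all occupied keys) and
#'   `worker_count`.
#' @export
partition_keys <- function(index, workers) {
  stopifnot(inherits(index, "kmer_index"))
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("`workers` must be >= 1", call. = FALSE)
  codes <- index$codes
  work <- as.numeric(index$sizes)^2
  chunks <- vector("list", 0L)
  if (length(codes)) {
    total <- sum(work)
    target <- total / workers
    cuts <- integer(0)
    acc <- 0
    remaining <- workers
    for (i in seq_along(codes)) {
      acc <- acc + work[i]
      # close the chunk once its work reaches the running target, keeping
      # at least one key per remaining worker
      if (remaining > 1L && acc >= target &&
          length(codes) - i >= remaining - 1L) {
        cuts <- c(cuts, i)
        acc <- 0
        remaining <- remaining - 1L
        target <- (total - sum(work[seq_len(i)])) / remaining
      }
    }
    bounds <- c(0L, cuts, length(codes))
    chunks <- lapply(seq_len(length(bounds) - 1L), function(j)
      codes[(bounds[j] + 1L):bounds[j + 1L]])
  }
  structure(list(chunks = chunks, worker_count = workers),
            class = "work_partition")
}

#' @export
print.work_partition <- function(x, ...) {
  cat(sprintf("work partition: %d chunk(s) for %d worker(s); keys per chunk: %s\n",
              length(x$chunks), x$worker_count,
              paste(lengths(x$chunks), collapse = ", ")))
  invisible(x)
}

#' Parallel unique-oligo search
#'
#' Runs phase two over disjoint chunks of the seed key space, one worker per
#' chunk. A chunk owns the within-bucket pairs of its keys and every mutant
#' cross pair whose *lower* key it owns, so each candidate pair is generated
#' by exactly one worker; workers return only their mark sets and the merge
#' is a set union, which makes the result identical to the serial engine for
#' any worker count. Forked processes are used where available (`parallel`
#' package); with `workers = 1` the serial engine is called directly.
#'
#' @inheritParams find_nonunique
#' @param workers Number of parallel workers (default 1).
#' @return A `uniqueness_result`, identical to [find_nonunique()] output.
#' @export
find_nonunique_parallel <- function(db, params, workers = 1L,
                                    within_est = FALSE, revcomp = FALSE) {
  stopifnot(inherits(db, "est_db"), inherits(params, "oligo_params"))
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("`workers` must be >= 1", call. = FALSE)
  if (workers == 1L)
    return(find_nonunique(db, params, within_est, revcomp))
  if (params$l > max(nchar(db$sequences))) {
    warning("l = ", params$l, " exceeds every sequence length; no windows",
            call. = FALSE)
    return(new_uniqueness_result(db, params$l, params$d,
                                 rep(list(integer(0)), length(db$sequences)),
                                 params, within_est, revcomp))
  }
  v <- engine_view(db, revcomp)
  vdb <- est_database(v$seqs, ids = paste0("slot", seq_along(v$seqs)))
  part <- partition_keys(build_index(vdb, params$q), workers)

  run_chunk <- function(keys) {
    cpp_find_nonunique(v$seqs, v$est, params$l, params$d,
                       params$q, params$k, params$m, within_est, keys)
  }
  can_fork <- .Platform$OS.type == "unix"
  per_chunk <- if (can_fork) {
    parallel::mclapply(part$chunks, run_chunk,
                       mc.cores = min(workers, length(part$chunks)))
  } else {
    lapply(part$chunks, run_chunk)
  }
  for (res in per_chunk) {
    if (inherits(res, "try-error") || !is.list(res))
      stop("parallel worker failed: ", paste(res, collapse = " "),
           call. = FALSE)
  }
  raw <- rep(list(integer(0)), length(v$seqs))
  for (res in per_chunk)
    for (i in seq_along(res))
      raw[[i]] <- union(raw[[i]], res[[i]])
  marks <- fold_marks(raw, db, params$l, revcomp)
  new_uniqueness_result(db, params$l, params$d, marks, params,
                        within_est, revcomp)
}
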