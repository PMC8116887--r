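#' Configure the external Sort-Reduce engine
#'
#' Sort-Reduce turns a stream of fine-grained `(key, counter-pair)` update
#' requests into one sorted, fully reduced run using two phases: phase 1
#' buffers updates up to the memory budget, sorts each buffer, merges equal
#' keys, and spills the reduced block to storage; phase 2 repeatedly merges
#' up to `merge_fanin` sorted runs (reducing equal keys during the merge)
#' until a single run remains. Reduction here is saturating 16-bit counter
#' addition; [sort_reduce()] also accepts any associative, commutative
#' user-defined reduction on counter pairs.
#'
#' @param mem_budget_bytes Phase-1 buffer limit in bytes; one update record
#'   occupies 12 bytes (8-byte key, two 2-byte counters).
#' @param merge_fanin Maximum number of runs merged per pass (>= 2).
#' @param spill_dir Working directory for run files (created if missing).
#' @param keep_intermediates Keep intermediate run files after each merge
#'   pass instead of deleting them (debugging aid).
#' @return A list of class `sr_config`.
#' @export
sr_config <- function(mem_budget_bytes = 64 * 2^20, merge_fanin = 16L,
                      spill_dir = tempfile("sortreduce"),
                      keep_intermediates = FALSE) {
  if (mem_budget_bytes < 12) abort("mem_budget_bytes must hold one 12-byte record")
  if (merge_fanin < 2) abort("merge_fanin must be >= 2")
  structure(list(mem_budget_bytes = as.numeric(mem_budget_bytes),
                 merge_fanin = as.integer(merge_fanin),
                 spill_dir = spill_dir,
                 keep_intermediates = isTRUE(keep_intermediates)),
            class = "sr_config")
}

.sr_max_records <- function(cfg) max(1, floor(cfg$mem_budget_bytes / 12))

.sr_dir <- function(cfg) {
  if (!dir.exists(cfg$spill_dir) &&
      !dir.create(cfg$spill_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("cannot create spill directory '%s'", cfg$spill_dir))
  cfg$spill_dir
}

#' Sort-Reduce phase 1: spill sorted, reduced runs
#'
#' Consumes a finite update stream (a data frame with numeric `key` and
#' non-negative integer `n`, `t` columns) and writes sorted run files, each
#' internally reduced by saturating counter addition, holding at most
#' `mem_budget_bytes / 12` input records.
#'
#' @param updates Data frame with columns `key`, `n`, `t`.
#' @param cfg An [sr_config()].
#' @param prefix File-name prefix for this stream's runs.
#' @param reduce_fn Optional user reduction (see [merge_runs()]); also
#'   applied to equal keys within each buffered block.
#' @return Character vector of run file paths (empty for an empty stream).
#' @export
phase1_spill <- function(updates, cfg = sr_config(), prefix = "run",
                         reduce_fn = NULL) {
  stopifnot(all(c("key", "n", "t") %in% names(updates)))
  if (nrow(updates) == 0) return(character(0))
  if (is.null(reduce_fn)) {
    return(cpp_spill_runs(as.numeric(updates$key), as.integer(updates$n),
                          as.integer(updates$t), .sr_max_records(cfg),
                          .sr_dir(cfg), prefix))
  }
  dir <- .sr_dir(cfg)
  maxrec <- .sr_max_records(cfg)
  blocks <- split(seq_len(nrow(updates)),
                  ceiling(seq_len(nrow(updates)) / maxrec))
  vapply(seq_along(blocks), function(b) {
    blk <- updates[blocks[[b]], , drop = FALSE]
    blk <- blk[order(blk$key), , drop = FALSE]
    out <- file.path(dir, sprintf("%s_%04d.srr", prefix, b))
    keys <- unique(blk$key)
    red <- vapply(keys, function(kk) {
      rows <- which(blk$key == kk)
      acc <- c(blk$n[rows[1]], blk$t[rows[1]])
      for (i in rows[-1])
        acc <- unlist(reduce_fn(acc[1], acc[2], blk$n[i], blk$t[i]))
      acc
    }, numeric(2))
    cpp_write_run(keys, as.integer(red[1, ]), as.integer(red[2, ]), out)
    out
  }, character(1))
}

#' Sort-Reduce phase 2: merge runs to a single sorted run
#'
#' Multi-way-merges sorted runs at fan-in `merge_fanin`, reducing equal keys,
#' and repeats passes (oldest runs first, single-threaded, deterministic)
#' until one run remains. A run whose keys are not strictly increasing
#' aborts with an integrity error.
#'
#' @param runs Character vector of run file paths.
#' @param cfg An [sr_config()].
#' @param reduce_fn Optional reduction `function(n1, t1, n2, t2)` returning a
#'   list/vector `(n, t)`; must be associative and commutative. When given,
#'   merging happens in R (intended for small experimental streams); the
#'   default saturating addition streams in native code.
#' @return Path of the final single run (class `sr_run` with record count).
#' @export
merge_runs <- function(runs, cfg = sr_config(), reduce_fn = NULL) {
  dir <- .sr_dir(cfg)
  if (length(runs) == 0) {
    out <- file.path(dir, "empty_final.srr")
    cpp_write_run(numeric(0), integer(0), integer(0), out)
    return(.sr_run(out))
  }
  pass <- 0L
  while (length(runs) > 1) {
    pass <- pass + 1L
    groups <- split(runs, ceiling(seq_along(runs) / cfg$merge_fanin))
    runs <- vapply(seq_along(groups), function(g) {
      out <- file.path(dir, sprintf("merge_p%03d_g%04d.srr", pass, g))
      if (is.null(reduce_fn)) {
        cpp_merge_runs_pass(groups[[g]], out)
      } else {
        .merge_runs_r(groups[[g]], out, reduce_fn)
      }
      if (!cfg$keep_intermediates) unlink(groups[[g]])
      out
    }, character(1))
  }
  .sr_run(runs)
}

# In-R merge for user-defined reductions (small inputs).
.merge_runs_r <- function(paths, out, reduce_fn) {
  recs <- dplyr::bind_rows(lapply(paths, function(p) {
    r <- cpp_read_run(p)
    tibble(key = r$key, n = r$n, t = r$t)
  }))
  recs <- recs[order(recs$key), , drop = FALSE]
  if (nrow(recs) > 0) {
    keys <- unique(recs$key)
    red <- lapply(keys, function(kk) {
      rows <- recs[recs$key == kk, , drop = FALSE]
      acc <- c(rows$n[1], rows$t[1])
      for (i in seq_len(nrow(rows))[-1]) {
        acc <- unlist(reduce_fn(acc[1], acc[2], rows$n[i], rows$t[i]))
      }
      acc
    })
    m <- do.call(rbind, red)
    cpp_write_run(keys, as.integer(m[, 1]), as.integer(m[, 2]), out)
  } else {
    cpp_write_run(numeric(0), integer(0), integer(0), out)
  }
  invisible(out)
}

.sr_run <- function(path) {
  structure(list(path = path, n_records = cpp_run_count(path)),
            class = "sr_run")
}

#' Run the full two-phase Sort-Reduce over an update stream
#'
#' `phase1_spill()` followed by `merge_runs()`: the result has strictly
#' increasing keys and, for every key, the reduction of all input values for
#' that key — identical (bit for bit) to a naive in-memory accumulation,
#' whatever the memory budget and fan-in.
#'
#' @inheritParams phase1_spill
#' @inheritParams merge_runs
#' @return An `sr_run` (final run path + record count); read it back with
#'   [read_run()].
#' @export
sort_reduce <- function(updates, cfg = sr_config(), reduce_fn = NULL) {
  runs <- phase1_spill(updates, cfg, reduce_fn = reduce_fn)
  merge_runs(runs, cfg, reduce_fn = reduce_fn)
}

#' Read a sorted run file into a tibble
#'
#' @param run An `sr_run` object or a run file path.
#' @return Tibble with columns `key`, `n`, `t`, sorted by `key`.
#' @export
read_run <- function(run) {
  path <- if (inherits(run, "sr_run")) run$path else run
  r <- cpp_read_run(path)
  tibble(key = r$key, n = r$n, t = r$t)
}

#' @export
print.sr_run <- function(x, ...) {
  cat(sprintf("<sr_run> %s records: %s\n", format(x$n_records, big.mark = ","),
              x$path))
  invisible(x)
}
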