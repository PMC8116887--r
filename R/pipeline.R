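#' Run the full detection pipeline on a pair of read sets
#'
#' Wires the units end to end for each root-space partition —
#' Count ([build_histogram()]), store construction ([build_store()]), cache
#' construction ([build_cache()]), Label ([label_reads()]) — then merges the
#' per-partition databases ([merge_dbs()]), groups and aligns interesting
#' reads ([group_reads()]), calls break-points
#' ([call_group_breakpoints()]) and renders the report. Output is invariant
#' to the number of partitions and to the cache budget.
#'
#' @param normal_fastq,tumoral_fastq FASTQ(.gz) paths.
#' @param k K-mer length.
#' @param partitions Number of root-space partitions `P`.
#' @param out_dir Output directory for histograms, stores, databases and
#'   reports.
#' @param sr_cfg,store_cfg,label_cfg Unit configurations.
#' @param cache_budget Cache budget in bytes per partition.
#' @param cmin,context Break-point calling parameters
#'   (see [call_breakpoints()]).
#' @return A `kmerscout_run` list: `db`, `groups`, `calls`, `report`,
#'   `stages` (per-stage log tibble), `paths`.
#' @export
run_pipeline <- function(normal_fastq, tumoral_fastq, k = 28L,
                         partitions = 1L, out_dir = tempfile("kmerscout"),
                         sr_cfg = NULL, store_cfg = store_config(),
                         label_cfg = label_config(),
                         cache_budget = 2^20, cmin = 3L, context = NULL) {
  k <- .check_k(k)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    abort(sprintf("cannot create '%s'", out_dir))
  if (is.null(sr_cfg))
    sr_cfg <- sr_config(spill_dir = file.path(out_dir, "spill"))
  parts <- partition_bounds(k, partitions)
  dbs <- list()
  stages <- list()
  for (p in seq_len(nrow(parts))) {
    part <- parts[p, ]
    t0 <- proc.time()[["elapsed"]]
    hist <- build_histogram(
      normal_fastq, tumoral_fastq, k = k, partition = part, sr_cfg = sr_cfg,
      path = file.path(out_dir, sprintf("partition%02d.kmh", p - 1L)))
    store <- build_store(hist, store_cfg,
                         path = file.path(out_dir,
                                          sprintf("partition%02d.kvr", p - 1L)))
    cache <- build_cache(hist, cache_budget)
    db <- label_reads(normal_fastq, tumoral_fastq, store, cache,
                      cfg = label_cfg, k = k, partition = part)
    st <- attr(db, "stats")
    dbs[[p]] <- db
    stages[[p]] <- tibble(
      partition = part$partition, entries = hist$n_entries,
      roots = hist$n_roots, singleton_roots = hist$singleton_roots,
      lookups = st$lookups, cache_hits = st$cache_hits,
      chunk_reads = st$chunk_reads, db_reads = nrow(db$reads),
      db_kmers = nrow(db$kmers),
      elapsed_sec = proc.time()[["elapsed"]] - t0)
  }
  db <- merge_dbs(dbs)
  write_db(db, file.path(out_dir, "interesting"))
  groups <- group_reads(db)
  calls <- call_group_breakpoints(groups, cmin = cmin, context = context)
  report <- render_report(calls, groups, path = file.path(out_dir, "breakpoints"))
  structure(list(db = db, groups = groups, calls = calls, report = report,
                 stages = dplyr::bind_rows(stages),
                 k = k, partitions = partitions,
                 paths = list(out_dir = out_dir,
                              report = file.path(out_dir, "breakpoints.report.txt"),
                              calls = file.path(out_dir, "breakpoints.calls.tsv"))),
            class = "kmerscout_run")
}

#' Simulate a patient and run the pipeline against its ground truth
#'
#' Convenience driver for parameter-recovery studies: [make_patient()],
#' [run_pipeline()], then [evaluate_calls()] against the manifest.
#'
#' @param cfg A [sim_config()].
#' @param k,partitions,cache_budget,label_cfg,cmin See [run_pipeline()].
#' @param out_dir Output directory.
#' @return A `kmerscout_run` with extra fields `patient` and `evaluation`.
#' @export
run_simulated <- function(cfg = sim_config(), k = 28L, partitions = 1L,
                          cache_budget = 2^20, label_cfg = label_config(),
                          cmin = 3L, out_dir = tempfile("kmerscout")) {
  patient <- make_patient(cfg, dir = file.path(out_dir, "patient"))
  run <- run_pipeline(patient$normal, patient$tumor, k = k,
                      partitions = partitions, out_dir = out_dir,
                      label_cfg = label_cfg, cache_budget = cache_budget,
                      cmin = cmin)
  origins <- parse_read_origins(patient$normal, patient$tumor)
  run$patient <- patient
  run$evaluation <- evaluate_calls(run$calls, run$groups, patient$manifest,
                                   origins, tolerance = k)
  run
}

#' @export
print.kmerscout_run <- function(x, ...) {
  cat(sprintf(
    "<kmerscout_run> k=%d, %d partition(s): %d interesting reads, %d interesting k-mers, %d groups, %d calls\n",
    x$k, x$partitions, nrow(x$db$reads), nrow(x$db$kmers), nrow(x$groups),
    nrow(x$calls)))
  if (!is.null(x$evaluation))
    print(x$evaluation)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `kmerscout_run`.
#' @param ... Unused.
#' @export
glance.kmerscout_run <- function(x, ...) {
  out <- tibble(k = x$k, partitions = x$partitions,
                interesting_reads = nrow(x$db$reads),
                interesting_kmers = nrow(x$db$kmers),
                groups = nrow(x$groups), calls = nrow(x$calls))
  if (!is.null(x$evaluation)) {
    out$recall <- x$evaluation$recall
    out$precision <- x$evaluation$precision
  }
  out
}
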