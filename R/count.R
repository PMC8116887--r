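#' Partition the root-code space into contiguous ranges
#'
#' Range-partitions the `4^(k-2)` stem codes into `P` half-open intervals of
#' width `ceiling(4^(k-2) / P)`. Partitions can be counted and labeled
#' independently (each with a tight band-pass filter) and merged afterwards;
#' running `P` partitions and concatenating is equivalent to `P = 1`.
#'
#' @param k K-mer length (4-28).
#' @param P Number of partitions (>= 1).
#' @return Tibble with columns `partition` (0-based), `root_lo`, `root_hi`
#'   (half-open code range).
#' @examples
#' partition_bounds(4, 2)   # [0, 8), [8, 16)
#' @export
partition_bounds <- function(k, P = 1L) {
  k <- .check_k(k)
  if (P < 1) abort("P must be >= 1")
  space <- 4^(k - 2)
  width <- ceiling(space / P)
  lo <- (seq_len(P) - 1) * width
  tibble(partition = seq_len(P) - 1L, root_lo = lo,
         root_hi = pmin(lo + width, space))
}

.full_partition <- function(k) {
  tibble(partition = 0L, root_lo = 0, root_hi = 4^(k - 2))
}

#' Read a FASTQ (optionally gzip-compressed) file
#'
#' Minimal 4-line-record FASTQ reader; quality lines are read and discarded.
#' Malformed records abort with the record number.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return Tibble with columns `id` (first header token), `desc` (rest of
#'   the header) and `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    abort(sprintf("'%s': truncated FASTQ (%d lines)", path, length(lines)))
  n <- length(lines) / 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0)
    abort(sprintf("'%s': malformed FASTQ record %d", path, bad[1]))
  hdr <- sub("^@", "", hdr)
  sp <- regexpr(" ", hdr, fixed = TRUE)
  tibble(id = ifelse(sp > 0, substr(hdr, 1, sp - 1), hdr),
         desc = ifelse(sp > 0, substr(hdr, sp + 1, nchar(hdr)), ""),
         seq = toupper(seq))
}

#' Enumerate histogram update requests for a pair of read sets
#'
#' One update per valid k-mer window whose root falls in the partition
#' range: normal reads contribute `(1, 0)`, tumoral reads `(0, 1)`. This is
#' the inspectable tibble view of the update stream (numeric sort keys,
#' hence `k <= 26`); [build_histogram()] streams the same updates through
#' native code and supports `k` up to 28.
#'
#' @param normal_fastq,tumoral_fastq FASTQ(.gz) paths.
#' @param k K-mer length.
#' @param partition One row of [partition_bounds()], or `NULL` for the whole
#'   root space.
#' @return Tibble with columns `key` (root-major sort key), `kmer`, `n`, `t`.
#' @export
emit_updates <- function(normal_fastq, tumoral_fastq, k = 28L,
                         partition = NULL) {
  k <- .check_k(k, max = 26L)
  if (is.null(partition)) partition <- .full_partition(k)
  one <- function(path, tumoral) {
    seqs <- read_fastq(path)$seq
    h <- cpp_read_kmer_hits(seqs, k, partition$root_lo[1], partition$root_hi[1])
    keys <- h$root * 32 + h$vidx
    stem <- cpp_decode_codes(h$root, k - 2L)
    stem[h$vidx >= 16] <- cpp_revcomp_str(stem[h$vidx >= 16])
    bases <- c("A", "C", "G", "T")
    tibble(key = keys,
           kmer = paste0(bases[(h$vidx %/% 4) %% 4 + 1], stem,
                         bases[h$vidx %% 4 + 1]),
           n = if (tumoral) 0L else 1L, t = if (tumoral) 1L else 0L)
  }
  dplyr::bind_rows(one(normal_fastq, FALSE), one(tumoral_fastq, TRUE))
}

#' Build the sorted, singleton-filtered normal/tumoral k-mer histogram
#'
#' The Count unit: every read of both samples is split into k-mers; updates
#' for roots inside the partition are spilled as sorted-reduced runs
#' (bounded by the Sort-Reduce memory budget), merged to a single run, and
#' roots whose total count across both samples is exactly 1 (*singletons*,
#' overwhelmingly sequencing errors) are dropped. Counters are 16-bit and
#' saturate at 65535; saturation is flagged in the header. The result is a
#' k-mer-indexed binary file (12 bytes per present k-mer) — the compact
#' format that the root-indexed 64-counter layout is folded from later.
#'
#' @inheritParams emit_updates
#' @param sr_cfg An [sr_config()].
#' @param path Output histogram file.
#' @param batch_reads Number of FASTQ records streamed per batch.
#' @return A `kmer_histogram` object (file-backed; see [read_histogram()]).
#' @export
build_histogram <- function(normal_fastq, tumoral_fastq, k = 28L,
                            partition = NULL, sr_cfg = sr_config(),
                            path = tempfile("histogram", fileext = ".kmh"),
                            batch_reads = 100000L) {
  k <- .check_k(k)
  if (is.null(partition)) partition <- .full_partition(k)
  lo <- partition$root_lo[1]; hi <- partition$root_hi[1]
  dir <- .sr_dir(sr_cfg)
  maxrec <- .sr_max_records(sr_cfg)
  runs <- character(0)
  for (s in 1:2) {
    fq <- if (s == 1) normal_fastq else tumoral_fastq
    con <- file(fq, "rt")
    batch <- 0L
    tryCatch({
      repeat {
        lines <- readLines(con, n = batch_reads * 4L)
        if (length(lines) == 0) break
        if (length(lines) %% 4 != 0)
          abort(sprintf("'%s': truncated FASTQ", fq))
        seqs <- toupper(lines[seq(2, length(lines), by = 4)])
        batch <- batch + 1L
        runs <- c(runs, cpp_count_spill(seqs, s == 2, k, lo, hi, maxrec, dir,
                                        sprintf("cnt_s%d_b%04d", s, batch)))
      }
    }, finally = close(con))
  }
  final <- merge_runs(runs, sr_cfg)
  info <- cpp_finalize_histogram(final$path, path, k, lo, hi)
  if (!sr_cfg$keep_intermediates) unlink(final$path)
  hist <- structure(
    list(path = path, k = k, partition = partition$partition[1],
         root_lo = lo, root_hi = hi, n_entries = info$n_entries,
         n_roots = info$n_roots, singleton_roots = info$singleton_roots,
         saturated = info$saturated),
    class = "kmer_histogram")
  writeLines(c(
    sprintf("k\t%d", k), sprintf("root_lo\t%s", format(lo, scientific = FALSE)),
    sprintf("root_hi\t%s", format(hi, scientific = FALSE)),
    sprintf("entries\t%.0f", info$n_entries),
    sprintf("roots\t%.0f", info$n_roots),
    sprintf("singleton_roots_removed\t%.0f", info$singleton_roots),
    sprintf("saturated\t%s", info$saturated)),
    paste0(path, ".summary.tsv"))
  hist
}

#' Re-open an existing histogram file
#' @param path A `.kmh` histogram file written by [build_histogram()].
#' @return A `kmer_histogram` object.
#' @export
open_histogram <- function(path) {
  info <- cpp_histogram_info(path)
  structure(list(path = path, k = info$k, partition = NA_integer_,
                 root_lo = info$root_lo, root_hi = info$root_hi,
                 n_entries = info$n_entries, n_roots = info$n_roots,
                 singleton_roots = info$singleton_roots,
                 saturated = info$saturated),
            class = "kmer_histogram")
}

#' Load histogram entries into a tibble
#'
#' @param hist A `kmer_histogram` (or histogram file path).
#' @return Tibble with one row per present k-mer: `kmer`, `root`,
#'   `root_code`, `variant` (0-31 slot within the root), `n`, `t`; sorted by
#'   root-major key.
#' @export
read_histogram <- function(hist) {
  path <- if (inherits(hist, "kmer_histogram")) hist$path else hist
  as_tibble(cpp_read_histogram(path))
}

#' Remove singleton roots from a sorted entry table
#'
#' Drops every entry of any root whose total count — summed over the root's
#' k-mer variants and both samples — equals 1. This is the same filtering
#' rule [build_histogram()] applies while streaming; exposed for entry
#' tables held in memory.
#'
#' @param entries Tibble with at least `root_code`, `n`, `t` (sorted so each
#'   root's entries are contiguous, as in [read_histogram()] output).
#' @return The filtered tibble.
#' @export
drop_singletons <- function(entries) {
  totals <- tapply(entries$n + entries$t, entries$root_code, sum)
  keep <- names(totals)[totals > 1]
  entries[as.character(entries$root_code) %in% keep, , drop = FALSE]
}

#' K-mer-indexed vs root-indexed histogram footprint
#'
#' The k-mer-indexed format spends 12 bytes per *present* k-mer (8-byte key
#' + two 2-byte counters); the root-indexed format spends 136 bytes per root
#' (8-byte key + 64 2-byte counters) regardless of how many of the root's 32
#' variants were observed. On data where most variants are absent the
#' reduction approaches `1 - 12/136` (about 91%).
#'
#' @param hist A `kmer_histogram`.
#' @return Tibble with `kmer_indexed_bytes`, `root_indexed_bytes`,
#'   `reduction_pct`.
#' @export
histogram_compaction <- function(hist) {
  kb <- 12 * hist$n_entries
  rb <- 136 * hist$n_roots
  tibble(kmer_indexed_bytes = kb, root_indexed_bytes = rb,
         reduction_pct = if (rb > 0) 100 * (1 - kb / rb) else NA_real_)
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf(
    "<kmer_histogram> k=%d roots [%s, %s): %s entries / %s roots (%s singleton roots removed)%s\n  %s\n",
    x$k, format(x$root_lo, scientific = FALSE),
    format(x$root_hi, scientific = FALSE),
    format(x$n_entries, big.mark = ","), format(x$n_roots, big.mark = ","),
    format(x$singleton_roots, big.mark = ","),
    if (isTRUE(x$saturated)) " [saturated]" else "", x$path))
  invisible(x)
}
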