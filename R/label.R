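#' Configure the interestingness rule
#'
#' A k-mer variant `v` of a root is *tumoral-interesting* when its tumoral
#' count is solid (`t_v >= min_tumor_support`), its normal count is at most
#' the contamination tolerance (`n_v <= max_normal_count`), and some *other*
#' variant `w != v` of the same root is well supported in the normal sample
#' (`n_w >= min_witness_count`). The witness is what makes the k-mer
#' *almost-matching*: the two variants share the middle `k - 2` bases, so
#' normal and tumoral reads can be aligned across samples at that locus. The
#' thresholds are deliberately configurable — they operationalize "seen
#' multiple times" (a k-mer seen once is most likely a read error) and
#' tolerance to normal contamination of the tumor sample.
#'
#' @param min_tumor_support Minimum tumoral count of the variant (>= 2).
#' @param max_normal_count Maximum normal count of the variant (>= 0).
#' @param min_witness_count Minimum normal count of the witness variant
#'   (>= 1).
#' @param symmetric Also detect normal-only k-mers with a tumoral witness
#'   (roles swapped); off by default.
#' @return A list of class `label_config`.
#' @export
label_config <- function(min_tumor_support = 4L, max_normal_count = 1L,
                         min_witness_count = 4L, symmetric = FALSE) {
  if (min_tumor_support < 2)
    abort("min_tumor_support must be >= 2 (a single observation is read-error noise)")
  if (max_normal_count < 0) abort("max_normal_count must be >= 0")
  if (min_witness_count < 1) abort("min_witness_count must be >= 1")
  structure(list(min_tumor_support = as.integer(min_tumor_support),
                 max_normal_count = as.integer(max_normal_count),
                 min_witness_count = as.integer(min_witness_count),
                 symmetric = isTRUE(symmetric)),
            class = "label_config")
}

# All-variant interestingness of whole root records: m x 32 logical matrix.
.classify_roots <- function(counters, cfg) {
  ncnt <- counters[, seq(1, 63, by = 2), drop = FALSE]
  tcnt <- counters[, seq(2, 64, by = 2), drop = FALSE]
  is_wit <- ncnt >= cfg$min_witness_count
  wit_other <- rowSums(is_wit) - is_wit >= 1
  res <- tcnt >= cfg$min_tumor_support & ncnt <= cfg$max_normal_count &
    wit_other
  if (cfg$symmetric) {
    is_wit_t <- tcnt >= cfg$min_witness_count
    wit_other_t <- rowSums(is_wit_t) - is_wit_t >= 1
    res <- res | (ncnt >= cfg$min_tumor_support &
                    tcnt <= cfg$max_normal_count & wit_other_t)
  }
  res
}

#' Classify k-mer variants of fetched root records
#'
#' @param counters A 64-counter root record (integer vector) or an
#'   `m x 64` matrix of records (slot `2v + 1` normal, `2v + 2` tumoral,
#'   1-based).
#' @param variant Integer vector of variant indices (0-31), one per record
#'   row (recycled for a single record).
#' @param cfg A [label_config()].
#' @return Logical vector: is each (record, variant) interesting?
#' @export
classify_kmer <- function(counters, variant, cfg = label_config()) {
  if (is.vector(counters)) counters <- matrix(as.integer(counters), nrow = 1)
  if (nrow(counters) == 1 && length(variant) > 1)
    counters <- counters[rep(1, length(variant)), , drop = FALSE]
  ncol_ok <- ncol(counters) == 64
  if (!ncol_ok) abort("root records have 64 counters")
  ncnt <- counters[, seq(1, 63, by = 2), drop = FALSE]
  tcnt <- counters[, seq(2, 64, by = 2), drop = FALSE]
  v1 <- variant + 1L
  n_v <- ncnt[cbind(seq_along(v1), v1)]
  t_v <- tcnt[cbind(seq_along(v1), v1)]
  witn <- rowSums(ncnt >= cfg$min_witness_count) - (n_v >= cfg$min_witness_count)
  res <- t_v >= cfg$min_tumor_support & n_v <= cfg$max_normal_count & witn >= 1
  if (cfg$symmetric) {
    witt <- rowSums(tcnt >= cfg$min_witness_count) -
      (t_v >= cfg$min_witness_count)
    res <- res | (n_v >= cfg$min_tumor_support &
                    t_v <= cfg$max_normal_count & witt >= 1)
  }
  unname(res)
}

#' Label interesting reads and k-mers for one partition
#'
#' The Label unit. Every in-partition k-mer of every read (both samples) is
#' resolved through cache -> band-pass -> Bloom -> store to its root record,
#' and [classify_kmer()] is applied per variant. The per-partition database
#' then records:
#'
#' * the **k-mer table** — one row per interesting k-mer with its root,
#'   counters and the ids of the reads containing it, and
#' * the **read table** — every read (either sample) containing at least one
#'   k-mer of a root that hosts an interesting variant, with all its hits on
#'   such roots. Admitting by root rather than by the interesting variant
#'   itself is what brings the normal-sample witness reads into the
#'   database, so that read groups span both samples and break-points can be
#'   reconstructed.
#'
#' @param normal_fastq,tumoral_fastq FASTQ(.gz) paths.
#' @param store A `root_store` built for the partition.
#' @param cache Optional `root_cache` (`NULL` disables caching; output is
#'   identical either way).
#' @param cfg A [label_config()].
#' @param k K-mer length (defaults to the store's).
#' @param partition One row of [partition_bounds()] or `NULL` for the whole
#'   root space.
#' @return An `interesting_db`: list with tibbles `reads` (`read_id`,
#'   `sample`, `sequence`, `hits` as `pos:kmer` semicolon list) and `kmers`
#'   (`kmer`, `root`, `n`, `t`, `read_ids`), plus `k`. Instrumentation
#'   (cache hits, chunk reads, look-ups) in `attr(db, "stats")`.
#' @export
label_reads <- function(normal_fastq, tumoral_fastq, store, cache = NULL,
                        cfg = label_config(), k = store$k, partition = NULL) {
  k <- .check_k(k)
  if (is.null(partition)) partition <- .full_partition(k)
  lo <- partition$root_lo[1]; hi <- partition$root_hi[1]

  rn <- read_fastq(normal_fastq)
  rt <- read_fastq(tumoral_fastq)
  reads <- dplyr::bind_rows(
    tibble(read_id = rn$id, sample = "N", sequence = rn$seq),
    tibble(read_id = rt$id, sample = "T", sequence = rt$seq))
  hits_raw <- cpp_read_kmer_hits(reads$sequence, k, lo, hi)
  hits <- tibble(read = hits_raw$read, pos = hits_raw$pos,
                 root = hits_raw$root, vidx = hits_raw$vidx)

  uroots <- sort(unique(hits$root))
  res <- .resolve_roots(uroots, store, cache)
  # variant-level interestingness, computed once per unique root (32 slots)
  int_flag <- logical(nrow(hits))
  keep <- logical(nrow(hits))
  if (nrow(hits) > 0 && length(uroots) > 0) {
    int_mat <- .classify_roots(res$counters, cfg) & res$found
    int_any <- rowSums(int_mat) > 0
    ridx <- match(hits$root, uroots)
    int_flag <- int_mat[cbind(ridx, hits$vidx + 1L)]
    keep <- int_any[ridx]
  }
  kept <- hits[keep, , drop = FALSE]
  kept$interesting <- int_flag[keep]
  if (nrow(kept) > 0) {
    kridx <- match(kept$root, uroots)
    kept$nv <- res$counters[cbind(kridx, 2L * kept$vidx + 1L)]
    kept$tv <- res$counters[cbind(kridx, 2L * kept$vidx + 2L)]
  } else {
    kept$nv <- kept$tv <- integer(0)
  }
  kept$read_id <- reads$read_id[kept$read]
  kept$sample <- reads$sample[kept$read]
  kept$kmer <- substr(reads$sequence[kept$read], kept$pos + 1L, kept$pos + k)

  empty_reads <- tibble(read_id = character(0), sample = character(0),
                        sequence = character(0), hits = character(0))
  empty_kmers <- tibble(kmer = character(0), root = character(0),
                        n = integer(0), t = integer(0),
                        read_ids = character(0))
  if (nrow(kept) == 0) {
    return(structure(list(reads = empty_reads, kmers = empty_kmers, k = k),
                     class = "interesting_db",
                     stats = tibble(lookups = length(uroots),
                                    cache_hits = res$cache_hits,
                                    chunk_reads = res$chunk_reads,
                                    reads_in = nrow(reads),
                                    kmer_hits = nrow(hits))))
  }
  read_tbl <- kept |>
    dplyr::arrange(.data$read_id, .data$pos) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      sample = .data$sample[1],
      sequence = reads$sequence[.data$read[1]],
      hits = paste(sprintf("%d:%s", .data$pos, .data$kmer), collapse = ";"),
      .groups = "drop") |>
    dplyr::arrange(.data$read_id)

  kmer_tbl <- kept[kept$interesting, , drop = FALSE] |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(
      root = cpp_decode_codes(.data$root[1], k - 2L),
      n = .data$nv[1], t = .data$tv[1],
      read_ids = paste(sort(unique(.data$read_id)), collapse = ","),
      .groups = "drop") |>
    dplyr::arrange(.data$kmer)

  structure(list(reads = read_tbl, kmers = kmer_tbl, k = k),
            class = "interesting_db",
            stats = tibble(lookups = length(uroots),
                           cache_hits = res$cache_hits,
                           chunk_reads = res$chunk_reads,
                           reads_in = nrow(reads), kmer_hits = nrow(hits)))
}

#' Merge per-partition interesting databases
#'
#' K-mer tables are concatenated (keys are disjoint across root
#' partitions); read entries sharing a `read_id` are unioned — hit lists
#' concatenated (deduplicated, sorted by position) — after checking that
#' sequence and sample agree. The result is invariant to partition order,
#' and merging the single-partition database is the identity.
#'
#' @param dbs List of `interesting_db` objects.
#' @return The merged `interesting_db`.
#' @export
merge_dbs <- function(dbs) {
  if (length(dbs) == 0) abort("nothing to merge")
  k <- unique(vapply(dbs, `[[`, integer(1), "k"))
  if (length(k) != 1) abort("databases use different k")
  kmers <- dplyr::bind_rows(lapply(dbs, `[[`, "kmers"))
  if (anyDuplicated(kmers$kmer))
    abort("k-mer tables overlap; partitions were not disjoint")
  kmers <- dplyr::arrange(kmers, .data$kmer)
  reads <- dplyr::bind_rows(lapply(dbs, `[[`, "reads"))
  merged <- reads |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      sample = {
        if (length(unique(.data$sample)) != 1)
          abort(sprintf("read '%s' labeled with conflicting samples",
                        dplyr::cur_group()$read_id))
        .data$sample[1]
      },
      sequence = {
        if (length(unique(.data$sequence)) != 1)
          abort(sprintf("read '%s' recorded with conflicting sequences",
                        dplyr::cur_group()$read_id))
        .data$sequence[1]
      },
      hits = {
        h <- unique(unlist(strsplit(.data$hits, ";", fixed = TRUE)))
        pos <- as.integer(sub(":.*", "", h))
        paste(h[order(pos)], collapse = ";")
      },
      .groups = "drop") |>
    dplyr::arrange(.data$read_id)
  structure(list(reads = merged, kmers = kmers, k = k),
            class = "interesting_db")
}

#' Write / read an interesting database as sorted TSVs
#'
#' Two gzip tab-separated tables — `<prefix>.reads.tsv.gz` (read_id, sample,
#' sequence, hits) and `<prefix>.kmers.tsv.gz` (kmer, root, n, t, read_ids)
#' — each deterministically sorted by key.
#'
#' @param db An `interesting_db`.
#' @param prefix Output path prefix.
#' @return `write_db()`: the two paths, invisibly. `read_db()`: the
#'   database.
#' @export
write_db <- function(db, prefix) {
  rp <- paste0(prefix, ".reads.tsv.gz")
  kp <- paste0(prefix, ".kmers.tsv.gz")
  readr::write_tsv(db$reads, rp)
  readr::write_tsv(db$kmers, kp)
  invisible(c(reads = rp, kmers = kp))
}

#' @rdname write_db
#' @param k K-mer length recorded in the reconstructed database.
#' @export
read_db <- function(prefix, k) {
  spec_r <- readr::cols(read_id = "c", sample = "c", sequence = "c",
                        hits = "c")
  spec_k <- readr::cols(kmer = "c", root = "c", n = "i", t = "i",
                        read_ids = "c")
  structure(list(
    reads = readr::read_tsv(paste0(prefix, ".reads.tsv.gz"),
                            col_types = spec_r, progress = FALSE),
    kmers = readr::read_tsv(paste0(prefix, ".kmers.tsv.gz"),
                            col_types = spec_k, progress = FALSE),
    k = as.integer(k)), class = "interesting_db")
}

#' @export
print.interesting_db <- function(x, ...) {
  cat(sprintf("<interesting_db> k=%d: %d reads, %d interesting k-mers\n",
              x$k, nrow(x$reads), nrow(x$kmers)))
  invisible(x)
}
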