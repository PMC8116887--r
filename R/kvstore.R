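#' Configure the chunked root key-value store
#'
#' @param chunk_bytes Data chunk size; one flash page (4096 bytes) by
#'   default, so a look-up costs exactly one page read. Must hold at least
#'   one 136-byte root record; 4096 bytes hold 30.
#' @param index_fanout Fan-out `F` of the multi-level implicit index: each
#'   index level keeps every `F`-th key of the level below, so a look-up
#'   descends reading at most `F` keys per level and positions double as
#'   child pointers.
#' @param bloom_bits_per_key,bloom_hashes Bloom filter sizing; the defaults
#'   (10 bits/key, 7 hashes) give a theoretical false-positive rate of about
#'   0.0082. The filter never has false negatives.
#' @param bloom_seeds Two integer seeds of the double-hashing mixer,
#'   persisted in the store header so the bitmap is reproducible.
#' @return A list of class `store_config`.
#' @export
store_config <- function(chunk_bytes = 4096L, index_fanout = 16L,
                         bloom_bits_per_key = 10L, bloom_hashes = 7L,
                         bloom_seeds = c(305419896, 2271560481)) {
  if (chunk_bytes < 136) abort("chunk_bytes must hold one 136-byte record")
  if (index_fanout < 2) abort("index_fanout must be >= 2")
  if (length(bloom_seeds) != 2) abort("bloom_seeds must be two integers")
  structure(list(chunk_bytes = as.integer(chunk_bytes),
                 index_fanout = as.integer(index_fanout),
                 bloom_bits_per_key = as.integer(bloom_bits_per_key),
                 bloom_hashes = as.integer(bloom_hashes),
                 bloom_seeds = as.numeric(bloom_seeds)),
            class = "store_config")
}

#' Build the immutable chunked key-value store from a histogram
#'
#' Folds the consecutive k-mer entries of each root into one 136-byte root
#' record (8-byte root code + 64 16-bit counters: slot `2v` normal, `2v + 1`
#' tumoral for variant `v`), packs records 30 per 4 KB chunk in root order,
#' builds the Bloom filter and band-pass bounds during the same pass, and
#' writes `header | bloom | data` as a single binary file. The store is
#' immutable thereafter; the in-memory first-key array and multi-level index
#' are rebuilt on open.
#'
#' @param hist A `kmer_histogram` from [build_histogram()].
#' @param cfg A [store_config()].
#' @param path Output store file.
#' @return A `root_store` handle (see [store_lookup()]).
#' @export
build_store <- function(hist, cfg = store_config(),
                        path = tempfile("store", fileext = ".kvr")) {
  hp <- if (inherits(hist, "kmer_histogram")) hist$path else hist
  cpp_build_store(hp, path, cfg$chunk_bytes, cfg$bloom_bits_per_key,
                  cfg$bloom_hashes, cfg$bloom_seeds[1], cfg$bloom_seeds[2])
  open_store(path, index_fanout = cfg$index_fanout)
}

#' Open an existing store file
#'
#' Reads the header and Bloom bitmap, scans the first key of every data
#' chunk, and rebuilds the multi-level implicit index in memory.
#'
#' @param path A `.kvr` store file.
#' @param index_fanout Index fan-out used for the rebuilt index.
#' @return A `root_store` handle.
#' @export
open_store <- function(path, index_fanout = 16L) {
  h <- cpp_open_store(path)
  structure(
    list(path = path, k = h$k, chunk_bytes = h$chunk_bytes,
         n_records = h$n_records, n_chunks = h$n_data_chunks,
         min_root = h$min_root, max_root = h$max_root,
         m_bits = h$m_bits, bits_per_key = h$bits_per_key,
         n_hashes = h$n_hashes, seeds = c(h$seed1, h$seed2),
         bloom = h$bloom, first_keys = h$first_keys,
         index = build_index(h$first_keys, index_fanout)),
    class = "root_store")
}

#' Build a multi-level implicit index over sorted first keys
#'
#' Level 1 is the first-key array itself (`first_keys[i]` = first root code
#' stored in chunk `i`); each level above keeps every `F`-th key of the
#' level below, so level `j + 1` has `ceiling(|level j| / F)` keys and the
#' `i`-th key of a level covers children `F*i .. F*(i+1) - 1` below — array
#' positions are the pointers. Construction stops at a single-key top.
#'
#' @param first_keys Sorted numeric vector of chunk first keys.
#' @param fanout Fan-out `F` (>= 2).
#' @return A `multilevel_index` (list of key arrays, bottom first).
#' @export
build_index <- function(first_keys, fanout = 16L) {
  fanout <- as.integer(fanout)
  if (fanout < 2) abort("fanout must be >= 2")
  levels <- list(as.numeric(first_keys))
  while (length(levels[[length(levels)]]) > 1) {
    below <- levels[[length(levels)]]
    levels[[length(levels) + 1]] <- below[seq(1, length(below), by = fanout)]
  }
  structure(list(levels = levels, fanout = fanout), class = "multilevel_index")
}

#' Locate the data chunk that may hold each root
#'
#' Descends the multi-level index top-down, scanning at most `F` keys per
#' level: the result is the unique chunk `i` with
#' `first_keys[i] <= root < first_keys[i + 1]` (chunk 0 for roots below the
#' first key, the last chunk beyond the last) — identical to a flat binary
#' search over the first-key array.
#'
#' @param index A `multilevel_index`.
#' @param roots Numeric vector of root codes.
#' @return Integer vector of 0-based chunk ids (`NA` for an empty index).
#' @export
locate_chunk <- function(index, roots) {
  levels <- index$levels
  fo <- index$fanout
  nfk <- length(levels[[1]])
  if (nfk == 0) return(rep(NA_integer_, length(roots)))
  if (length(roots) == 0) return(integer(0))
  idx <- rep(0, length(roots))
  for (lv in rev(seq_along(levels))) {
    arr <- levels[[lv]]
    beg <- idx * fo
    cand <- outer(0:(fo - 1), beg, "+")          # 0-based candidate positions
    vals <- matrix(Inf, nrow = fo, ncol = length(roots))
    ok <- cand < length(arr)
    vals[ok] <- arr[cand[ok] + 1]
    cnt <- colSums(vals <= rep(roots, each = fo))
    idx <- beg + pmax(cnt - 1, 0)
  }
  as.integer(idx)
}

#' Look roots up in the store
#'
#' The look-up pipeline per probe: band-pass filter (reject roots outside
#' `[min_root, max_root]` with zero storage reads), Bloom filter (reject
#' most absent roots with zero storage reads, never a present one), index
#' descent to a chunk, then exactly **one** chunk read and a binary search
#' among its <= 30 records. A Bloom false positive resolves to absent after
#' its single chunk read; no probe ever costs more than one data-chunk read.
#'
#' @param store A `root_store`.
#' @param roots Numeric vector of root codes (see [encode_kmer()] /
#'   [canonical_root()]).
#' @return A `root_lookup` list: `root`, `found` (logical), `counters`
#'   (length(roots) x 64 integer matrix, zero rows where absent) and the
#'   instrumentation counters `chunk_reads`, `bandpass_rejects`,
#'   `bloom_rejects`.
#' @export
store_lookup <- function(store, roots) {
  roots <- as.numeric(roots)
  m <- length(roots)
  found <- logical(m)
  counters <- matrix(0L, nrow = m, ncol = 64)
  inband <- store$n_records > 0 & roots >= store$min_root &
    roots <= store$max_root
  maybe <- inband
  if (any(inband)) {
    maybe[inband] <- cpp_bloom_maybe(store$bloom, roots[inband], store$m_bits,
                                     store$n_hashes, store$seeds[1],
                                     store$seeds[2])
  }
  reads <- 0
  if (any(maybe)) {
    ids <- cpp_locate_chunks(roots[maybe], store$first_keys,
                             store$index$fanout)
    res <- cpp_read_store_records(store$path, ids, roots[maybe])
    found[maybe] <- res$found
    counters[maybe, ] <- res$counters
    reads <- res$chunk_reads
  }
  structure(list(root = roots, found = found, counters = counters,
                 chunk_reads = reads,
                 bandpass_rejects = sum(!inband),
                 bloom_rejects = sum(inband & !maybe)),
            class = "root_lookup")
}

#' Batched look-ups with tags
#'
#' Semantically identical to issuing [store_lookup()] per item: the multiset
#' of `(tag, result)` pairs matches sequential look-ups exactly. The batch
#' is processed in sub-batches of `queue_depth`; concurrency degree and
#' queue depth are configuration for an asynchronous backend, not semantics,
#' and results should not be relied on to arrive in submission order.
#'
#' @inheritParams store_lookup
#' @param tags Vector of caller tags, one per root.
#' @param queue_depth,threads Batch shaping knobs (no semantic effect).
#' @return A `root_lookup` with an extra `tag` field.
#' @export
lookup_batch <- function(store, roots, tags = seq_along(roots),
                         queue_depth = 64L, threads = 1L) {
  if (length(tags) != length(roots)) abort("one tag per root")
  if (length(roots) == 0) {
    out <- store_lookup(store, numeric(0))
    out$tag <- tags
    return(out)
  }
  grp <- ceiling(seq_along(roots) / max(1L, as.integer(queue_depth)))
  parts <- lapply(split(seq_along(roots), grp), function(ix)
    c(store_lookup(store, roots[ix]), list(tag = tags[ix])))
  structure(list(
    root = unname(unlist(lapply(parts, `[[`, "root"))),
    found = unname(unlist(lapply(parts, `[[`, "found"))),
    counters = do.call(rbind, lapply(parts, `[[`, "counters")),
    chunk_reads = sum(vapply(parts, `[[`, numeric(1), "chunk_reads")),
    bandpass_rejects = sum(vapply(parts, `[[`, numeric(1), "bandpass_rejects")),
    bloom_rejects = sum(vapply(parts, `[[`, numeric(1), "bloom_rejects")),
    tag = unname(unlist(lapply(parts, `[[`, "tag")))), class = "root_lookup")
}

#' All root codes present in a store (in key order)
#' @param store A `root_store`.
#' @return Numeric vector of root codes.
#' @export
store_roots <- function(store) cpp_store_all_roots(store$path)

#' Random positive look-up benchmark
#'
#' Draws `n_lookups` probes uniformly (with replacement, seeded) from the
#' roots present in the store and measures the look-up path. Every probe
#' must return a present record, and the one-read contract bounds chunk
#' reads by `n_lookups`.
#'
#' @param store A `root_store`.
#' @param n_lookups Number of probes.
#' @param threads,queue_depth Batch shaping (see [lookup_batch()]).
#' @param seed Seed fixing the probe sequence.
#' @return One-row tibble: `lookups`, `present`, `chunk_reads`,
#'   `elapsed_sec`, `lookups_per_sec`.
#' @export
bench_random_lookups <- function(store, n_lookups = 10000L, threads = 1L,
                                 queue_depth = 64L, seed = 1L) {
  all_roots <- store_roots(store)
  if (length(all_roots) == 0) abort("store is empty")
  probes <- withr::with_seed(seed,
    all_roots[sample.int(length(all_roots), n_lookups, replace = TRUE)])
  t0 <- proc.time()[["elapsed"]]
  res <- lookup_batch(store, probes, queue_depth = queue_depth,
                      threads = threads)
  dt <- proc.time()[["elapsed"]] - t0
  tibble(lookups = n_lookups, present = sum(res$found),
         chunk_reads = res$chunk_reads, elapsed_sec = dt,
         lookups_per_sec = if (dt > 0) n_lookups / dt else NA_real_)
}

#' Analytic payload sizing of a key-value store
#'
#' Pure arithmetic — nothing is materialized: `n_items * (key_bytes +
#' value_bytes)` reported in bytes and binary gigabytes. With the root
#' record widths (8-byte key, 128-byte value), a billion items weigh about
#' 127 GiB.
#'
#' @param n_items Number of key-value items.
#' @param key_bytes,value_bytes Per-item widths.
#' @return Tibble with `n_items`, `bytes`, `gib`.
#' @export
store_sizing <- function(n_items, key_bytes = 8, value_bytes = 128) {
  bytes <- n_items * (key_bytes + value_bytes)
  tibble(n_items = n_items, bytes = bytes, gib = bytes / 2^30)
}

#' @export
print.root_store <- function(x, ...) {
  cat(sprintf(
    "<root_store> k=%d: %s records in %s chunks of %d B (%d records/chunk)\n  bloom %.0f bits (%d/key, %d hashes), roots [%s, %s]\n  index levels: %s\n  %s\n",
    x$k, format(x$n_records, big.mark = ","),
    format(x$n_chunks, big.mark = ","), x$chunk_bytes,
    x$chunk_bytes %/% 136L, x$m_bits, x$bits_per_key, x$n_hashes,
    format(x$min_root, scientific = FALSE),
    format(x$max_root, scientific = FALSE),
    paste(vapply(x$index$levels, length, integer(1)), collapse = " > "),
    x$path))
  invisible(x)
}

#' @rdname build_store
#' @param x A `root_store`.
#' @param ... Unused.
#' @export
glance.root_store <- function(x, ...) {
  n <- x$n_records
  m <- x$m_bits
  h <- x$n_hashes
  tibble(k = x$k, n_records = n, n_chunks = x$n_chunks,
         chunk_bytes = x$chunk_bytes,
         records_per_chunk = x$chunk_bytes %/% 136L,
         record_bytes = 136L, min_root = x$min_root, max_root = x$max_root,
         bloom_bits = m, bloom_hashes = h,
         bloom_fpr_expected = if (m > 0) (1 - exp(-h * n / m))^h else NA_real_,
         index_levels = length(x$index$levels))
}
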