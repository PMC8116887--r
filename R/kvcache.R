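#' Build the static frequency-predicted root cache
#'
#' The histogram's counter values predict future look-ups: a root whose
#' k-mers were counted often will be probed often during labeling. The cache
#' therefore ranks roots by total count (both samples, all variants)
#' descending — ties broken by ascending root code — and greedily admits
#' whole roots while the accounted size stays within the budget; a root that
#' does not fit is skipped and ranking continues. Entries are kept in the
#' compact k-mer-indexed format (12 bytes per present k-mer: 8-byte key +
#' two 2-byte counters), which is what the accounting charges; container
#' overhead is implementation detail and not counted.
#'
#' Whole-root admission is deliberate: the Label unit always needs all the
#' counters of a root, so a partially cached root would still cost a storage
#' read and the hit would buy nothing.
#'
#' @param hist A `kmer_histogram`.
#' @param budget_bytes Memory allowance for cached entries (>= 0).
#' @return A `root_cache`.
#' @export
build_cache <- function(hist, budget_bytes) {
  if (budget_bytes < 0) abort("budget_bytes must be >= 0")
  ent <- read_histogram(hist)
  empty <- structure(list(roots = numeric(0), offset = integer(0),
                          len = integer(0), variant = integer(0),
                          n = integer(0), t = integer(0),
                          bytes = 0, budget_bytes = as.numeric(budget_bytes)),
                     class = "root_cache")
  if (nrow(ent) == 0 || budget_bytes < 12) return(empty)
  per <- ent |>
    dplyr::group_by(.data$root_code) |>
    dplyr::summarise(total = sum(.data$n + .data$t),
                     nk = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$root_code)
  bytes <- 12 * per$nk
  admit <- logical(nrow(per))
  used <- 0
  for (i in seq_len(nrow(per))) {
    if (used + bytes[i] <= budget_bytes) {
      admit[i] <- TRUE
      used <- used + bytes[i]
    }
  }
  keep <- sort(per$root_code[admit])
  if (length(keep) == 0) return(empty)
  sub <- ent[ent$root_code %in% keep, , drop = FALSE]
  sub <- sub[order(sub$root_code, sub$variant), , drop = FALSE]
  len <- as.integer(table(factor(sub$root_code, levels = keep)))
  structure(list(roots = keep,
                 offset = c(0L, cumsum(len)[-length(len)]),
                 len = len, variant = sub$variant, n = sub$n, t = sub$t,
                 bytes = used, budget_bytes = as.numeric(budget_bytes)),
            class = "root_cache")
}

#' Look roots up in the cache
#'
#' On a hit the full 64-counter root record is reconstructed from the
#' compact entries (zeros for absent variants) — identical to the record the
#' store would return. A miss means the caller falls through to
#' [store_lookup()]; caching never changes results.
#'
#' @param cache A `root_cache`.
#' @param roots Numeric vector of root codes.
#' @return List with `root`, `found` (hit/miss) and `counters`
#'   (length(roots) x 64, zeros on miss).
#' @export
cache_lookup <- function(cache, roots) {
  roots <- as.numeric(roots)
  m <- length(roots)
  counters <- matrix(0L, nrow = m, ncol = 64)
  pos <- match(roots, cache$roots)
  found <- !is.na(pos)
  hit <- which(found)
  if (length(hit) > 0) {
    reps <- cache$len[pos[hit]]
    row <- rep(hit, reps)
    flat <- sequence(reps) + rep(cache$offset[pos[hit]], reps)
    v <- cache$variant[flat]
    counters[cbind(row, 2L * v + 1L)] <- cache$n[flat]
    counters[cbind(row, 2L * v + 2L)] <- cache$t[flat]
  }
  list(root = roots, found = found, counters = counters)
}

#' Hit statistics of a cache over a probe stream
#'
#' @param cache A `root_cache`.
#' @param probes Numeric vector of probed root codes.
#' @return One-row tibble: `hits`, `misses`, `hit_fraction` (0 for an empty
#'   stream).
#' @export
hit_stats <- function(cache, probes) {
  h <- sum(probes %in% cache$roots)
  m <- length(probes) - h
  tibble(hits = h, misses = m,
         hit_fraction = if (length(probes) > 0) h / length(probes) else 0)
}

# Cache-then-store resolution used by the Label unit. Returns the merged
# counters plus instrumentation; results are identical to store-only.
.resolve_roots <- function(roots, store, cache = NULL) {
  m <- length(roots)
  counters <- matrix(0L, nrow = m, ncol = 64)
  found <- logical(m)
  hits <- 0
  miss_ix <- seq_len(m)
  if (!is.null(cache) && length(cache$roots) > 0) {
    cl <- cache_lookup(cache, roots)
    found <- cl$found
    counters[found, ] <- cl$counters[found, , drop = FALSE]
    hits <- sum(found)
    miss_ix <- which(!found)
  }
  reads <- 0
  if (length(miss_ix) > 0) {
    sl <- store_lookup(store, roots[miss_ix])
    found[miss_ix] <- sl$found
    counters[miss_ix, ] <- sl$counters
    reads <- sl$chunk_reads
  }
  list(root = roots, found = found, counters = counters,
       cache_hits = hits, chunk_reads = reads)
}

#' Hit fraction as a function of cache budget
#'
#' Builds one cache per budget from the same histogram and replays the probe
#' stream through each; hit fraction is non-decreasing in budget.
#'
#' @param hist A `kmer_histogram`.
#' @param probes Numeric vector of probed root codes.
#' @param budgets Numeric vector of budgets (bytes).
#' @return Tibble of class `cache_hit_curve`: `budget_bytes`, `cached_bytes`,
#'   `cached_roots`, `hit_fraction`.
#' @export
cache_hit_curve <- function(hist, probes, budgets) {
  rows <- lapply(budgets, function(b) {
    cc <- build_cache(hist, b)
    dplyr::mutate(hit_stats(cc, probes), budget_bytes = b,
                  cached_bytes = cc$bytes, cached_roots = length(cc$roots))
  })
  out <- dplyr::bind_rows(rows)[, c("budget_bytes", "cached_bytes",
                                    "cached_roots", "hit_fraction")]
  class(out) <- c("cache_hit_curve", class(out))
  out
}

#' @export
print.root_cache <- function(x, ...) {
  cat(sprintf("<root_cache> %s roots, %s / %s bytes used\n",
              format(length(x$roots), big.mark = ","),
              format(x$bytes, big.mark = ","),
              format(x$budget_bytes, big.mark = ",")))
  invisible(x)
}

#' @rdname cache_hit_curve
#' @param object A `cache_hit_curve`.
#' @param ... Unused.
#' @export
autoplot.cache_hit_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$budget_bytes,
                                       y = .data$hit_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(b) sprintf("%.0f KiB", b / 1024)) +
    ggplot2::labs(x = "cache budget", y = "hit fraction",
                  title = "Frequency-predicted cache effectiveness") +
    ggplot2::ylim(0, 1)
}
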