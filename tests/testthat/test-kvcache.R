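test_that("admission is greedy by total count with the stated tie-breaks", {
  # roots built from explicit k-mers: A (total 10, two k-mers = 24 B),
  # B (3, one = 12 B), C (2, one = 12 B); budget 36 B -> {A, B}
  km_a <- c("AACGTACGTT", "CACGTACGTT")   # same stem, two variants
  km_b <- "AATTGCATCC"
  km_c <- "AAGGCCTTAA"
  hist <- histogram_from_entries(
    c(km_a, km_b, km_c), n = c(5L, 5L, 3L, 2L), t = c(0L, 0L, 0L, 0L),
    k = 10)
  roots <- encode_kmer(canonical_root(stem_of(c(km_a[1], km_b, km_c))))
  cache <- build_cache(hist, 36)
  expect_setequal(cache$roots, roots[1:2])
  expect_equal(cache$bytes, 36)
  expect_length(build_cache(hist, 0)$roots, 0)
  # tie on totals -> lower root code admitted first
  km_tie <- c("AATTGCATCC", "AAGGCCTTAA")
  h2 <- histogram_from_entries(km_tie, n = c(2L, 2L), t = c(0L, 0L), k = 10)
  r2 <- encode_kmer(canonical_root(stem_of(km_tie)))
  c2 <- build_cache(h2, 12)
  expect_equal(c2$roots, min(r2))
  # a root too big for the remaining budget is skipped, ranking continues
  c3 <- build_cache(hist, 12)       # A (24 B) cannot fit, B (12 B) can
  expect_equal(c3$roots, roots[2])
})

test_that("cache hits reconstruct the exact store record", {
  withr::with_seed(61, kms <- unique(replicate(600, random_dna(10))))
  hist <- histogram_from_entries(
    kms, n = withr::with_seed(62, sample(0:30, length(kms), TRUE)),
    t = withr::with_seed(63, sample(2:30, length(kms), TRUE)), k = 10)
  store <- build_store(hist)
  cache <- build_cache(hist, 3000)
  expect_gt(length(cache$roots), 0)
  hit <- cache_lookup(cache, cache$roots)
  expect_true(all(hit$found))
  via_store <- store_lookup(store, cache$roots)
  expect_equal(hit$counters, via_store$counters)
  # misses fall through
  others <- setdiff(store_roots(store), cache$roots)
  expect_false(any(cache_lookup(cache, others)$found))
  # per-variant placement: (v, n, t) at counters[2v], counters[2v+1]
  ent <- read_histogram(hist)
  one <- ent[ent$root_code == cache$roots[1], ]
  rec <- cache_lookup(cache, cache$roots[1])$counters[1, ]
  expect_equal(rec[2 * one$variant + 1], one$n)
  expect_equal(rec[2 * one$variant + 2], one$t)
})

test_that("hit statistics and the budget curve behave monotonically", {
  withr::with_seed(64, kms <- unique(replicate(500, random_dna(10))))
  hist <- histogram_from_entries(
    kms, n = withr::with_seed(65, as.integer(rpois(length(kms), 6)) + 1L),
    t = rep(1L, length(kms)), k = 10)
  ent <- read_histogram(hist)
  roots <- unique(ent$root_code)
  cache <- build_cache(hist, 2000)
  expect_equal(hit_stats(cache, cache$roots)$hit_fraction, 1)
  expect_equal(hit_stats(build_cache(hist, 0), roots)$hit_fraction, 0)
  expect_equal(hit_stats(cache, numeric(0))$hit_fraction, 0)
  probes <- withr::with_seed(66, sample(roots, 5000, replace = TRUE))
  curve <- cache_hit_curve(hist, probes, budgets = c(0, 500, 2000, 8000, 1e6))
  expect_false(is.unsorted(curve$hit_fraction))
  expect_equal(curve$hit_fraction[1], 0)
  expect_equal(dplyr::last(curve$hit_fraction), 1)
})

test_that("frequency-ranked caching beats its size on skewed probes", {
  # Zipf(1) look-ups over the root set: counter totals mirror probe
  # frequency, so a cache holding a fraction f of roots serves >> f of
  # probes.
  withr::with_seed(67, kms <- unique(replicate(800, random_dna(12))))
  kms <- kms[!duplicated(canonical_root(stem_of(kms)))]
  nr <- length(kms)
  zipf_w <- 1 / seq_len(nr)
  probes_per_root <- withr::with_seed(68,
    as.integer(stats::rmultinom(1, 20000, zipf_w)))
  hist <- histogram_from_entries(kms, n = pmax(probes_per_root, 2L),
                                 t = rep(0L, nr), k = 12)
  ent <- read_histogram(hist)
  root_of_km <- encode_kmer(canonical_root(stem_of(kms)))
  probes <- withr::with_seed(69,
    sample(rep(root_of_km, probes_per_root)))
  budget <- 12 * floor(nr / 10)            # room for ~10% of roots
  cache <- build_cache(hist, budget)
  frac_roots <- length(cache$roots) / nr
  hf <- hit_stats(cache, probes)$hit_fraction
  expect_gt(hf, frac_roots)
  expect_gt(hf, 0.4)                       # skew advantage is large
})

test_that("per-partition caches serve at least the single-cache fraction", {
  withr::with_seed(70, kms <- unique(replicate(900, random_dna(12))))
  kms <- kms[!duplicated(canonical_root(stem_of(kms)))]
  nr <- length(kms)
  counts <- withr::with_seed(71,
    as.integer(stats::rmultinom(1, 30000, 1 / seq_len(nr))))
  hist <- histogram_from_entries(kms, n = pmax(counts, 2L),
                                 t = rep(0L, nr), k = 12)
  root_of_km <- encode_kmer(canonical_root(stem_of(kms)))
  probes <- withr::with_seed(72, sample(rep(root_of_km, counts)))
  budget <- 12 * floor(nr / 12)
  single <- hit_stats(build_cache(hist, budget), probes)$hit_fraction
  parts <- partition_bounds(12, 4)
  ent <- read_histogram(hist)
  agg_hits <- 0
  for (i in 1:4) {
    in_part <- ent$root_code >= parts$root_lo[i] &
      ent$root_code < parts$root_hi[i]
    sub <- ent[in_part, ]
    if (nrow(sub) == 0) next
    hsub <- histogram_from_entries(sub$kmer, sub$n, sub$t, k = 12)
    csub <- build_cache(hsub, budget)
    psub <- probes[probes >= parts$root_lo[i] & probes < parts$root_hi[i]]
    agg_hits <- agg_hits + hit_stats(csub, psub)$hits
  }
  expect_gte(agg_hits / length(probes), single)
})

test_that("caching is transparent to the resolution pipeline", {
  withr::with_seed(73, kms <- unique(replicate(400, random_dna(10))))
  hist <- histogram_from_entries(
    kms, n = withr::with_seed(74, sample(1:20, length(kms), TRUE)),
    t = withr::with_seed(75, sample(1:20, length(kms), TRUE)), k = 10)
  store <- build_store(hist)
  roots <- store_roots(store)
  probes <- c(roots, roots[1:10], -5, 4^8 - 1)
  plain <- kmerscout:::.resolve_roots(probes, store, NULL)
  cached <- kmerscout:::.resolve_roots(probes, store, build_cache(hist, 5000))
  expect_equal(cached$found, plain$found)
  expect_equal(cached$counters, plain$counters)
  expect_gt(cached$cache_hits, 0)
  expect_lt(cached$chunk_reads, plain$chunk_reads)
})
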