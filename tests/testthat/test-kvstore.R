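# A store over a few hundred random roots, shared across the blocks below.
make_store_fixture <- function(n_kmers = 900, k = 10, seed = 41,
                               cfg = store_config()) {
  withr::with_seed(seed, kms <- unique(replicate(n_kmers, random_dna(k))))
  hist <- histogram_from_entries(
    kms, n = withr::with_seed(seed + 1, sample(0:40, length(kms), TRUE)),
    t = withr::with_seed(seed + 2, sample(2:40, length(kms), TRUE)), k = k)
  list(hist = hist, store = build_store(hist, cfg),
       entries = read_histogram(hist))
}

# In-memory oracle: root code -> 64-slot record assembled from the entries.
oracle_records <- function(entries) {
  roots <- sort(unique(entries$root_code))
  rec <- matrix(0L, nrow = length(roots), ncol = 64)
  i <- match(entries$root_code, roots)
  rec[cbind(i, 2L * entries$variant + 1L)] <- entries$n
  rec[cbind(i, 2L * entries$variant + 2L)] <- entries$t
  list(roots = roots, rec = rec)
}

test_that("records fold per root and pack 30 per 4 KB chunk", {
  fx <- make_store_fixture()
  s <- fx$store
  expect_equal(s$chunk_bytes %/% 136L, 30L)
  expect_equal(s$n_chunks, ceiling(s$n_records / 30))
  orc <- oracle_records(fx$entries)
  expect_equal(s$n_records, length(orc$roots))
  expect_equal(store_roots(s), orc$roots)
  # 31 roots -> 2 chunks (30 + 1)
  withr::with_seed(42, {
    kms <- character(0)
    while (length(unique(canonical_root(stem_of(kms)))) < 31)
      kms <- unique(c(kms, random_dna(8)))
  })
  kms <- kms[!duplicated(canonical_root(stem_of(kms)))][1:31]
  h31 <- histogram_from_entries(kms, rep(2L, 31), rep(0L, 31), k = 8)
  expect_equal(build_store(h31)$n_chunks, 2)
  # a lone observed variant lands at counter slots 2v, 2v+1
  km <- "ACGTACAT"
  v <- variant_index(km)
  h1 <- histogram_from_entries(km, 2L, 1L, k = 8)
  rec <- store_lookup(build_store(h1), encode_kmer(canonical_root(stem_of(km))))
  expected <- integer(64)
  expected[2 * v + 1] <- 2L
  expected[2 * v + 2] <- 1L
  expect_equal(rec$counters[1, ], expected)
})

test_that("the multi-level index mirrors flat binary search", {
  idx <- build_index(0:255 * 10, fanout = 16)
  expect_equal(vapply(idx$levels, length, integer(1)), c(256L, 16L, 1L))
  idx2 <- build_index(0:256 * 10, fanout = 16)
  expect_equal(vapply(idx2$levels, length, integer(1)), c(257L, 17L, 2L, 1L))
  fk <- sort(withr::with_seed(43, sample.int(1e6, 500)))
  idx3 <- build_index(fk, fanout = 16)
  probes <- withr::with_seed(44, runif(10000) * 1.1e6)
  got <- locate_chunk(idx3, probes)
  flat <- pmax(findInterval(probes, fk) - 1L, 0L)
  expect_equal(got, as.integer(flat))
  expect_equal(kmerscout:::cpp_locate_chunks(probes, fk, 16L),
               as.integer(flat))
  # exact first keys map to their own chunk; locate is monotone
  expect_equal(locate_chunk(idx3, fk), seq_along(fk) - 1L)
  sp <- sort(probes)
  expect_false(is.unsorted(locate_chunk(idx3, sp)))
  expect_equal(locate_chunk(idx3, fk[1] - 1), 0L)
})

test_that("look-ups equal an in-memory map with at most one read each", {
  fx <- make_store_fixture()
  s <- fx$store
  orc <- oracle_records(fx$entries)
  res <- store_lookup(s, orc$roots)
  expect_true(all(res$found))
  expect_equal(res$counters, orc$rec)
  expect_lte(res$chunk_reads, length(orc$roots))
  # absent probes: never found, never more than one read each
  absent <- withr::with_seed(45,
    setdiff(floor(runif(10000) * 4^8), orc$roots))
  ra <- store_lookup(s, absent)
  expect_false(any(ra$found))
  expect_lte(ra$chunk_reads, length(absent))
  expect_equal(ra$chunk_reads,
               length(absent) - ra$bandpass_rejects - ra$bloom_rejects)
  # out-of-band probes are rejected with zero storage reads
  rb <- store_lookup(s, s$max_root + 1)
  expect_false(rb$found)
  expect_equal(rb$chunk_reads, 0)
  expect_equal(rb$bandpass_rejects, 1)
})

test_that("the Bloom filter never rejects a present root and stays near
          its theoretical false-positive rate", {
  fx <- make_store_fixture(n_kmers = 2000, seed = 46)
  s <- fx$store
  present <- store_roots(s)
  expect_true(all(kmerscout:::cpp_bloom_maybe(
    s$bloom, present, s$m_bits, s$n_hashes, s$seeds[1], s$seeds[2])))
  # in-band absent probes: empirical FPR within 2x of (1 - e^(-hn/m))^h
  width <- s$max_root - s$min_root
  absent <- withr::with_seed(47,
    setdiff(floor(s$min_root + runif(40000) * width), present))
  maybe <- kmerscout:::cpp_bloom_maybe(s$bloom, absent, s$m_bits, s$n_hashes,
                                       s$seeds[1], s$seeds[2])
  fpr <- mean(maybe)
  theory <- (1 - exp(-s$n_hashes * s$n_records / s$m_bits))^s$n_hashes
  expect_lt(fpr, 2 * theory)
  expect_gt(theory, 0.004)  # defaults: about 0.0082
  expect_lt(theory, 0.02)
})

test_that("batched look-ups are sequential look-ups, tag for tag", {
  fx <- make_store_fixture(seed = 48)
  s <- fx$store
  present <- store_roots(s)
  probes <- withr::with_seed(49, c(
    sample(present, 500, replace = TRUE),
    floor(runif(500) * 4^8)))
  seq_res <- store_lookup(s, probes)
  bat <- lookup_batch(s, probes, tags = sprintf("t%04d", seq_along(probes)),
                      queue_depth = 37)
  ord <- match(sprintf("t%04d", seq_along(probes)), bat$tag)
  expect_equal(bat$root[ord], probes)
  expect_equal(bat$found[ord], seq_res$found)
  expect_equal(bat$counters[ord, ], seq_res$counters)
  expect_equal(bat$chunk_reads, seq_res$chunk_reads)
  # empty batch and duplicate roots
  e <- lookup_batch(s, numeric(0), tags = character(0))
  expect_length(e$found, 0)
  dup <- lookup_batch(s, rep(present[1], 3), tags = 1:3)
  expect_true(all(dup$found))
  expect_equal(dup$counters[1, ], dup$counters[3, ])
})

test_that("the random positive benchmark returns only present records", {
  fx <- make_store_fixture(seed = 50)
  rep1 <- bench_random_lookups(fx$store, n_lookups = 2000, seed = 5)
  expect_equal(rep1$present, 2000)
  expect_lte(rep1$chunk_reads, 2000)
  rep2 <- bench_random_lookups(fx$store, n_lookups = 2000, seed = 5)
  expect_equal(rep1$present, rep2$present)
})

test_that("analytic sizing reproduces the billion-item payload", {
  sz <- store_sizing(1e9, key_bytes = 8, value_bytes = 128)
  expect_equal(sz$bytes, 1e9 * 136)
  expect_equal(sz$gib, 1e9 * 136 / 2^30)
  expect_lt(abs(sz$gib - 127), 1)
})

test_that("a store survives the close/open round trip", {
  fx <- make_store_fixture(seed = 51)
  s2 <- open_store(fx$store$path)
  expect_equal(s2$first_keys, fx$store$first_keys)
  expect_equal(s2$min_root, fx$store$min_root)
  probes <- store_roots(fx$store)[1:50]
  expect_equal(store_lookup(s2, probes)$counters,
               store_lookup(fx$store, probes)$counters)
  g <- glance(s2)
  expect_equal(g$record_bytes, 136L)
  expect_equal(g$records_per_chunk, 30L)
})
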