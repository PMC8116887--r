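test_that("the interestingness rule needs support, purity and a witness", {
  rec <- integer(64)
  rec[2 * 3 + 2] <- 9L                 # variant 3: (n=0, t=9)
  rec[2 * 17 + 1] <- 12L               # sibling variant 17: (n=12, t=0)
  expect_true(classify_kmer(rec, 3L))
  # fails the normal-contamination bound
  rec2 <- rec
  rec2[2 * 3 + 1] <- 5L                # (n=5, t=9)
  expect_false(classify_kmer(rec2, 3L))
  # no almost-matching witness in the normal sample
  rec3 <- integer(64)
  rec3[2 * 3 + 2] <- 9L
  expect_false(classify_kmer(rec3, 3L))
  # the variant itself cannot be its own witness
  rec4 <- integer(64)
  rec4[2 * 3 + 1] <- 1L
  rec4[2 * 3 + 2] <- 9L
  expect_false(classify_kmer(rec4, 3L))
  # thresholds are configurable
  expect_false(classify_kmer(rec3, 3L, label_config(min_witness_count = 1)))
  expect_true(classify_kmer(rec2, 3L, label_config(max_normal_count = 5)))
  # symmetric mode mirrors the rule
  rec5 <- integer(64)
  rec5[2 * 3 + 1] <- 9L                # normal-only variant
  rec5[2 * 17 + 2] <- 12L              # tumoral witness
  expect_false(classify_kmer(rec5, 3L))
  expect_true(classify_kmer(rec5, 3L, label_config(symmetric = TRUE)))
})

test_that("a tumor-only SNV yields interesting k-mers and spanning reads", {
  # constructed genome, error-free tiled reads: tumor coverage 9, normal 12
  k <- 12
  withr::with_seed(81, genome <- random_dna(2000))
  snv_at <- 1000
  ref_base <- substr(genome, snv_at, snv_at)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  tumor_genome <- paste0(substr(genome, 1, snv_at - 1), alt_base,
                         substr(genome, snv_at + 1, 2000))
  r <- 50
  tile <- function(seqn, offset) {
    s <- seq(offset, nchar(seqn) - r + 1, by = r)
    substring(seqn, s, s + r - 1)
  }
  reads_n <- unlist(lapply(seq(1, by = 4, length.out = 12),
                           function(o) tile(genome, o)))        # coverage 12
  reads_t <- unlist(lapply(seq(1, by = 5, length.out = 9),
                           function(o) tile(tumor_genome, o)))  # coverage 9
  fn <- write_tmp_fastq(reads_n)
  ft <- write_tmp_fastq(reads_t)
  hist <- build_histogram(fn, ft, k = k)
  store <- build_store(hist)
  db <- label_reads(fn, ft, store, NULL, cfg = label_config(), k = k)
  expect_gt(nrow(db$kmers), 0)
  # every interesting k-mer is tumor-heavy and normal-clean
  expect_true(all(db$kmers$t >= 4))
  expect_true(all(db$kmers$n <= 1))
  # interesting k-mers carry the alt allele at a window edge
  expect_true(all(vapply(db$kmers$kmer, function(x)
    substr(x, 1, 1) == alt_base || substr(x, k, k) == alt_base, logical(1))))
  # reads from both samples enter the database
  expect_setequal(unique(db$reads$sample), c("N", "T"))
  # error-free identical samples give an empty database
  hist0 <- build_histogram(fn, fn, k = k)
  store0 <- build_store(hist0)
  db0 <- label_reads(fn, fn, store0, NULL, k = k)
  expect_equal(nrow(db0$kmers), 0)
  expect_equal(nrow(db0$reads), 0)
})

test_that("labeling is cache-transparent and partition-invariant", {
  cfgs <- sim_config(L = 4000, alpha = 15, r = 60, error_rate = 0.001,
                     n_snv = 2, n_ins = 0, n_del = 0, min_separation = 40,
                     seed = 82)
  p <- make_patient(cfgs, tempfile("pt"))
  k <- 12
  hist <- build_histogram(p$normal, p$tumor, k = k)
  store <- build_store(hist)
  db_plain <- label_reads(p$normal, p$tumor, store, NULL, k = k)
  db_cache <- label_reads(p$normal, p$tumor, store,
                          build_cache(hist, 2^20), k = k)
  expect_equal(db_cache$reads, db_plain$reads)
  expect_equal(db_cache$kmers, db_plain$kmers)
  # partitions: label each, merge, compare to P = 1
  parts <- partition_bounds(k, 3)
  dbs <- lapply(1:3, function(i) {
    h <- build_histogram(p$normal, p$tumor, k = k, partition = parts[i, ])
    s <- build_store(h)
    label_reads(p$normal, p$tumor, s, NULL, k = k, partition = parts[i, ])
  })
  merged <- merge_dbs(dbs)
  expect_equal(merged$kmers, db_plain$kmers)
  expect_equal(merged$reads, db_plain$reads)
  # merge of one database is the identity, and order does not matter
  expect_equal(merge_dbs(list(db_plain))$reads, db_plain$reads)
  expect_equal(merge_dbs(rev(dbs))$kmers, merged$kmers)
})

test_that("databases round-trip through the sorted TSV format", {
  cfgs <- sim_config(L = 3000, alpha = 15, r = 60, error_rate = 0,
                     n_snv = 2, n_ins = 0, n_del = 0, min_separation = 40,
                     contamination = 0, seed = 83)
  p <- make_patient(cfgs, tempfile("pt"))
  hist <- build_histogram(p$normal, p$tumor, k = 12)
  db <- label_reads(p$normal, p$tumor, build_store(hist), NULL, k = 12)
  prefix <- tempfile("db")
  write_db(db, prefix)
  back <- read_db(prefix, k = 12)
  expect_equal(back$reads, db$reads)
  expect_equal(back$kmers, db$kmers)
})

test_that("merging rejects conflicting read records", {
  a <- structure(list(
    reads = tibble::tibble(read_id = "r1", sample = "T", sequence = "ACGT",
                           hits = "0:ACGT"),
    kmers = tibble::tibble(kmer = "ACGT", root = "CG", n = 0L, t = 5L,
                           read_ids = "r1"), k = 4L),
    class = "interesting_db")
  b <- a
  b$reads$sequence <- "TTTT"
  b$kmers$kmer <- "TTTT"
  expect_error(merge_dbs(list(a, b)), "conflicting sequences")
})
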