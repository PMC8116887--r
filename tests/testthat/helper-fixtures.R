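# Shared fixtures: tiny FASTQ writers, random update streams and the naive
# counting oracle the external-memory paths are checked against.

random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

write_tmp_fastq <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                            gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  write_fastq(tibble::tibble(id = ids, desc = "", seq = seqs), path)
  path
}

# Brute-force per-k-mer counting with root-singleton removal: the oracle for
# build_histogram() at small k.
naive_histogram <- function(normal_seqs, tumor_seqs, k) {
  tally <- function(seqs) {
    km <- unlist(lapply(seqs, function(s) kmers_of_read(s, k)$kmer))
    table(km)
  }
  tn <- tally(normal_seqs)
  tt <- tally(tumor_seqs)
  kmers <- sort(unique(c(names(tn), names(tt))))
  if (length(kmers) == 0) {
    return(tibble::tibble(kmer = character(0), root = character(0),
                          n = integer(0), t = integer(0)))
  }
  out <- tibble::tibble(
    kmer = kmers,
    root = canonical_root(stem_of(kmers)),
    key = sort_key(kmers),
    n = as.integer(pmin(ifelse(is.na(tn[kmers]), 0, tn[kmers]), 65535)),
    t = as.integer(pmin(ifelse(is.na(tt[kmers]), 0, tt[kmers]), 65535)))
  totals <- tapply(out$n + out$t, out$root, sum)
  out <- out[totals[out$root] > 1, , drop = FALSE]
  out[order(out$key), c("kmer", "root", "n", "t")]
}

# Naive in-memory accumulation oracle for sort_reduce().
naive_accumulate <- function(updates) {
  agg <- stats::aggregate(cbind(n, t) ~ key, data = updates, FUN = sum)
  agg <- agg[order(agg$key), , drop = FALSE]
  tibble::tibble(key = agg$key, n = as.integer(pmin(agg$n, 65535)),
                 t = as.integer(pmin(agg$t, 65535)))
}

random_updates <- function(n_updates, n_keys, seed) {
  withr::with_seed(seed, {
    tumoral <- sample(c(TRUE, FALSE), n_updates, replace = TRUE)
    tibble::tibble(key = sample.int(n_keys, n_updates, replace = TRUE),
                   n = as.integer(!tumoral), t = as.integer(tumoral))
  })
}

# A histogram file built from an explicit entry tibble (kmer strings),
# bypassing FASTQ: route the entries through sort_reduce + finalize.
histogram_from_entries <- function(kmers, n, t, k) {
  updates <- tibble::tibble(key = sort_key(kmers), n = n, t = t)
  cfg <- sr_config()
  run <- sort_reduce(updates, cfg)
  path <- tempfile(fileext = ".kmh")
  kmerscout:::cpp_finalize_histogram(run$path, path, k, 0, 4^(k - 2))
  open_histogram(path)
}
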