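#' Configure the synthetic tumor/normal patient generator
#'
#' The generator embodies the abstract sampling model the detector is built
#' for: a random reference sequence N, a tumor sequence T derived from N by
#' point mutations, insertions and deletions, and two read sets of uniform
#' length `r` covering each position `alpha` times on average, drawn from
#' both strands with per-base substitution errors. The tumor sample can be
#' contaminated with reads drawn from N, mimicking normal-cell admixture in
#' a biopsy.
#'
#' @param L Reference length in bases.
#' @param alpha Mean coverage (reads per position).
#' @param r Uniform read length in bases.
#' @param error_rate Per-base substitution error probability.
#' @param n_snv,n_ins,n_del Numbers of injected point mutations, insertions
#'   and deletions.
#' @param indel_len Inclusive length range for insertions and deletions.
#' @param min_separation Minimum distance between injected mutations (and
#'   from the sequence ends); defaults to `3 * 28` so each mutation's k-mer
#'   context is independent of its neighbours at the default k.
#' @param contamination Fraction of tumor-sample reads actually drawn from
#'   the normal genome.
#' @param seed Integer seed; every downstream operation is deterministic
#'   per seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 2e5, alpha = 30, r = 100, error_rate = 0.001,
                       n_snv = 20L, n_ins = 3L, n_del = 3L,
                       indel_len = c(2L, 20L), min_separation = 84L,
                       contamination = 0.05, seed = 1L) {
  if (L <= r) abort("L must exceed the read length")
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  if (contamination < 0 || contamination >= 1)
    abort("contamination must be in [0, 1)")
  if (length(indel_len) != 2 || indel_len[1] < 1 || indel_len[2] < indel_len[1])
    abort("indel_len must be an increasing pair of positive lengths")
  structure(list(L = as.numeric(L), alpha = alpha, r = as.integer(r),
                 error_rate = error_rate, n_snv = as.integer(n_snv),
                 n_ins = as.integer(n_ins), n_del = as.integer(n_del),
                 indel_len = as.integer(indel_len),
                 min_separation = as.integer(min_separation),
                 contamination = contamination, seed = as.integer(seed)),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

#' Generate the random reference sequence
#'
#' I.i.d. uniform bases from a seeded generator.
#'
#' @param L Sequence length.
#' @param seed Integer seed.
#' @return A single DNA string of length `L`.
#' @export
make_reference <- function(L, seed = 1L) {
  withr::with_seed(seed,
    paste(sample(.BASES, L, replace = TRUE), collapse = ""))
}

#' Derive the tumor sequence by injecting mutations
#'
#' Mutation sites are drawn without replacement, at least `min_separation`
#' bases apart and away from the ends (bounded retries, then failure). A
#' point mutation substitutes a uniformly different base; an insertion adds
#' a random sequence after its anchor position; a deletion removes the span
#' following its anchor. The manifest records every mutation in reference
#' coordinates, VCF-style (anchored REF/ALT for indels), and
#' [apply_manifest()] replays it exactly.
#'
#' @param ref Reference sequence string.
#' @param cfg A [sim_config()].
#' @return List with `tumor` (mutated sequence) and `manifest` (tibble
#'   `type`, `pos` 1-based, `ref`, `alt`).
#' @export
apply_mutations <- function(ref, cfg) {
  L <- nchar(ref)
  n_mut <- cfg$n_snv + cfg$n_ins + cfg$n_del
  withr::with_seed(cfg$seed + 1L, {
    sep <- cfg$min_separation
    margin <- sep + cfg$indel_len[2] + 1L
    # spacing transform: sorted draws from a shrunken range, then shifted
    # apart by (i-1)*sep, give pairwise separation >= sep by construction
    hi <- L - margin - (n_mut - 1L) * sep
    if (hi < margin || hi - margin + 1L < n_mut)
      abort("could not place mutations with the requested separation")
    pos <- sort(sample(seq(margin, hi), n_mut)) +
      (seq_len(n_mut) - 1L) * sep
    type <- sample(rep(c("SNV", "INS", "DEL"),
                       c(cfg$n_snv, cfg$n_ins, cfg$n_del)))
    refs <- alts <- character(n_mut)
    for (i in seq_len(n_mut)) {
      p <- pos[i]
      base <- substr(ref, p, p)
      if (type[i] == "SNV") {
        refs[i] <- base
        alts[i] <- sample(setdiff(.BASES, base), 1)
      } else if (type[i] == "INS") {
        ins <- paste(sample(.BASES, sample(cfg$indel_len[1]:cfg$indel_len[2], 1),
                            replace = TRUE), collapse = "")
        refs[i] <- base
        alts[i] <- paste0(base, ins)
      } else {
        d <- sample(cfg$indel_len[1]:cfg$indel_len[2], 1)
        refs[i] <- substr(ref, p, p + d)
        alts[i] <- base
      }
    }
  })
  manifest <- tibble(type = type, pos = pos, ref = refs, alt = alts)
  list(tumor = apply_manifest(ref, manifest), manifest = manifest)
}

#' Replay a mutation manifest on the reference
#'
#' @param ref Reference sequence string.
#' @param manifest Manifest tibble from [apply_mutations()].
#' @return The mutated sequence.
#' @export
apply_manifest <- function(ref, manifest) {
  manifest <- manifest[order(manifest$pos, decreasing = TRUE), , drop = FALSE]
  out <- ref
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$pos[i]
    stopifnot(substr(out, p, p + nchar(manifest$ref[i]) - 1L) ==
                manifest$ref[i])
    out <- paste0(substr(out, 1, p - 1L), manifest$alt[i],
                  substr(out, p + nchar(manifest$ref[i]), nchar(out)))
  }
  out
}

#' Sample uniform-coverage reads from a sequence
#'
#' Draws `round(alpha * |seq| / r)` reads (unless `n_reads` overrides):
#' start positions uniform, strand uniform — reverse-strand reads are
#' emitted as the reverse complement — and each base substituted with
#' probability `error_rate` by a uniformly different base. Read ids are
#' `sim_<tag>_<index>`; the description carries
#' `origin=<pos>:<strand>:<source>` for provenance.
#'
#' @param seq Source sequence (N or T).
#' @param tag Sample tag used in read ids (`"N"` or `"T"`).
#' @param cfg A [sim_config()].
#' @param n_reads Override for the read count.
#' @param source Source genome recorded in the provenance field (defaults
#'   to `tag`).
#' @param seed Seed (defaults to `cfg$seed + 2`).
#' @param id_offset Start index for read ids (used for contamination mixes).
#' @return Tibble: `id`, `desc`, `seq`.
#' @export
simulate_reads <- function(seq, tag, cfg, n_reads = NULL, source = tag,
                           seed = cfg$seed + 2L, id_offset = 0L) {
  len <- nchar(seq)
  r <- cfg$r
  if (len < r) abort("sequence shorter than the read length")
  if (is.null(n_reads)) n_reads <- round(cfg$alpha * len / r)
  withr::with_seed(seed, {
    starts <- sample.int(len - r + 1L, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- substring(seq, starts, starts + r - 1L)
    reads[strand == "-"] <- cpp_revcomp_str(reads[strand == "-"])
    if (cfg$error_rate > 0) {
      nerr <- rbinom(n_reads, r, cfg$error_rate)
      for (i in which(nerr > 0)) {
        at <- sample.int(r, nerr[i])
        ch <- strsplit(reads[i], "")[[1]]
        ch[at] <- vapply(ch[at], function(b) sample(setdiff(.BASES, b), 1), "")
        reads[i] <- paste(ch, collapse = "")
      }
    }
  })
  tibble(id = sprintf("sim_%s_%06d", tag, id_offset + seq_len(n_reads)),
         desc = sprintf("origin=%d:%s:%s", starts, strand, source),
         seq = reads)
}

#' Write reads as (gzip) FASTQ with constant quality
#'
#' @param reads Tibble from [simulate_reads()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id, " ", reads$desc),
                           reads$seq, "+",
                           strrep("I", nchar(reads$seq))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  tryCatch(writeLines(lines, con), finally = close(con))
  invisible(path)
}

#' Simulate a full patient: normal and tumor read sets plus ground truth
#'
#' The normal sample is drawn from N. The tumor sample mixes
#' `(1 - contamination)` of its reads from T with `contamination` drawn
#' from N (sequenced as sample T, but carrying no somatic signal). Ground
#' truth is written as a minimal VCF 4.2, and the configuration as JSON,
#' next to the FASTQ files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List: `normal`, `tumor` (FASTQ.gz paths), `truth` (VCF path),
#'   `config` (JSON path), `reference`, `tumor_seq`, `manifest`.
#' @export
make_patient <- function(cfg = sim_config(), dir = tempfile("patient")) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    abort(sprintf("cannot create '%s'", dir))
  ref <- make_reference(cfg$L, cfg$seed)
  mut <- apply_mutations(ref, cfg)
  normal <- simulate_reads(ref, "N", cfg, seed = cfg$seed + 2L)
  n_t <- round(cfg$alpha * nchar(mut$tumor) / cfg$r)
  n_contam <- round(cfg$contamination * n_t)
  tumor <- simulate_reads(mut$tumor, "T", cfg, n_reads = n_t - n_contam,
                          source = "T", seed = cfg$seed + 3L)
  if (n_contam > 0) {
    tumor <- dplyr::bind_rows(
      tumor,
      simulate_reads(ref, "T", cfg, n_reads = n_contam, source = "N",
                     seed = cfg$seed + 4L, id_offset = n_t - n_contam))
  }
  np <- write_fastq(normal, file.path(dir, "normal.fastq.gz"))
  tp <- write_fastq(tumor, file.path(dir, "tumor.fastq.gz"))
  vp <- file.path(dir, "truth.vcf")
  write_truth_vcf(mut$manifest, vp)
  jp <- file.path(dir, "sim_config.json")
  jsonlite::write_json(unclass(cfg), jp, auto_unbox = TRUE, digits = NA)
  list(normal = np, tumor = tp, truth = vp, config = jp, reference = ref,
       tumor_seq = mut$tumor, manifest = mut$manifest)
}

#' Write / read the ground-truth manifest as minimal VCF 4.2
#'
#' @param manifest Manifest tibble.
#' @param path VCF path.
#' @return The path (write) or the manifest tibble (read).
#' @export
write_truth_vcf <- function(manifest, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=kmerscout-simulator",
           paste0("##contig=<ID=simref>"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("simref\t%d\t%s\t%s\t%s\t.\t.\tTYPE=%s",
                  manifest$pos,
                  sprintf("mut%03d", seq_len(nrow(manifest))),
                  manifest$ref, manifest$alt, manifest$type)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_truth_vcf
#' @export
read_truth_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(tibble(type = character(0), pos = integer(0),
                  ref = character(0), alt = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  tibble(type = sub("TYPE=", "", vapply(f, `[`, character(1), 8)),
         pos = as.integer(vapply(f, `[`, character(1), 2)),
         ref = vapply(f, `[`, character(1), 4),
         alt = vapply(f, `[`, character(1), 5))
}
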