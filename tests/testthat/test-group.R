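# A hand-built database around one locus: tumor reads carry an A->G change
# at the base just left of a shared anchor stem.
make_toy_db <- function(k = 8) {
  withr::with_seed(91, ctx <- random_dna(60))
  normal_local <- ctx
  alt <- setdiff(c("A", "C", "G", "T"), substr(ctx, 25, 25))[1]
  tumor_local <- paste0(substr(ctx, 1, 24), alt, substr(ctx, 26, 60))
  # anchor k-mer starts at the SNV: stem is mutation-free
  anchor <- substr(tumor_local, 25, 25 + k - 1)
  reads_n <- substring(normal_local, c(5, 10, 15, 20), c(5, 10, 15, 20) + 39)
  reads_t <- substring(tumor_local, c(6, 11, 16, 21), c(6, 11, 16, 21) + 39)
  # one tumor read sequenced on the opposite strand
  reads_t[4] <- revcomp(reads_t[4])
  all_reads <- tibble::tibble(
    read_id = c(sprintf("n%02d", 1:4), sprintf("t%02d", 1:4)),
    sample = rep(c("N", "T"), each = 4),
    sequence = c(reads_n, reads_t))
  hits <- lapply(seq_len(nrow(all_reads)), function(i) {
    km <- kmers_of_read(all_reads$sequence[i], k)
    km[canonical_root(stem_of(km$kmer)) ==
         canonical_root(stem_of(anchor)), , drop = FALSE]
  })
  keepers <- lengths(lapply(hits, `[[`, "pos")) > 0
  db <- structure(list(
    reads = tibble::tibble(
      read_id = all_reads$read_id[keepers],
      sample = all_reads$sample[keepers],
      sequence = all_reads$sequence[keepers],
      hits = vapply(hits[keepers], function(h)
        paste(sprintf("%d:%s", h$pos, h$kmer), collapse = ";"), character(1))),
    kmers = tibble::tibble(
      kmer = anchor, root = canonical_root(stem_of(anchor)),
      n = 0L, t = 4L, read_ids = "t01,t02,t03,t04"),
    k = k), class = "interesting_db")
  list(db = db, anchor = anchor, alt = alt)
}

test_that("groups collect both samples and orient reverse-strand members", {
  toy <- make_toy_db()
  g <- group_reads(toy$db)
  expect_equal(nrow(g), 1)
  mem <- g$members[[1]]
  expect_setequal(mem$sample, c("N", "T"))
  expect_equal(sum(mem$sample == "N"), 4)
  expect_equal(sum(mem$sample == "T"), 4)
  # the flipped member was restored to anchor orientation
  expect_true(any(mem$flipped))
  stem <- stem_of(toy$anchor)
  root <- canonical_root(stem)
  for (i in seq_len(nrow(mem))) {
    at <- substr(mem$oriented[i], mem$anchor_offset[i] + 1,
                 mem$anchor_offset[i] + nchar(root))
    expect_true(at %in% c(root))
  }
})

test_that("identical member sets deduplicate to the lowest root", {
  toy <- make_toy_db()
  db2 <- toy$db
  # second interesting k-mer of the same locus: same member set
  second <- paste0("A", stem_of(toy$anchor), "A")
  db2$kmers <- dplyr::bind_rows(
    db2$kmers,
    tibble::tibble(kmer = second, root = canonical_root(stem_of(second)),
                   n = 0L, t = 4L, read_ids = db2$kmers$read_ids))
  g <- group_reads(db2)
  expect_equal(nrow(g), 1)
})

test_that("layouts stack members gaplessly with a shared anchor column", {
  toy <- make_toy_db()
  g <- group_reads(toy$db)
  lay <- build_layout(g[1, ], k = attr(g, "k"))
  mem <- lay$members
  # anchor stem occupies identical columns in every member
  stem <- stem_of(toy$anchor)
  for (i in seq_len(nrow(mem))) {
    cols0 <- mem$col_start[i] + mem$anchor_offset[i]
    expect_equal(cols0, 0L)
  }
  # unanimous anchor columns read back the root itself
  root <- canonical_root(stem)
  expect_equal(substr(lay$cons_n, 0 - lay$col_lo + 1, 0 - lay$col_lo + nchar(root)),
               root)
  # single-read group degenerates to the read itself
  solo <- g$members[[1]][2, ]
  lone <- build_layout(solo, k = attr(g, "k"))
  expect_equal(gsub("\\.", "", lone$cons_n), solo$oriented)
})

test_that("a point divergence produces one single-column call", {
  toy <- make_toy_db()
  g <- group_reads(toy$db)
  lay <- build_layout(g[1, ], k = attr(g, "k"))
  calls <- call_breakpoints(lay, cmin = 3)
  expect_equal(nrow(calls), 1)
  # the changed base sits just outside the anchor stem: left of it when the
  # stem is its own root, mirrored to the right when members were flipped
  stem <- stem_of(toy$anchor)
  expected_col <- if (canonical_root(stem) == stem) -1L else attr(g, "k") - 2L
  expect_equal(calls$breakpoint_col, expected_col)
  expect_equal(calls$run_length, 1L)
  expect_gte(calls$n_normal, 3)
  expect_gte(calls$n_tumor, 3)
  # identical consensi -> no calls
  lay0 <- lay
  lay0$cons_t <- lay0$cons_n
  lay0$cov_t <- lay0$cov_n
  expect_equal(nrow(call_breakpoints(lay0, cmin = 3)), 0)
})

test_that("an insertion surfaces as divergence starting at its column", {
  k <- 10
  withr::with_seed(92, left <- random_dna(40))
  withr::with_seed(93, right <- paste0("A", random_dna(39)))
  withr::with_seed(94, ins <- paste0("C", random_dna(4)))  # differs at onset
  normal_seq <- paste0(left, right)
  tumor_seq <- paste0(left, ins, right)
  # anchor on the k-mer whose last base is the first inserted base
  anchor <- substr(tumor_seq, 41 - k + 1, 41)
  r <- 30
  tiles <- function(seqn) {
    s <- unlist(lapply(1:6, function(o) seq(o * 2, nchar(seqn) - r + 1, by = r)))
    substring(seqn, s, s + r - 1)
  }
  reads <- tibble::tibble(
    read_id = sprintf("x%03d", seq_len(length(tiles(normal_seq)) +
                                         length(tiles(tumor_seq)))),
    sample = rep(c("N", "T"), c(length(tiles(normal_seq)),
                                length(tiles(tumor_seq)))),
    sequence = c(tiles(normal_seq), tiles(tumor_seq)))
  root <- canonical_root(stem_of(anchor))
  hitlists <- lapply(seq_len(nrow(reads)), function(i) {
    km <- kmers_of_read(reads$sequence[i], k)
    km[canonical_root(stem_of(km$kmer)) == root, , drop = FALSE]
  })
  keep <- lengths(lapply(hitlists, `[[`, "pos")) > 0
  db <- structure(list(
    reads = tibble::tibble(
      read_id = reads$read_id[keep], sample = reads$sample[keep],
      sequence = reads$sequence[keep],
      hits = vapply(hitlists[keep], function(h)
        paste(sprintf("%d:%s", h$pos, h$kmer), collapse = ";"),
        character(1))),
    kmers = tibble::tibble(kmer = anchor, root = root, n = 0L, t = 6L,
                           read_ids = "x001"),
    k = k), class = "interesting_db")
  g <- group_reads(db)
  lay <- build_layout(g[1, ], k)
  calls <- call_breakpoints(lay, cmin = 2)
  expect_gte(nrow(calls), 1)
  # divergence onset sits where the inserted bases begin: just outside the
  # anchor stem, mirrored if the members were flipped to root orientation
  stem <- stem_of(anchor)
  expected_col <- if (canonical_root(stem) == stem) k - 2L else -1L
  onset <- calls[calls$breakpoint_col == expected_col, ]
  expect_equal(nrow(onset), 1)
})

test_that("reports carry one block and one TSV row per call", {
  toy <- make_toy_db()
  g <- group_reads(toy$db)
  calls <- call_group_breakpoints(g, cmin = 3)
  rep <- render_report(calls, g)
  expect_equal(nrow(rep$tsv), nrow(calls))
  expect_equal(sum(grepl("^group ", rep$text)), nrow(calls))
  expect_equal(rep$tsv$group_id, sort(rep$tsv$group_id))
  # marker line points at the break-point column
  expect_true(any(grepl("\\*$", rep$text)))
  # empty call set -> header-only TSV
  empty <- render_report(calls[0, ], g)
  expect_equal(nrow(empty$tsv), 0)
  expect_length(empty$text, 0)
  # files are written when a path is given
  pre <- tempfile("rep")
  render_report(calls, g, path = pre)
  expect_true(file.exists(paste0(pre, ".report.txt")))
  expect_true(file.exists(paste0(pre, ".calls.tsv")))
})

test_that("orientation of the input reads does not change the calls", {
  toy <- make_toy_db()
  g1 <- group_reads(toy$db)
  c1 <- call_group_breakpoints(g1, cmin = 3)
  flipped_db <- toy$db
  flipped_db$reads$sequence <- revcomp(flipped_db$reads$sequence)
  flipped_db$reads$hits <- vapply(seq_len(nrow(flipped_db$reads)), function(i) {
    km <- kmers_of_read(flipped_db$reads$sequence[i], toy$db$k)
    km <- km[canonical_root(stem_of(km$kmer)) ==
               canonical_root(stem_of(toy$anchor)), , drop = FALSE]
    paste(sprintf("%d:%s", km$pos, km$kmer), collapse = ";")
  }, character(1))
  g2 <- group_reads(flipped_db)
  c2 <- call_group_breakpoints(g2, cmin = 3)
  expect_equal(c2$breakpoint_col, c1$breakpoint_col)
  expect_equal(c2$run_length, c1$run_length)
})

test_that("evaluation scores calls against the manifest by distance", {
  manifest <- tibble::tibble(type = "SNV", pos = 5000L, ref = "A", alt = "G")
  groups <- structure(
    tibble::tibble(group_id = 1L, root = "CGTA", n_members = 1L,
                   n_normal = 1L, n_tumor = 0L,
                   members = list(tibble::tibble(
                     read_id = "r1", sample = "N",
                     oriented = strrep("A", 50), flipped = FALSE,
                     anchor_offset = 10L))),
    class = c("read_groups", class(tibble::tibble())), k = 28L)
  calls <- tibble::tibble(group_id = 1L, root = "CGTA",
                          breakpoint_col = -7L, run_length = 1L,
                          n_normal = 5L, n_tumor = 5L,
                          normal_context = "", tumor_context = "")
  origins <- tibble::tibble(read_id = "r1", origin = 5000L, strand = "+",
                            source = "N")
  ev <- evaluate_calls(calls, groups, manifest, origins)
  # column -7 + offset 10 = read position 3 -> reference 5003: within k
  expect_equal(ev$calls$ref_pos, 5003)
  expect_true(ev$truth$recovered)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # no calls -> recall 0
  ev0 <- evaluate_calls(calls[0, ], groups, manifest, origins)
  expect_equal(ev0$recall, 0)
  expect_true(is.na(ev0$precision))
  # a distant call is a false positive
  far <- calls
  far$breakpoint_col <- 500L
  evf <- evaluate_calls(far, groups, manifest, origins)
  expect_equal(evf$recall, 0)
  expect_equal(evf$precision, 0)
  g <- glance(ev)
  expect_equal(g$recall_SNV, 1)
  expect_s3_class(tidy(ev), "tbl_df")
})
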