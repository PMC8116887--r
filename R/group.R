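#' Cluster interesting reads on shared roots
#'
#' The Group unit's clustering step: one candidate group per root carrying
#' at least one interesting k-mer, whose members are all database reads
#' (both samples) with a hit on that root. A member whose hit k-mer has its
#' stem on the opposite strand of the root (stem flag 1) is replaced by its
#' reverse complement, with the anchor offset recomputed, so the anchor stem
#' matches literally in every oriented member — reverse-complement k-mers
#' mark the same locus and aligning them doubles the effective coverage.
#' Groups with identical member sets are deduplicated, keeping the lowest
#' root.
#'
#' @param db A merged `interesting_db`.
#' @return A `read_groups` tibble: `group_id`, `root`, `n_members`,
#'   `n_normal`, `n_tumor` and a `members` list-column of per-member tibbles
#'   (`read_id`, `sample`, `oriented`, `flipped`, `anchor_offset` = 0-based
#'   column of the stem start in the oriented read).
#' @export
group_reads <- function(db) {
  k <- db$k
  anchors <- sort(unique(db$kmers$root))
  hit_long <- .parse_hits(db$reads, k)
  out <- list()
  for (root in anchors) {
    h <- hit_long[hit_long$root == root, , drop = FALSE]
    if (nrow(h) == 0) next
    h <- h[order(h$read_id, h$pos), , drop = FALSE]
    h <- h[!duplicated(h$read_id), , drop = FALSE]  # first occurrence anchors
    len <- nchar(h$sequence)
    flipped <- h$flag == 1L
    oriented <- h$sequence
    oriented[flipped] <- cpp_revcomp_str(oriented[flipped])
    offset <- ifelse(flipped, len - h$pos - k + 1L, h$pos + 1L)
    out[[length(out) + 1]] <- tibble(
      root = root,
      members = list(tibble(read_id = h$read_id, sample = h$sample,
                            oriented = oriented, flipped = flipped,
                            anchor_offset = as.integer(offset))))
  }
  groups <- dplyr::bind_rows(out)
  if (nrow(groups) == 0) {
    return(structure(tibble(group_id = integer(0), root = character(0),
                            n_members = integer(0), n_normal = integer(0),
                            n_tumor = integer(0), members = list()),
                     class = c("read_groups", class(tibble())), k = k))
  }
  memset <- vapply(groups$members, function(m)
    paste(sort(m$read_id), collapse = "\r"), character(1))
  groups <- groups[order(groups$root), , drop = FALSE]
  groups <- groups[!duplicated(memset[order(groups$root)]), , drop = FALSE]
  groups$group_id <- seq_len(nrow(groups))
  groups$n_members <- vapply(groups$members, nrow, integer(1))
  groups$n_normal <- vapply(groups$members, function(m)
    sum(m$sample == "N"), integer(1))
  groups$n_tumor <- vapply(groups$members, function(m)
    sum(m$sample == "T"), integer(1))
  groups <- groups[, c("group_id", "root", "n_members", "n_normal",
                       "n_tumor", "members")]
  structure(groups, class = c("read_groups", class(tibble())), k = k)
}

# Long view of the per-read hit lists: read_id, sample, sequence, pos, kmer,
# root (string), flag.
.parse_hits <- function(read_tbl, k) {
  if (nrow(read_tbl) == 0) {
    return(tibble(read_id = character(0), sample = character(0),
                  sequence = character(0), pos = integer(0),
                  kmer = character(0), root = character(0), flag = integer(0)))
  }
  parts <- strsplit(read_tbl$hits, ";", fixed = TRUE)
  nrep <- lengths(parts)
  flat <- unlist(parts)
  pos <- as.integer(sub(":.*", "", flat))
  kmer <- sub("^[0-9]+:", "", flat)
  stem <- stem_of(kmer)
  root <- canonical_root(stem)
  tibble(read_id = rep(read_tbl$read_id, nrep),
         sample = rep(read_tbl$sample, nrep),
         sequence = rep(read_tbl$sequence, nrep),
         pos = pos, kmer = kmer, root = root,
         flag = as.integer(stem != root))
}

#' Gapless anchor alignment of one read group
#'
#' Shifts every oriented member so its anchor stem starts at column 0 and
#' stacks them without gaps; per column and per sample the base multiset,
#' coverage and majority consensus (ties give `N`) are computed. Indels
#' therefore surface as runs of divergent columns rather than gapped
#' columns — a documented property of the anchor alignment.
#'
#' @param group One row of a `read_groups` tibble (or its `members` tibble).
#' @param k K-mer length (anchor stem spans columns `0 .. k - 3`).
#' @return A `group_layout`: `members` (with `col_start`), `col_lo`/`col_hi`
#'   column extent, per-sample consensus strings `cons_n`, `cons_t` and
#'   coverage vectors `cov_n`, `cov_t`.
#' @export
build_layout <- function(group, k) {
  members <- if (is.data.frame(group) && "members" %in% names(group)) {
    group$members[[1]]
  } else {
    group
  }
  if (nrow(members) == 0) abort("empty group")
  len <- nchar(members$oriented)
  col_start <- -members$anchor_offset
  col_lo <- min(col_start)
  col_hi <- max(col_start + len - 1L)
  ncol <- col_hi - col_lo + 1L
  counts <- list(N = matrix(0L, nrow = 4, ncol = ncol),
                 T = matrix(0L, nrow = 4, ncol = ncol))
  for (i in seq_len(nrow(members))) {
    b <- match(strsplit(members$oriented[i], "")[[1]], c("A", "C", "G", "T"))
    cols <- (col_start[i] - col_lo) + seq_along(b)
    ok <- !is.na(b)  # ambiguous bases contribute nothing to any column
    s <- members$sample[i]
    counts[[s]][cbind(b[ok], cols[ok])] <- counts[[s]][cbind(b[ok], cols[ok])] + 1L
  }
  consensus <- function(m) {
    cov <- colSums(m)
    top <- apply(m, 2, max)
    nmax <- colSums(m == rep(top, each = 4))
    base <- c("A", "C", "G", "T")[max.col(t(m), ties.method = "first")]
    base[cov == 0] <- "."
    base[cov > 0 & nmax > 1] <- "N"
    list(cons = paste(base, collapse = ""), cov = cov)
  }
  cn <- consensus(counts$N)
  ct <- consensus(counts$T)
  members$col_start <- col_start
  structure(list(members = members, col_lo = col_lo, col_hi = col_hi,
                 k = k, cons_n = cn$cons, cons_t = ct$cons,
                 cov_n = cn$cov, cov_t = ct$cov),
            class = "group_layout")
}

#' Call candidate break-points from a layout
#'
#' Finds the columns where both samples have coverage of at least `cmin`
#' and an unambiguous, differing consensus. Because every member carries
#' the anchor stem at columns `0 .. k - 3`, divergence can only start on a
#' side of the anchor, and — with mutations far enough apart that a group
#' spans one locus — the break-point is where the two consensi *begin* to
#' diverge moving away from the anchor. Each side of the anchor with any
#' divergent column therefore yields one call, placed at the divergent
#' column nearest the anchor (the divergence onset). Downstream of an indel
#' the gapless layout keeps diverging, with chance re-matches fragmenting
#' the region; those fragments are part of the same divergence region, not
#' separate break-points. `+-context` bases of both consensi around the
#' call are reported.
#'
#' @param layout A `group_layout`.
#' @param cmin Minimum per-sample coverage at a divergent column.
#' @param context Context half-window in bases (default `2 k`).
#' @return Tibble with one row per divergence region: `breakpoint_col`
#'   (column relative to the anchor stem start), `run_length` (number of
#'   divergent columns in the region), `n_normal`, `n_tumor` (supporting
#'   coverage at the break-point column), `normal_context`,
#'   `tumor_context`.
#' @export
call_breakpoints <- function(layout, cmin = 3L, context = NULL) {
  if (is.null(context)) context <- 2L * layout$k
  cn <- strsplit(layout$cons_n, "")[[1]]
  ct <- strsplit(layout$cons_t, "")[[1]]
  div <- layout$cov_n >= cmin & layout$cov_t >= cmin &
    cn != ct & cn != "N" & ct != "N" & cn != "." & ct != "."
  empty <- tibble(breakpoint_col = integer(0), run_length = integer(0),
                  n_normal = integer(0), n_tumor = integer(0),
                  normal_context = character(0), tumor_context = character(0))
  if (!any(div)) return(empty)
  cols <- which(div) - 1L + layout$col_lo        # anchor-relative columns
  stem_hi <- layout$k - 3L
  sides <- list(left = cols[cols < 0], mid = cols[cols >= 0 & cols <= stem_hi],
                right = cols[cols > stem_hi])
  ncolumns <- length(div)
  rows <- purrr::map_dfr(names(sides), function(sd) {
    cc <- sides[[sd]]
    if (length(cc) == 0) return(empty)
    bp <- if (sd == "left") max(cc) else min(cc)   # divergence onset
    s <- bp - layout$col_lo + 1L
    wlo <- max(1L, s - context)
    whi <- min(ncolumns, s + context)
    tibble(breakpoint_col = bp, run_length = length(cc),
           n_normal = layout$cov_n[s], n_tumor = layout$cov_t[s],
           normal_context = paste(cn[wlo:whi], collapse = ""),
           tumor_context = paste(ct[wlo:whi], collapse = ""))
  })
  dplyr::arrange(rows, .data$breakpoint_col)
}

#' Group, align and call break-points for a whole database
#'
#' Convenience driver over [group_reads()], [build_layout()] and
#' [call_breakpoints()].
#'
#' @param groups A `read_groups` tibble (from [group_reads()]).
#' @param cmin,context See [call_breakpoints()].
#' @return A `breakpoint_calls` tibble: `group_id`, `root` plus the
#'   [call_breakpoints()] columns, sorted by `group_id`.
#' @export
call_group_breakpoints <- function(groups, cmin = 3L, context = NULL) {
  k <- attr(groups, "k")
  rows <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    lay <- build_layout(groups[i, ], k)
    calls <- call_breakpoints(lay, cmin = cmin, context = context)
    if (nrow(calls) == 0) return(NULL)
    dplyr::mutate(calls, group_id = groups$group_id[i],
                  root = groups$root[i], .before = 1)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(group_id = integer(0), root = character(0),
                   breakpoint_col = integer(0), run_length = integer(0),
                   n_normal = integer(0), n_tumor = integer(0),
                   normal_context = character(0), tumor_context = character(0))
  }
  structure(dplyr::arrange(rows, .data$group_id, .data$breakpoint_col),
            class = c("breakpoint_calls", class(tibble())), k = k)
}

#' Render the human-readable and machine-readable break-point report
#'
#' One text block per call — anchor root, oriented member reads with offsets
#' and sample tags, both consensus lines and a `*` marker under the
#' break-point column — and one TSV row per call (`group_id`, `anchor_root`,
#' `breakpoint_offset`, `n_normal_reads`, `n_tumor_reads`, `normal_context`,
#' `tumor_context`), sorted by group id.
#'
#' @param calls A `breakpoint_calls` tibble.
#' @param groups The `read_groups` the calls came from.
#' @param path Optional output prefix; writes `<path>.report.txt` and
#'   `<path>.calls.tsv`.
#' @return List with `text` (character vector) and `tsv` (tibble),
#'   invisibly when `path` is given.
#' @export
render_report <- function(calls, groups, path = NULL) {
  k <- attr(groups, "k")
  tsv <- tibble(group_id = calls$group_id, anchor_root = calls$root,
                breakpoint_offset = calls$breakpoint_col,
                n_normal_reads = calls$n_normal,
                n_tumor_reads = calls$n_tumor,
                normal_context = calls$normal_context,
                tumor_context = calls$tumor_context)
  blocks <- character(0)
  for (i in seq_len(nrow(calls))) {
    g <- groups[groups$group_id == calls$group_id[i], ]
    lay <- build_layout(g, k)
    pad <- function(s, start) {
      paste0(strrep(" ", start - lay$col_lo), s)
    }
    mem <- lay$members[order(lay$members$sample, lay$members$read_id), ]
    lines <- c(
      sprintf("group %d  anchor root %s  breakpoint at column %d",
              calls$group_id[i], calls$root[i], calls$breakpoint_col[i]),
      sprintf("  %s [%s] %s", pad(mem$oriented, mem$col_start), mem$sample,
              mem$read_id),
      sprintf("  %s [N consensus]", pad(lay$cons_n, lay$col_lo)),
      sprintf("  %s [T consensus]", pad(lay$cons_t, lay$col_lo)),
      sprintf("  %s*", strrep(" ", calls$breakpoint_col[i] - lay$col_lo)),
      "")
    blocks <- c(blocks, lines)
  }
  out <- list(text = blocks, tsv = tsv)
  if (!is.null(path)) {
    writeLines(blocks, paste0(path, ".report.txt"))
    readr::write_tsv(tsv, paste0(path, ".calls.tsv"))
    return(invisible(out))
  }
  out
}

#' @rdname call_group_breakpoints
#' @param object A `breakpoint_calls` tibble.
#' @param ... Unused.
#' @export
autoplot.breakpoint_calls <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$breakpoint_col,
                               y = factor(.data$group_id),
                               size = .data$n_normal + .data$n_tumor)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "break-point column (relative to anchor stem)",
                  y = "read group", size = "supporting\ncoverage",
                  title = "Candidate break-points by read group")
}
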