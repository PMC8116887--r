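#' Recover read provenance from simulated FASTQ headers
#'
#' Simulated reads carry `origin=<pos>:<strand>:<source>` in the FASTQ
#' description (1-based start on the source sequence, `+`/`-` strand, `N` or
#' `T` source genome).
#'
#' @param ... FASTQ(.gz) paths.
#' @return Tibble: `read_id`, `origin`, `strand`, `source`.
#' @export
parse_read_origins <- function(...) {
  paths <- c(...)
  purrr::map_dfr(paths, function(p) {
    fq <- read_fastq(p)
    m <- regmatches(fq$desc, regexec("origin=([0-9]+):([+-]):([NT])", fq$desc))
    ok <- lengths(m) == 4
    tibble(read_id = fq$id[ok],
           origin = as.integer(vapply(m[ok], `[`, character(1), 2)),
           strand = vapply(m[ok], `[`, character(1), 3),
           source = vapply(m[ok], `[`, character(1), 4))
  })
}

#' Score calls against the ground-truth mutation manifest
#'
#' Maps every call back to reference coordinates through the provenance of
#' its member reads (a layout column `c` sits at read position
#' `c + anchor_offset` of the oriented member; undoing the orientation flip
#' and the sequencing strand gives the reference base the column covers;
#' the per-call position is the median over normal-origin members). A truth
#' mutation is *recovered* when any call lies within `tolerance` bases of
#' its position; a call is a *true positive* when it lies within `tolerance`
#' of any truth mutation.
#'
#' @param calls A `breakpoint_calls` tibble.
#' @param groups The `read_groups` the calls came from.
#' @param manifest Ground-truth manifest tibble (`type`, `pos`, `ref`,
#'   `alt`) from [apply_mutations()] / [read_truth_vcf()].
#' @param origins Read provenance from [parse_read_origins()].
#' @param tolerance Matching tolerance in bases (default: the k used).
#' @return A `call_evaluation` object; see [tidy()] for per-mutation rows
#'   and [glance()] for recall/precision.
#' @export
evaluate_calls <- function(calls, groups, manifest, origins,
                           tolerance = NULL) {
  k <- attr(groups, "k")
  if (is.null(tolerance)) tolerance <- k
  call_pos <- rep(NA_real_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- groups[groups$group_id == calls$group_id[i], ]
    mem <- g$members[[1]]
    mem <- dplyr::inner_join(mem, origins, by = "read_id")
    use <- mem[mem$source == "N", , drop = FALSE]
    if (nrow(use) == 0) use <- mem
    if (nrow(use) == 0) next
    read_pos <- calls$breakpoint_col[i] + use$anchor_offset
    fwd <- (use$strand == "+") == (!use$flipped)
    len <- nchar(use$oriented)
    ref <- ifelse(fwd, use$origin + read_pos,
                  use$origin + len - 1L - read_pos)
    call_pos[i] <- median(ref)
  }
  truth_hit <- vapply(manifest$pos, function(p)
    any(abs(call_pos - p) <= tolerance, na.rm = TRUE), logical(1))
  call_hit <- vapply(call_pos, function(p)
    !is.na(p) && any(abs(manifest$pos - p) <= tolerance), logical(1))
  structure(list(
    calls = dplyr::mutate(as_tibble(calls), ref_pos = call_pos,
                          true_positive = call_hit),
    truth = dplyr::mutate(manifest, recovered = truth_hit),
    tolerance = tolerance,
    recall = if (nrow(manifest) > 0) mean(truth_hit) else NA_real_,
    precision = if (nrow(calls) > 0) mean(call_hit) else NA_real_),
    class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat(sprintf(
    "<call_evaluation> recall %.3f (%d/%d mutations), precision %.3f (%d/%d calls), tolerance %d\n",
    x$recall, sum(x$truth$recovered), nrow(x$truth), x$precision,
    sum(x$calls$true_positive), nrow(x$calls), x$tolerance))
  invisible(x)
}

#' @rdname evaluate_calls
#' @param x A `call_evaluation`.
#' @param ... Unused.
#' @export
tidy.call_evaluation <- function(x, ...) x$truth

#' @rdname evaluate_calls
#' @export
glance.call_evaluation <- function(x, ...) {
  by_type <- x$truth |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(recall = mean(.data$recovered), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type", values_from = "recall",
                       names_prefix = "recall_")
  dplyr::bind_cols(
    tibble(recall = x$recall, precision = x$precision,
           n_truth = nrow(x$truth), n_calls = nrow(x$calls),
           tolerance = x$tolerance),
    by_type)
}

#' @rdname evaluate_calls
#' @param object A `call_evaluation`.
#' @export
autoplot.call_evaluation <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = object$truth,
      ggplot2::aes(x = .data$pos, y = 1.05, shape = .data$recovered,
                   color = .data$type), size = 3) +
    ggplot2::geom_point(
      data = object$calls[!is.na(object$calls$ref_pos), ],
      ggplot2::aes(x = .data$ref_pos, y = 0.95), shape = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::ylim(0.5, 1.5) +
    ggplot2::labs(x = "reference position", y = NULL,
                  title = "Truth mutations (top) vs mapped calls (bottom)") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
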