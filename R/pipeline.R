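#' Run the full BSA-seq genome scan
#'
#' Chains the core method: pool consecutive SNPs into blocks of at least
#' `min_block_depth` informative reads ([build_blocks()]), test each
#' block's bulk allele counts against the cross-design null frequency
#' ([block_p_values()]), score sliding windows by the average -log10(P)
#' ([scan_windows()]) and merge significant windows into candidate
#' regions ([call_candidate_regions()]).
#'
#' @param bulk A bulk-count tibble ([read_bulk_counts()] layout).
#' @param layout A genome layout tibble `chrom, length`.
#' @param design A [cross_design()] (default: BC1 to the mutant parent).
#' @inheritParams block_p_values
#' @inheritParams build_blocks
#' @inheritParams scan_windows
#' @return An object of class `bsa_scan`: a list with `blocks`,
#'   `windows`, `regions` and `params`. `tidy()` returns the window
#'   table, `glance()` a one-row summary, and `autoplot()` a
#'   per-chromosome score track.
#' @examples
#' \donttest{
#' sim <- simulate_bsa_dataset(sim_config(seed = 1))
#' scan <- run_bsa_scan(sim$bulk, sim$layout)
#' glance(scan)
#' scan$regions
#' }
#' @export
run_bsa_scan <- function(bulk, layout, design = cross_design("bc1_mutant"),
                         min_block_depth = 20,
                         test = c("binomial", "fisher"),
                         sidedness = c("two_sided", "greater"),
                         window_size = 2e6, step = 1e5,
                         min_blocks = 5, threshold = 2.0) {
  test <- match.arg(test)
  sidedness <- match.arg(sidedness)
  blocks <- build_blocks(bulk, min_block_depth = min_block_depth) |>
    block_p_values(design, test = test, sidedness = sidedness)
  windows <- scan_windows(blocks, layout, window_size = window_size,
                          step = step, min_blocks = min_blocks,
                          threshold = threshold)
  regions <- withCallingHandlers(
    call_candidate_regions(windows),
    message = function(m) invokeRestart("muffleMessage"))
  structure(list(
    blocks = blocks, windows = windows, regions = regions,
    params = list(design = design, min_block_depth = min_block_depth,
                  test = test, sidedness = sidedness,
                  window_size = window_size, step = step,
                  min_blocks = min_blocks, threshold = threshold)),
    class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<bsa_scan>  %d blocks, %d windows (%d significant), ",
    "%d candidate region(s)\n"),
    g$n_blocks, g$n_windows, g$n_significant, g$n_regions))
  if (nrow(x$regions) > 0) {
    with(x$regions, cat(sprintf("  %s:%d-%d  peak %.2f\n",
                                chrom, start, end, peak_score)))
  }
  invisible(x)
}

#' @rdname run_bsa_scan
#' @param x,object A `bsa_scan` object.
#' @param ... Unused.
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, ...) x$windows

#' @rdname run_bsa_scan
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks),
         n_windows = nrow(x$windows),
         n_significant = sum(x$windows$significant),
         n_regions = nrow(x$regions),
         max_score = if (all(is.na(x$windows$avg_neglog10p))) NA_real_
                     else max(x$windows$avg_neglog10p, na.rm = TRUE),
         threshold = x$params$threshold)
}

#' @rdname run_bsa_scan
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, ...) {
  w <- filter(object$windows, !is.na(.data$avg_neglog10p))
  p <- ggplot2::ggplot(w, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$avg_neglog10p)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = filter(w, .data$significant),
                        color = "#2166ac", size = 0.8) +
    ggplot2::geom_hline(yintercept = object$params$threshold,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        strip.position = "right") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression("average" ~ -log[10] * "(P)")) +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "#2166ac", alpha = 0.12)
  }
  p
}

#' @rdname run_bsa_scan
#' @param y Unused.
#' @export
plot.bsa_scan <- function(x, y, ...) print(autoplot(x, ...))
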