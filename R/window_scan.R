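#' Sliding-window average -log10(P) scan
#'
#' Tiles each chromosome with windows of `window_size` bp starting at
#' position 1 and advancing by `step` bp (the final windows are truncated
#' at the chromosome end). A block belongs to a window iff its midpoint
#' (the rounded-down mean of its first and last SNP positions) lies inside
#' the window. Each window's score is the arithmetic mean of
#' -log10(p_value) over its member blocks,
#' `avg = sum(-log10(P_i)) / n`,
#' with `n` the number of member blocks. Windows with fewer than
#' `min_blocks` blocks are flagged `filtered` and are never significant
#' regardless of score — sparse windows are noise-prone. The remaining
#' windows are significant iff their score strictly exceeds `threshold`.
#'
#' Windows with no blocks carry a missing (`NA`) score: no evidence is not
#' evidence of no difference.
#'
#' @param blocks A block tibble with `p_value` ([block_p_values()]).
#' @param layout A genome layout tibble `chrom, length` covering every
#'   block's chromosome.
#' @param window_size Window width in bp (default 2 Mb).
#' @param step Window increment in bp (default 100 kb).
#' @param min_blocks Minimum block count for a window to be scored
#'   (default 5; windows with `n < 5` are filtered).
#' @param threshold Significance threshold on the average -log10(P)
#'   (default 2; strict inequality).
#' @return A tibble `chrom, start, end, n_blocks, avg_neglog10p, filtered,
#'   significant`, one row per window, ordered by chromosome then start.
#' @examples
#' blocks <- tibble::tibble(chrom = "chr1", start_pos = 5e5, end_pos = 5e5 + 100,
#'                          n_snps = 3L, mut_reads = 20L, wt_reads = 0L,
#'                          depth = 20L, p_value = 1e-4)
#' layout <- tibble::tibble(chrom = "chr1", length = 3e6)
#' scan_windows(blocks, layout, min_blocks = 1)
#' @export
scan_windows <- function(blocks, layout, window_size = 2e6, step = 1e5,
                         min_blocks = 5, threshold = 2.0) {
  stopifnot(step <= window_size, min_blocks >= 1, threshold > 0)
  unknown <- setdiff(unique(blocks$chrom), layout$chrom)
  if (length(unknown) > 0) {
    abort(paste0("blocks on chromosome(s) absent from layout: ",
                 paste(unknown, collapse = ", ")),
          class = "bsascan_validation_error")
  }
  # full window grid, anchored at position 1 of every chromosome
  grid <- layout |>
    mutate(start = purrr::map(.data$length,
                              function(L) seq(1, L, by = step))) |>
    tidyr::unnest("start") |>
    mutate(end = pmin(.data$start + window_size - 1, .data$length)) |>
    select("chrom", "start", "end")

  if (nrow(blocks) > 0) {
    # a block's midpoint lies in windows whose start index k (0-based on the
    # step grid) satisfies mid - window_size + 1 <= 1 + k*step <= mid
    mid <- (blocks$start_pos + blocks$end_pos) %/% 2
    k_lo <- pmax(0, ceiling((mid - window_size) / step))
    k_hi <- (mid - 1) %/% step
    hits <- tibble(chrom = blocks$chrom, mid = mid,
                   nlp = -log10(pmax(blocks$p_value, 1e-300)),
                   k_lo = k_lo, k_hi = k_hi) |>
      mutate(k = purrr::map2(.data$k_lo, .data$k_hi, seq)) |>
      tidyr::unnest("k") |>
      mutate(start = 1 + .data$k * step) |>
      group_by(.data$chrom, .data$start) |>
      summarise(n_blocks = dplyr::n(), avg_neglog10p = mean(.data$nlp),
                .groups = "drop")
    grid <- left_join(grid, hits, by = c("chrom", "start"))
  } else {
    grid <- mutate(grid, n_blocks = NA_integer_, avg_neglog10p = NA_real_)
  }
  grid |>
    mutate(n_blocks = as.integer(dplyr::coalesce(.data$n_blocks, 0L)),
           filtered = .data$n_blocks < min_blocks,
           significant = !.data$filtered &
             !is.na(.data$avg_neglog10p) &
             .data$avg_neglog10p > threshold) |>
    arrange(.data$chrom, .data$start)
}

#' Merge significant windows into candidate regions
#'
#' Significant windows on the same chromosome that overlap or abut are
#' merged into one region spanning their union. Overlapping windows share
#' the evidence that raised them, so the candidate interval is their
#' envelope. Region calling is idempotent and independent of the window
#' input order.
#'
#' @param windows A window tibble from [scan_windows()].
#' @return A tibble `chrom, start, end, peak_score, n_windows` with one
#'   row per merged region (`peak_score` = max member window score), sorted
#'   by chromosome then start. Empty if no window is significant (a notice
#'   is emitted).
#' @export
call_candidate_regions <- function(windows) {
  sig <- windows |>
    filter(.data$significant) |>
    arrange(.data$chrom, .data$start, .data$end)
  if (nrow(sig) == 0) {
    inform("no significant windows: no candidate regions called")
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_score = double(), n_windows = integer()))
  }
  sig |>
    mutate(end_dbl = as.double(.data$end)) |>
    group_by(.data$chrom) |>
    mutate(new_run = .data$start > dplyr::lag(cummax(.data$end_dbl),
                                              default = -Inf) + 1,
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              peak_score = max(.data$avg_neglog10p),
              n_windows = dplyr::n(), .groups = "drop") |>
    select("chrom", "start", "end", "peak_score", "n_windows") |>
    arrange(.data$chrom, .data$start)
}
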