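#' Per-SNP mutant-allele purity profile
#'
#' Within a candidate region (or genome-wide), the fraction of bulk reads
#' carrying the mutant parent's allele is computed at every SNP with
#' sufficient informative depth: `purity = mut / (mut + wt)`. Sites below
#' `min_site_depth` are skipped, not zeroed — a shallow site is missing
#' data, not evidence.
#'
#' @param bulk A bulk-count tibble, sorted by position within chromosome.
#' @param min_site_depth Minimum `wt + mut` depth for a SNP to be profiled
#'   (default 5 reads).
#' @param regions Optional region tibble (`chrom, start, end`, 1-based
#'   inclusive); when given, only SNPs inside a region are profiled.
#' @return A tibble `chrom, pos, depth, purity` over profiled SNPs.
#' @export
purity_profile <- function(bulk, min_site_depth = 5, regions = NULL) {
  check_sorted_unique(bulk, "bulk sites")
  prof <- bulk |>
    mutate(depth = .data$wt_count + .data$mut_count) |>
    filter(.data$depth >= min_site_depth) |>
    mutate(purity = .data$mut_count / .data$depth) |>
    select("chrom", "pos", "depth", "purity")
  if (!is.null(regions)) {
    prof <- prof |>
      inner_join(select(regions, "chrom", region_start = "start",
                        region_end = "end"),
                 by = "chrom", relationship = "many-to-many") |>
      filter(.data$pos >= .data$region_start,
             .data$pos <= .data$region_end) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      select("chrom", "pos", "depth", "purity")
  }
  prof
}

#' Find runs of SNPs whose bulk reads derive from the mutant parent
#'
#' In a selected bulk, stretches of sequence identical to the mutant
#' parent mark the haplotype shared by all selected individuals; they are
#' detected as maximal runs of consecutive profiled SNPs whose
#' mutant-allele purity is at least `min_purity`. A run is reported iff it
#' contains at least `min_snps` SNPs. Runs break at profiled, impure SNPs;
#' SNPs skipped for low depth do not break a run (missing data is not
#' evidence of recombination). Decreasing `min_purity` or `min_snps` never
#' removes segments.
#'
#' The purity cutoff is deliberately below 1: at ~10x pool depth a
#' sequencing error at a single site would otherwise break a genuine
#' mutant-origin run.
#'
#' @param profile A purity profile from [purity_profile()].
#' @param min_purity Per-SNP purity for a SNP to extend a run
#'   (default 0.95).
#' @param min_snps Minimum run length in SNPs (default 10).
#' @return A tibble `chrom, start, end, n_snps, mean_purity`, one row per
#'   reported segment (`start`/`end` = first/last member SNP, 1-based
#'   inclusive), disjoint within chromosome.
#' @export
find_origin_runs <- function(profile, min_purity = 0.95, min_snps = 10) {
  stopifnot(min_purity > 0.5, min_purity <= 1, min_snps >= 1)
  profile |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(pure = .data$purity >= min_purity,
           run = cumsum(!.data$pure)) |>
    filter(.data$pure) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = dplyr::first(.data$pos), end = dplyr::last(.data$pos),
              n_snps = dplyr::n(), mean_purity = mean(.data$purity),
              .groups = "drop") |>
    filter(.data$n_snps >= min_snps) |>
    select("chrom", "start", "end", "n_snps", "mean_purity") |>
    arrange(.data$chrom, .data$start)
}

#' Narrow candidate regions by sequence origin
#'
#' Convenience wrapper: profile mutant-allele purity inside the supplied
#' candidate regions and report mutant-origin runs ([purity_profile()]
#' then [find_origin_runs()]).
#'
#' @inheritParams purity_profile
#' @inheritParams find_origin_runs
#' @param regions A region tibble from [call_candidate_regions()].
#' @return A segment tibble as from [find_origin_runs()]; every segment
#'   lies inside a supplied region.
#' @export
narrow_regions <- function(bulk, regions, min_purity = 0.95, min_snps = 10,
                           min_site_depth = 5) {
  # runs are confined to one region: profile and scan each region separately
  segs <- purrr::pmap(list(regions$chrom, regions$start, regions$end),
                      function(ch, s, e) {
    profile <- purity_profile(bulk, min_site_depth = min_site_depth,
                              regions = tibble(chrom = ch, start = s, end = e))
    find_origin_runs(profile, min_purity = min_purity, min_snps = min_snps)
  })
  arrange(bind_rows(segs), .data$chrom, .data$start)
}
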