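#' Per-site major allele and purity
#'
#' For each site, the major base is the most frequent of A/C/G/T (ties
#' broken in fixed base order A < C < G < T) and the purity is its count
#' divided by the total number of observations at the site, including
#' non-ACGT (`count_other`) observations: purity measures the fraction of
#' *all* observed alleles that the major base accounts for.
#'
#' @param sites A base-count tibble ([read_base_counts()] layout).
#' @return The input with columns `depth` (total observations including
#'   `count_other`), `major_base` and `purity` appended. Sites with zero
#'   depth are errors: purity is undefined there.
#' @examples
#' sim_example_sites() |> site_purity()
#' @export
site_purity <- function(sites) {
  m <- as.matrix(sites[paste0("count_", BASES)])
  depth <- rowSums(m) + sites$count_other
  if (any(depth == 0)) {
    abort(sprintf("purity undefined at zero-depth site (row %d)",
                  which(depth == 0)[1]),
          class = "bsascan_validation_error")
  }
  # max.col with ties.method "first" implements the A < C < G < T tie-break
  j <- max.col(m, ties.method = "first")
  mutate(sites,
         depth = as.integer(depth),
         major_base = BASES[j],
         purity = m[cbind(seq_len(nrow(m)), j)] / depth)
}

#' Call homozygous parent-versus-reference SNP markers
#'
#' A site becomes a marker iff its depth reaches `min_depth`, its major
#' base accounts for at least `min_purity` of all observations, and the
#' major base differs from the reference. The wild-type allele of the
#' marker is the reference base; the mutant allele is the major base.
#' Thresholds are inclusive: a site at exactly `min_depth` reads or
#' exactly `min_purity` purity passes.
#'
#' Raising `min_depth` or `min_purity` can only shrink the call set.
#'
#' @param sites A base-count tibble sorted by `(chrom, pos)` with no
#'   duplicated positions.
#' @param min_depth Minimum site depth (default 10 reads).
#' @param min_purity Minimum major-allele fraction (default 0.90).
#' @return A tibble `chrom, pos, wt_allele, mut_allele, depth, purity`
#'   with one row per called marker, in genome order.
#' @examples
#' sim_example_sites() |> call_parent_snps()
#' @export
call_parent_snps <- function(sites, min_depth = 10, min_purity = 0.90) {
  stopifnot(min_depth >= 1, min_purity > 0, min_purity <= 1)
  check_sorted_unique(sites, "sites")
  scored <- site_purity(sites)
  scored |>
    filter(.data$depth >= min_depth,
           .data$purity >= min_purity,
           .data$major_base != .data$ref) |>
    mutate(wt_allele = .data$ref, mut_allele = .data$major_base) |>
    select("chrom", "pos", "wt_allele", "mut_allele", "depth", "purity")
}

check_sorted_unique <- function(df, what) {
  grouped <- split(df$pos, df$chrom)
  for (ch in names(grouped)) {
    p <- grouped[[ch]]
    if (is.unsorted(p, strictly = FALSE)) {
      abort(sprintf("%s must be sorted by position within chromosome (%s)",
                    what, ch), class = "bsascan_validation_error")
    }
    if (anyDuplicated(p)) {
      abort(sprintf("%s has duplicated positions on %s", what, ch),
            class = "bsascan_validation_error")
    }
  }
  invisible(df)
}
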