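#' Chi-square goodness-of-fit test for segregation ratios
#'
#' Tests observed phenotype class counts against a Mendelian expected
#' ratio (1:1 for a backcross, 3:1 for an F2 recessive, ...). Expected
#' counts are `total * ratio_k / sum(ratio)`; the statistic is
#' `sum((obs - exp)^2 / exp)` with no continuity correction, on
#' `classes - 1` degrees of freedom, with the upper-tail chi-square
#' p-value (via [stats::chisq.test()]). The statistic is invariant under
#' scaling of the ratio (1:1 is the same test as 2:2).
#'
#' @param observed Integer vector of class counts (at least 2 classes,
#'   positive total).
#' @param ratio Positive numeric vector of expected proportions, same
#'   length as `observed`; e.g. `c(3, 1)`.
#' @return An object of class `seg_test` with fields `observed`,
#'   `expected`, `ratio`, `chi2`, `df` and `p`. `tidy()` and `glance()`
#'   return one-row tibbles; `print()` shows the statistic rounded
#'   half-up to 3 decimals, the convention used for reported segregation
#'   tables.
#' @examples
#' segregation_test(c(218, 194), c(1, 1))   # BC1, chi2 = 1.398
#' segregation_test(c(1661, 503), c(3, 1))  # F2,  chi2 = 3.559
#' @export
segregation_test <- function(observed, ratio) {
  stopifnot(length(observed) >= 2, length(ratio) == length(observed),
            sum(observed) > 0)
  if (any(ratio <= 0)) {
    abort("segregation_test: expected ratio classes must be positive",
          class = "bsascan_validation_error")
  }
  ht <- stats::chisq.test(observed, p = ratio / sum(ratio))
  structure(list(observed = as.integer(observed),
                 expected = as.double(ht$expected),
                 ratio = ratio,
                 chi2 = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = unname(ht$p.value)),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("Segregation goodness-of-fit: %s vs ratio %s\n",
              paste(x$observed, collapse = ":"),
              paste(x$ratio, collapse = ":")))
  cat(sprintf("  chi2 = %.3f on %d df, p = %.4g\n",
              round_half_up(x$chi2, 3), x$df, x$p))
  invisible(x)
}

#' @rdname segregation_test
#' @param x A `seg_test` object.
#' @param ... Unused.
#' @method tidy seg_test
#' @export
tidy.seg_test <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p,
         n = sum(x$observed))
}

#' @rdname segregation_test
#' @method glance seg_test
#' @export
glance.seg_test <- function(x, ...) tidy(x)

#' Expected bulk mutant-allele frequency under a cross design
#'
#' @param design A [cross_design()].
#' @param locus `"unlinked"` (loci segregating independently of the
#'   selected trait) or `"causal"` (the selected locus, fixed in the
#'   bulk).
#' @return The expected mutant-allele frequency: 0.75 / 1.0 for a BC1
#'   bulk, 0.5 / 1.0 for an F2 recessive bulk.
#' @examples
#' expected_bulk_allele_freq(cross_design("bc1_mutant"), "unlinked")
#' @export
expected_bulk_allele_freq <- function(design,
                                      locus = c("unlinked", "causal")) {
  stopifnot(inherits(design, "cross_design"))
  locus <- match.arg(locus)
  if (locus == "causal") design$causal_freq else design$null_freq
}

#' Sequencing fold coverage
#'
#' Total sequenced bases divided by genome size, rounded half-up to one
#' decimal — the convention used when reporting resequencing yield as
#' genome folds.
#'
#' @param total_bases Total sequenced bases (bp).
#' @param genome_size Genome size (bp); must be positive.
#' @return Fold coverage, one decimal.
#' @examples
#' fold_coverage(94.7e9, 2.5e9)  # 37.9
#' @export
fold_coverage <- function(total_bases, genome_size) {
  if (any(genome_size <= 0)) {
    abort("fold_coverage: genome_size must be positive",
          class = "bsascan_validation_error")
  }
  round_half_up(total_bases / genome_size, 1)
}

# round() in R rounds half to even; reported statistics use half-up
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5) / 10^digits
}
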