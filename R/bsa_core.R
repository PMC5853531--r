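#' Mapping-population cross design
#'
#' The cross design fixes the expected mutant-allele frequency in a
#' phenotype-selected bulk. For a BC1 backcross to the mutant parent, every
#' individual carries at least one mutant haplotype, so at loci unlinked to
#' the causal gene the selected bulk is half heterozygous and half
#' homozygous mutant: expected mutant-allele frequency 0.75. For an F2 with
#' a recessive trait, selection does not shift unlinked frequencies: 0.5.
#' At the causal locus every selected individual is homozygous mutant, so
#' the frequency is 1 in both designs.
#'
#' @param kind `"bc1_mutant"` (BC1 to the mutant parent) or
#'   `"f2_recessive"`.
#' @return An object of class `cross_design` with fields `kind`,
#'   `null_freq` and `causal_freq`.
#' @examples
#' cross_design("bc1_mutant")
#' @export
cross_design <- function(kind = c("bc1_mutant", "f2_recessive")) {
  kind <- match.arg(kind)
  null_freq <- switch(kind, bc1_mutant = 0.75, f2_recessive = 0.5)
  structure(list(kind = kind, null_freq = null_freq, causal_freq = 1.0),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf(
    "<cross_design: %s>  null mutant-allele freq %.2f, causal freq %.2f\n",
    x$kind, x$null_freq, x$causal_freq))
  invisible(x)
}

#' Pool consecutive SNPs into blocks of a minimum read depth
#'
#' Individual SNP sites in a ~10x pool are too shallow to test on their
#' own, so consecutive sites are pooled left to right: a block starts at
#' the first unassigned SNP and absorbs following SNPs until the pooled
#' informative depth (`wt_count + mut_count`; non-parental `other_count`
#' reads are excluded) reaches `min_block_depth`, then closes. A trailing
#' run that never reaches the minimum is discarded. Blocks never span
#' chromosomes and every SNP belongs to at most one block.
#'
#' @param bulk A bulk-count tibble ([read_bulk_counts()] layout), sorted by
#'   position within chromosome.
#' @param min_block_depth Minimum pooled `wt + mut` depth per block
#'   (default 20 reads).
#' @return A tibble `chrom, start_pos, end_pos, n_snps, mut_reads,
#'   wt_reads, depth`, with attribute `"discarded"`: a tibble
#'   `chrom, n_snps, depth` counting trailing SNPs that did not reach the
#'   minimum depth. Pooling conserves reads: block depths plus discarded
#'   depth equal the total input `wt + mut` depth.
#' @export
build_blocks <- function(bulk, min_block_depth = 20) {
  stopifnot(min_block_depth >= 1)
  check_sorted_unique(bulk, "bulk sites")
  per_chrom <- function(df) {
    d <- df$wt_count + df$mut_count
    n <- length(d)
    block_id <- integer(n)
    id <- 1L
    acc <- 0
    for (i in seq_len(n)) {
      block_id[i] <- id
      acc <- acc + d[i]
      if (acc >= min_block_depth) {
        id <- id + 1L
        acc <- 0
      }
    }
    complete <- if (acc > 0 && acc < min_block_depth) id - 1L else id
    keep <- block_id <= complete
    blocks <- tibble(block_id = block_id[keep], pos = df$pos[keep],
                     wt = df$wt_count[keep], mut = df$mut_count[keep]) |>
      group_by(.data$block_id) |>
      summarise(start_pos = dplyr::first(.data$pos),
                end_pos = dplyr::last(.data$pos),
                n_snps = dplyr::n(), mut_reads = sum(.data$mut),
                wt_reads = sum(.data$wt), .groups = "drop") |>
      select(-"block_id") |>
      mutate(depth = .data$mut_reads + .data$wt_reads)
    list(blocks = blocks,
         discarded = tibble(n_snps = sum(!keep), depth = sum(d[!keep])))
  }
  chroms <- unique(bulk$chrom)
  res <- purrr::map(chroms, function(ch) per_chrom(bulk[bulk$chrom == ch, ]))
  blocks <- bind_rows(purrr::map2(res, chroms, function(r, ch) {
    mutate(r$blocks, chrom = ch, .before = 1)
  }))
  discarded <- bind_rows(purrr::map2(res, chroms, function(r, ch) {
    mutate(r$discarded, chrom = ch, .before = 1)
  }))
  attr(blocks, "discarded") <- discarded
  blocks
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Standard two-sided Fisher: the p-value sums the hypergeometric
#' probabilities, over all tables with the observed margins, of every table
#' whose probability does not exceed that of the observed table. Computed
#' by [stats::fisher.test()].
#'
#' @param tbl A 2x2 matrix of non-negative integer counts with at least
#'   one positive entry.
#' @return The two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2))   # modal table: p = 1
#' @export
fisher_exact_two_sided <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(identical(dim(tbl), c(2L, 2L)))
  if (any(tbl < 0)) {
    abort("fisher_exact_two_sided: negative entry",
          class = "bsascan_validation_error")
  }
  if (sum(tbl) == 0) {
    abort("fisher_exact_two_sided: all entries zero",
          class = "bsascan_validation_error")
  }
  # a zero margin leaves a single admissible table
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) return(1)
  stats::fisher.test(tbl)$p.value
}

binomial_block_p <- function(mut, depth, null_freq, sidedness) {
  if (sidedness == "greater") {
    stats::pbinom(mut - 1, depth, null_freq, lower.tail = FALSE)
  } else {
    stats::binom.test(mut, depth, p = null_freq)$p.value
  }
}

#' Block p-values against the cross-design null allele frequency
#'
#' Each block's pooled counts are tested against the bulk allele frequency
#' expected at loci unlinked to the causal gene (`design$null_freq`).
#'
#' Two exact tests are available:
#' \describe{
#'   \item{`"binomial"` (default)}{the exact binomial test of `mut_reads`
#'     out of `depth` against `null_freq`. Two-sided by the usual
#'     minimum-likelihood rule, or upper-tail with
#'     `sidedness = "greater"` (the selected bulk can only be enriched for
#'     the mutant allele at the causal locus).}
#'   \item{`"fisher"`}{Fisher's exact test of the observed counts against a
#'     pseudo-observation of the expected counts at the same depth:
#'     `rbind(c(mut, wt), c(round(null_freq * depth), depth - round(...)))`.
#'     Note that at typical pooled depths (20-30 reads) this construction
#'     bounds the attainable per-block -log10(P) near 1.5 even for a pure
#'     mutant block, so the default window threshold of 2 is effectively
#'     unreachable with it; it is provided for comparison and for deeper
#'     pools. See the package vignette.}
#' }
#'
#' p-values are floored at 1e-300 before any log transform downstream.
#'
#' @param blocks A block tibble from [build_blocks()].
#' @param design A [cross_design()].
#' @param test `"binomial"` or `"fisher"`.
#' @param sidedness `"two_sided"` or `"greater"` (binomial test only;
#'   Fisher is two-sided as quoted).
#' @return `blocks` with a `p_value` column appended.
#' @export
block_p_values <- function(blocks, design,
                           test = c("binomial", "fisher"),
                           sidedness = c("two_sided", "greater")) {
  test <- match.arg(test)
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(design, "cross_design"))
  if (any(blocks$depth == 0)) {
    abort("block p-value undefined at zero depth",
          class = "bsascan_validation_error")
  }
  pf <- if (test == "fisher") {
    function(mut, wt) {
      depth <- mut + wt
      e_mut <- round(design$null_freq * depth)
      fisher_exact_two_sided(matrix(c(mut, wt, e_mut, depth - e_mut),
                                    nrow = 2, byrow = TRUE))
    }
  } else {
    function(mut, wt) binomial_block_p(mut, mut + wt, design$null_freq,
                                       sidedness)
  }
  # blocks repeat the same (mut, wt) pairs often; test each pair once
  key <- paste(blocks$mut_reads, blocks$wt_reads)
  uk <- !duplicated(key)
  p_unique <- purrr::map2_dbl(blocks$mut_reads[uk], blocks$wt_reads[uk], pf)
  p <- pmax(p_unique[match(key, key[uk])], 1e-300)
  mutate(blocks, p_value = p)
}
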