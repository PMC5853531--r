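# Independent oracles and tiny fixture builders shared across the suite.

# Exhaustive two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, hypergeometric probability from log-binomial
# coefficients, sum those not exceeding the observed probability (standard
# minimum-likelihood rule, relative tie tolerance 1e-7).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  probs <- exp(lp)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact binomial tail / two-sided p by direct summation of dbinom.
binom_greater_oracle <- function(x, n, p) {
  sum(dbinom(x:n, n, p))
}
binom_two_oracle <- function(x, n, p) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Bulk-count tibble with the given informative depths, split mut/wt.
make_bulk <- function(depths, mut = depths, chrom = "chr1",
                      pos = seq_along(depths) * 100L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 wt_allele = "A", mut_allele = "G",
                 wt_count = as.integer(depths - mut),
                 mut_count = as.integer(mut), other_count = 0L)
}

# Base-count tibble from a named list of count vectors.
make_sites <- function(ref, A = 0, C = 0, G = 0, T = 0, other = 0,
                       chrom = "chr1", pos = seq_along(ref) * 10L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                 count_A = as.integer(rep_len(A, length(ref))),
                 count_C = as.integer(rep_len(C, length(ref))),
                 count_G = as.integer(rep_len(G, length(ref))),
                 count_T = as.integer(rep_len(T, length(ref))),
                 count_other = as.integer(rep_len(other, length(ref))))
}

# A small single-chromosome simulation scenario for fast tests.
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(layout = tibble::tibble(chrom = "chr1", length = 30e6),
         causal_chrom = "chr1", causal_pos = 15e6, n_progeny = 80,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}
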