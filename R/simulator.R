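#' Simulation configuration for a BSA-seq experiment
#'
#' Bundles the genetic and sequencing parameters of a simulated
#' bulked-segregant experiment. The defaults emulate a desk-scale version
#' of a backcross mapping design: a 150 Mb genome in 5 chromosomes,
#' parental SNP markers every 10 kb on average, 120 BC1 progeny from which
#' a 28-individual mutant bulk is drawn, pooled sequencing at a mean of
#' 10 reads per SNP site with a 1% per-read miscall rate, and a
#' recombination rate of 2e-8 crossovers/bp/meiosis (2 cM/Mb, a typical
#' plant genome-wide average).
#'
#' @param layout Genome layout tibble `chrom, length`.
#' @param snp_spacing Mean bp between parental SNPs (homogeneous Poisson
#'   placement).
#' @param n_progeny Number of progeny in the mapping population.
#' @param bulk_size Number of phenotype-selected individuals pooled
#'   (default 28).
#' @param design A [cross_design()].
#' @param causal_chrom,causal_pos Location of the planted causal SNP.
#' @param recomb_rate Crossovers per bp per meiosis (default 2e-8).
#' @param mean_depth Expected pooled reads per SNP site (default 10).
#' @param error_rate Per-read base-miscall probability (default 0.01);
#'   miscalls are uniform over the three other bases, so the observed
#'   mutant-allele fraction at true frequency f is
#'   `f (1 - e) + (1 - f) e / 3`.
#' @param seed Integer seed; all randomness in
#'   [simulate_bsa_dataset()] flows from it.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(seed = 1)
#' @export
sim_config <- function(layout = tibble(chrom = paste0("chr", 1:5),
                                       length = rep(30e6, 5)),
                       snp_spacing = 10e3,
                       n_progeny = 120,
                       bulk_size = 28,
                       design = cross_design("bc1_mutant"),
                       causal_chrom = "chr3",
                       causal_pos = 15e6,
                       recomb_rate = 2e-8,
                       mean_depth = 10,
                       error_rate = 0.01,
                       seed = 1) {
  stopifnot(inherits(design, "cross_design"),
            snp_spacing > 0, n_progeny >= 1, bulk_size >= 1,
            recomb_rate >= 0, recomb_rate <= 1,
            error_rate >= 0, error_rate <= 1, mean_depth > 0)
  i <- match(causal_chrom, layout$chrom)
  if (is.na(i) || causal_pos < 1 || causal_pos > layout$length[i]) {
    abort("causal locus outside the genome layout",
          class = "bsascan_validation_error")
  }
  structure(list(layout = layout, snp_spacing = snp_spacing,
                 n_progeny = n_progeny, bulk_size = bulk_size,
                 design = design, causal_chrom = causal_chrom,
                 causal_pos = causal_pos, recomb_rate = recomb_rate,
                 mean_depth = mean_depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Place parental SNP markers along the genome
#'
#' SNP positions are drawn per chromosome as a homogeneous Poisson process
#' with the given mean spacing (count ~ Poisson(length / spacing),
#' positions uniform, sorted, deduplicated). Wild-type alleles are drawn
#' uniformly from A/C/G/T and the mutant allele uniformly from the three
#' other bases.
#'
#' @param layout Genome layout tibble `chrom, length`.
#' @param snp_spacing Mean bp between SNPs.
#' @param seed Optional integer seed (scoped; the caller's RNG state is
#'   untouched). When `NULL`, the current RNG stream is used.
#' @return A parent-SNP tibble `chrom, pos, wt_allele, mut_allele, depth,
#'   purity` (synthetic parent depth ~ Poisson(38), purity 1).
#' @export
place_snps <- function(layout, snp_spacing, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  one <- function(ch, L) {
    n <- rpois(1, L / snp_spacing)
    pos <- sort(unique(ceiling(runif(n) * L)))
    n <- length(pos)
    wt <- sample(BASES, n, replace = TRUE)
    shift <- sample.int(3, n, replace = TRUE)
    mut <- BASES[(match(wt, BASES) - 1 + shift) %% 4 + 1]
    tibble(chrom = ch, pos = as.integer(pos), wt_allele = wt,
           mut_allele = mut, depth = rpois(n, 38), purity = 1)
  }
  bind_rows(purrr::map2(layout$chrom, layout$length, one))
}

#' Simulate recombinant progeny genotypes
#'
#' Each F1 gamete is built per chromosome by drawing a Poisson number of
#' crossovers (rate `recomb_rate` x chromosome length), placing them
#' uniformly, and alternating parental origin from a fair starting draw
#' (no interference). A BC1 individual is one F1 gamete plus the
#' recurrent mutant-parent haplotype, so it carries 1 or 2 mutant copies
#' at every SNP; an F2 individual is two independent F1 gametes. The
#' phenotype is mutant iff the individual is homozygous mutant at the
#' causal locus (recessive trait).
#'
#' @param snps Parent-SNP tibble from [place_snps()] (must contain a SNP
#'   at the causal locus).
#' @param config A [sim_config()].
#' @inheritParams place_snps
#' @return A list with `genotypes` (integer matrix, individuals x SNPs,
#'   mutant-allele copies 0/1/2) and `phenotype` (character,
#'   `"mutant"`/`"wild"`).
#' @export
simulate_progeny <- function(snps, config, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  causal_idx <- which(snps$chrom == config$causal_chrom &
                        snps$pos == config$causal_pos)
  if (length(causal_idx) != 1) {
    abort("snps must contain exactly one SNP at the causal locus",
          class = "bsascan_validation_error")
  }
  chroms <- config$layout$chrom
  lens <- setNames(config$layout$length, chroms)
  pos_by_chrom <- split(seq_len(nrow(snps)), snps$chrom)

  gamete <- function() {
    origin <- integer(nrow(snps))
    for (ch in names(pos_by_chrom)) {
      idx <- pos_by_chrom[[ch]]
      L <- lens[[ch]]
      n_x <- rpois(1, config$recomb_rate * L)
      start <- rbinom(1, 1, 0.5)
      if (n_x == 0) {
        origin[idx] <- start
      } else {
        breaks <- sort(runif(n_x) * L)
        seg <- findInterval(snps$pos[idx], breaks)
        origin[idx] <- (start + seg) %% 2
      }
    }
    origin  # 1 = mutant-parent allele
  }
  n <- config$n_progeny
  geno <- matrix(0L, nrow = n, ncol = nrow(snps))
  for (i in seq_len(n)) {
    geno[i, ] <- if (config$design$kind == "bc1_mutant") {
      1L + gamete()
    } else {
      gamete() + gamete()
    }
  }
  list(genotypes = geno,
       phenotype = ifelse(geno[, causal_idx] == 2L, "mutant", "wild"),
       causal_idx = causal_idx)
}

#' Pool a bulk and draw sequencing read counts
#'
#' The bulk is an equal-weight pool of `bulk_size` individuals (DNA
#' bulked in equal ratio): the true bulk mutant-allele frequency at each
#' SNP is the mean mutant-copy dosage over bulk members divided by 2.
#' Per-site depth is Poisson(`mean_depth`), independent across sites;
#' each read reports the mutant allele with probability
#' `f (1 - e) + (1 - f) e / 3`, the wild-type allele with the symmetric
#' expression, and some other base otherwise (uniform miscall model).
#'
#' @param progeny Output of [simulate_progeny()].
#' @param snps The SNP tibble the genotypes refer to.
#' @param config A [sim_config()].
#' @param select `"mutant"`: bulk drawn from mutant-phenotype individuals
#'   (errors if fewer than `bulk_size` are available — increase
#'   `n_progeny`); `"random"`: drawn from all progeny ignoring phenotype
#'   (a null bulk for calibration).
#' @inheritParams place_snps
#' @return A list with `bulk` (tibble in [read_bulk_counts()] layout) and
#'   `truth` (tibble `chrom, pos, true_freq, is_causal` recording the
#'   exact bulk allele frequency before sequencing noise).
#' @export
make_bulk_counts <- function(progeny, snps, config, seed = NULL,
                             select = c("mutant", "random")) {
  if (!is.null(seed)) withr::local_seed(seed)
  select <- match.arg(select)
  pool_from <- if (select == "mutant") {
    which(progeny$phenotype == "mutant")
  } else {
    seq_along(progeny$phenotype)
  }
  if (length(pool_from) < config$bulk_size) {
    abort(sprintf(paste0(
      "only %d individuals available for a bulk of %d; ",
      "increase n_progeny"), length(pool_from), config$bulk_size),
      class = "bsascan_validation_error")
  }
  members <- sample(pool_from, config$bulk_size)
  f <- colSums(progeny$genotypes[members, , drop = FALSE]) /
    (2 * config$bulk_size)
  e <- config$error_rate
  p_mut <- f * (1 - e) + (1 - f) * e / 3
  p_wt <- (1 - f) * (1 - e) + f * e / 3
  n <- nrow(snps)
  depth <- rpois(n, config$mean_depth)
  mut <- rbinom(n, depth, p_mut)
  rest <- depth - mut
  wt <- rbinom(n, rest, ifelse(p_mut < 1, p_wt / (1 - p_mut), 0))
  bulk <- tibble(chrom = snps$chrom, pos = snps$pos,
                 wt_allele = snps$wt_allele, mut_allele = snps$mut_allele,
                 wt_count = as.integer(wt), mut_count = as.integer(mut),
                 other_count = as.integer(rest - wt))
  truth <- tibble(chrom = snps$chrom, pos = snps$pos, true_freq = f,
                  is_causal = seq_len(n) == progeny$causal_idx)
  list(bulk = bulk, truth = truth)
}

#' Simulate a complete BSA-seq dataset
#'
#' Runs the full generative chain — SNP placement (a SNP is planted at
#' the causal locus if the random placement missed it), progeny
#' recombination, bulk selection, pooled read sampling — from the single
#' seed in `config`. Identical configs give byte-identical output files.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `snps.tsv`,
#'   `bulk_counts.tsv`, `genome.tsv` and `truth.tsv` there.
#' @param select Bulk selection mode, see [make_bulk_counts()].
#' @return A list with tibbles `snps`, `bulk`, `layout`, `truth`, plus
#'   `progeny` (genotypes and phenotypes) and `config`.
#' @examples
#' \donttest{
#' sim <- simulate_bsa_dataset(sim_config(seed = 7))
#' dplyr::filter(sim$truth, is_causal)$true_freq  # exactly 1
#' }
#' @export
simulate_bsa_dataset <- function(config, out_dir = NULL,
                                 select = c("mutant", "random")) {
  stopifnot(inherits(config, "sim_config"))
  select <- match.arg(select)
  withr::local_seed(config$seed)
  snps <- place_snps(config$layout, config$snp_spacing)
  if (!any(snps$chrom == config$causal_chrom &
             snps$pos == config$causal_pos)) {
    wt <- sample(BASES, 1)
    causal_row <- tibble(chrom = config$causal_chrom,
                         pos = as.integer(config$causal_pos),
                         wt_allele = wt,
                         mut_allele = sample(setdiff(BASES, wt), 1),
                         depth = rpois(1, 38), purity = 1)
    snps <- arrange(bind_rows(snps, causal_row), .data$chrom, .data$pos)
  }
  progeny <- simulate_progeny(snps, config)
  pooled <- make_bulk_counts(progeny, snps, config, select = select)
  out <- list(snps = snps, bulk = pooled$bulk, layout = config$layout,
              truth = pooled$truth, progeny = progeny, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_parent_snps(snps, file.path(out_dir, "snps.tsv"))
    write_bulk_counts(pooled$bulk, file.path(out_dir, "bulk_counts.tsv"))
    write_genome_layout(config$layout, file.path(out_dir, "genome.tsv"))
    write_tsv_with_header(pooled$truth, file.path(out_dir, "truth.tsv"))
  }
  out
}

#' Tiny deterministic example base-count table
#'
#' Four hand-written sites used in documentation examples: a clean
#' homozygous SNP, a boundary-purity SNP, a homozygous-reference site and
#' a low-depth site.
#'
#' @return A base-count tibble ([read_base_counts()] layout).
#' @export
sim_example_sites <- function() {
  tibble(chrom = "chr1", pos = c(101L, 205L, 310L, 420L),
         ref = c("A", "A", "C", "G"),
         count_A = c(0L, 1L, 1L, 0L), count_C = c(0L, 0L, 14L, 0L),
         count_G = c(12L, 11L, 0L, 4L), count_T = c(0L, 0L, 0L, 1L),
         count_other = c(0L, 0L, 0L, 0L))
}
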