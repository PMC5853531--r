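---
title: "Mapping recessive loci by pooled-sequencing bulked segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive loci by pooled-sequencing bulked segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The experimental design and its statistics

A recessive mutant is crossed to a wild-type line; the F1 is backcrossed
to the mutant parent to produce a BC1 population (or selfed to produce an
F2). Individuals showing the mutant phenotype are pooled in equal ratio
and the pool is resequenced at modest depth alongside the mutant parent.

The key observation is Mendelian. In a BC1 to the mutant parent, every
individual inherits one complete mutant haplotype; the other haplotype is
an F1 gamete that carries the mutant allele with probability ½ at any
locus. Selecting mutant-phenotype individuals forces homozygosity at the
causal locus, so the expected mutant-allele frequency in the selected
bulk is

* 1.0 at the causal locus and at loci tightly linked to it,
* 0.75 at unlinked loci (half heterozygous, half homozygous mutant),

decaying between the two with map distance. For an F2 recessive bulk the
null is 0.5. `cross_design()` fixes these two frequencies and every
downstream test inherits them. The scan looks for genomic intervals where
the pooled reads are significantly enriched for the mutant parent's
alleles beyond the 0.75 baseline.

## From base counts to markers

Parent markers are homozygous differences between the mutant parent and
the reference: a site qualifies when its read depth is at least 10, its
major allele accounts for at least 90% of all observed alleles, and the
major allele differs from the reference (`call_parent_snps()`). Both
thresholds are inclusive. Two details are worth stating:

* the purity denominator includes non-ACGT observations — an ambiguous
  read is evidence against homozygosity, so this is the conservative
  reading of "fraction of all alleles observed";
* ties between equally frequent bases break in fixed order A < C < G < T,
  making calls deterministic.

Only substitutions are called; indel discovery requires a realigning
caller and is out of scope. Users with variants already in a VCF can
enter through `read_vcf_biallelic_snps()`, which keeps biallelic SNPs at
which the parent is homozygous-alternate and reads the bulk's `AD` field.
Multi-allelic records are skipped, never split, because the method is
defined on exactly two parental alleles.

## Blocks and the exact test

At ~10× pool depth a single SNP cannot distinguish 0.75 from 1.0, so
consecutive SNPs are pooled greedily, left to right, into *blocks* until
the combined informative depth (wild-type + mutant reads; other bases are
excluded — the statistic counts reads attributable to a parental genome)
reaches 20. A trailing run that never reaches 20 is discarded rather than
emitted as an underpowered block. Blocks never span chromosomes. The
minimum is interpreted as pooled block depth, not per-SNP depth: pooling
shallow sites is the reason blocks exist.

Each block is tested against the design null. The default is the exact
binomial test of `mut_reads` out of `depth` against 0.75 (two-sided, by
the minimum-likelihood rule; a one-sided "greater" variant is available
since selection can only enrich the mutant allele at the causal locus).

A Fisher's-exact alternative is provided (`test = "fisher"`): it compares
the observed counts with a pseudo-observation of the expected counts at
the same depth, `rbind(c(mut, wt), c(round(0.75 d), d − round(0.75 d)))`.
We made the binomial the default after a power analysis of the Fisher
construction at realistic block depths. With blocks of 20–30 reads, the
most extreme possible observation (every read mutant) yields a two-sided
Fisher p of only ~0.02–0.05 — a per-block −log₁₀(P) of ~1.3–1.8 —
because the expected row carries as much sampling noise as the observed
row. The window score, an *average* of such values, can therefore never
exceed the threshold of 2, at any true allele frequency. The binomial
test is exactly the limit of the Fisher construction as the expected row
is scaled to infinite depth (a noise-free expectation), and under it a
pure-mutant block of depth 25 scores −log₁₀(P) ≈ 2.6–3.0 while null
blocks average ≈ 0.4, so the threshold of 2 separates the two regimes
cleanly at 10× coverage. Both tests are exposed and both are exercised by
the test suite (the Fisher implementation is verified against exhaustive
hypergeometric enumeration for every 2×2 table with total ≤ 30).

One caveat recorded as a tested property: for an asymmetric null such as
0.75, no exact two-sided p-value is a monotone function of the absolute
deviation |mut/depth − 0.75| — equal-magnitude deviations on opposite
sides carry different probability mass. Monotonicity holds within each
side of the null, and that is the form the package guarantees.

p-values are floored at 1e-300 before log transforms; this protects the
arithmetic and cannot affect threshold decisions.

## The sliding-window scan

Windows of 2 Mb advance in 100 kb steps, anchored at position 1 of every
chromosome (the anchor is arbitrary; fixing it makes runs comparable).
A block joins a window if its midpoint (rounded-down mean of its first
and last SNP) lies inside — midpoint assignment prevents a block
straddling a window edge from being counted twice. The score is the
arithmetic mean of −log₁₀(Pᵢ) over member blocks. Two filters apply, both
strict:

* windows with fewer than 5 blocks are marked `filtered` and can never be
  significant, whatever their score — averages of few blocks are noisy;
* remaining windows are significant only when the score *exceeds* 2
  (a score of exactly 2.0 is not significant).

Windows with no blocks report a missing score, never 0: absence of
markers is not evidence of equality. Significant windows that overlap or
abut merge into candidate regions (`call_candidate_regions()`), each
carrying its peak window score. With 100 kb steps a ~1500-window genome
scan at a per-window false-positive rate far below 1/1500 (the average of
≥5 null blocks essentially never exceeds 2) keeps the genome-wide error
negligible without explicit multiple-testing correction; the fixed
threshold of 2 is the method's calibration and we do not re-derive it.

## Narrowing by sequence origin

All selected BC1 individuals share the mutant parent's haplotype around
the causal locus, so inside a candidate region the bulk reads should be
*exclusively* mutant-derived until the nearest recombination breakpoint
present in the bulk. `narrow_regions()` profiles the per-SNP mutant read
fraction (sites with fewer than 5 informative reads are skipped, not
zeroed) and reports maximal runs of consecutive SNPs with fraction
≥ 0.95, keeping runs of at least 10 SNPs. Literal 100% identity would be
brittle: at 10× depth a single miscalled read drops a site to 0.9, so
the 0.95 cutoff tolerates one error read in deep sites while still
rejecting genuinely heterozygous territory (expected fraction 0.75,
i.e. ≤ 0.9 at depth 10 in ~94% of sites). Shallow skipped sites do not
break runs — missing data is not evidence of recombination. Both
thresholds are exposed (`min_purity`, `min_snps`, `min_site_depth`).

## The simulator

`simulate_bsa_dataset()` generates the complete experiment the scan
expects, with ground truth. Defaults describe the reference scenario used
throughout the test suite and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| genome | 5 chromosomes × 30 Mb | desk-scale stand-in for a large plant genome |
| SNP spacing | 10 kb (Poisson) | ~15,000 markers; parental divergence of a distant intraspecific cross |
| progeny | 120 BC1 | comfortably yields ≥ 28 mutants (expected 60) |
| bulk size | 28 | typical selected-bulk size for a qualitative trait |
| mean pool depth | 10× per SNP site (Poisson) | low-coverage pooled resequencing |
| error rate | 1% per read | post-filtering short-read miscall scale |
| recombination | 2 × 10⁻⁸ /bp/meiosis (2 cM/Mb) | plant genome-wide average order of magnitude |
| causal locus | chr3:15,000,000 | mid-chromosome, so decay is visible on both flanks |

Meiosis is modelled per chromosome as Poisson crossovers placed uniformly
with a fair starting haplotype — no interference, no hotspots. Reads are
drawn per site as Poisson depth and multinomial allele counts with
uniform miscall to the three other bases, so the observed mutant fraction
at true frequency *f* is *f*(1 − *e*) + (1 − *f*)*e*/3. Equal-ratio
pooling is modelled as exactly equal weight per individual.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: alignment and mapping artifacts
(repeats, reference bias), depth autocorrelation along the genome,
variable DNA contributions between pooled individuals, crossover
interference, and genotyping error in the parent SNP set. The recovery
rates measured here are an upper bound on what identical parameters would
achieve on real reads.

Two calibration facts follow from the design and are asserted as
invariants: the truth allele frequency at the causal SNP is exactly 1 in
every mutant-selected bulk, and truly unlinked loci (other chromosomes)
average 0.75. Note that "far on the same chromosome" is not unlinked: a
30 Mb chromosome at 2 cM/Mb spans only 0.6 Morgan, so linkage to a
mid-chromosome locus never fully decays within it.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive (pileup/VCF convention); BED
  output converts to 0-based half-open, a bijection that is tested.
* Exact ties: purity and depth thresholds are ≥; the window score
  threshold and the block-count filter are strict, matching their
  definitions above.
* `round()`-half-even vs half-up: reported χ² (3 decimals) and fold
  coverage (1 decimal) round half-up, the convention of the tables they
  imitate; internal arithmetic is never rounded.
* Zero-depth sites, empty files with headers, empty region sets and
  chromosomes without SNPs are all valid inputs with defined (empty)
  outputs; negative counts, duplicate or unsorted positions, identical
  wild-type/mutant alleles and unknown chromosomes raise typed errors.
* All simulator randomness flows from one integer seed through scoped
  RNG (`withr`), so identical configurations produce byte-identical
  files and the caller's RNG state is never disturbed.

## Scale of the validation runs

The bundled tests and the acceptance script run the reference scenario at
10 seeds per experiment (recovery and null calibration) and 20 seeds for
decay and origin-purity properties; a full suite completes in about two
minutes on one CPU. These sizes give binomial confidence adequate for
the pass criteria (e.g. ≥ 9/10 recoveries) while keeping the package
pleasant to check.

## Known limitations

* One bulk per trait: two-bulk contrasts (mutant vs wild pools) and
  Δ(SNP-index)-style statistics are not implemented.
* The fixed threshold of 2 is inherited from the method's calibration;
  no FDR machinery is provided, and very dense marker sets with deep
  pools may warrant a higher threshold.
* Indel markers, read-level simulation (FASTQ/BAM), and alignment are out
  of scope; inputs are count tables or a VCF with allele depths.
* The Fisher block test is retained for comparison but is underpowered at
  shallow pool depths, as analysed above; use it only with block depths
  well above ~50.
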