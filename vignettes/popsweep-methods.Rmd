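---
title: "Methods: sweep screening, mixed-model association and marker statistics in popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep screening, mixed-model association and marker statistics in popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

# Scope and model

`popsweep` implements the computational chain of a two-population
("tall-legged" TL vs "short-legged" SL) whole-genome resequencing study of
a quantitative trait, leg length, defined throughout as body height minus
chest depth in cm. The chain is: SNP quality control and
functional-consequence annotation; population structure by genotype
p-distance neighbor-joining and PCA; sliding-window Fst and nucleotide
diversity with a joint top-percentile sweep screen; mixed-linear-model
(MLM) association with a genomic kinship matrix; hypergeometric term
enrichment; and candidate-marker statistics with PCR-RFLP assay design.
Because no public cohort accompanies the design, a Balding-Nichols
simulator generates data with the statistical structure every stage
assumes, and all validation is against either printed, recomputable
numbers or independent oracles.

# Quality control (`filter_variants`)

Variants pass, in order: site quality >= 20, read support >= 4,
minor-allele frequency >= 0.05 (over non-missing calls, cohort-wide,
since filtering precedes any group split), missingness <= 0.1. All
thresholds are inclusive, and a removed variant is attributed to the
*first* rule it fails, so the report's per-rule counts always sum to
`n_input - n_pass`. "Read support" is a caller-level flag that cannot be
reconstructed from a VCF; we interpret it as mean per-sample depth at the
site, the closest site-level analogue, with a `support_mode = "site"`
switch for the total-depth reading. MAF is computed on the analysis
cohort, not per population.

# Population structure

**p-distance.** For two diploid individuals at one biallelic site the
dissimilarity is 0 for identical homozygotes, 1 for opposite homozygotes,
and 0.5 whenever a heterozygote is involved - including the
heterozygote-heterozygote pair, which scores 0.5, not 0 (two random
gametes from AC x AC differ half the time). A practical consequence worth
knowing: two individuals with identical calls do not sit at distance 0
unless they are homozygous everywhere. Pairs are averaged over the loci
non-missing in *both* individuals (pairwise deletion), and the per-pair
locus count is retained so sparse pairs can be inspected.

**Neighbor joining.** Saitou-Nei NJ with deterministic tie-breaking
(lowest row/column index in the Q matrix). Negative branch lengths, a
known artifact of NJ on noisy distances, are clamped to zero with the
deficit moved to the sibling branch so path lengths are preserved; each
clamp is logged. Bootstrap support resamples variant columns with
replacement and reports, per internal bipartition of the full-data tree,
the fraction of replicate trees containing it.

**PCA.** Genotypes are standardized per variant as
`(d - E(d)) / sqrt((E(d)/2)(1 - E(d)/2) * 2)` - the usual
allele-frequency normalization `sqrt(2 p (1 - p))` with `p = E(d)/2` -
with missing calls imputed to the variant mean (zero after centering) and
monomorphic variants dropped. The sample covariance is `X = M M' / S`
(`S` = number of variants) and coordinates are eigenvectors of `X`. For
calls (0, 1, 2) at one variant the standardized values are
±1/sqrt(0.5) ≈ ±1.414; a circulating variant of this formula with
`1 - E/4` in place of `1 - E/2` (giving ±1.155) is an arithmetic slip,
not a different estimator, and we use the community-standard form.

# Sweep screening

Windows are 100 kb with a 50 kb step (50% overlap), truncated at
chromosome ends, so a chromosome of length L yields
`floor((L-1)/step) + 1` windows.

**Fst** is Weir & Cockerham (1984): per-site variance components a
(between populations), b (between individuals within populations) and c
(within individuals) are accumulated over the window and combined as the
weighted ratio of sums `sum(a) / sum(a+b+c)` - the vcftools windowed
convention. Negative estimates (sampling noise around zero
differentiation) are reported as computed.

**Nucleotide diversity** per site is
`c_ref * c_alt / choose(n_chr, 2)` over non-missing chromosomes, summed
over the window and divided by the window length in bp, so monomorphic
and uncovered positions contribute zero (again the vcftools convention).

**Joint screen.** A window is selected for a focal population when its
Fst and its diversity statistic both sit at or above their genome-wide
95th percentiles (linear-interpolation quantiles, pooled across
chromosomes). Published "top 5% of both" descriptions leave the direction
of the diversity ranking open; the default statistic is
`log2(pi_other / pi_focal)`, so *depleted* diversity in the focal
population ranks high - the classic sweep signature - with a `"raw"` mode
(rank by low focal diversity directly) selectable. Zero-diversity windows
receive a pseudocount of 1% of the smallest nonzero value (logged), and
windows with fewer than 5 usable SNPs are excluded from ranking
(configurable). Under independent null statistics the screen selects
about `0.05^2 = 0.25%` of windows, which the test suite verifies.
Thresholds are computed per focal direction, not shared.

# Mixed-model association

The MLM is `y = X alpha + x beta + u + e` with `u ~ (0, sigma_g^2 K)`,
`e ~ (0, sigma_e^2 I)` and `K = W W' / p` the centered genomic
relationship matrix. `K` is eigendecomposed once; the restricted
likelihood of `lambda = sigma_g^2 / sigma_e^2` is profiled on a grid over
`log10(lambda) in [-5, 5]` with local refinement, under the
covariates-only null model, and that `lambda` is reused for every SNP -
the standard genome-scale approximation, with exact per-SNP
re-optimization behind `per_snp_lambda = TRUE`. Each SNP is then tested
by generalized least squares with a Wald F statistic on `(1, n - q - 1)`
degrees of freedom, so with `K = I` (or as `sigma_g^2 -> 0`) the p-values
coincide with per-SNP ordinary least squares exactly - a property the
acceptance tests check to 1e-6 - and the null type-I error at 0.05 is
exact under normality. Missing genotypes are mean-imputed per SNP,
monomorphic SNPs are skipped with `NA`, the genome-wide threshold is
Bonferroni `alpha / N`, and the genomic-control inflation factor
`lambda_GC = median(chi2_1(p)) / 0.4549` is reported with a Q-Q table. A
"structure matrix" of covariates (e.g. top PCs) can be supplied; it is
treated as fixed-effect columns.

# Marker statistics and genotype association

For a biallelic locus with genotype counts `(n_AA, n_Aa, n_aa)`:
`p = (2 n_AA + n_Aa) / 2n`, homozygosity `Ho = p^2 + q^2`,
heterozygosity `He = 1 - Ho`, effective allele number `Ne = 1 / Ho`, and
`PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` (the general multi-allele form is
implemented; all study loci are biallelic). The Hardy-Weinberg chi-square
uses expected counts from the sample allele frequencies with *no*
continuity correction and df = 1 - verified to reproduce the published
2.73 from counts 16/114/119; a Yates-corrected statistic would not.

Genotype-phenotype association is a one-way fixed-effect ANOVA
(`y = mu + G_k + e`) followed by pairwise comparisons under two
procedures: LSD (pooled-variance t on the residual df) and Dunnett's T3
(Welch t per pair). The studentized maximum modulus distribution behind
exact T3 critical values has no base-R implementation, so T3 p-values use
the standard independence bound `1 - (2 P(T <= |t|) - 1)^C` over the `C`
comparisons, which is mildly conservative. Group means carry
significance letters at p < 0.05, assigned by maximal-clique cover of the
non-significance graph with letters ordered by ascending mean; tables
report mean ± SD by default (SE selectable). Note that with three groups
and unadjusted LSD p-values, the chance that *no* pair is flagged under
the null is about 0.88, not 0.95 - the calibration test therefore asserts
the multiplicity-adjusted T3 procedure.

# Enrichment and RFLP design

Term enrichment is the exact hypergeometric upper tail `P(X >= k)` of
`k` selected genes in a term of size `n`, drawing `K` from a universe of
`N`. The universe defaults to all genes in the supplied annotation. Raw
p-values with a p < 0.05 flag are primary, matching common practice in
this literature; Benjamini-Hochberg adjustment is available and
recommended when many terms are tested. Because the test is discrete,
the realized null flag rate is below the nominal 5% for small terms (about
3% at the fixture sizes used in the tests).

PCR-RFLP design substitutes each allele into the amplicon, scans for
IUPAC-ambiguous recognition motifs (forward strand by default; most RFLP
motifs are palindromic, and reverse-strand scanning is a flag), and
reports cut coordinates as bases-to-the-left-of-the-cut. An enzyme is
usable when its site count differs between alleles. The heterozygote
pattern is the multiset union of the two homozygote digests, matching gel
interpretation; fragments always sum to the amplicon length.

# The simulator: what it emulates and what it does not

`sim_config()` defaults *are* the stated world of the emulated study
design: 15 + 15 samples (expandable to 125 + 125 for power checks), two
5 Mb chromosomes with 20,000 independent SNPs, background Fst 0.03
(within the weak-differentiation range where >95% of windows fall below
Fst 0.05), three 200 kb sweep regions focal in SL with differentiation
boost 0.9, and one causal SNP of 3 cm per alt allele against a residual
SD of 1 cm. Choices the design leaves open were fixed once, before any
acceptance measurement: ancestral frequencies Uniform(0.05, 0.95)
(avoiding rare-allele degeneracy under the 0.05 MAF filter) with the
causal site at 0.5 so it segregates in both groups; chest depth
N(30, 1.5) cm and height = chest depth + leg length, since only the
difference is defined; per-sample depth Poisson(8), near the emulated
~8x coverage; site quality Uniform(50, 999); 2% missingness. The sweep
boost moves the focal population's frequency a fraction `boost` of the
way toward the nearest fixed state, which simultaneously raises Fst and
depletes focal diversity; `boost = 1` forces fixation.

The simulator draws *independent* sites: no linkage disequilibrium,
recombination maps, coalescent ancestry or selection dynamics. A green
recovery test therefore establishes that the estimators and the screen
work on data satisfying their own assumptions - it does not establish
power on real genomes, where LD widens sweep footprints and inflates the
effective number of independent tests. Phenotypes are single-locus
additive with Gaussian noise; polygenic background is emulated only
through the kinship term in the analysis, not the generator.

# Numerical and design choices

* One RNG stream seeded once per simulation; the pipeline derives
  per-stage seeds from the global seed. Identical configs give
  byte-identical output files (the VCF/GFF3 writers are package code for
  exactly this reason; parsing uses Bioconductor infrastructure).
* Quantiles are R type-7 (linear interpolation); NJ ties break on the
  lowest index pair; letters assignment is deterministic.
* Windowed estimators return `NA` (not 0) when a window has no usable
  SNP; zero-diversity windows entering a log-ratio receive a logged
  pseudocount.
* The annotation classifier resolves one category per variant with
  precedence Exonic > Splicing > Intronic > Upstream/Downstream >
  Upstream > Downstream > Intergenic; "Exonic" means overlapping a
  *coding* exon, flanks are strand-aware 1 kb beyond the transcript span,
  and splice windows are the first/last 2 bp of each intron. Summary
  percentages take an explicit denominator because published totals can
  exceed the sum of printed component rows.
* Bonferroni uses the number of SNPs actually tested.

# Known limitations

Exonic sub-classification assumes single-nucleotide substitutions and
complete codons (a trailing partial codon is reported as synonymous with
a warning upstream). T3 p-values are bounds, not exact SMM quantiles.
The NJ implementation is quadratic-per-join and intended for cohort-scale
(tens to low hundreds of samples) trees. The MLM's EMMAX-style shared
`lambda` slightly misestimates per-SNP variance for very large effects;
the exact mode exists but is slower. Enrichment takes flat term files
and does no ontology-graph propagation.
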