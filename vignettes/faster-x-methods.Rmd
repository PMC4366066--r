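---
title: "Methods: faster-X analysis of expression and protein-coding divergence"
author: "fasterX package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: faster-X analysis of expression and protein-coding divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasterX)
```

## The scientific question

In XY systems, population-genetic theory predicts that X-linked genes can
diverge faster than autosomal genes ("faster-X"): beneficial recessive
mutations are exposed to selection in hemizygous males, and the X's reduced
effective population size (3/4 of the autosomal value at an equal sex
ratio, since the population carries `2F + M` X copies against `2(F + M)`
autosomal copies; see `chromosomeCopyAccounting()`) increases drift.  The
effect is expected to be strongest in male-biased genes (MBGs).  But
X-linked and autosomal genes also differ systematically in expression
level, tissue specificity and the number of protein interactions — all of
which correlate with evolutionary rate.  The analyses in this package ask
whether an X-vs-autosome difference in divergence survives after those
properties are controlled for, using two complementary adjustments: a
standardized multiple regression with rank tests on its residuals, and a
distribution-free matched comparison inside combined covariate deciles.

## Per-gene properties

* **Expression level** is the unweighted mean of the two species' mean
  log2 signals; **expression divergence** is the absolute difference of
  the species means; **expression polymorphism** is the pooled
  within-species standard deviation (per-species denominators `n - 1`,
  pooled by degrees of freedom).  These definitions are deliberately
  simple, symmetric in the species, and exactly recoverable by the
  synthetic-data generator; the divergence/polymorphism estimators used to
  build any particular published dataset may differ in detail, so
  `summarizeExpression()` is the package default, not a claim of identity.
* **Tissue specificity** is the tau index over an `N`-tissue expression
  atlas: `tau = sum_i (1 - x_i / max(x)) / (N - 1)`; 0 for uniform
  expression, 1 for single-tissue expression, scale-invariant.
* **Sex bias** is a threshold classification on log2(male) - log2(female):
  MBG above `+threshold`, FBG below `-threshold`, NBG otherwise.  The
  default threshold of 1 (2-fold) involves no significance filter, so it
  is reproducible without replicate-level variance assumptions; it is an
  argument, not a constant.

## Divergence estimation

Two estimators share one QC path (`validateCds()`: terminal stop codons
trimmed, internal stop codons fatal for the gene, codons containing `N` or
`-` excluded pairwise).

**NG86 counting.**  Synonymous/nonsynonymous site counts per codon
(single-nucleotide changes to stop codons excluded from both classes) are
averaged over the two sequences; differences at multi-hit codons are
averaged over all minimal mutational pathways, excluding pathways through
stop codons; proportions receive the Jukes-Cantor correction, undefined
above 3/4.  `dS` is exactly 0 when zero synonymous differences are
observed — which makes the zero-synonymous exclusion rule (below) an
observable, estimator-independent criterion.

**Single-ratio codon model ML.**  `gy94ML()` maximizes the pairwise
likelihood over divergence `t` (expected substitutions per codon),
transition/transversion ratio `kappa` and `omega = dN/dS`, under the
codon substitution model in which a single-nucleotide codon change `i -> j`
has rate `pi_j * kappa^[transition] * omega^[nonsynonymous]` and one omega
applies to all sites.  Equilibrium frequencies are F3x4: products of
position-specific nucleotide frequencies estimated from the pair.  The
phrase "average nucleotide frequencies at third codon positions" used in
parts of the literature conflates two constructions; the package defaults
to the standard position-specific F3x4 and exposes
`thirdPositionOnly = TRUE` (third-position frequencies reused at all
positions) as a sensitivity variant.

Numerical choices: transition probabilities come from an
eigendecomposition of the symmetrized reversible generator
`diag(sqrt(pi)) Q diag(1/sqrt(pi))` (with a scaling-and-squaring fallback
if the decomposition degrades); position-specific nucleotide frequencies
are floored at 1e-6 before the product so short alignments cannot make
codons structurally unreachable; optimization is bounded L-BFGS-B in
log-parameter space with three starts (NG86-informed, neutral `omega = 1`,
`omega = 0.1`), bounds `t` in [1e-6, 10], `kappa` in [0.01, 100], `omega`
in [1e-4, 99], and tolerance 1e-8 on the log-likelihood; an identical pair
returns `t` at its lower bound with `dN = dS = 0`.  `dN` and `dS` are
decomposed from `t` using the model's equilibrium synonymous flux, with
site counts defined by the neutral (`omega = 1`) flux — the
mutational-opportunity definition — which preserves `dN/dS = omega`
exactly.

**Gene filters.**  `applyDivergenceFilters()` excludes genes in a fixed
order, each with exactly one primary reason: length error, internal stop
codon, zero observed synonymous changes, `omega >= 9` (inclusive).  The
ordering makes per-reason counts reproducible.  The companion site-level
rule (`consensusSiteFilter()`) retains a site only when read depth
exceeds 7 and phred-scaled consensus quality exceeds 40, both strictly:
depth 7 or quality 40 are masked.

## The statistical battery

All tests default to two-sided (one-sided variants are exposed), and no
multiple-testing correction is applied anywhere; raw P values are
reported.  Mann-Whitney U and Wilcoxon signed-rank use exact null
distributions when the relevant sample size is at most 25 and no ties
(or zeros) interfere, otherwise normal approximations with tie and
continuity corrections; T is reported as the smaller rank sum.  Spearman's
rho is the product-moment correlation of midranks with a t-approximation
P.  P values delegate to `stats::wilcox.test()` / `stats::cor.test()`;
the test suite checks the exact branches against complete enumeration
oracles and the approximate branches against permutation oracles.

`fitStandardizedOls()` z-scores the response and every covariate, so the
slopes are standardized coefficients b\* and `R` is the multiple
correlation; per-coefficient P values are the OLS t tests, which coincide
numerically with partial-correlation tests.  `residualGroupTest()` applies
the Mann-Whitney test to the residuals split X vs A.

`stratifiedXAComparison()` implements the distribution-free adjustment:
each of the three covariates is cut into `n_bins` (default 10) equal-size
rank bins **within the analyzed gene subset** (e.g. within MBGs, matching
how the comparison is used), with stable gene-ID tie-breaking and
remainder genes assigned to the lower bins, so bins are exact and depend
only on ranks (any strictly monotone covariate transform leaves the
comparison unchanged).  Genes are assigned their combined 3-dimensional
category; categories containing both X-linked and autosomal genes
contribute one matched pair of class means; the per-category differences
go into the signed-rank test.  Computing bins within the analyzed subset
(rather than genome-wide before subsetting) is one of two defensible
readings; it is the default because the matched comparison is defined on
the subset being compared.

## The synthetic-data generator

`generateDataset()` emulates the five inputs of the analysis at desk
scale: a gene table with chromosome and sex-bias labels, replicate-level
log2 expression measurements for two species, a gene-by-tissue atlas, an
interaction edge list, and codon-aligned orthologous CDS pairs evolved
under exactly the codon model the estimator fits (Gillespie event
sampling along a single lineage of total length `t`; by reversibility
this is equivalent in distribution to two stationary branches of length
`t/2`).

Default study conditions, chosen once and documented here:

* 16% X-linked genes and a 20/20/60% MBG/FBG/NBG split, the approximate
  composition of a genome-scale Drosophila expression dataset
  (roughly 1,500 X-linked of 9,700 genes; roughly 1,800 MBGs and 5,700
  NBGs of 9,200).
* 25 tissues, the size of the FlyAtlas adult+larval atlas; symmetric
  Dirichlet tissue profiles with per-class concentrations 0.2/0.4/0.8
  (MBG/FBG/NBG), reproducing the observation that male-biased genes are
  more tissue-specific.
* `kappa = 2`; gamma-distributed divergence time with mean 0.06
  substitutions per codon; per-class true-omega means 0.15/0.10/0.07 —
  order-of-magnitude matches to closely related Drosophila species pairs,
  with no attempt at exact calibration.
* Expression divergence arises mechanistically as the absolute value of a
  centred normal between-species contrast (a folded normal — what an
  absolute difference of two log2 species means is), whose scale is the
  log-linear covariate model
  `exp(intercept - 0.35 zLev + 0.30 zTau - 0.25 zDeg)`; the coefficient
  signs and resulting Spearman correlations (about -0.3 with level, +0.28
  with tau, -0.29 with interactions) reproduce the canonical genome-wide
  structure.  The folded-normal mechanism matters: it keeps the response
  only mildly skewed, which is what makes the per-category mean
  differences of the stratified test approximately symmetric under the
  null and the test calibrated.  An earlier all-lognormal design inflated
  the stratified test's type-I error to about 7-9% and was rejected at
  design time; the `sigma` entry (default 0) retains optional extra
  log-scale dispersion for sensitivity studies.
* `x_mbg_inflation` multiplies the divergence of genes that are both
  X-linked and male-biased; 1 is the null.  Because the inflation is
  multiplicative on the scale, the ratio of X-MBG to A-MBG mean divergence
  equals the inflation in expectation.  No published effect-size estimate
  exists as a multiplier, so values other than 1 are for power studies
  only.
* Interaction degrees are negative-binomial with per-class means 40/50/80
  (MBGs involved in fewer interactions) realized through a
  configuration-model graph (igraph stub matching, self-loops and
  multi-edges removed); the gene table records the *realized* incident
  edge count, while the generative divergence model uses the drawn target
  degree, so each gene's covariates and response depend only on its own
  RNG substream.
* Class labels are assigned by deterministic largest-remainder quota
  (bias quotas within each chromosome class), so configured proportions
  are exact at any `nGenes`.  Every gene draws from a substream derived
  from the master seed: enlarging a dataset leaves existing genes'
  level, tau, divergence and sequences unchanged (the graph and hence
  realized degrees necessarily change with n).
* Replicate-level measurements (default 4 strains per species) are
  constructed so species means and pooled within-species SDs recover the
  generative divergence and polymorphism *exactly*, which gives the
  expression-summary stage a sharp correctness check.

What passing tests on this generator do and do not show: they validate
the estimators, the filters, the calibration and power of the adjusted
comparisons under a data-generating process with the assumed correlation
structure.  They do not validate microarray normalization, probe effects,
cross-species atlas transfer, alignment error, or any claim about real
effect sizes; the generator makes no attempt to match empirical
D. yakuba / D. santomea parameters beyond orders of magnitude.

## Problem sizes used in the checks

The calibration study uses 1,000 null datasets of 2,000 genes (stratified
test applied to the MBG subset, as in the real analysis), the power study
200 datasets of 7,500 genes (1,500 MBGs) at inflation 1.5, and the ML
recovery study 100 replicate pairs of 500 codons at `t = 0.2`,
`kappa = 2` for each omega in {0.2, 0.5, 1.0}; these sizes give
Monte-Carlo standard errors small enough for the stated tolerances
(binomial SE about 0.7% at n = 1000; SE of the mean omega-hat about
0.005-0.026).

## Known limitations

* The pairwise ML model assumes stationarity, reversibility, one omega
  across sites and lineages, and no codon-usage selection; `dS`
  differences driven by codon bias are outside its scope.
* The stratified comparison needs enough genes per combined category;
  with sparse strata it degrades to few matched pairs, and the exact
  signed-rank branch is mildly conservative at small pair counts.
* The residual contrast inherits OLS assumptions for the *adjustment*
  (linearity in the standardized covariates), though the test on
  residuals is rank-based.
* Polymorphism summaries require at least two replicates per species and
  are reported as undefined otherwise, never as zero.
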