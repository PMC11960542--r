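---
title: "Methods: multiomic QTL mapping, complex-QTL networks, and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic QTL mapping, complex-QTL networks, and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented in `moqtl`, the
modeling conventions they follow, and the deliberate deviations from common
large-cohort practice that make the pipeline testable at desk scale.

## Scope and design philosophy

`moqtl` implements a complete multiomic cis-QTL integration pipeline:
phenotype normalization, kinship-aware linear mixed model (LMM) mapping with
a two-step multiple-testing correction, stepwise conditional signal
discovery with LD-based filtering, complex-QTL module detection, temporal
classification of eQTLs, Bayes-factor colocalization with GWAS summary
statistics, prioritization of motif-overlapping putative causal variants
(MOPCVs), and enrichment statistics.

Every stochastic method is paired with a synthetic-data generator that
plants a known truth, so the package's test suite can verify recovery
end to end rather than only unit behavior. Problem sizes used in the tests
(hundreds of samples, one synthetic chromosome with dozens of LD blocks)
are package choices made for fast, deterministic validation; the methods
themselves do not depend on these sizes.

## Synthetic genotypes: founder-mosaic model

`simulate_genotype_panel()` builds haplotypes as mosaics of a small pool of
founder templates. Each haplotype carries one template per LD block and
switches templates at block boundaries with a fixed recombination
probability, so LD is strong within a block and decays with the number of
boundaries crossed. Families are formed by transmitting recombined
haplotypes from two in-family founders to offspring, inducing realistic
genetic relatedness; the expected genetic-relationship-matrix entry for a
parent–offspring pair under the standardized-dosage GRM is 0.5, which the
tests verify empirically.

Phenotypes are generated on a latent Gaussian scale — planted cis effects
act on standardized dosages, plus optional hidden confounding factors and
polygenic background — then mapped through a Poisson–log-normal observation
model to counts with sample-specific library sizes. GWAS summary statistics
are drawn directly at the summary level: `z ~ MVN(sqrt(N) R b, R)` with
`se = 1/sqrt(2 N p (1 - p))`, where `R` is the reference-panel dosage
correlation matrix and `b` the standardized joint effects.

## Normalization

Counts are normalized by trimmed mean of M-values (TMM; trim fractions 0.30
on M-values and 0.05 on A-values), computed via edgeR — a deliberate
build-over-buy choice for a standard primitive; the test suite still
re-derives the factors step by step as an independent oracle. Retained
elements (expression: TPM ≥ 0.1 and counts ≥ 6 in ≥ 20% of samples;
peaks: not low in ≥ 20% of samples; autosomes only) are then transformed
per element by the rank-based inverse normal transform
`qnorm((rank - 0.5)/n)` with average ties.

Hidden confounders are estimated as the top principal components of the
element-by-sample matrix (restricted to the most variable elements). This
is a PCA substitution for factor-analysis approaches (e.g. PEER) used on
real cohorts: PCA is deterministic, dependency-free, and in the planted
simulations recovers the confounding subspace equally well.
`optimize_factor_count()` selects the factor count maximizing discoveries
on a pilot scan, choosing the smallest count that attains the maximum.

## LMM mapping and the two-step correction

The cis scan fits `y = C a + g b + u + e` with `u ~ N(0, s_u^2 K)` for a
genetic relatedness matrix `K`. Following the standard fast-LMM device, `K`
is eigendecomposed once; the variance ratio `delta = s_e^2/s_u^2` is
estimated by REML on a log10 grid over [1e-5, 1e5] with golden-section
refinement, under the null model per element; each candidate variant is
then tested by generalized least squares in the rotated coordinates, using
Frisch–Waugh residualization so the per-variant cost is a vector product.
With `K = I` the scan reduces exactly to OLS t-tests (verified to 1e-8).

Multiple testing is corrected in two steps. Within an element, the minimum
nominal p-value is Bonferroni-corrected by the effective number of tests:
cis variants are processed in chunks of at most 200; per chunk, the
effective count is the smallest number of eigenvalues of the dosage
correlation matrix reaching 99% cumulative mass. Across elements,
Benjamini–Hochberg is applied to the corrected lead p-values, with
significance at q < 0.05.

Conditional signals (up to 3) are discovered stepwise by adding previously
found leads as fixed covariates, with the same two-step correction per
iteration. A post-discovery filter removes conditional leads in LD with
their primary (r² ≥ 0.8 or D' ≥ 0.8 in the reference panel), handles leads
absent from or monomorphic in the panel, renumbers survivors sequentially,
and records every removal with a reason code. For elements retaining
conditionals, the primary signal is re-estimated with the conditional leads
regressed out before colocalization.

LD statistics are hand-implemented: `ld_r2()` is the squared Pearson
correlation of dosages (requiring ≥ 10 complete pairs), and `ld_dprime()`
estimates haplotype frequencies from unphased genotypes by
expectation–maximization and normalizes `D` by its bound.

## Complex-QTL modules

Within each tissue, significant primary QTLs whose lead variants are within
100 kb and in strict LD (r² > 0.8) form edges of a shared-signal graph.
Communities are detected by Louvain modularity maximization. Because the
Louvain heuristic can return local optima on small graphs and is
RNG-dependent, `louvain_communities()` runs 20 seeded restarts and keeps
the best-modularity partition, making the result deterministic; on all toy
graphs up to 8 vertices the tests verify it equals exhaustive modularity
maximization (`brute_force_modularity()`). Communities of size ≥ 2 are
complex-QTL modules, labeled by the phenotype composition of their members
(e.g. `caQTL-haQTL-eQTL`); remaining QTLs are singletons.

## Temporal classification

For SNP–eGene pairs measured across early-developmental (EDev) and adult
tissues, classification uses local false sign rates (LFSR): a pair is
EDev-specific if its minimum LFSR over EDev tissues is below 0.05 while the
adult minimum is not, adult-specific in the reverse case, shared if both,
and dropped if neither; an LFSR exactly equal to 0.05 counts as not
significant. Annotations propagate through complex modules by two rules:
any member with no association makes the whole module "No Association";
otherwise a mixture of EDev-specific and shared members becomes all
shared. The operation is idempotent and verified against an enumeration of
all 2- and 3-member module compositions.

## Colocalization and credible sets

Colocalization follows the single-causal-variant enumeration over five
hypotheses (H0 none, H1/H2 one trait only, H3 two distinct causal variants,
H4 one shared causal variant) with priors `p1 = p2 = 1e-4`, `p12 = 1e-5`,
computed entirely in log space from Wakefield log approximate Bayes
factors, `log ABF = 0.5 log(1 - r) + z^2 r / 2` with
`r = W^2/(W^2 + se^2)` and prior effect SD `W = 0.15`. The implementation
is hand-written (no external coloc dependency) and verified to 1e-12
against brute-force enumeration of causal configurations for all regions of
up to six variants.

A colocalization is accepted when all five inclusive criteria hold: ≥ 50
overlapping variants, PP.H4 ≥ 0.80, lead candidate GWAS p ≤ 5e-8, lead
candidate QTL p ≤ 5e-5, and lead candidate posterior ≥ 0.01. The 99%
credible set orders variants by decreasing per-variant shared-causal
posterior and includes them until cumulative mass first reaches 0.99
(including the crossing variant); sets of at most 25 variants are flagged
high-confidence. Simulations drawing causal effects from the `N(0, 0.15^2)`
prior the ABF assumes show the sets are calibrated (coverage ≥ 99%).

GWAS loci are defined by sliding-window greedy LD pruning of genome-wide
significant variants (dropping the smaller-MAF member of correlated pairs,
ties by later position), and passing colocalizations are assigned to loci
by LD (r² ≥ 0.7 within 350 kb), falling back to nearest-locus assignment
when the lead is absent from the reference panel.

## MOPCV prioritization

High-confidence credible-set variants are intersected with transcription
factor motif occurrences using BED conventions (a 1-based variant position
`p` overlaps a 0-based half-open interval `[s, e)` iff `s ≤ p - 1 < e`).
Motif-overlapping variants are ranked: **High** if the variant is in its
own caQTL signal's credible set and inside that signal's associated
accessibility peak; **Moderate** if inside a caPeak associated with a
different signal; **Low** otherwise. Report percentages use 1-decimal
round-half-up arithmetic.

## Enrichment

`fisher_enrichment()` reports the exact conditional test p-value (verified
against full hypergeometric enumeration), the sample odds ratio with a
Woolf (normal-approximation) confidence interval on the log scale, and
applies +0.5 continuity correction to the odds ratio and CI only when a
cell is zero. Lead-variant chromatin-state enrichment collapses the
18-state chromHMM-style vocabulary into five groups (Promoter, Enhancer,
Transcribed, Repressed, Quiescent) before testing, with BH correction
across states.

## Known limitations

- The simulator models a single synthetic chromosome with exchangeable
  block LD; it is a validation instrument, not a population-genetic model.
- The single-causal-variant assumption of the colocalization module is
  inherited from the ABF framework; regions with allelic heterogeneity
  should be conditioned first (`regress_primary_signal()`).
- PCA hidden factors are a deterministic stand-in for factor-analysis
  confounder estimation on real cohorts.
- The credible-set calibration guarantee holds when true effects follow the
  `N(0, W^2)` prior; misspecified `W` degrades calibration smoothly.
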