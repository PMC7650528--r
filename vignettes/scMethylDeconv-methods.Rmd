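---
title: "Methods: imputing methylation references from single-cell expression and deconvolving bulk methylomes"
author: "scMethylDeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputing methylation references from single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMethylDeconv)
```

# The problem and the model

Bulk DNA methylation data from a solid tissue is a convex mixture of
cell-type-specific methylomes weighted by cell-type proportions. With a
reference matrix of those methylomes over informative features, proportions
can be estimated by regression; without one — the situation for most solid
tissues — they cannot. This package constructs the missing methylation
reference computationally, starting from a tissue's single-cell RNA-seq
atlas, on the strength of one empirical regularity: for a usable minority of
genes, promoter methylation across purified samples is strongly
*anti*-correlated with expression, so methylation is predictable from
expression.

The model has four parts, mirroring the exported function groups.

## Marker selection and the expression reference

For K annotated cell types we run K one-vs-rest Wilcoxon rank-sum scans,
adjusting p values within each scan by Benjamini–Hochberg. A marker of cell
type k must satisfy three conditions: FDR < 0.05; highest *and non-zero*
median expression in k; and a marker specificity score (MSS) — the number of
other cell types with exactly zero median expression — of at least the
configured minimum, K − 1 by default. The zero-median requirement is what
makes the later translation to methylation possible: a maximally specific
marker is *silent* in every other cell type, so the unexpressed-state
methylation value applies there verbatim. The reference entry is the median
(default) or mean of log2-scale expression over the cells of each type.
Because downstream fraction estimation is an unconstrained robust regression
with a-posteriori constraints, medians are admissible; they are preferred
for robustness to the heavy tails of single-cell data.

Counts are normalised by scaling each cell to the maximum total count across
cells and transforming log2(x + 1), so zero counts map to exactly zero —
which the MSS rule depends on.

Two deliberate resolutions of under-specified details: (i) the one-vs-rest
comparison pools all other cell types into a single group, matching the
"given cell type against all others" framing; (ii) ties for the highest
median are broken by the higher mean, then by lexicographic cell-type name,
and a message reports how many genes were affected.

For purified *bulk* expression panels (`buildBulkReference`) the rule set is
the one appropriate for continuous bulk profiles: FDR < 0.05, pooled log2
fold change > 2, and a gap of at least 0.2 to the second-highest expressing
cell type. Fold changes are differences of log-scale means, consistent with
log-transformed input. A rank-and-cap preset of `selectMarkers`
(`mode = "rank-cap"`: FDR < 0.05, log2FC > 0.5, highest mean, top 20 per
type by fold change) serves the case of closely related cell types, where
zero-median specificity is unattainable.

## The imputable-gene scan

CpG-level methylation is collapsed to gene promoters as the mean beta of
CpGs in the strand-aware window 1–200 bp upstream of the TSS (both ends
inclusive, TSS excluded), falling back to first-exon CpGs when the window is
empty. "Range" filters — methylation range > 0.1 and expression range > 1,
with range = max − min after removing missing values — restrict the scan to
genes whose variation is large enough to be biologically meaningful; the
expression threshold of 1 corresponds approximately to the gap between the
expressed and unexpressed modes on the log2 scale. Significance uses the
*nominal* two-sided p value of the Pearson correlation (t transform, n − 2
df) at 0.05; the core imputable set is the significantly anti-correlated
genes. A linear correlation suffices because the true relationship, though
nonlinear, is monotone. The enhancer variant regresses each variable CpG
(range > 0.5) on each variable gene within ±500 kb of the TSS but outside
±5 kb, gates pairs at BH FDR < 0.05 and R² > 0.8, and resolves multi-gene
CpGs by the largest |t| (ties: smaller p, then lexicographic gene id).

## The probabilistic imputation model

All expression values of the matched compendium are modelled as a two-state
mixture of gamma distributions (unexpressed/expressed). The EM fit excludes
zeros — the gamma density is undefined at 0, and on a log2(x + 1) scale a
zero is a raw zero count, unambiguously unexpressed; `posteriorExpressed`
accordingly returns 0 at x = 0 by definition. Initialisation splits the
positive values at the overall median with method-of-moments estimates per
half, plus five seeded random-quantile splits; the best final log-likelihood
wins. The M-step solves the weighted gamma likelihood by Newton iteration on
the shape parameter. Convergence is declared when the relative
log-likelihood change falls below 1e−8 (cap 1000 iterations); the trace is
stored and is non-decreasing by construction of EM. Components are reported
ordered by mean, so "unexpressed" is always the smaller-mean state
regardless of initialisation.

For each marker gene in the core set, samples with posterior probability of
expression strictly below 0.2 are non-expressing, and the imputed
unexpressed-state beta is the median promoter methylation over them. The
posterior distribution is strongly bimodal under the two-state model, which
is why the imputed values are insensitive to moving the threshold to 0.3 (a
property the test suite checks on synthetic data). When no sample falls
below the threshold, a logistic regression of beta on expression —
quasi-binomial IRLS on the continuous proportions, predictions clipped to
[1e−6, 1 − 1e−6] — is extrapolated to zero expression; a non-converging fit
marks the gene non-imputable.

The methylation reference sets M(g, k) = 0 where g is expressed in k and the
imputed value elsewhere. The default expressed rule is "reference value
> 0", exact for MSS = K−1 markers whose medians are structurally zero
elsewhere; a posterior-based rule (posterior of the reference value ≥ 0.5)
is available for references without exact zeros. The quality weight w_g is
the mean of M(g, k) over unexpressed cell types — near 1 when silencing
coincides with full methylation, near 0 when the imputation carries no
contrast. Genes expressed in all K types are dropped as uninformative.
`wMin = 0.4` (the default minimum retained weight) is this package's own
choice of a conservative cut: below it, a feature contributes less than half
of the maximal methylation contrast and mostly adds noise to the regression.
Merging two references averages values *and* weights of shared genes —
weights are deterministic functions of the values, so averaging both is the
consistent rule — and copies exclusive genes unchanged.

The enhancer-level analogue z-scores each gene across samples before the
logistic fit and across cell types in the reference before prediction; the
weight of an enhancer CpG is its mean imputed beta over cell types with
below-average expression of the linked gene, the natural analogue of the
promoter-level unexpressed-state weight (the promoter definition needs exact
zeros, which rank-capped references do not guarantee).

## Fraction estimation and cell-type-specific differential methylation

Fractions minimise ‖W^(1/2)(y − M f)‖ via Huber's M-estimator (tuning
constant 1.345, the classical 95%-efficiency default; at most 50 IRLS
iterations, coefficient tolerance 1e−8), implemented by multiplying both y
and the rows of M by √w and fitting robustly. An intercept is included by
default: it is what makes the raw coefficients invariant to shifts in the
mean of the profile, a property the estimator is chosen for; strict-objective
mode (`intercept = FALSE`) is available. Negative coefficients are zeroed
and the remainder rescaled to sum to one; a sample where *no* coefficient is
positive is a typed error, not a silent zero vector. Scale invariance of the
constrained fractions follows because rescaling y rescales all raw
coefficients equally.

The differential-methylation model regresses each CpG on
[f_1 … f_K, f_1·z … f_K·z, covariates] by least squares — no global
intercept, since simplex fractions span it (an intercept is added with a
warning for non-simplex input). Errors are homoscedastic per CpG; t and p
values for the interaction terms use the residual degrees of freedom, and BH
adjustment is applied within each cell type. Binary phenotypes are encoded
0/1 and not centred. Rank-deficient designs (e.g. a cell type with fraction
identically zero, or constant fractions making interactions collinear) have
the offending columns dropped and the affected cell types flagged not
testable — never silently reported as null results.

# The synthetic-data module

Every input class the pipeline consumes can be generated with recorded
ground truth, so all stages are testable without downloads.

* `simSingleCellCounts`: negative-binomial counts (dispersion 0.4) with
  independent dropout (rate 0.1) for 2000 genes, K = 4 types of 150–700
  cells — the scale of a typical tissue atlas — and 50 planted markers per
  type, expressed (NB mean 8) only in their own type with structural zeros
  elsewhere, so MSS = K−1 recovery is well-defined.
* `simMatchedOmics`: 3000 genes × 34 samples (the scale of an array-based
  purified-sample compendium); expression i.i.d. from the two-state gamma
  mixture (unexpressed Gamma(2, 0.5), expressed Gamma(20, 0.5), π_E = 0.3 —
  means 1 and 10, separated by the expression-range threshold as in real
  data). Planted genes (10% by default) link beta to expression through a
  decreasing logistic with steepness 1.5 and per-gene midpoints N(4, 1.2)
  truncated to ±2.5: the midpoint spread reproduces the gene-to-gene
  heterogeneity of unexpressed-state methylation seen in real compendia and
  gives the quality weights a realistic spread — a reference in which every
  unexpressed feature had the same beta would be nearly collinear with the
  regression intercept. Noise is truncated Gaussian (sd 0.05) so planted
  effects stay interpretable on the beta scale. Null genes get a constant
  per-gene baseline plus the same noise.
* `simCellDMCData`: 500 samples, K = 4 Dirichlet(1) fractions, 2000 CpGs,
  100 planted effects of magnitude Δβ = 0.1 (random sign) in one target cell
  type, noise sd 0.02, balanced binary phenotype.
* `simTissueTruth` couples the first two on a shared gene universe (every
  planted marker carries the logistic link) and records the true per-type
  methylation profile of each marker: the link evaluated at the expressed-
  or unexpressed-state mean.

What the generators deliberately do **not** emulate: batch effects,
doublets, ambient RNA, cell-type-correlated library sizes, spatially
structured CpG dependence, array measurement error that depends on the beta
value, and impure "purified" compendium samples. Passing tests on these data
therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on any real tissue; the realism of the NB
+ dropout and logistic-link choices is a modelling convenience, not a
claim.

# Numerical and design choices

* Wilcoxon scans use the normal approximation with tie correction and
  continuity correction, vectorised across genes (single-cell data have
  massive ties at zero, where exact enumeration is unavailable anyway);
  groups smaller than 25 fall back to `stats::wilcox.test`. The vectorised
  path is cross-checked against `wilcox.test` in the tests.
* Duplicate feature ids on input are collapsed to the max-variance row,
  deterministically, with a message.
* Coordinates are 1-based inclusive internally; BED input is converted on
  read (start + 1) and the promoter window excludes the TSS itself.
* `overlapSignificance` reports both the one-tailed hypergeometric p and a
  Monte-Carlo empirical p (default 1e5 draws) so enrichment claims can be
  made without distributional assumptions.
* Dirichlet mixture weights support a "matched" mode: concentrations
  α_k = m_k·s₀ with s₀ set so the average variance across cell types matches
  a target, for emulating realistic compositional variability.
* Missing betas are never imputed on read; `imputeMissingBeta` (k = 5
  nearest samples by correlation) must be invoked explicitly.
* All generators and the pipeline restore the caller's RNG state; stage
  seeds are derived deterministically from the run seed, so adding a stage
  never perturbs earlier stages' randomness.

Problem sizes in the test suite and acceptance script (gamma-mixture
recovery at 50,000 draws, 100 mixtures, 2000–5000 CpGs, 500 bulk samples)
were chosen as the smallest sizes at which the statistical properties under
test — recovery rates, null calibration, parameter consistency — are stable
across seeds.

# Known limitations

* Imputation covers only the 10–20% of markers falling in the anti-correlated
  core; tissues whose markers are regulated without promoter methylation
  contrast will yield sparse references.
* The expressed-state methylation is fixed at zero; partially methylated
  expressed promoters are not modelled.
* The two-state mixture cannot represent intermediate expression states; a
  gene dosage-regulated across types violates the model's dichotomy.
* Resolution beyond 5–6 cell types degrades: closely related types share
  markers, zero-median specificity becomes unattainable, and the interaction
  model's power drops as K grows (2K + covariates coefficients per CpG).
* Hierarchical (two-stage) deconvolution and constrained quadratic-program
  estimators are out of scope; the estimator here is robust regression with
  a-posteriori constraints.
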