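---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexg)
```

`cortexg` links two bodies of data at the level of a cortical parcellation:
a regions × genes matrix of median post-mortem expression, and per-cohort
MRI + cognitive data from which regional associations with general
cognitive functioning (*g*) are estimated and meta-analysed. This vignette
records the models, the tunable parameters, what the synthetic generators
do and do not emulate, and the places where the design was genuinely open
and a choice had to be made.

## Components of regional expression

`fit_expression_components()` standardises every gene across regions
(sample SD, n − 1) and decomposes the standardised matrix by singular
values — equivalent to an eigendecomposition of the gene–gene correlation
matrix but feasible at 8,000+ genes because only the regions × regions
problem is ever formed. Loadings are scaled to equal gene–component
correlations, so the variance explained by component *j* is
`sum(loadings[, j]^2) / n_genes × 100`, and the full unrotated spectrum sums
to 100%. Scores are the standardised data projected on the unit-norm weight
vectors and then z-scaled separately per hemisphere.

Hemisphere scaling exists because donor-median atlases are typically built
from unequal numbers of donors per hemisphere, producing a small artefactual
offset in raw mean expression (about 0.056 log2 units in the atlas this
pipeline is designed around) that propagates into component scores.
Standardising each regional map within hemisphere removes the offset while
preserving the within-hemisphere ordering; the operation is idempotent and
is applied identically to component scores, single-gene profiles and
cell-type mean profiles, so all spatial regressions see commensurate maps.

Varimax rotation (Kaiser normalisation, tolerance 1e-10) is applied to the
retained `k = 2` loading columns; rotated components are re-ordered by
explained variance and every component is oriented so that its
largest-magnitude loading is positive. Orientation is genuinely arbitrary
in a PCA, so the canonical rule matters only for reproducibility; all
congruence comparisons use |φ|.

**Partition stability.** The regions are split into 5 random partitions,
50 times; each partition in turn is the small set (~13–14 of 68 regions)
against the union of the others (~54–55), giving 250 paired fits whose
first 10 unrotated components are compared by |φ|. Genes are standardised
*within* each fold — the alternative (reusing full-sample standardisation)
leaks information from the large set into the small one, which defeats the
point of the check. A consequence worth knowing: even for noiseless
low-rank data, fold-specific standardisation perturbs the correlation
structure slightly, so |φ| is near 1 but not exactly 1 unless the planted
eigenvalues are well separated. Unrotated components are compared because
rotation entangles fold-specific subspaces. Components beyond the numerical
rank of a fold are reported as missing rather than as spurious congruences.

**Cross-model congruence.** Two fitted models are compared on their matched
genes via the full |φ| matrix plus an assignment maximising total |φ|
(exhaustive for k ≤ 6, greedy beyond, ties to the lower index pair), so a
second component of one solution may legitimately pair with the third of
another.

## The latent g model

Cognitive tests are first residualised for age and sex per test,
preserving missingness. `fit_latent_g()` then fits a one-factor model with
the factor variance fixed at 1 (loadings stay comparable across tests) by
full-information maximum likelihood: rows are grouped by missingness
pattern and the casewise normal likelihood evaluated from per-pattern
sufficient statistics, with an analytic gradient. Residual variances are
optimised on the log scale, so Heywood cases cannot cross zero (near-zero
variances are flagged and floored at 1e-6); within-domain residual
covariances are free parameters added for every test pair sharing a
nominated domain, approximating a hierarchical domain structure without a
second-order factor. Tests are standardised internally, which makes all
results invariant to affine rescaling of any input test.

The χ² statistic is the likelihood-ratio against the saturated
mean/covariance model (fitted by EM under missingness; closed-form when
complete), i.e. the n·F_ML convention; an `(n − 1)/n` rescaling is
available via `chisq_scale`. The independence baseline factorises per
variable. CFI, TLI and RMSEA follow the standard formulas
(`fit_indices()`), with RMSEA = 0 and TLI undefined at zero df; SRMR is the
root mean squared standardised residual over the lower triangle including
the diagonal, standardised by the observed variances. Factor scores use the
regression method per missingness pattern and can be oriented against a
designated higher-is-better reference test.

Numerical choices: starting loadings come from the first eigenvector of the
available-case correlation matrix; convergence is relative log-likelihood
change below 1e-10 in BFGS, with up to five jittered restarts before a
convergence error (with trace) is raised.

## Regional associations and meta-analysis

Within each cohort, regional values more than 4 SD from the full-sample
mean are set missing (`exclude_outliers()`), then each region × measure is
regressed on *g* with covariates (age, sex, head position, site dummies,
optional lag, optional global measure), both the measure and *g* z-scored
on the analysis sample — i.e. after exclusions and casewise deletion, which
matches the sample the regression actually sees. Whole-cortex associations
run the summed (volume, surface area) or mean (thickness) measure through
the identical code path, and their totals can be fed back as a
global-measure covariate.

Pooling uses the DerSimonian–Laird method-of-moments estimator with normal
reference p-values; REML-style alternatives were deliberately not added
because the method-of-moments formulas are the contract the rest of the
pipeline (and its tests) pin down to 1e-10. BH-FDR is applied within each
measure family of 68 regions by default (`fdr_family = "global"` pools all
204), reflecting that each measure map is reported as its own family.
Age moderation regresses cohort βs on cohort mean age by weighted least
squares with the between-cohort variance re-estimated by the method of
moments under the moderator model and floored at zero.

## Spatial inference

`spin_permutations()` draws uniform rotations via normalised quaternions,
applies each to the left-hemisphere centroids and its sagittal-plane mirror
to the right, and rebuilds a bijection by visiting regions in random order
and assigning each the nearest unassigned rotated region. Random-order
greedy matching is the documented tie-break; exact duplicates among
centroids are rejected as ambiguous. Each permutation preserves hemisphere
membership and each map's value multiset.

`spatial_correlation()` reports the Pearson r (linear or absolute form) or
the quadratic coefficient of `map_b ~ map_a + map_a²`, a parametric
p-value, and a spin p-value computed by permuting `map_a` only — the
expression side of every comparison — with the two-sided
`(1 + count)/(1 + n_perm)` estimator. The +1 correction means the smallest
reportable p at 1,000 permutations is ≈ .000999; conventions that report
`p < .0001` from a zero count at the same n_perm are uncorrected, and the
corrected estimator is kept here because it is valid (never exactly zero)
at any n_perm. Sidedness is absolute-value based throughout.

## Component-adjusted gene and cell-type mapping

For each gene, the z-scored *g*-map is regressed on the gene's
hemisphere-scaled, z-scored profile plus the two component score maps; the
gene coefficient is the component-adjusted standardised association.
Profiles with multiple correlation > 0.999 with the score maps are flagged
and their estimates masked (the coefficient is not identified). The spin
null for these regressions permutes the *gene profile* while holding the
maps and covariates fixed, so one shared permutation set serves every gene;
this is an interpretation choice (one could instead spin the g-map) and is
recorded in the output. Selection proceeds in three audited stages:
per-measure FDR (Q < .05 across all tested genes within a measure), the
three-measure intersection, and spin p < .05 on all three measures for the
intersection only — spin p-values are not spent on genes that cannot be
selected. Cell-type analysis averages each type's gene profiles (types with
fewer than two genes are skipped), hemisphere-scales the mean profile, and
applies the identical adjusted regression with BH-FDR across the
type × measure family.

Loading-distribution tests compare component loadings across cell-type
gene sets: Kruskal–Wallis with tie correction, Dunn z tests of each type
against the unclassified baseline with Holm adjustment, and per-group
skewness (g1 = m₃/m₂^1.5) and kurtosis. Kurtosis defaults to the raw
fourth-moment convention (normal ≈ 3) rather than excess, matching how
such summaries are usually tabulated in this literature; the convention is
recorded in the result and switchable. The ±0.3 / ±0.6 loading-threshold
gene sets are exported by `loading_threshold_sets()` for external ontology
tools; no enrichment statistics are computed in-package.

## What the generators emulate — and what they do not

`simulate_expression()` plants two orthogonal regional score maps (paired
left/right correlation 0.9 by construction, exact orthogonality enforced by
projection) and mixes them into each gene with unit-norm coefficients whose
squared component-1 share is Beta-distributed with mean 0.65, so that at the
default planted variance fraction of 0.5 the unrotated eigenvalue shares
land near 32% and 18% — the regime the pipeline is designed for. A constant
0.056 log2 offset is added to left-hemisphere raw values, and each donor
adds independent Gaussian noise (SD 0.1) before the median matrix is formed.

The optional specific-gene module is a set of genes sharing one spatial
profile orthogonalised against both components, with gene-specific jitter
(SD 0.3). Modelling the specific signal as a co-expressed module, rather
than as mutually independent gene effects, is a deliberate design choice:
with only 68 regions, per-gene regressions of one map on many mutually
orthogonal profiles bound every t statistic near √(n−4)/√(k−1) no matter
how large the planted effects are, so independent planted effects are
undetectable in principle at this parcellation — whereas a shared spatial
signal tagged by several genes is exactly the situation the three-stage
selection rule can and should recover.

`simulate_beta_maps()` builds each measure's true regional *g*-association
as a degree-2 polynomial of the planted scores — a balance term (maximal
association where both scores are near zero) plus linear alignment with the
score maps — plus the module profile and spatially uncorrelated noise, on a
standardised scale that is then mapped to published effect magnitudes
(means ≈ 0.103/0.102/0.031, SDs ≈ 0.034/0.027/0.035 for volume, surface
area, thickness). The linear fraction (default 0.62) is there because
observed adjusted-regression standard errors in real data of this kind
(~0.05 at 68 regions) imply that the component score maps capture most of
the g-map variance linearly; a purely even quadratic cannot reproduce that,
and without it no specific gene of realistic effect size could ever pass
FDR. The balance term keeps the negative absolute-score correlation that
motivates the quadratic/absolute-score spatial tests.

`simulate_cohort()` generates tests as λ·g + domain residual + unique
noise on unit-variance scales (default λ = 0.7, within-domain residual
covariance 0.1), with planted age (0.2 SD) and sex (0.1) effects, MCAR
missingness on request (the mechanism under which FIML is unbiased), and
regional morphometry as β·g plus small covariate effects (0.1 SD per
covariate; age negative) and Gaussian noise. Sex is Bernoulli(0.5), age
uniform over a configurable range, site categorical — magnitudes are
conventions, chosen once, since no empirical generative values exist for
them. Default cohort sizes follow the study shape this pipeline targets
(37,840 / 1,043 / 636; mean ages differ across cohorts so the
age-moderation test has leverage).

What the generators do **not** emulate: microarray probe structure, spatial
autocorrelation of expression beyond the planted components (noise is white
across regions), non-normal test distributions, informative missingness,
scanner/site effects on the *covariance* structure (sites shift means
only), and inter-regional dependence of morphometry noise. Passing tests on
this synthetic world therefore demonstrate correctness of the estimators
and selection logic under the planted model, not robustness to every
artefact of real atlas or cohort data.

## Problem sizes used in the shipped checks

The packaged tests run the study shape (68 regions, 3 measures, 3 cohorts)
with 300–2,000 genes and cohorts of 600–1,500 participants; loading
recovery uses 10 seeds at 1,000 genes, the latent-g recovery 20 seeds at
n = 1,000, pooling bias 1,000 replicates at k = 50, selection
recall/FDR 50 replicates at 800 genes, and spin calibration 500 simulated
map pairs at 500 permutations. The acceptance script runs one full study at
1,500 genes with the real cohort sizes and 1,000 spin permutations. These
sizes were chosen as the smallest at which the sampling error of each check
is comfortably below its decision margin.

## Known limitations

* The FIML fit assumes multivariate normality of the residualised tests;
  robust (sandwich) standard errors are not implemented.
* The spin null treats the parcellation's centroids as exact; very uneven
  region sizes are not reweighted.
* The DerSimonian–Laird normal reference is anti-conservative at very small
  k (here k = 3); the meta-analytic p-values should be read accordingly,
  and the spatial tests — the pipeline's primary inferences — do not rely
  on them.
* Right-hemisphere genes inherit the left-hemisphere QC decision by design
  (matching the atlas's donor imbalance), so a gene inconsistent only on
  the right is not caught.
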