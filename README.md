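# cortexg

Regional gene expression across the human cortex does not vary gene-by-gene
at random: a small number of spatial components carry much of the
region-to-region covariation in expression profiles. `cortexg` implements an
imaging-transcriptomics pipeline that (i) extracts and validates the two
major spatial components of a regions × genes cortical expression matrix,
(ii) meta-analyses regional associations between cortical morphometry
(volume, surface area, thickness) and a latent factor of general cognitive
functioning (*g*) across several cohorts, and (iii) asks how the two sides
relate: whether regions whose anatomy tracks *g* sit at particular positions
along the expression components, and which individual genes or cell types
carry *g*-related spatial signal **beyond** those shared components.

It is written for researchers combining parcellated post-mortem expression
atlases (e.g. donor-median matrices summarised to a 68-region cortical
parcellation) with cohort MRI + cognitive data. Every pipeline input can
also be simulated with known ground truth, so each stage is testable without
any restricted data.

## The statistical core

* **Components.** Genes are standardised across regions and the correlation
  structure decomposed by singular values; loadings are gene–component
  correlations, regional scores are z-scaled separately per hemisphere to
  remove a hemispheric sampling artefact, and the retained components are
  varimax-rotated. Stability is quantified with Tucker's congruence
  coefficient φ = Σaᵢbᵢ / √(Σaᵢ²·Σbᵢ²) over random region partitions
  (5 folds × 50 repetitions = 250 train/test comparisons) and across
  independent models via a best-match assignment of components.
* **Latent g.** Per cohort, a one-factor confirmatory factor model with
  unit factor variance, estimated by full-information maximum likelihood
  over missingness patterns, optional within-domain residual covariances,
  normal-theory fit indices (CFI, TLI, RMSEA, SRMR), and regression-method
  factor scores.
* **Regional associations and pooling.** Standardised β of each regional
  measure on *g* (covariates: age, sex, scanner head position, site, lag),
  4-SD outlier screening, then DerSimonian–Laird random-effects pooling per
  region × measure (68 × 3 = 204 meta-analyses) with BH-FDR per measure and
  an age-moderation meta-regression.
* **Spatial inference.** Map–map tests with parametric p-values and a
  spherical spin permutation null: random 3-D rotations of parcel centroids
  (mirrored across hemispheres) with greedy nearest-centroid reassignment,
  `p = (1 + #{|null| ≥ |obs|}) / (1 + n_perm)`.
* **Specific genes and cell types.** Each gene's hemisphere-scaled profile
  is regressed against the *g*-maps controlling for both component score
  maps; candidates must pass per-measure FDR, the 3-measure intersection,
  and spin tests on all measures. Cell-type mean profiles get the same
  treatment, and component loadings are compared across cell-type gene sets
  (Kruskal–Wallis, Dunn versus the unclassified baseline, Holm-adjusted).

## Worked example

A full synthetic study at the default study shape (68 regions, six donors,
three cohorts of 37,840 / 1,043 / 636 participants; 1,500 genes of which 10
form a planted *g*-related module orthogonal to the components):

```r
library(cortexg)
library(dplyr)
library(purrr)

study <- simulate_study(seed = 42, n_genes = 1500)
qc <- donor_consistency_filter(study$expression$donors, study$expression$median)
sum(qc$retained)
#> [1] 1500

pca <- fit_expression_components(study$expression$median, k = 2)
pca
#> <expression_pca> 68 regions x 1500 genes, k = 2 (varimax)
#>   variance explained (%): C1 26.1, C2 24.3

assoc <- imap(study$cohorts, function(ch, nm) {
  ph <- residualize_tests(ch$phenotypes)
  m  <- fit_latent_g(ph, reference_test = "test_01")
  regional_g_associations(exclude_outliers(ch$morphometry), ph,
                          g_scores = setNames(m$scores, ph$id), cohort = nm)
}) |> list_rbind()
meta <- run_meta_grid(assoc)
nrow(meta); mean(meta$beta[meta$measure == "volume"])
#> [1] 204
#> [1] 0.098

perms <- spin_permutations(study$parcellation, n_perm = 1000, seed = 43)
maps <- tidyr::pivot_wider(select(meta, region, hemisphere, measure, beta),
                           names_from = measure, values_from = beta)
sc <- pca$scores[match(maps$region, pca$scores$region), ]
spatial_correlation(sc$C1, maps$volume, perms, form = "absolute")
#>       form statistic p_parametric p_spin n_perm n_regions
#> 1 absolute    -0.323      0.00729  0.018   1000        68

gene_assoc <- gene_g_associations(study$expression$median, maps, pca)
sel <- select_candidate_genes(gene_assoc, study$expression$median, maps, pca, perms)
sel$audit
#>   stage           measure          n
#> 1 fdr_per_measure surface_area    11
#> 2 fdr_per_measure thickness       11
#> 3 fdr_per_measure volume          10
#> 4 intersection    all             10
#> 5 spin_filtered   all             10
all(sel$genes == study$expression$truth$planted_genes)
#> [1] TRUE
```

Reading the output: the two rotated components each explain ~25% of the
expression variance (unrotated ~32% and ~18%); pooling the three cohorts
yields 204 regional meta-analyses with mean *g*-volume β ≈ 0.10; regions
with stronger *g*-volume associations have component scores closer to zero
(absolute-score r = −0.32, spin p = .018); and the three-stage selection
recovers exactly the ten planted module genes with no false positives.

## Package layout

* `R/simulate.R` — ground-truth generators (parcellation, expression,
  beta maps, cohorts, whole studies)
* `R/expression-atlas.R` — donor medians, consistency QC, hemisphere scaling
* `R/components.R` — correlation PCA, varimax, congruence suite
* `R/latent-g.R` — FIML one-factor model, fit indices, factor scores
* `R/morphometry.R`, `R/meta.R` — regional models and random-effects pooling
* `R/spatial.R` — spin permutations and map association tests
* `R/genes.R` — component-adjusted gene/cell-type mapping and selection
* `vignettes/cortexg-methods.Rmd` — modelling assumptions and design notes
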