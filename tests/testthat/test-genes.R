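# Component-adjusted single-gene and cell-type mapping, the three-stage
# selection rule, and loading-distribution tests.

study_fixture <- function(seed = 7, n_genes = 600, n_planted = 5) {
  ex <- simulate_expression(n_regions = 68, n_genes = n_genes,
                            n_planted_genes = n_planted, seed = seed)
  list(
    ex = ex,
    gmaps = simulate_beta_maps(ex, seed = seed),
    pca = fit_expression_components(ex$median, k = 2),
    parc = simulate_sphere_parcellation(34, seed = seed)
  )
}

test_that("a gene identical to a component score map is flagged and absorbed", {
  fx <- study_fixture(seed = 3, n_genes = 60, n_planted = 0)
  expr <- fx$ex$median
  expr$gene_0001 <- fx$pca$scores$C1  # overwrite one gene with the score map
  expect_warning(
    res <- gene_g_associations(expr, fx$gmaps, fx$pca),
    "collinear"
  )
  hit <- res[res$gene == "gene_0001", ]
  expect_true(all(hit$collinear))
  expect_true(all(is.na(hit$beta)))  # absorbed by the covariate, unidentified
  expect_false(any(res$collinear[res$gene != "gene_0001"]))
})

test_that("a planted specific gene is estimated near its effect and reaches FDR significance", {
  ex <- simulate_expression(n_regions = 68, n_genes = 2000,
                            n_planted_genes = 1, seed = 42)
  gmaps <- simulate_beta_maps(ex, gene_effect = 0.4, seed = 42)
  pca <- fit_expression_components(ex$median, k = 2)
  res <- gene_g_associations(ex$median, gmaps, pca)
  planted <- ex$truth$planted_genes
  hit <- res[res$gene == planted, ]
  expect_equal(mean(hit$beta), 0.4, tolerance = 0.1)
  expect_true(all(hit$fdr_q < 0.05))
})

test_that("the adjusted beta is invariant to affine rescaling of the raw gene profile", {
  fx <- study_fixture(seed = 5, n_genes = 50, n_planted = 0)
  res1 <- gene_g_associations(fx$ex$median, fx$gmaps, fx$pca, genes = "gene_0010")
  expr2 <- fx$ex$median
  expr2$gene_0010 <- 5 + 3 * expr2$gene_0010
  res2 <- gene_g_associations(expr2, fx$gmaps, fx$pca, genes = "gene_0010")
  expect_equal(res1$beta, res2$beta, tolerance = 1e-10)
})

test_that("three-stage selection recovers the planted module with non-increasing stage sizes", {
  fx <- study_fixture(seed = 11, n_genes = 600, n_planted = 5)
  perms <- spin_permutations(fx$parc, n_perm = 199, seed = 11)
  assoc <- gene_g_associations(fx$ex$median, fx$gmaps, fx$pca)
  sel <- select_candidate_genes(assoc, fx$ex$median, fx$gmaps, fx$pca, perms)
  audit <- sel$audit
  n_fdr <- min(audit$n[audit$stage == "fdr_per_measure"])
  n_int <- audit$n[audit$stage == "intersection"]
  n_spin <- audit$n[audit$stage == "spin_filtered"]
  expect_lte(n_int, n_fdr)
  expect_lte(n_spin, n_int)
  planted <- fx$ex$truth$planted_genes
  expect_gte(mean(planted %in% sel$genes), 0.8)
  expect_lte(length(setdiff(sel$genes, planted)), 1)
})

test_that("selection returns an empty, fully audited result when nothing passes", {
  fx <- study_fixture(seed = 23, n_genes = 150, n_planted = 0)
  gmaps_null <- fx$gmaps
  set.seed(99)
  for (m in c("volume", "surface_area", "thickness")) {
    gmaps_null[[m]] <- rnorm(68, 0.1, 0.03)
  }
  perms <- spin_permutations(fx$parc, n_perm = 99, seed = 1)
  assoc <- gene_g_associations(fx$ex$median, gmaps_null, fx$pca)
  sel <- select_candidate_genes(assoc, fx$ex$median, gmaps_null, fx$pca, perms)
  expect_length(sel$genes, 0)
  expect_equal(sel$audit$n[sel$audit$stage == "intersection"], 0)
})

test_that("a duplicated single-gene cell set reproduces that gene's association", {
  fx <- study_fixture(seed = 31, n_genes = 80, n_planted = 1)
  planted <- fx$ex$truth$planted_genes
  cell_map <- tibble::tibble(gene = c(planted, planted),
                             cell_type = "planted_cells")
  ct <- celltype_g_associations(fx$ex$median, cell_map, fx$gmaps, fx$pca)
  single <- gene_g_associations(fx$ex$median, fx$gmaps, fx$pca, genes = planted)
  expect_equal(ct$beta, single$beta, tolerance = 1e-10)
  expect_equal(ct$n_genes, rep(2L, 3))
})

test_that("cell types with too few genes are skipped and null sets control FDR", {
  fx <- study_fixture(seed = 37, n_genes = 120, n_planted = 0)
  cell_map <- tibble::tibble(gene = c("gene_0001", "gene_0002", "gene_0003"),
                             cell_type = c("a", "a", "tiny"))
  expect_warning(
    ct <- celltype_g_associations(fx$ex$median, cell_map, fx$gmaps, fx$pca),
    "tiny"
  )
  expect_setequal(unique(ct$cell_type), "a")

  # random gene sets against maps with no planted gene signal
  set.seed(61)
  sig <- vapply(1:30, function(i) {
    genes <- sample(sprintf("gene_%04d", 1:120), 27)
    cm <- tibble::tibble(gene = genes, cell_type = rep(paste0("t", 1:9), each = 3))
    res <- suppressWarnings(
      celltype_g_associations(fx$ex$median, cm, fx$gmaps, fx$pca)
    )
    mean(res$fdr_q < 0.05)
  }, numeric(1))
  expect_lte(mean(sig), 0.05 + 0.05)
})

test_that("Kruskal-Wallis and Dunn statistics match direct rank arithmetic", {
  values <- c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5)
  groups <- c("a", "a", "a", "b", "b", "b", rep("unclassified", 4))
  # direct computation: pooled ranks, tie-corrected H
  r <- rank(values)
  n <- length(values)
  group_stats <- tapply(r, groups, function(x) c(sum(x), length(x)))
  h_raw <- 12 / (n * (n + 1)) *
    sum(vapply(group_stats, function(s) s[1]^2 / s[2], numeric(1))) -
    3 * (n + 1)
  ties <- table(values)
  h <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  kw <- kruskal.test(values, factor(groups))
  expect_equal(unname(kw$statistic), h, tolerance = 1e-10)

  dn <- dunn_control_test(values, groups, control = "unclassified")
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  vb <- n * (n + 1) / 12 - tie_term
  z_a <- (mean(r[groups == "a"]) - mean(r[groups == "unclassified"])) /
    sqrt(vb * (1 / 3 + 1 / 4))
  expect_equal(dn$z[dn$group == "a"], z_a, tolerance = 1e-10)
  expect_equal(dn$p_adjusted,
               p.adjust(2 * pnorm(-abs(dn$z)), method = "holm"),
               tolerance = 1e-12)
})

test_that("disjoint-support groups reach the maximal H for their configuration", {
  values <- c(1, 2, 3, 10, 11, 12)
  groups <- rep(c("low", "high"), each = 3)
  kw <- kruskal.test(values, factor(groups))
  # with no ties, two groups of 3: H = 12/(6*7) * (6^2/3 + 15^2/3) - 21
  expect_equal(unname(kw$statistic), 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-10)
})

test_that("loading distribution tests report moments, main effects and post-hocs per component", {
  fx <- study_fixture(seed = 43, n_genes = 400, n_planted = 0)
  set.seed(43)
  marked <- sample(fx$pca$loadings$gene, 90)
  cell_map <- tibble::tibble(gene = marked,
                             cell_type = rep(paste0("type", 1:3), each = 30))
  out <- loading_distribution_tests(fx$pca, cell_map)
  expect_setequal(unique(out$kruskal$component), c("C1", "C2"))
  expect_equal(nrow(out$dunn), 2 * 3)
  expect_true(all(out$moments$n[out$moments$cell_type == "unclassified"] == 310))
  expect_equal(attr(out, "kurtosis"), "raw")
  # raw fourth-moment kurtosis of a normal sample is near 3, not 0
  uncl <- out$moments[out$moments$cell_type == "unclassified", ]
  expect_gt(min(uncl$kurtosis), 1.5)

  # null calibration: group labels carry no information
  set.seed(91)
  pvals <- vapply(1:60, function(i) {
    v <- rnorm(120)
    g <- sample(rep(c("x", "y", "unclassified"), each = 40))
    kruskal.test(v, factor(g))$p.value
  }, numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("threshold gene sets partition by sign and are consistent with the loadings", {
  fx <- study_fixture(seed = 47, n_genes = 100, n_planted = 0)
  sets <- loading_threshold_sets(fx$pca, thresholds = 0.3)
  pos <- sets$gene[sets$component == "C1" & sets$direction == "positive"]
  l <- fx$pca$loadings
  expect_setequal(pos, l$gene[l$C1 > 0.3])
  expect_equal(nrow(dplyr::filter(sets, threshold == 0.3)), nrow(sets))
})
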