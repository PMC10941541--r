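# The generators must be deterministic, respect their stated constraints,
# and plant exactly the structure the downstream stages are tested against.

test_that("sphere parcellation gives unit-norm, mirror-symmetric, reproducible centroids", {
  p <- simulate_sphere_parcellation(34, seed = 1)
  expect_equal(nrow(p), 68)
  norms <- sqrt(p$x^2 + p$y^2 + p$z^2)
  expect_true(all(abs(norms - 1) < 1e-12))

  expect_identical(p, simulate_sphere_parcellation(34, seed = 1))
  expect_false(identical(p, simulate_sphere_parcellation(34, seed = 2)))

  p3 <- simulate_sphere_parcellation(3, seed = 7)
  left <- p3[p3$hemisphere == "left", ]
  right <- p3[p3$hemisphere == "right", ]
  expect_equal(right$x, -left$x)
  expect_equal(right$y, left$y)
  expect_equal(right$z, left$z)

  expect_error(simulate_sphere_parcellation(2), "at least 3")
})

test_that("expression generator validates inputs and is seed-deterministic", {
  expect_error(simulate_expression(n_regions = 67), "even")
  expect_error(simulate_expression(n_genes = 5), "at least 10")
  expect_error(simulate_expression(n_donors = 0), "at least 1")

  a <- simulate_expression(n_regions = 20, n_genes = 50, n_donors = 3, seed = 9)
  b <- simulate_expression(n_regions = 20, n_genes = 50, n_donors = 3, seed = 9)
  expect_identical(a$median, b$median)
  expect_identical(a$donors, b$donors)
})

test_that("zero donor noise makes all donor matrices identical to the median", {
  ex <- simulate_expression(n_regions = 12, n_genes = 30, n_donors = 4,
                            donor_noise_sd = 0, seed = 3)
  per_donor <- split(ex$donors, ex$donors$donor)
  first <- per_donor[[1]][c("region", "gene", "expression")]
  for (d in per_donor[-1]) {
    expect_equal(d$expression, first$expression)
  }
  med <- median_across_donors(ex$donors)
  expect_equal(as.matrix(med[gene_cols <- setdiff(names(med), c("region", "hemisphere"))]),
               as.matrix(ex$median[gene_cols]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("planted truth satisfies its structural invariants", {
  ex <- simulate_expression(n_regions = 68, n_genes = 200, seed = 11)
  s <- ex$truth$scores
  expect_lt(abs(sum(s[, 1] * s[, 2])), 1e-8)
  hemi <- ex$truth$hemisphere
  for (j in 1:2) {
    expect_gt(cor(s[hemi == "left", j], s[hemi == "right", j]), 0.7)
  }
  # left hemisphere raw mean exceeds right by about the configured offset
  m <- as.matrix(ex$median[setdiff(names(ex$median), c("region", "hemisphere"))])
  gap <- mean(m[hemi == "left", ]) - mean(m[hemi == "right", ])
  expect_lt(abs(gap - 0.056), 0.02)
})

test_that("planted variance fraction is recovered by an independent eigendecomposition", {
  ex <- simulate_expression(n_regions = 68, n_genes = 2000,
                            planted_var_frac = 0.5, seed = 21)
  m <- as.matrix(ex$median[setdiff(names(ex$median), c("region", "hemisphere"))])
  ev <- svd(scale(m), nu = 0, nv = 0)$d^2
  shares <- ev / sum(ev)
  expect_equal(sum(shares[1:2]), 0.50, tolerance = 0.05)
})

test_that("donor-consistency retention is high at low noise and monotone in noise", {
  ex <- simulate_expression(n_regions = 68, n_genes = 300, n_donors = 6,
                            donor_noise_sd = 0.1, seed = 5)
  qc <- donor_consistency_filter(ex$donors, ex$median)
  expect_gte(mean(qc$retained), 0.99)

  retained_at <- function(noise, seed) {
    ex <- simulate_expression(n_regions = 20, n_genes = 120, n_donors = 4,
                              donor_noise_sd = noise, seed = seed)
    sum(donor_consistency_filter(ex$donors, ex$median)$retained)
  }
  seeds <- 1:4
  lo <- mean(vapply(seeds, function(s) retained_at(0.1, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) retained_at(0.8, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) retained_at(2.5, s), numeric(1)))
  expect_true(lo >= mid && mid >= hi)
})

test_that("true beta maps are an exact quadratic in the planted scores when noise-free", {
  ex <- simulate_expression(n_regions = 30, n_genes = 40, seed = 2)
  bm <- simulate_beta_maps(ex, gene_effect = 0, noise_frac = 0, seed = 1)
  s <- ex$truth$scores
  for (m in c("volume", "surface_area", "thickness")) {
    fit <- lm(bm[[m]] ~ s[, 1] + s[, 2] + I(s[, 1]^2) + I(s[, 2]^2))
    expect_lt(max(abs(resid(fit))), 1e-10)
  }
})

test_that("cohort generator enforces preconditions and plants the factor structure", {
  bm <- simulate_beta_maps(simulate_expression(n_regions = 10, n_genes = 20,
                                               seed = 1), seed = 1)
  expect_error(simulate_cohort(100, bm, n_tests = 2), "at least 3")
  expect_error(simulate_cohort(100, bm, loadings = 1.2), "\\[0, 1\\)")

  # null factor: zero loadings, no shared domain variance
  ch0 <- simulate_cohort(5000, bm, n_tests = 6, loadings = 0,
                         residual_cov = 0, test_age_beta = 0,
                         test_sex_beta = 0, seed = 4)
  tests <- as.matrix(ch0$phenotypes[grep("^test_", names(ch0$phenotypes))])
  r <- cor(tests)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # null association maps give region-wise betas centred on zero
  bm0 <- bm
  for (m in c("volume", "surface_area", "thickness")) bm0[[m]] <- 0
  ch <- simulate_cohort(10000, bm0, n_tests = 4, covariate_beta = 0, seed = 8)
  assoc <- regional_g_associations(
    ch$morphometry, ch$phenotypes,
    g_scores = setNames(ch$truth$g, ch$phenotypes$id),
    covariates = character(0)
  )
  expect_lt(abs(mean(assoc$beta)), 0.01)
})

test_that("cohort missingness is applied at the requested MCAR rate", {
  bm <- simulate_beta_maps(simulate_expression(n_regions = 10, n_genes = 20,
                                               seed = 1), seed = 1)
  ch <- simulate_cohort(2000, bm, n_tests = 8, missing_rate = 0.2, seed = 3)
  tests <- as.matrix(ch$phenotypes[grep("^test_", names(ch$phenotypes))])
  expect_equal(mean(is.na(tests)), 0.2, tolerance = 0.02)
})
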