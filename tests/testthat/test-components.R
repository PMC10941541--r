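# Correlation-matrix PCA, varimax bookkeeping, congruence and the
# stability/validation suite.

test_that("exact rank-2 structure is fully captured by two components", {
  df <- make_rank2_df(n_regions = 20, n_genes = 40, seed = 2)
  fit <- fit_expression_components(df, k = 2, rotate = FALSE)
  expect_equal(sum(fit$variance_explained), 100, tolerance = 1e-6)
  expect_true(all(abs(fit$loadings$C1) <= 1 + 1e-8))
})

test_that("the full unrotated spectrum sums to 100% and varimax preserves the k-subspace", {
  ex <- simulate_expression(n_regions = 24, n_genes = 80, seed = 6)
  expect_equal(sum(fit_expression_components(ex$median, k = 2,
                                             rotate = FALSE)$eigenvalue_shares),
               100, tolerance = 1e-8)
  un <- fit_expression_components(ex$median, k = 3, rotate = FALSE)
  ro <- fit_expression_components(ex$median, k = 3, rotate = TRUE)
  expect_equal(sum(un$variance_explained), sum(ro$variance_explained),
               tolerance = 1e-8)
  expect_equal(ro$rotation, "varimax")
})

test_that("component orientation is canonical and sign flips are equivalent models", {
  ex <- simulate_expression(n_regions = 24, n_genes = 80, seed = 8)
  fit <- fit_expression_components(ex$median, k = 2)
  for (cc in c("C1", "C2")) {
    l <- fit$loadings[[cc]]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # refitting after negating the input's standardised structure cannot
  # change explained variance
  m <- as.matrix(ex$median[-(1:2)])
  neg <- make_expression_df(-m)
  fit2 <- fit_expression_components(neg, k = 2)
  expect_equal(fit2$variance_explained, fit$variance_explained,
               tolerance = 1e-8)
})

test_that("congruence matches the direct formula and its symmetries", {
  x <- c(1, 2, 3)
  expect_equal(congruence_coefficient(x, 2 * x), 1, tolerance = 1e-12)
  expect_equal(congruence_coefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(congruence_coefficient(c(1, 2, 3), c(3, 2, 1)), 10 / 14,
               tolerance = 1e-10)
  set.seed(1)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(congruence_coefficient(a, b), congruence_coefficient(b, a))
  expect_equal(congruence_coefficient(-a, b), -congruence_coefficient(a, b))
  expect_error(congruence_coefficient(c(0, 0), c(1, 1)), "zero vector")
  expect_error(congruence_coefficient(1:3, 1:4), "equal length")
})

test_that("partition stability emits n_folds x n_reps evaluations and separates planted from noise components", {
  ex <- simulate_expression(n_regions = 68, n_genes = 400,
                            planted_var_frac = 0.5, seed = 10)
  rep_counts <- partition_stability(ex$median, n_folds = 5, n_reps = 4,
                                    k = 4, seed = 3)
  expect_equal(nrow(rep_counts), 5 * 4 * 4)
  expect_true(all(rep_counts$abs_phi >= 0 & rep_counts$abs_phi <= 1, na.rm = TRUE))

  sm <- summary(rep_counts)
  expect_gt(sm$mean_abs_phi[sm$component == 1], 0.85)
  expect_gt(sm$mean_abs_phi[sm$component == 2], 0.7)
  expect_lt(max(sm$mean_abs_phi[sm$component >= 3]),
            min(sm$mean_abs_phi[sm$component <= 2]))
})

test_that("partition stability is near-exact for noiseless well-separated structure", {
  set.seed(4)
  s <- qr.Q(qr(matrix(rnorm(40 * 2), 40))) %*% diag(c(3, 1))
  w <- matrix(rnorm(2 * 60), 2)
  df <- make_expression_df(s %*% w)
  rep <- partition_stability(df, n_folds = 4, n_reps = 3, k = 2, seed = 1)
  expect_true(all(rep$abs_phi > 0.9))
  expect_gt(mean(rep$abs_phi), 0.97)
})

test_that("cross-model congruence recovers identity and permuted assignments", {
  ex <- simulate_expression(n_regions = 30, n_genes = 60, seed = 14)
  fit <- fit_expression_components(ex$median, k = 3, rotate = FALSE)
  self <- cross_model_congruence(fit, fit)
  expect_equal(self$assignment$component_b, 1:3)
  expect_true(all(abs(self$assignment$abs_phi - 1) < 1e-12))

  swapped <- fit
  swapped$loadings <- fit$loadings[c("gene", "C1", "C3", "C2")]
  names(swapped$loadings) <- c("gene", "C1", "C2", "C3")
  cm <- cross_model_congruence(fit, swapped)
  expect_equal(cm$assignment$component_b, c(1, 3, 2))
})

test_that("shared planted loadings give high matched congruence across datasets", {
  phis <- vapply(1:3, function(s) {
    ex1 <- simulate_expression(n_regions = 68, n_genes = 800, seed = 100 + s)
    # same regional truth, independent donor noise realisation
    ex2 <- simulate_expression(n_regions = 68, n_genes = 800, seed = 100 + s,
                               donor_noise_sd = 0.4)
    f1 <- fit_expression_components(ex1$median, k = 2, rotate = FALSE)
    f2 <- fit_expression_components(ex2$median, k = 2, rotate = FALSE)
    min(cross_model_congruence(f1, f2)$assignment$abs_phi)
  }, numeric(1))
  expect_true(all(phis > 0.9))
})

test_that("recovered loadings are congruent with the planted truth", {
  phis <- vapply(1:3, function(s) {
    ex <- simulate_expression(n_regions = 68, n_genes = 1000,
                              planted_var_frac = 0.5, seed = 200 + s)
    fit <- fit_expression_components(ex$median, k = 2, rotate = FALSE)
    min(abs(congruence_coefficient(fit$loadings$C1, ex$truth$loadings[, 1])),
        abs(congruence_coefficient(fit$loadings$C2, ex$truth$loadings[, 2])))
  }, numeric(1))
  expect_true(all(phis > 0.95))
})

test_that("k beyond the data rank and zero-variance genes are rejected or dropped", {
  df <- make_rank2_df(n_regions = 10, n_genes = 20)
  expect_error(fit_expression_components(df, k = 12), "at most")
  df$g001 <- 1
  expect_warning(fit_expression_components(df, k = 2), "zero-variance")
})
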