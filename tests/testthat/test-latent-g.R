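# One-factor FIML latent-g model: residualisation, estimation, fit indices
# and factor scores.

sim_battery <- function(n, bm_seed = 1, ...) {
  ex <- simulate_expression(n_regions = 10, n_genes = 20, seed = bm_seed)
  bm <- simulate_beta_maps(ex, seed = bm_seed)
  simulate_cohort(n, bm, ...)
}

test_that("residualising tests removes planted age and sex structure exactly", {
  set.seed(3)
  n <- 1000
  d <- tibble::tibble(age = runif(n, 40, 80), sex = rbinom(n, 1, 0.5))
  d$test_01 <- 2 * d$age
  d$test_02 <- rnorm(n) + 0.5 * scale(d$age)[, 1]
  out <- residualize_tests(d)
  expect_lt(max(abs(out$test_01)), 1e-10)
  expect_lt(abs(cor(out$test_02, d$age)), 1e-10)

  # no planted effects: residuals equal centred scores
  d2 <- tibble::tibble(age = rep(1, 20) + rnorm(20, 0, 1e-9), sex = 0,
                       test_01 = rnorm(20))
  expect_error(residualize_tests(dplyr::mutate(d2, test_01 = 1)), "constant")
})

test_that("a saturated three-test model has zero chi-square at zero df", {
  ch <- sim_battery(400, n_tests = 3, residual_cov = 0, seed = 2)
  m <- fit_latent_g(residualize_tests(ch$phenotypes))
  expect_equal(m$df, 0)
  expect_lt(m$fit$chisq, 1e-4)
  expect_equal(m$fit$rmsea, 0)
  expect_true(is.na(m$fit$tli))
})

test_that("fit indices match hand-evaluated formulas", {
  ix <- fit_indices(50, 20, 500, 30, 100)
  expect_equal(ix$cfi, 1 - 30 / 470, tolerance = 1e-10)
  expect_equal(ix$rmsea, sqrt(30 / 2000), tolerance = 1e-10)
  expect_equal(ix$tli, ((500 / 30) - (50 / 20)) / ((500 / 30) - 1),
               tolerance = 1e-10)
  expect_equal(fit_indices(20, 20, 500, 30, 100)$rmsea, 0)
})

test_that("loadings are recovered within tolerance with and without missingness", {
  errs <- vapply(1:3, function(s) {
    ch <- sim_battery(1000, n_tests = 10, loadings = 0.7, residual_cov = 0,
                      seed = 300 + s)
    m <- fit_latent_g(residualize_tests(ch$phenotypes))
    max(abs(m$lambda - 0.7))
  }, numeric(1))
  expect_true(all(errs < 0.05))

  ch <- sim_battery(1500, n_tests = 8, loadings = 0.7, residual_cov = 0,
                    missing_rate = 0.2, seed = 41)
  m <- fit_latent_g(residualize_tests(ch$phenotypes))
  expect_lt(max(abs(m$lambda - 0.7)), 0.05)
})

test_that("the complete-data fit agrees with an independent ML factor analysis", {
  ch <- sim_battery(800, n_tests = 6, loadings = c(0.8, 0.7, 0.6, 0.7, 0.5, 0.6),
                    residual_cov = 0, seed = 17)
  ph <- residualize_tests(ch$phenotypes)
  m <- fit_latent_g(ph)
  tests <- scale(as.matrix(ph[grep("^test_", names(ph))]))
  fa <- stats::factanal(covmat = cov(tests), factors = 1, n.obs = nrow(tests))
  lam_fa <- as.numeric(fa$loadings)
  expect_equal(unname(m$lambda), lam_fa, tolerance = 0.01)
})

test_that("within-domain residual covariances are recovered", {
  ch <- sim_battery(3000, n_tests = 8, loadings = 0.6, residual_cov = 0.15,
                    seed = 23)
  ph <- residualize_tests(ch$phenotypes)
  doms <- ch$truth$domain_labels
  m <- fit_latent_g(ph, domains = doms, residual_cov_domains = unique(doms))
  offdiag <- vapply(m$residual_cov_pairs, function(pr) m$theta[pr[1], pr[2]],
                    numeric(1))
  expect_equal(mean(offdiag), 0.15, tolerance = 0.05)
  m0 <- fit_latent_g(ph)
  expect_gt(m$fit$cfi, m0$fit$cfi)
})

test_that("factor scores track the planted g and orientation flips correctly", {
  ch <- sim_battery(1000, n_tests = 10, loadings = 0.7, seed = 31)
  ph <- residualize_tests(ch$phenotypes)
  m <- fit_latent_g(ph, reference_test = "test_01")
  expect_gt(cor(m$scores, ch$truth$g), 0.9)
  flipped <- orient_g(-m$scores, ph$test_01)
  expect_equal(attr(flipped, "orientation"), -1)
  expect_gt(cor(as.numeric(flipped), ph$test_01, use = "complete.obs"), 0)
})

test_that("regression scores follow the model-implied formula, with the single-indicator limit", {
  lambda <- c(1, 0.01, 0.01)
  psi <- c(1e-6, 1, 1)
  sigma <- tcrossprod(lambda) + diag(psi)
  model <- structure(list(lambda = setNames(lambda, paste0("test_0", 1:3)),
                          mu = rep(0, 3), implied_sigma = sigma,
                          orientation = 1,
                          tests = paste0("test_0", 1:3)),
                     class = "latent_g")
  set.seed(5)
  d <- tibble::tibble(test_01 = rnorm(200), test_02 = rnorm(200),
                      test_03 = rnorm(200))
  sc <- factor_scores(model, d)
  expect_equal(cor(sc, scale(d$test_01)[, 1]), 1, tolerance = 1e-3)

  d$test_02[1:50] <- NA
  sc2 <- factor_scores(model, d)
  expect_true(all(is.finite(sc2)))
  d_all_na <- d
  d_all_na[1, paste0("test_0", 1:3)] <- NA
  expect_true(is.na(factor_scores(model, d_all_na)[1]))
})

test_that("the fit is invariant to affine rescaling of an input test", {
  ch <- sim_battery(600, n_tests = 5, loadings = 0.7, seed = 53)
  ph <- residualize_tests(ch$phenotypes)
  m1 <- fit_latent_g(ph)
  ph2 <- dplyr::mutate(ph, test_03 = 100 + 7 * .data$test_03)
  m2 <- fit_latent_g(ph2)
  expect_equal(unname(m1$lambda), unname(m2$lambda), tolerance = 1e-5)
  expect_equal(m1$scores, m2$scores, tolerance = 1e-5)
  expect_equal(m1$fit$chisq, m2$fit$chisq, tolerance = 1e-5)
})

test_that("tidy and glance expose loadings and fit indices", {
  ch <- sim_battery(400, n_tests = 4, seed = 61)
  m <- fit_latent_g(residualize_tests(ch$phenotypes))
  td <- tidy(m)
  expect_named(td, c("test", "loading", "residual_variance"))
  gl <- glance(m)
  expect_true(all(c("cfi", "tli", "rmsea", "srmr", "chisq") %in% names(gl)))
  expect_gt(gl$cfi, 0.8)
})
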