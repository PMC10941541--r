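# One-factor confirmatory factor model of general cognitive functioning (g):
# full-information maximum likelihood over missingness patterns, optional
# within-domain residual covariances, normal-theory fit indices, and
# regression-method factor scores.
#
# The casewise normal likelihood is evaluated on per-pattern sufficient
# statistics; the saturated mean/covariance model (the chi-square reference)
# is fitted by EM when data are incomplete, and the independence baseline
# factorises per variable.

#' Residualise cognitive tests for age and sex
#'
#' Replaces each test column with the residuals of its least-squares
#' regression on age and sex, preserving the missingness pattern.
#'
#' @param data Data frame of participants.
#' @param tests Character vector of test column names; defaults to columns
#'   starting with `"test_"`.
#' @param age,sex Names of the age and sex columns.
#' @return `data` with the test columns residualised.
#' @export
residualize_tests <- function(data, tests = NULL, age = "age", sex = "sex") {
  if (is.null(tests)) tests <- grep("^test_", names(data), value = TRUE)
  if (length(tests) == 0) abort("No test columns found.")
  for (tt in tests) {
    y <- data[[tt]]
    ok <- !is.na(y) & !is.na(data[[age]]) & !is.na(data[[sex]])
    if (sum(ok) < 10) abort(sprintf("Test `%s` has fewer than 10 complete cases.", tt))
    if (sd(y[ok]) == 0) abort(sprintf("Test `%s` is constant.", tt))
    fit <- lm(y ~ a + s, data = data.frame(y = y[ok], a = data[[age]][ok],
                                           s = data[[sex]][ok]))
    out <- rep(NA_real_, length(y))
    out[ok] <- stats::resid(fit)
    data[[tt]] <- out
  }
  data
}

# ---- pattern-wise FIML machinery ------------------------------------------

# Split rows of y by missingness pattern; keep sufficient statistics.
fiml_patterns <- function(y) {
  obs <- !is.na(y)
  key <- apply(obs, 1, paste, collapse = "")
  keep <- rowSums(obs) > 0
  split_idx <- split(which(keep), key[keep])
  lapply(split_idx, function(idx) {
    o <- which(obs[idx[1], ])
    yo <- y[idx, o, drop = FALSE]
    nk <- length(idx)
    ybar <- colMeans(yo)
    s <- crossprod(sweep(yo, 2, ybar)) / nk
    list(obs = o, n = nk, ybar = ybar, s = s, rows = idx)
  })
}

# -2 log-likelihood of N(mu, sigma) over the missingness patterns; when
# `with_grad`, also accumulates d(-2ll)/dmu and the symmetric-matrix
# derivative G with d(-2ll) = tr(G dSigma).
fiml_m2ll <- function(mu, sigma, patterns, with_grad = FALSE) {
  total <- 0
  p <- length(mu)
  g_mu <- if (with_grad) numeric(p)
  g_sig <- if (with_grad) matrix(0, p, p)
  for (pt in patterns) {
    o <- pt$obs
    sig <- sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) {
      return(if (with_grad) list(value = 1e10, ok = FALSE) else 1e10)
    }
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    d <- pt$ybar - mu[o]
    total <- total + pt$n * (length(o) * log(2 * pi) + logdet +
                               sum(inv * pt$s) + drop(t(d) %*% inv %*% d))
    if (with_grad) {
      invd <- inv %*% d
      g_mu[o] <- g_mu[o] - 2 * pt$n * invd
      g_sig[o, o] <- g_sig[o, o] +
        pt$n * (inv - inv %*% pt$s %*% inv - tcrossprod(invd))
    }
  }
  if (with_grad) list(value = total, g_mu = g_mu, g_sig = g_sig, ok = TRUE)
  else total
}

# Gradient of the one-factor -2ll in theta = (mu, lambda, log psi, rescov).
lgm_gradient <- function(theta, p, cov_pairs, patterns) {
  lambda <- theta[(p + 1):(2 * p)]
  psi <- exp(theta[(2 * p + 1):(3 * p)])
  sigma <- lgm_sigma(theta, p, cov_pairs)
  gr <- fiml_m2ll(theta[1:p], sigma, patterns, with_grad = TRUE)
  if (!gr$ok) return(numeric(length(theta)))
  g <- gr$g_sig
  out <- c(gr$g_mu, 2 * drop(g %*% lambda), diag(g) * psi)
  if (length(cov_pairs)) {
    out <- c(out, vapply(cov_pairs, function(pr) 2 * g[pr[1], pr[2]],
                         numeric(1)))
  }
  out
}

# Saturated (unstructured mean/covariance) FIML fit; EM when incomplete.
fiml_saturated <- function(y, patterns, tol = 1e-8, max_iter = 500) {
  p <- ncol(y)
  n <- sum(vapply(patterns, `[[`, numeric(1), "n"))
  complete <- length(patterns) == 1 && length(patterns[[1]]$obs) == p
  if (complete) {
    mu <- patterns[[1]]$ybar
    sigma <- patterns[[1]]$s
    return(list(mu = mu, sigma = sigma, m2ll = fiml_m2ll(mu, sigma, patterns)))
  }
  mu <- vapply(seq_len(p), function(j) mean(y[, j], na.rm = TRUE), numeric(1))
  sigma <- diag(vapply(seq_len(p), function(j) {
    v <- var(y[, j], na.rm = TRUE)
    if (!is.finite(v) || v <= 0) 1 else v
  }, numeric(1)), p)
  last <- Inf
  for (it in seq_len(max_iter)) {
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    for (pt in patterns) {
      o <- pt$obs
      mis <- setdiff(seq_len(p), o)
      yo <- y[pt$rows, o, drop = FALSE]
      if (length(mis) == 0) {
        sum_y <- sum_y + colSums(yo)
        sum_yy <- sum_yy + crossprod(yo)
        next
      }
      inv_oo <- solve(sigma[o, o, drop = FALSE])
      b <- sigma[mis, o, drop = FALSE] %*% inv_oo
      cond_cov <- sigma[mis, mis, drop = FALSE] -
        b %*% sigma[o, mis, drop = FALSE]
      em <- sweep(yo, 2, mu[o]) %*% t(b)
      em <- sweep(em, 2, mu[mis], "+")
      full <- matrix(0, pt$n, p)
      full[, o] <- yo
      full[, mis] <- em
      sum_y <- sum_y + colSums(full)
      cp <- crossprod(full)
      cp[mis, mis] <- cp[mis, mis] + pt$n * cond_cov
      sum_yy <- sum_yy + cp
    }
    mu <- sum_y / n
    sigma <- sum_yy / n - tcrossprod(mu)
    cur <- fiml_m2ll(mu, sigma, patterns)
    if (is.finite(last) && abs(last - cur) < tol * (abs(cur) + 1)) break
    last <- cur
  }
  list(mu = mu, sigma = sigma, m2ll = fiml_m2ll(mu, sigma, patterns))
}

# Independence baseline: per-variable ML over observed cases.
fiml_independence <- function(y) {
  p <- ncol(y)
  m2ll <- 0
  for (j in seq_len(p)) {
    v <- y[!is.na(y[, j]), j]
    s2 <- mean((v - mean(v))^2)
    m2ll <- m2ll + length(v) * (log(2 * pi * s2) + 1)
  }
  m2ll
}

# ---- the one-factor model --------------------------------------------------

# theta = c(mu (p), lambda (p), log psi (p), rescov (q))
lgm_sigma <- function(theta, p, cov_pairs) {
  lambda <- theta[(p + 1):(2 * p)]
  psi <- exp(theta[(2 * p + 1):(3 * p)])
  sigma <- tcrossprod(lambda) + diag(psi, p)
  if (length(cov_pairs)) {
    rc <- theta[(3 * p + 1):length(theta)]
    for (i in seq_along(cov_pairs)) {
      pr <- cov_pairs[[i]]
      sigma[pr[1], pr[2]] <- sigma[pr[1], pr[2]] + rc[i]
      sigma[pr[2], pr[1]] <- sigma[pr[1], pr[2]]
    }
  }
  sigma
}

#' Fit a one-factor latent g model by FIML
#'
#' Maximum-likelihood one-factor confirmatory factor model with the factor
#' variance fixed to 1 (so loadings are comparable across tests), estimated
#' by full-information maximum likelihood over the observed missingness
#' patterns. Tests are standardised internally (observed mean/SD), making
#' the fit invariant to affine rescaling of any input test. Residual
#' variances are optimised on the log scale, so Heywood cases cannot go
#' negative; near-zero variances are flagged. Optionally, free residual
#' covariances are added for every pair of tests sharing a domain label in
#' `residual_cov_domains` (approximating a hierarchical domain structure).
#'
#' @param data Data frame containing the (already residualised) test scores.
#' @param tests Test column names; defaults to columns starting `"test_"`.
#' @param domains Per-test domain labels (same length as `tests`).
#' @param residual_cov_domains Domain labels whose within-domain test pairs
#'   receive free residual covariances.
#' @param reference_test Optional name of a higher-is-better test used to
#'   orient the factor: scores are flipped if they correlate negatively with
#'   it.
#' @param chisq_scale `"n"` (normal-theory default, chi-square = n * F_ML)
#'   or `"n-1"`.
#' @param max_restarts Random restarts attempted on non-convergence.
#' @return Object of class `"latent_g"` with `lambda` (standardised-test
#'   loadings), `theta` (residual covariance matrix), `mu`, `fit` (chi
#'   squares, df, CFI, TLI, RMSEA, SRMR), `scores` (per-participant g,
#'   regression method; NA when every test is missing), `orientation`,
#'   `logLik`, `n`, `convergence` details.
#' @export
fit_latent_g <- function(data, tests = NULL, domains = NULL,
                         residual_cov_domains = NULL,
                         reference_test = NULL,
                         chisq_scale = c("n", "n-1"),
                         max_restarts = 5) {
  chisq_scale <- match.arg(chisq_scale)
  if (is.null(tests)) tests <- grep("^test_", names(data), value = TRUE)
  p <- length(tests)
  if (p < 3) abort("Need at least 3 tests for one-factor identifiability.")
  y_raw <- as.matrix(data[tests])
  centre <- colMeans(y_raw, na.rm = TRUE)
  scl <- apply(y_raw, 2, sd, na.rm = TRUE)
  if (any(!is.finite(scl) | scl == 0)) abort("Constant test column.")
  y <- sweep(sweep(y_raw, 2, centre), 2, scl, "/")
  n <- sum(rowSums(!is.na(y)) > 0)

  cov_pairs <- list()
  if (!is.null(residual_cov_domains)) {
    if (is.null(domains) || length(domains) != p) {
      abort("`domains` must be given (one label per test) to use residual covariances.")
    }
    for (dd in unique(residual_cov_domains)) {
      members <- which(domains == dd)
      if (length(members) >= 2) {
        prs <- combn(members, 2, simplify = FALSE)
        cov_pairs <- c(cov_pairs, prs)
      }
    }
  }
  q <- length(cov_pairs)
  df_model <- p * (p + 1) / 2 - 2 * p - q
  if (df_model < 0) abort("Model has negative degrees of freedom.")

  patterns <- fiml_patterns(y)

  # starting values: loadings from the first eigenvector of the
  # available-case correlation matrix
  r0 <- suppressWarnings(cor(y, use = "pairwise.complete.obs"))
  r0[!is.finite(r0)] <- 0
  diag(r0) <- 1
  e1 <- eigen(r0, symmetric = TRUE)
  lam0 <- e1$vectors[, 1] * sqrt(max(e1$values[1], 1))
  if (mean(lam0) < 0) lam0 <- -lam0
  lam0 <- pmin(pmax(lam0, -0.95), 0.95)
  start <- c(colMeans(y, na.rm = TRUE), lam0, log(pmax(1 - lam0^2, 0.05)),
             rep(0, q))

  objective <- function(theta) {
    fiml_m2ll(theta[1:p], lgm_sigma(theta, p, cov_pairs), patterns)
  }
  gradient <- function(theta) lgm_gradient(theta, p, cov_pairs, patterns)

  fit <- optim(start, objective, gradient, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-10))
  restart <- 0
  trace <- tibble(restart = 0, convergence = fit$convergence, m2ll = fit$value)
  while (fit$convergence != 0 && restart < max_restarts) {
    restart <- restart + 1
    jitter <- with_seed(restart, rnorm(length(start), 0, 0.1))
    alt <- optim(start + jitter, objective, gradient, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-10))
    trace <- dplyr::bind_rows(trace, tibble(restart = restart,
                                            convergence = alt$convergence,
                                            m2ll = alt$value))
    if (alt$value < fit$value || fit$convergence != 0) fit <- alt
  }
  if (fit$convergence != 0) {
    abort(paste0("One-factor FIML fit did not converge; trace:\n",
                 paste(utils::capture.output(print(trace)), collapse = "\n")))
  }

  theta <- fit$par
  mu <- theta[1:p]
  lambda <- theta[(p + 1):(2 * p)]
  psi <- exp(theta[(2 * p + 1):(3 * p)])
  if (any(psi < 1e-5)) {
    warn("Near-zero residual variance (Heywood tendency); floored at 1e-6.")
    psi <- pmax(psi, 1e-6)
  }
  if (mean(lambda) < 0) lambda <- -lambda  # canonical direction
  sigma <- lgm_sigma(c(mu, lambda, log(psi), theta[seq_len(q) + 3 * p]),
                     p, cov_pairs)
  names(lambda) <- tests

  sat <- fiml_saturated(y, patterns)
  m2ll_model <- fit$value
  chisq <- max(m2ll_model - sat$m2ll, 0)
  chisq_b <- max(fiml_independence(y) - sat$m2ll, 0)
  df_b <- p * (p + 1) / 2 - p
  if (chisq_scale == "n-1") {
    chisq <- chisq * (n - 1) / n
    chisq_b <- chisq_b * (n - 1) / n
  }
  srmr <- srmr_value(sat$sigma, sigma)
  fit_ix <- fit_indices(chisq, df_model, chisq_b, df_b, n, srmr = srmr)

  scores <- lgm_scores(y, mu, lambda, sigma)
  orientation <- 1
  if (!is.null(reference_test)) {
    ref <- y[, match(reference_test, tests)]
    r <- suppressWarnings(cor(scores, ref, use = "pairwise.complete.obs"))
    if (is.finite(r) && r < 0) {
      orientation <- -1
      scores <- -scores
    }
  }

  structure(
    list(
      lambda = lambda,
      theta = sigma - tcrossprod(lambda),
      mu = mu,
      residual_cov_pairs = cov_pairs,
      fit = fit_ix,
      scores = scores,
      orientation = orientation,
      logLik = -m2ll_model / 2,
      n = n,
      df = df_model,
      tests = tests,
      convergence = trace,
      implied_sigma = sigma,
      saturated = sat
    ),
    class = "latent_g"
  )
}

# Regression-method factor scores per missingness pattern.
lgm_scores <- function(y, mu, lambda, sigma) {
  n <- nrow(y)
  p <- ncol(y)
  scores <- rep(NA_real_, n)
  obs <- !is.na(y)
  key <- apply(obs, 1, paste, collapse = "")
  for (kk in unique(key)) {
    rows <- which(key == kk)
    o <- which(obs[rows[1], ])
    if (length(o) == 0) next
    w <- solve(sigma[o, o, drop = FALSE], lambda[o])
    scores[rows] <- sweep(y[rows, o, drop = FALSE], 2, mu[o]) %*% w
  }
  scores
}

# Root mean square standardised residual, lower triangle incl. diagonal,
# both matrices standardised by the observed (saturated) variances.
srmr_value <- function(s_obs, s_imp) {
  d_obs <- sqrt(diag(s_obs))
  r_obs <- s_obs / tcrossprod(d_obs)
  r_imp <- s_imp / tcrossprod(d_obs)
  resid <- (r_obs - r_imp)[lower.tri(r_obs, diag = TRUE)]
  sqrt(mean(resid^2))
}

#' Normal-theory fit indices
#'
#' Computes CFI, TLI, RMSEA (and passes through SRMR) from model and
#' independence-baseline chi-square statistics:
#' `CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b, chisq_m - df_m, 0)`,
#' `TLI = ((chisq_b/df_b) - (chisq_m/df_m)) / ((chisq_b/df_b) - 1)`,
#' `RMSEA = sqrt(max(chisq_m - df_m, 0) / (df_m * n))`. For a saturated
#' model (`df_m = 0`) RMSEA is 0 and TLI is undefined (NA).
#'
#' @param chisq,df Model chi-square and degrees of freedom.
#' @param chisq_baseline,df_baseline Independence-model chi-square and df.
#' @param n Sample size.
#' @param srmr Optional SRMR to carry through.
#' @return One-row tibble `chisq`, `df`, `p`, `chisq_baseline`,
#'   `df_baseline`, `cfi`, `tli`, `rmsea`, `srmr`.
#' @export
fit_indices <- function(chisq, df, chisq_baseline, df_baseline, n, srmr = NA_real_) {
  num <- max(chisq - df, 0)
  den <- max(chisq_baseline - df_baseline, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (df == 0) {
    tli <- NA_real_
    rmsea <- 0
  } else {
    ratio_b <- chisq_baseline / df_baseline
    tli <- (ratio_b - chisq / df) / (ratio_b - 1)
    rmsea <- sqrt(max(chisq - df, 0) / (df * n))
  }
  tibble(
    chisq = chisq, df = df,
    p = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    chisq_baseline = chisq_baseline, df_baseline = df_baseline,
    cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr
  )
}

#' Orient factor scores against a reference
#'
#' Multiplies scores by -1 when they correlate negatively with a
#' higher-is-better reference measure, so that higher g reflects better
#' performance.
#'
#' @param scores Numeric factor scores.
#' @param reference Numeric reference values (same length).
#' @return Oriented scores with attribute `"orientation"` (+1 or -1).
#' @export
orient_g <- function(scores, reference) {
  r <- suppressWarnings(cor(scores, reference, use = "pairwise.complete.obs"))
  flip <- is.finite(r) && r < 0
  out <- if (flip) -scores else scores
  attr(out, "orientation") <- if (flip) -1 else 1
  out
}

#' Factor scores for new data
#'
#' Regression-method g scores from a fitted [fit_latent_g()] model, using
#' each participant's observed tests only.
#'
#' @param model A `"latent_g"` object.
#' @param data Data frame containing the model's test columns (on the scale
#'   of the data the model was fitted to).
#' @return Numeric vector of scores (NA when all tests are missing).
#' @export
factor_scores <- function(model, data) {
  stopifnot(inherits(model, "latent_g"))
  y_raw <- as.matrix(data[model$tests])
  centre <- colMeans(y_raw, na.rm = TRUE)
  scl <- apply(y_raw, 2, sd, na.rm = TRUE)
  y <- sweep(sweep(y_raw, 2, centre), 2, scl, "/")
  model$orientation * lgm_scores(y, model$mu, model$lambda, model$implied_sigma)
}

#' @export
print.latent_g <- function(x, ...) {
  cat(sprintf("<latent_g> %d tests, n = %d, df = %d\n",
              length(x$lambda), x$n, x$df))
  cat(sprintf("  chisq = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$fit$chisq, x$fit$cfi, x$fit$tli, x$fit$rmsea, x$fit$srmr))
  invisible(x)
}

#' @rdname fit_latent_g
#' @param x A `"latent_g"` object.
#' @param ... Unused.
#' @export
tidy.latent_g <- function(x, ...) {
  tibble(
    test = x$tests,
    loading = unname(x$lambda),
    residual_variance = diag(x$theta)
  )
}

#' @rdname fit_latent_g
#' @export
glance.latent_g <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n, logLik = x$logLik), x$fit)
}
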