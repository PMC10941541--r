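# Random-effects pooling of regional standardised betas across cohorts:
# DerSimonian-Laird estimation, the region-by-measure grid with BH-FDR,
# and age-moderation meta-regression.

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments random-effects meta-analysis of study estimates:
#' with fixed-effect weights `w = 1/se^2`, `Q = sum(w * (b - b_fixed)^2)`,
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`; pooled
#' estimate and SE use weights `1/(se^2 + tau2)` and the p-value comes from
#' the standard normal reference.
#'
#' @param beta Study estimates.
#' @param se Study standard errors (> 0).
#' @return One-row tibble `beta`, `se`, `tau2`, `q`, `k`, `p`,
#'   `fixed_beta`, `fixed_se`, `degenerate` (TRUE when k = 1).
#' @examples
#' dersimonian_laird(c(0.10, 0.15, 0.05), c(0.02, 0.05, 0.04))
#' @export
dersimonian_laird <- function(beta, se) {
  k <- length(beta)
  if (k < 1) abort("Need at least one study.")
  if (length(se) != k || any(!is.finite(se)) || any(se <= 0)) {
    abort("`se` must be positive and match `beta` in length.")
  }
  w <- 1 / se^2
  fixed <- sum(w * beta) / sum(w)
  fixed_se <- sqrt(1 / sum(w))
  if (k == 1) {
    return(tibble(beta = beta, se = se, tau2 = 0, q = 0, k = 1L,
                  p = 2 * pnorm(-abs(beta / se)),
                  fixed_beta = fixed, fixed_se = fixed_se, degenerate = TRUE))
  }
  q <- sum(w * (beta - fixed)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * beta) / sum(ws)
  pooled_se <- sqrt(1 / sum(ws))
  tibble(beta = pooled, se = pooled_se, tau2 = tau2, q = q, k = as.integer(k),
         p = 2 * pnorm(-abs(pooled / pooled_se)),
         fixed_beta = fixed, fixed_se = fixed_se, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted Q values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at 1),
#' invariant to input order.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted Q values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("P-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Meta-analyse the regional association grid
#'
#' Pools the per-cohort standardised betas for every region-by-measure cell
#' with [dersimonian_laird()] and applies BH-FDR within each measure family
#' (optionally globally). A cell present in only some cohorts is pooled over
#' the cohorts that have it, with `k` recording how many contributed.
#'
#' @param associations Stacked output of [regional_g_associations()] across
#'   cohorts: needs columns `cohort`, `region`, `measure`, `beta`, `se`.
#' @param fdr_family `"measure"` (default: BH across regions within each
#'   measure) or `"global"` (across the whole grid).
#' @return Tibble with one row per region-by-measure: `region`,
#'   `hemisphere` (if present), `measure`, `beta`, `se`, `tau2`, `q`, `k`,
#'   `p`, `fdr_q`.
#' @export
run_meta_grid <- function(associations, fdr_family = c("measure", "global")) {
  fdr_family <- match.arg(fdr_family)
  hemi <- if ("hemisphere" %in% names(associations)) {
    distinct(associations, .data$region, .data$hemisphere)
  } else {
    NULL
  }
  out <- associations |>
    group_by(.data$region, .data$measure) |>
    summarise(dersimonian_laird(.data$beta, .data$se), .groups = "drop")
  out <- if (fdr_family == "measure") {
    out |>
      group_by(.data$measure) |>
      mutate(fdr_q = bh_fdr(.data$p)) |>
      ungroup()
  } else {
    out |> mutate(fdr_q = bh_fdr(.data$p))
  }
  if (!is.null(hemi)) {
    out <- left_join(out, hemi, by = "region") |>
      dplyr::relocate("hemisphere", .after = "region")
  }
  out |> dplyr::select(-"degenerate")
}

#' Age-moderation meta-regression
#'
#' For every region-by-measure cell, regresses the cohort betas on cohort
#' mean age by weighted least squares, with the between-cohort variance
#' re-estimated by the method of moments under the moderator model (floored
#' at zero) and used in the weights. Slopes are tested against the standard
#' normal; BH-FDR is applied across the grid.
#'
#' @param associations Stacked per-cohort associations (as in
#'   [run_meta_grid()]).
#' @param cohort_ages Named vector: mean age per cohort.
#' @return Tibble `region`, `measure`, `slope`, `se`, `tau2`, `k`, `p`,
#'   `fdr_q`.
#' @export
age_moderation <- function(associations, cohort_ages) {
  fit_one <- function(beta, se, age) {
    k <- length(beta)
    if (k < 3) abort("Age moderation needs at least 3 cohorts.")
    if (sd(age) == 0) abort("Cohort mean ages are identical (collinear with intercept).")
    x <- cbind(1, age)
    w <- 1 / se^2
    xtwx <- crossprod(x, w * x)
    b_f <- solve(xtwx, crossprod(x, w * beta))
    e <- beta - x %*% b_f
    q_e <- sum(w * e^2)
    # trace of P = W - WX(X'WX)^-1 X'W
    p_tr <- sum(w) - sum(diag(solve(xtwx, crossprod(x, w^2 * x))))
    tau2 <- max(0, (q_e - (k - 2)) / p_tr)
    ws <- 1 / (se^2 + tau2)
    xtwx_s <- crossprod(x, ws * x)
    b <- solve(xtwx_s, crossprod(x, ws * beta))
    vcv <- solve(xtwx_s)
    slope <- b[2]
    slope_se <- sqrt(vcv[2, 2])
    tibble(slope = slope, se = slope_se, tau2 = tau2, k = as.integer(k),
           p = 2 * pnorm(-abs(slope / slope_se)))
  }
  associations |>
    mutate(mean_age = unname(cohort_ages[.data$cohort])) |>
    group_by(.data$region, .data$measure) |>
    summarise(fit_one(.data$beta, .data$se, .data$mean_age), .groups = "drop") |>
    mutate(fdr_q = bh_fdr(.data$p))
}
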