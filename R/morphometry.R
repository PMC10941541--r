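# Per-cohort, per-region standardised associations between g and cortical
# morphometry, with covariate control, 4-SD outlier exclusion and
# whole-cortex (global-measure) variants.

#' Exclude extreme regional values
#'
#' Sets to missing any value lying more than `sd_threshold` standard
#' deviations from the mean of its region-measure column, with the mean and
#' SD computed once from the full sample.
#'
#' @param morphometry Long tibble: `id`, `region`, `hemisphere`, one column
#'   per measure.
#' @param measures Measure columns to screen; default all value columns.
#' @param sd_threshold Exclusion threshold in SD units (default 4).
#' @return The tibble with outliers set to NA; per-region exclusion counts
#'   in attribute `"exclusions"` (tibble `region`, `measure`, `n_excluded`).
#' @export
exclude_outliers <- function(morphometry, measures = NULL, sd_threshold = 4) {
  if (is.null(measures)) {
    measures <- setdiff(names(morphometry), c("id", REGION_COLS))
  }
  counts <- list()
  for (m in measures) {
    vals <- morphometry[[m]]
    for (r in unique(morphometry$region)) {
      idx <- which(morphometry$region == r & !is.na(vals))
      if (length(idx) < 10) abort("Need at least 10 observations per region.")
      v <- vals[idx]
      s <- sd(v)
      if (s == 0) {
        warn(sprintf("Zero variance for %s in %s; no exclusions.", m, r))
        next
      }
      z <- (v - mean(v)) / s
      out <- abs(z) > sd_threshold
      if (any(out)) vals[idx[out]] <- NA
      counts[[length(counts) + 1L]] <- tibble(region = r, measure = m,
                                              n_excluded = sum(out))
    }
    morphometry[[m]] <- vals
  }
  attr(morphometry, "exclusions") <- list_rbind(counts)
  morphometry
}

# One standardised regression: y and g z-scored on the analysis sample,
# beta/SE/p for the g coefficient from least squares with covariates.
standardised_beta <- function(y, g, covars) {
  ok <- if (ncol(covars) == 0) {
    complete.cases(y, g)
  } else {
    complete.cases(y, g, covars)
  }
  n <- sum(ok)
  if (n < 50) abort("Fewer than 50 complete cases for a regional model.")
  x <- cbind(intercept = 1, g = zscale(g[ok]),
             as.matrix(covars[ok, , drop = FALSE]))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    abort(paste0("Rank-deficient design; offending column(s): ",
                 paste(bad, collapse = ", ")))
  }
  yz <- zscale(y[ok])
  fit <- lm.fit(x, yz)
  rss <- sum(fit$residuals^2)
  df <- n - ncol(x)
  xtxinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(rss / df * diag(xtxinv))
  b <- fit$coefficients["g"]
  se_g <- se[which(colnames(x) == "g")]
  tibble(beta = unname(b), se = se_g, n = n, df = df,
         p = 2 * pt(abs(b / se_g), df, lower.tail = FALSE))
}

# Expand covariate columns: factors/characters become centred dummy codes.
covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) return(matrix(0, nrow(data), 0))
  pieces <- lapply(covariates, function(cc) {
    v <- data[[cc]]
    if (is.numeric(v)) {
      out <- matrix(v, ncol = 1, dimnames = list(NULL, cc))
    } else {
      lev <- sort(unique(na.omit(v)))
      if (length(lev) < 2) return(NULL)
      out <- vapply(lev[-1], function(l) as.numeric(v == l), numeric(length(v)))
      colnames(out) <- paste0(cc, "_", lev[-1])
      out[is.na(v), ] <- NA
    }
    out
  })
  do.call(cbind, pieces[!vapply(pieces, is.null, logical(1))])
}

#' Regional standardised g-morphometry associations
#'
#' For every region and morphometry measure, estimates the standardised
#' association between g and the regional measure by least squares, with the
#' measure and g z-scored on the analysis sample and covariates (age, sex,
#' scanner head position, site dummies, optional appointment lag and
#' optional global measure) controlled. Missing covariates imply casewise
#' deletion.
#'
#' @param morphometry Long tibble (`id`, `region`, `hemisphere`, measure
#'   columns), typically after [exclude_outliers()].
#' @param phenotypes One row per participant; must contain `id`, the
#'   covariates, and a `g` column (or pass `g_scores`).
#' @param g_scores Optional named vector of g scores (names = `id`),
#'   overriding `phenotypes$g`.
#' @param measures Measure columns; default all value columns.
#' @param covariates Covariate column names in `phenotypes`; character
#'   columns are dummy-coded.
#' @param global_measure Optional named list mapping measure name to a
#'   per-participant global value (e.g. whole-cortex volume) to control.
#' @param cohort Cohort label stamped on the output.
#' @return Tibble `cohort`, `region`, `hemisphere`, `measure`, `beta`,
#'   `se`, `n`, `df`, `p`.
#' @export
regional_g_associations <- function(morphometry, phenotypes,
                                    g_scores = NULL,
                                    measures = NULL,
                                    covariates = c("age", "sex", "head_x",
                                                   "head_y", "head_z", "site"),
                                    global_measure = NULL,
                                    cohort = "cohort") {
  if (is.null(measures)) {
    measures <- setdiff(names(morphometry), c("id", REGION_COLS))
  }
  covariates <- intersect(covariates, names(phenotypes))
  g <- if (!is.null(g_scores)) {
    unname(g_scores[phenotypes$id])
  } else {
    phenotypes$g
  }
  if (is.null(g)) abort("No g scores supplied.")
  covm <- covariate_matrix(phenotypes, covariates)

  rows <- list()
  for (m in measures) {
    wide <- morphometry |>
      dplyr::select(dplyr::all_of(c("id", REGION_COLS, m))) |>
      tidyr::pivot_wider(names_from = "region", values_from = dplyr::all_of(m),
                         id_cols = "id")
    wide <- wide[match(phenotypes$id, wide$id), ]
    hemi <- morphometry |>
      distinct(.data$region, .data$hemisphere)
    covm_m <- covm
    if (!is.null(global_measure[[m]])) {
      covm_m <- cbind(covm, global = unname(global_measure[[m]][phenotypes$id]))
    }
    for (r in setdiff(names(wide), "id")) {
      est <- standardised_beta(wide[[r]], g, as.data.frame(covm_m))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(cohort = cohort, region = r,
               hemisphere = hemi$hemisphere[match(r, hemi$region)],
               measure = m),
        est
      )
    }
  }
  list_rbind(rows)
}

#' Whole-cortex g associations
#'
#' Sums volume and surface area (and averages thickness) across regions per
#' participant and estimates the same standardised model as
#' [regional_g_associations()] on the totals — the identical code path, so
#' regional and whole-cortex estimates are directly comparable. The returned
#' totals can also be passed back as `global_measure` to correct regional
#' associations for the whole-cortex measure.
#'
#' @inheritParams regional_g_associations
#' @param summary_fun Named list mapping measure to the across-region
#'   summary function (default sum for volume/surface area, mean for
#'   thickness).
#' @return List with `associations` (tibble as in
#'   [regional_g_associations()], region = `"whole_cortex"`) and `totals`
#'   (named list of per-participant global values).
#' @export
whole_cortex_associations <- function(morphometry, phenotypes,
                                      g_scores = NULL, measures = NULL,
                                      covariates = c("age", "sex", "head_x",
                                                     "head_y", "head_z", "site"),
                                      summary_fun = list(volume = sum,
                                                         surface_area = sum,
                                                         thickness = mean),
                                      cohort = "cohort") {
  if (is.null(measures)) {
    measures <- setdiff(names(morphometry), c("id", REGION_COLS))
  }
  totals <- list()
  long <- list()
  for (m in measures) {
    f <- summary_fun[[m]] %||% sum
    tot <- morphometry |>
      group_by(.data$id) |>
      summarise(value = f(.data[[m]]), .groups = "drop")
    totals[[m]] <- setNames(tot$value, tot$id)
    long[[m]] <- tot |>
      mutate(region = "whole_cortex", hemisphere = "both") |>
      rename(!!m := "value")
  }
  combined <- purrr::reduce(long, function(a, b) {
    left_join(a, b, by = c("id", "region", "hemisphere"))
  })
  assoc <- regional_g_associations(
    combined, phenotypes, g_scores = g_scores, measures = measures,
    covariates = covariates, cohort = cohort
  )
  list(associations = assoc, totals = totals)
}
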