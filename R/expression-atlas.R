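# Regional expression assembly and quality control: median summaries across
# donors, the donor-consistency gene filter, and hemisphere-wise rescaling.

#' Median expression across donors
#'
#' Summarises donor-level regional expression to a single regions-by-genes
#' table by taking, for every region-gene cell, the median over the donors
#' that cover that region.
#'
#' @param donors Long tibble with columns `donor`, `region`, `hemisphere`,
#'   `gene`, `expression`. Donors may be missing regions; every region must
#'   be covered by at least one donor.
#' @return Wide expression tibble (`region`, `hemisphere`, one column per
#'   gene).
#' @export
median_across_donors <- function(donors) {
  required <- c("donor", "region", "hemisphere", "gene", "expression")
  if (!all(required %in% names(donors))) {
    abort(paste0("`donors` must have columns ", paste(required, collapse = ", "), "."))
  }
  missing_rows <- donors |>
    group_by(.data$region) |>
    summarise(all_na = all(is.na(.data$expression)), .groups = "drop") |>
    filter(.data$all_na)
  if (nrow(missing_rows) > 0) {
    abort(paste0("Regions covered by no donor: ",
                 paste(missing_rows$region, collapse = ", ")))
  }
  donors |>
    group_by(.data$region, .data$hemisphere, .data$gene) |>
    summarise(expression = median(.data$expression, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "expression") |>
    arrange(match(.data$region, unique(donors$region)))
}

#' Donor-consistency gene filter
#'
#' For each gene, correlates (Spearman) every donor's regional expression
#' profile with the cross-donor median profile over the designated
#' hemisphere's regions, averages the correlations across donors, and
#' retains genes whose mean correlation strictly exceeds `threshold`. The
#' default threshold 0.446 is the published constant for this filter (quoted
#' as equivalent to one-sided p < .05); it is a configuration value, not
#' recomputed from the region count. Genes retained in the designated
#' hemisphere are retained everywhere.
#'
#' @param donors Long donor tibble as in [median_across_donors()].
#' @param median_df Optional wide median expression tibble; computed from
#'   `donors` when omitted.
#' @param threshold Retention threshold on the mean Spearman correlation
#'   (strictly greater).
#' @param hemisphere Hemisphere whose regions define the profiles
#'   ("left"/"right").
#' @return Tibble `gene`, `mean_rho`, `retained`, in the gene order of the
#'   input. A donor-gene profile with zero rank variance contributes a
#'   correlation of 0 (with a warning).
#' @export
donor_consistency_filter <- function(donors, median_df = NULL,
                                     threshold = 0.446,
                                     hemisphere = "left") {
  if (is.null(median_df)) median_df <- median_across_donors(donors)
  check_expression_df(median_df, "median_df")
  med <- expr_matrix(median_df)
  keep_regions <- median_df$region[median_df$hemisphere == hemisphere]
  if (length(keep_regions) < 2) {
    abort("Need at least 2 regions in the designated hemisphere.")
  }
  med <- med[match(keep_regions, rownames(med)), , drop = FALSE]

  donor_ids <- unique(donors$donor)
  genes <- colnames(med)

  # donor x region x gene cube over the designated hemisphere
  wide <- donors |>
    filter(.data$region %in% keep_regions) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "expression")
  rho_sum <- matrix(0, length(donor_ids), length(genes),
                    dimnames = list(donor_ids, genes))
  n_const <- 0L
  for (d in donor_ids) {
    dm <- wide |> filter(.data$donor == d)
    m <- as.matrix(dm[genes])
    rownames(m) <- dm$region
    common <- intersect(rownames(m), keep_regions)
    if (length(common) < 2) {
      abort(sprintf("Donor %s has fewer than 2 regions in the %s hemisphere.",
                    d, hemisphere))
    }
    dr <- apply(m[common, , drop = FALSE], 2, rank)
    mr <- apply(med[common, , drop = FALSE], 2, rank)
    dsd <- apply(dr, 2, sd)
    msd <- apply(mr, 2, sd)
    ok <- dsd > 0 & msd > 0
    n_const <- n_const + sum(!ok)
    rho <- numeric(length(genes))
    if (any(ok)) {
      rho[ok] <- vapply(which(ok), function(j) cor(dr[, j], mr[, j]), numeric(1))
    }
    rho_sum[d, ] <- rho
  }
  if (n_const > 0) {
    warn(sprintf("%d donor-gene profiles had zero rank variance; they contribute rho = 0.",
                 n_const))
  }
  mean_rho <- unname(colMeans(rho_sum))
  tibble(gene = genes, mean_rho = mean_rho, retained = mean_rho > threshold)
}

#' Hemisphere-wise standardisation of regional maps
#'
#' Standardises each value column to mean 0 and sample SD 1 (n - 1
#' denominator) separately within the left and right hemispheres. This
#' removes the hemisphere mean-offset sampling artefact from regional maps
#' (component scores, single-gene profiles, cell-type mean profiles) before
#' spatial analysis. Idempotent.
#'
#' @param df Tibble with `region`, `hemisphere` and one or more numeric
#'   columns.
#' @param cols Columns to rescale (tidy-select); defaults to all value
#'   columns.
#' @return `df` with the selected columns rescaled within hemisphere.
#' @export
scale_by_hemisphere <- function(df, cols = NULL) {
  check_expression_df(df)
  target <- if (is.null(cols)) gene_cols(df) else {
    names(tidyselect::eval_select(rlang::enquo(cols), df))
  }
  for (h in unique(df$hemisphere)) {
    idx <- which(df$hemisphere == h)
    if (length(idx) < 2) abort("Need at least 2 regions per hemisphere.")
    sub <- as.matrix(df[idx, target])
    sds <- apply(sub, 2, sd)
    if (any(!is.finite(sds) | sds == 0)) {
      abort(paste0("Zero within-hemisphere variance in column(s): ",
                   paste(target[!is.finite(sds) | sds == 0], collapse = ", ")))
    }
    df[idx, target] <- as_tibble(scale(sub))
  }
  df
}
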