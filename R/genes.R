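# Component-adjusted single-gene and cell-type associations with regional
# g-maps, the three-measure intersection selection rule, and cell-type
# loading-distribution tests.

# Hemisphere-scale, then globally z-score, the gene columns of a wide
# expression table; returns a regions x genes matrix.
scaled_gene_matrix <- function(expression, genes = NULL) {
  check_expression_df(expression)
  if (!is.null(genes)) {
    expression <- dplyr::select(expression,
                                dplyr::all_of(c(REGION_COLS, genes)))
  }
  scaled <- scale_by_hemisphere(expression)
  m <- expr_matrix(scaled)
  scale(m)
}

# Pivot wide g-map table to a named list of aligned numeric vectors.
gmap_list <- function(g_maps, region_order) {
  check_expression_df(g_maps, "g_maps")
  idx <- match(region_order, g_maps$region)
  if (anyNA(idx)) abort("`g_maps` regions do not match the expression regions.")
  lapply(setNames(gene_cols(g_maps), gene_cols(g_maps)),
         function(m) g_maps[[m]][idx])
}

component_score_matrix <- function(components, region_order) {
  scores <- if (inherits(components, "expression_pca")) components$scores else components
  check_expression_df(scores, "components")
  idx <- match(region_order, scores$region)
  if (anyNA(idx)) abort("Component scores do not cover every region.")
  as.matrix(scores[idx, gene_cols(scores)[1:2]])
}

# Core vectorised adjusted regression of one z-scored map on each z-scored
# gene profile plus the two component score maps.
adjusted_fit <- function(g_mat, y, s) {
  n <- length(y)
  x <- cbind(1, s)
  qx <- qr(x)
  resid_of <- function(v) v - x %*% qr.coef(qx, v)
  yr <- drop(resid_of(y))
  gr <- apply(g_mat, 2, function(v) drop(resid_of(v)))
  den <- unname(colSums(gr^2))
  num <- unname(drop(crossprod(gr, yr)))
  beta <- num / den
  df <- n - ncol(x) - 1
  rss <- sum(yr^2) - num^2 / den
  se <- sqrt(pmax(rss, 0) / df / den)
  t_stat <- beta / se
  tibble(
    gene = colnames(g_mat),
    beta = beta, se = se, df = df,
    p = 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  )
}

#' Component-adjusted single-gene g-map associations
#'
#' For every gene, regresses the (z-scored) regional g-association map on
#' the gene's hemisphere-scaled regional expression profile while
#' controlling for the two major component score maps; the gene coefficient
#' is the component-adjusted standardised association. BH-FDR is applied
#' within each measure across all tested genes. Genes whose profile is
#' nearly collinear with the component scores (multiple correlation >
#' 0.999) are flagged.
#'
#' @param expression Wide median expression tibble (raw scale; hemisphere
#'   scaling is applied internally).
#' @param g_maps Wide tibble `region`, `hemisphere`, one column per
#'   morphometry measure (e.g. pooled meta-analytic betas).
#' @param components An `"expression_pca"` fit (or its scores tibble); the
#'   first two score columns are the adjustment maps.
#' @param genes Optional subset of genes to test (default: all columns).
#' @param perms Optional `"spin_perms"`; when supplied, a spin p-value is
#'   computed for every tested gene by permuting the gene profile with the
#'   shared permutation set (covariates held fixed).
#' @return Tibble `gene`, `measure`, `beta`, `se`, `df`, `p`, `fdr_q`,
#'   `collinear`, and `p_spin` when `perms` is given.
#' @export
gene_g_associations <- function(expression, g_maps, components,
                                genes = NULL, perms = NULL) {
  g_mat <- scaled_gene_matrix(expression, genes)
  region_order <- expression$region
  s <- component_score_matrix(components, region_order)
  maps <- gmap_list(g_maps, region_order)

  # collinearity with the component maps: multiple correlation of each gene
  # profile on [1, s1, s2]
  xs <- cbind(1, s)
  qs <- qr(xs)
  g_res <- g_mat - xs %*% qr.coef(qs, g_mat)
  tot <- colSums(scale(g_mat, scale = FALSE)^2)
  r2 <- 1 - colSums(g_res^2) / tot
  collinear <- sqrt(pmax(r2, 0)) > 0.999
  if (any(collinear)) {
    warn(sprintf("%d gene profile(s) are collinear with the component scores.",
                 sum(collinear)))
  }

  out <- purrr::imap(maps, function(y, m) {
    res <- adjusted_fit(g_mat, zscale(y), s)
    res$measure <- m
    res$collinear <- collinear
    # a profile indistinguishable from the covariates has no identified
    # coefficient; keep the row but mask the estimate
    res[collinear, c("beta", "se", "p")] <- NA_real_
    res$fdr_q <- NA_real_
    res$fdr_q[!collinear] <- bh_fdr(res$p[!collinear])
    if (!is.null(perms)) {
      res$p_spin <- spin_p_genes(g_mat, zscale(y), s, perms,
                                 observed = res$beta)
    }
    res
  }) |>
    list_rbind() |>
    dplyr::relocate("measure", .after = "gene")
  out
}

# Spin p-values for every column of g_mat against one map.
spin_p_genes <- function(g_mat, y, s, perms, observed) {
  n_perm <- nrow(perms)
  x <- cbind(1, s)
  qx <- qr(x)
  resid_of <- function(v) v - x %*% qr.coef(qx, v)
  yr <- drop(resid_of(y))
  count <- numeric(ncol(g_mat))
  for (i in seq_len(n_perm)) {
    gp <- g_mat[perms[i, ], , drop = FALSE]
    gr <- apply(gp, 2, function(v) drop(resid_of(v)))
    beta_null <- drop(crossprod(gr, yr)) / colSums(gr^2)
    count <- count + (abs(beta_null) >= abs(observed))
  }
  (1 + count) / (1 + n_perm)
}

#' Select candidate genes across the three morphometry measures
#'
#' The three-stage selection rule: (1) per-measure FDR significance; (2)
#' genes significant for all three measures; (3) within the intersection,
#' spin-test p below threshold for all three measures (spin p-values are
#' computed only for the intersection, using the shared permutation set).
#'
#' @param associations Output of [gene_g_associations()] (without spin
#'   p-values; they are computed here for the intersection).
#' @param expression,g_maps,components As in [gene_g_associations()].
#' @param perms A `"spin_perms"` object for stage 3.
#' @param fdr_threshold,spin_threshold Stage thresholds (default .05).
#' @return List with `genes` (the selected ids), `audit` (set sizes per
#'   stage/measure) and `details` (per-gene association rows for the
#'   intersection, including `p_spin`).
#' @export
select_candidate_genes <- function(associations, expression, g_maps,
                                   components, perms,
                                   fdr_threshold = 0.05,
                                   spin_threshold = 0.05) {
  measures <- unique(associations$measure)
  if (length(measures) < 3) abort("Associations for three measures are required.")
  per_measure <- lapply(setNames(measures, measures), function(m) {
    associations$gene[which(associations$measure == m &
                              associations$fdr_q < fdr_threshold)]
  })
  intersection <- purrr::reduce(per_measure, intersect)

  details <- NULL
  selected <- character(0)
  if (length(intersection) > 0) {
    details <- gene_g_associations(expression, g_maps, components,
                                   genes = intersection, perms = perms)
    spin_ok <- details |>
      group_by(.data$gene) |>
      summarise(pass = all(.data$p_spin < spin_threshold), .groups = "drop")
    selected <- spin_ok$gene[spin_ok$pass]
  }
  audit <- dplyr::bind_rows(
    tibble(stage = "fdr_per_measure", measure = measures,
           n = unname(lengths(per_measure)[measures])),
    tibble(stage = "intersection", measure = "all",
           n = length(intersection)),
    tibble(stage = "spin_filtered", measure = "all",
           n = length(selected))
  )
  list(genes = selected, audit = audit, details = details)
}

#' Cell-type mean-profile associations with g-maps
#'
#' Averages the expression profiles of each cell type's genes, hemisphere
#' scales the mean profile, and tests its component-adjusted association
#' with every g-map exactly as for single genes; BH-FDR is applied across
#' the cell-type-by-measure family.
#'
#' @param expression Wide median expression tibble (raw scale).
#' @param cell_map Tibble `gene`, `cell_type` (genes absent from it are
#'   treated as unclassified and are not tested here).
#' @param g_maps,components,perms As in [gene_g_associations()].
#' @param min_genes Minimum genes per cell type (default 2; smaller sets
#'   are skipped with a warning).
#' @return Tibble `cell_type`, `n_genes`, `measure`, `beta`, `se`, `p`,
#'   `fdr_q` (and `p_spin` when `perms` is given).
#' @export
celltype_g_associations <- function(expression, cell_map, g_maps,
                                    components, perms = NULL,
                                    min_genes = 2) {
  check_expression_df(expression)
  genes_avail <- gene_cols(expression)
  in_matrix <- cell_map$gene %in% genes_avail
  types <- split(cell_map$gene[in_matrix], cell_map$cell_type[in_matrix])
  small <- names(types)[lengths(types) < min_genes]
  if (length(small)) {
    warn(paste0("Skipping cell type(s) with fewer than ", min_genes,
                " genes: ", paste(small, collapse = ", ")))
    types <- types[lengths(types) >= min_genes]
  }
  if (length(types) == 0) abort("No cell type has enough genes.")

  raw <- expr_matrix(expression)
  prof <- vapply(types, function(gs) rowMeans(raw[, gs, drop = FALSE]),
                 numeric(nrow(raw)))
  prof_df <- dplyr::bind_cols(
    tibble(region = expression$region, hemisphere = expression$hemisphere),
    as_tibble(prof)
  )
  res <- gene_g_associations(prof_df, g_maps, components, perms = perms) |>
    rename(cell_type = "gene") |>
    mutate(n_genes = unname(lengths(types)[.data$cell_type]),
           .after = "cell_type")
  # FDR family: all tested cell types x measures
  res$fdr_q <- bh_fdr(res$p)
  res
}

# Sample skewness g1 and kurtosis (raw fourth-moment b2; excess = b2 - 3).
moment_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x, excess = FALSE) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - if (excess) 3 else 0
}

#' Dunn's pairwise rank tests against a control group
#'
#' Kruskal-Wallis-style pairwise z statistics on the pooled ranks, with the
#' tie-corrected variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N - 1))) * (1/n_i + 1/n_j)`, comparing
#' each group against the control; p-values are Holm-adjusted over the
#' family.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @param control Name of the control/baseline group.
#' @param p_adjust Adjustment method (default `"holm"`).
#' @return Tibble `group`, `z`, `p`, `p_adjusted`.
#' @export
dunn_control_test <- function(values, groups, control, p_adjust = "holm") {
  groups <- as.character(groups)
  if (!control %in% groups) abort("`control` must be one of the groups.")
  r <- rank(values)
  n_total <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  var_base <- n_total * (n_total + 1) / 12 - tie_term
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  others <- setdiff(names(mean_rank), control)
  z <- vapply(others, function(gg) {
    (mean_rank[[gg]] - mean_rank[[control]]) /
      sqrt(var_base * (1 / n_g[[gg]] + 1 / n_g[[control]]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  tibble(group = others, z = unname(z), p = unname(p),
         p_adjusted = p.adjust(p, method = p_adjust))
}

#' Distribution of component loadings across cell types
#'
#' Per component: descriptive moments (mean, SD, skewness, kurtosis) of the
#' loadings per cell-type group (genes not in `cell_map` form the
#' "unclassified" baseline), a Kruskal-Wallis test of a cell-classification
#' main effect, and Dunn post-hoc z tests of each cell type against the
#' unclassified baseline with Holm-adjusted p-values.
#'
#' @param components An `"expression_pca"` fit or its loadings tibble
#'   (`gene` plus one column per component).
#' @param cell_map Tibble `gene`, `cell_type`.
#' @param kurtosis_excess Report excess kurtosis instead of the raw
#'   fourth-moment convention (default FALSE: raw).
#' @return List with `moments` (per component x group), `kruskal` (per
#'   component H, df, p) and `dunn` (per component x cell type z, p,
#'   Holm-adjusted p); the kurtosis convention is recorded in the
#'   `"kurtosis"` attribute.
#' @export
loading_distribution_tests <- function(components, cell_map,
                                       kurtosis_excess = FALSE) {
  loadings <- if (inherits(components, "expression_pca")) {
    components$loadings
  } else {
    components
  }
  comp_cols <- setdiff(names(loadings), "gene")
  grp <- cell_map$cell_type[match(loadings$gene, cell_map$gene)]
  grp[is.na(grp)] <- "unclassified"
  sizes <- table(grp)
  if (sum(sizes >= 2) < 2) abort("Need at least 2 groups with at least 2 members.")
  if (any(sizes < 1)) grp <- droplevels(grp)

  moments <- list()
  kruskal <- list()
  dunn <- list()
  for (cc in comp_cols) {
    v <- loadings[[cc]]
    moments[[cc]] <- tibble(
      component = cc,
      cell_type = names(sizes),
      n = as.integer(sizes),
      mean = tapply(v, grp, mean)[names(sizes)],
      sd = tapply(v, grp, sd)[names(sizes)],
      skewness = tapply(v, grp, moment_skewness)[names(sizes)],
      kurtosis = tapply(v, grp, function(x) {
        moment_kurtosis(x, excess = kurtosis_excess)
      })[names(sizes)]
    )
    kw <- kruskal.test(v, factor(grp))
    kruskal[[cc]] <- tibble(component = cc,
                            h = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p = kw$p.value)
    dunn[[cc]] <- dunn_control_test(v, grp, control = "unclassified") |>
      mutate(component = cc, .before = 1) |>
      rename(cell_type = "group")
  }
  out <- list(moments = list_rbind(moments),
              kruskal = list_rbind(kruskal),
              dunn = list_rbind(dunn))
  attr(out, "kurtosis") <- if (kurtosis_excess) "excess" else "raw"
  out
}

#' Export loading-threshold gene sets
#'
#' Utility listing, per component and threshold, the genes whose loadings
#' exceed the threshold in either direction — the sets conventionally
#' submitted to external gene-ontology overrepresentation tools (no
#' enrichment is computed here).
#'
#' @param components An `"expression_pca"` fit or loadings tibble.
#' @param thresholds Positive loading thresholds (default 0.3 and 0.6).
#' @return Tibble `component`, `threshold`, `direction`, `gene`.
#' @export
loading_threshold_sets <- function(components, thresholds = c(0.3, 0.6)) {
  loadings <- if (inherits(components, "expression_pca")) {
    components$loadings
  } else {
    components
  }
  comp_cols <- setdiff(names(loadings), "gene")
  rows <- list()
  for (cc in comp_cols) {
    for (th in thresholds) {
      for (dir in c("positive", "negative")) {
        sel <- if (dir == "positive") loadings[[cc]] > th else loadings[[cc]] < -th
        if (any(sel)) {
          rows[[length(rows) + 1L]] <- tibble(
            component = cc, threshold = th, direction = dir,
            gene = loadings$gene[sel]
          )
        }
      }
    }
  }
  list_rbind(rows)
}
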