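# ggplot2 methods for the main result types.

#' Plot component scores against each other
#'
#' Scatter of the hemisphere-scaled regional scores on the first two
#' components, coloured by hemisphere.
#'
#' @param object An `"expression_pca"` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expression_pca <- function(object, ...) {
  comp <- gene_cols(object$scores)[1:2]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[comp[1]]], y = .data[[comp[2]]],
                               colour = .data$hemisphere)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste0(comp[1], " score (", object$rotation, ")"),
      y = paste0(comp[2], " score (", object$rotation, ")"),
      title = "Regional component scores (scaled per hemisphere)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot partition-stability congruence by component
#'
#' Boxplots of the absolute congruence coefficients between small-set and
#' large-set solutions across all train/test evaluations, by component
#' index. High, tight boxes for the leading components and a drop from the
#' third onwards indicate that the major components do not rely on
#' individual regions.
#'
#' @param object A `"congruence_report"` from [partition_stability()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.congruence_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$component), y = .data$abs_phi)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Component", y = "|congruence|",
                  title = "Partition stability of expression components") +
    ggplot2::theme_minimal()
}

#' Plot meta-analytic g-association maps
#'
#' Pooled standardised beta per region, ordered by effect size, one facet
#' per morphometry measure; FDR-significant regions are filled.
#'
#' @param meta Output of [run_meta_grid()].
#' @param fdr_threshold Significance threshold for the fill (default .05).
#' @return A ggplot.
#' @export
plot_meta_associations <- function(meta, fdr_threshold = 0.05) {
  ggplot2::ggplot(
    meta |>
      mutate(significant = .data$fdr_q < fdr_threshold),
    ggplot2::aes(x = .data$beta,
                 y = stats::reorder(.data$region, .data$beta),
                 alpha = .data$significant)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0
    ) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3)) +
    ggplot2::labs(x = "Pooled standardised β", y = NULL,
                  title = "Meta-analytic regional g associations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot a g-map against component scores
#'
#' Scatter of a regional g-association map against one component's scores
#' with a quadratic fit, illustrating the balance pattern (stronger
#' g-regions near score zero).
#'
#' @param g_map Wide map tibble (`region`, `hemisphere`, measure columns).
#' @param components An `"expression_pca"` fit.
#' @param measure Measure column to plot.
#' @param component Score column (default first).
#' @return A ggplot.
#' @export
plot_balance <- function(g_map, components, measure = "volume",
                         component = NULL) {
  scores <- components$scores
  comp <- component %||% gene_cols(scores)[1]
  df <- left_join(g_map, scores, by = c("region", "hemisphere"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[comp]], y = .data[[measure]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hemisphere)) +
    ggplot2::geom_smooth(formula = y ~ x + I(x^2), method = "lm",
                         se = FALSE, colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = paste(comp, "score"),
                  y = paste("g ~", measure, "standardised β"),
                  title = "Balance between component ends and g associations") +
    ggplot2::theme_minimal()
}
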