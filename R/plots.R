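#' Volcano plot of variant test results
#'
#' @param object A `promvar_tests` tibble.
#' @param causal_q FDR threshold highlighted (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.promvar_tests <- function(object, causal_q = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(significant = .data$q <= causal_q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#2166ac"),
                                 name = sprintf("FDR ≤ %g", causal_q)) +
    ggplot2::labs(x = expression(log[2] ~ "fold-change (RM - BY)"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-replicate activity for the two alleles of a variant
#'
#' Boxplots of per-replicate log2 activity for the BY and RM oligos of
#' one variant, with lines connecting replicates.
#'
#' @param expression Expression tibble (`oligo_id`, `replicate`,
#'   `activity`).
#' @param pairs Pair table from [variant_pairs()].
#' @param variant Variant id to display.
#' @return A ggplot.
#' @export
plot_allele_activity <- function(expression, pairs, variant) {
  pr <- pairs %>% filter(.data$variant_id == variant)
  if (nrow(pr) == 0) abort(sprintf("variant '%s' not found in pairs", variant))
  df <- expression %>%
    filter(.data$oligo_id %in% c(pr$by_oligo[1], pr$rm_oligo[1])) %>%
    mutate(allele = ifelse(.data$oligo_id == pr$by_oligo[1], "BY", "RM"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$allele, y = .data$activity)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       colour = "grey50", alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$replicate))) +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "RNA/DNA"),
                  colour = "replicate", title = variant) +
    ggplot2::theme_minimal()
}

#' Model performance bars for a set of evaluated prediction models
#'
#' @param results Rows from [fit_and_evaluate()] (a `auc` or `rho`
#'   column).
#' @return A ggplot.
#' @export
plot_model_performance <- function(results) {
  metric <- if ("auc" %in% names(results)) "auc" else "rho"
  ggplot2::ggplot(results,
                  ggplot2::aes(x = stats::reorder(.data$model_id,
                                                  .data[[metric]]),
                               y = .data[[metric]])) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::glance
glance.promvar_tests <- function(x, ...) {
  tibble(n_variants = nrow(x),
         n_significant = sum(x$q <= 0.05),
         pi1 = estimate_pi1(x$p)$pi1,
         median_abs_logFC = median(abs(x$logFC)))
}

#' @exportS3Method generics::tidy
tidy.promvar_tests <- function(x, ...) {
  as_tibble(x)
}
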