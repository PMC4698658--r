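#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparisons of an ANOVA + Tukey HSD fit
#'
#' @param x an `anova_tukey` from [compare_groups_anova()].
#' @param ... unused.
#' @return Tibble of pairwise mean differences with Tukey-adjusted p-values.
#' @exportS3Method generics::tidy
tidy.anova_tukey <- function(x, ...) x$tukey

#' One-row summary of an ANOVA + Tukey HSD fit
#'
#' @param x an `anova_tukey`.
#' @param ... unused.
#' @return Tibble with the F statistic, degrees of freedom and overall p.
#' @exportS3Method generics::glance
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value)
}

#' Per-group sizes of a log-rank comparison
#'
#' @param x a `logrank_result` from [logrank_test()].
#' @param ... unused.
#' @return Tibble with one row per group.
#' @exportS3Method generics::tidy
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(group = names(x$group_sizes),
                 n = unlist(x$group_sizes, use.names = FALSE))
}

#' One-row summary of a log-rank test
#'
#' @param x a `logrank_result`.
#' @param ... unused.
#' @return Tibble with `chi_square`, `df`, `p_value`.
#' @exportS3Method generics::glance
glance.logrank_result <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value)
}

#' Per-gene cumulative rank-sums of a signature
#'
#' @param x a `signature_result` from [rank_and_aggregate()].
#' @param ... unused.
#' @return Tibble of genes with rank-sums and signature membership.
#' @exportS3Method generics::tidy
tidy.signature_result <- function(x, ...) {
  dplyr::mutate(x$rank_sums,
                in_top = .data$gene %in% x$top_genes,
                in_bottom = .data$gene %in% x$bottom_genes)
}

#' One-row summary of a signature derivation
#'
#' @param x a `signature_result`.
#' @param ... unused.
#' @return Tibble with counts and the rank-order convention used.
#' @exportS3Method generics::glance
glance.signature_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$rank_sums),
                 n_types = length(unique(x$ranks$cancer_type)),
                 n_top = length(x$top_genes),
                 n_bottom = length(x$bottom_genes),
                 rank_order = x$rank_order)
}

#' Kaplan-Meier step plot of a survival comparison
#'
#' @param object a `survival_comparison` from [survival_compare()].
#' @param ... unused.
#' @return A ggplot of the per-group survival curves, annotated with the
#'   log-rank p-value.
#' @exportS3Method ggplot2::autoplot
autoplot.survival_comparison <- function(object, ...) {
  curves <- dplyr::bind_rows(
    purrr::map_dfr(unique(object$curves$group), function(g)
      tibble::tibble(group = g, time = 0, n_risk = NA_integer_,
                     n_event = 0L, n_censor = 0L, estimate = 1)),
    object$curves)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$estimate,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  subtitle = sprintf("Log-rank p = %.3g", object$logrank$p_value)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of EMT scores by group
#'
#' @param score_table output of [compute_emt_score()].
#' @param group grouping column (default `sample_type`).
#' @return A ggplot.
#' @export
plot_emt_scores <- function(score_table, group = "sample_type") {
  ggplot2::ggplot(score_table,
                  ggplot2::aes(x = .data[[group]], y = .data$emt_score)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "EMT score") +
    ggplot2::theme_minimal()
}

#' Frequency plot of an enrichment screen
#'
#' Plots per-gene metastatic vs primary alteration frequencies, highlighting
#' Bonferroni-significant genes.
#'
#' @param screen output of [run_enrichment_screen()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(x = .data$freq_primary,
                                       y = .data$freq_metastatic,
                                       colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Frequency in primary tumors",
                  y = "Frequency in metastatic tumors",
                  colour = "Bonferroni\nsignificant") +
    ggplot2::theme_minimal()
}
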