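#' Per-sample EMT score
#'
#' The EMT score of a sample is the sum of its mesenchymal gene expression
#' minus the sum of its epithelial gene expression, on log2-transformed
#' values. Genes missing from the expression matrix are dropped (see
#' [validate_gene_sets()]); the genes actually used are recorded as
#' attributes `"mesenchymal_used"` and `"epithelial_used"`.
#'
#' @param cohort an [omics_cohort()].
#' @param emt_sets an [emt_gene_sets()].
#' @return Tibble with columns `sample_id`, `cancer_type`, `sample_type`,
#'   `emt_score`.
#' @export
compute_emt_score <- function(cohort, emt_sets = default_emt_gene_sets()) {
  stopifnot(inherits(cohort, "omics_cohort"))
  validate_gene_sets(cohort, emt_sets = emt_sets)
  expr <- cohort$expression
  mes <- intersect(emt_sets$mesenchymal, rownames(expr))
  epi <- intersect(emt_sets$epithelial, rownames(expr))
  score <- colSums(expr[mes, , drop = FALSE]) -
    colSums(expr[epi, , drop = FALSE])
  out <- dplyr::mutate(
    dplyr::select(cohort$clinical, "sample_id", "cancer_type", "sample_type"),
    emt_score = unname(score[cohort$sample_ids]))
  attr(out, "mesenchymal_used") <- mes
  attr(out, "epithelial_used") <- epi
  out
}

#' Split values at their arithmetic mean
#'
#' Labels each value `"high"` if it is greater than or equal to the mean of
#' the values being split, `"low"` otherwise (ties at the mean are high).
#' The threshold is attached as attribute `"threshold"`. If all values are
#' identical every sample is labeled high, with a warning.
#'
#' @param values finite numeric vector, length >= 2.
#' @return Factor with levels `low`, `high` and attribute `threshold`.
#' @export
stratify_by_mean <- function(values) {
  if (length(values) < 2) rlang::abort("need at least 2 values to stratify")
  if (!all(is.finite(values))) rlang::abort("values must be finite")
  thr <- mean(values)
  if (length(unique(values)) == 1L) {
    rlang::warn("all values identical; every sample labeled 'high' (mean attained)")
  }
  labels <- factor(ifelse(values >= thr, "high", "low"), levels = c("low", "high"))
  attr(labels, "threshold") <- thr
  labels
}

#' Classify samples into low/high EMT groups
#'
#' Adds an `emt_class` column to an EMT score table by splitting scores at
#' their mean ([stratify_by_mean()]). By default the mean is computed over
#' tumor samples only (primary + metastatic) and other sample types are left
#' unclassified (`NA`), since survival analyses concern tumors; set
#' `tumors_only = FALSE` to split over all samples.
#'
#' @param score_table output of [compute_emt_score()] (or any tibble with
#'   `emt_score` and `sample_type` columns).
#' @param tumors_only restrict the mean and the classification to
#'   primary/metastatic samples.
#' @return The input tibble plus `emt_class` (`low`/`high`), with the
#'   threshold in attribute `"threshold"`.
#' @export
classify_emt <- function(score_table, tumors_only = TRUE) {
  use <- if (tumors_only) {
    score_table$sample_type %in% c("primary", "metastatic")
  } else rep(TRUE, nrow(score_table))
  if (sum(use) < 2) rlang::abort("fewer than 2 samples to classify")
  labels <- stratify_by_mean(score_table$emt_score[use])
  score_table$emt_class <- factor(NA, levels = c("low", "high"))
  score_table$emt_class[use] <- labels
  attr(score_table, "threshold") <- attr(labels, "threshold")
  score_table
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Compares a numeric response (typically the EMT score) across groups
#' (typically sample types) with a one-way ANOVA F-test followed by Tukey's
#' honest-significant-difference test for all pairwise mean differences
#' (Tukey-Kramer for unequal group sizes). Groups with fewer than 2 samples
#' are excluded with a warning.
#'
#' @param data data frame holding the response and grouping columns.
#' @param value,group column names (strings) of the response and the groups.
#' @return An `anova_tukey` object; see [tidy.anova_tukey()] and
#'   [glance.anova_tukey()].
#' @export
compare_groups_anova <- function(data, value = "emt_score", group = "sample_type") {
  y <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("excluding group(s) with < 2 samples: ",
                       paste(small, collapse = ", ")))
    keep2 <- !(g %in% small)
    y <- y[keep2]; g <- g[keep2]
  }
  if (length(unique(g)) < 2) rlang::abort("need at least 2 usable groups")
  g <- factor(g)
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(list(
    f_statistic = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1],
    group_sizes = as.list(table(g)),
    tukey = tibble::tibble(
      group1 = vapply(pairs, `[`, "", 1),
      group2 = vapply(pairs, `[`, "", 2),
      mean_diff = unname(tk[, "diff"]),
      conf_low = unname(tk[, "lwr"]),
      conf_high = unname(tk[, "upr"]),
      p_adj = unname(tk[, "p adj"]))
  ), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey)
  invisible(x)
}
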