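#' Kaplan-Meier product-limit curve
#'
#' Estimates the survival function from right-censored times. Deaths and
#' censorings tied at the same time follow the standard convention: deaths
#' are processed first, so censored observations at an event time remain in
#' the risk set for that event.
#'
#' @param times non-negative follow-up times.
#' @param events 0 (censored) / 1 (death) indicators.
#' @return Tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `estimate` (S(t)); rows at each distinct observed time.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) rlang::abort("empty survival input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 estimate = fit$surv)
}

#' Log-rank (Mantel-Cox) test
#'
#' Compares event distributions between two or more groups over the pooled
#' event times (observed minus expected events with hypergeometric
#' variance); the statistic is chi-square distributed with `k - 1` degrees
#' of freedom. Empty groups are excluded with a warning.
#'
#' @param times,events as in [km_estimate()].
#' @param groups group label per observation.
#' @return A `logrank_result` with `chi_square`, `df`, `p_value` and
#'   `group_sizes`; see [glance.logrank_result()].
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]
  if (is.factor(groups) && any(table(groups[keep]) == 0)) {
    rlang::warn(paste0("excluding group(s) with zero observations: ",
                       paste(names(which(table(groups[keep]) == 0)), collapse = ", ")))
  }
  groups <- as.character(groups)[keep]
  if (length(unique(groups)) < 2) rlang::abort("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  structure(list(
    chi_square = unname(sd$chisq),
    df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    group_sizes = as.list(stats::setNames(as.integer(sd$n),
                                          sub("^groups=", "", names(sd$n))))
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi-square = %.3f, df = %d, p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("Group sizes: %s\n",
              paste(sprintf("%s=%d", names(x$group_sizes),
                            unlist(x$group_sizes)), collapse = ", ")))
  invisible(x)
}

#' Stratify samples by mutation status of one gene
#'
#' @param cohort an [omics_cohort()] with a mutation matrix.
#' @param gene gene symbol present in the mutation matrix.
#' @return Tibble `sample_id`, `label` in \{no_mutation, mutation\}.
#' @export
stratify_mutation <- function(cohort, gene) {
  stopifnot(inherits(cohort, "omics_cohort"))
  gene <- toupper(gene)
  if (is.null(cohort$mutation) || !(gene %in% rownames(cohort$mutation))) {
    rlang::abort(sprintf("gene %s not in the mutation matrix", gene))
  }
  tibble::tibble(
    sample_id = cohort$sample_ids,
    label = factor(ifelse(cohort$mutation[gene, ] == 1, "mutation", "no_mutation"),
                   levels = c("no_mutation", "mutation")))
}

#' Two-group k-means stratification of samples
#'
#' Clusters samples by their profile over a gene set (Euclidean distance,
#' k = 2, best of `n_restarts` random starts by within-cluster sum of
#' squares, fixed seed). Clusters are relabeled deterministically:
#' `cluster_high` is the cluster whose samples have the larger mean value
#' over the gene set, so the labeling does not depend on k-means' arbitrary
#' cluster numbering.
#'
#' @param mat gene-by-sample numeric matrix (e.g. expression or CNA calls).
#' @param genes gene set to cluster on; must be present in `mat`.
#' @param seed integer seed for the restarts.
#' @param n_restarts number of random starts (default 25).
#' @return Tibble `sample_id`, `label` in \{cluster_low, cluster_high\}.
#' @export
kmeans_stratify <- function(mat, genes, seed = 1L, n_restarts = 25L) {
  genes <- intersect(toupper(genes), rownames(mat))
  if (length(genes) == 0) rlang::abort("no listed gene is present in the matrix")
  x <- t(mat[genes, , drop = FALSE])
  if (nrow(x) < 2) rlang::abort("need at least 2 samples")
  if (nrow(unique(x)) < 2) rlang::abort("degenerate clustering input: all samples identical")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2L, nstart = n_restarts)
  means <- tapply(rowMeans(x), km$cluster, mean)
  high_id <- as.integer(names(means)[which.max(means)])
  tibble::tibble(
    sample_id = rownames(x),
    label = factor(ifelse(km$cluster == high_id, "cluster_high", "cluster_low"),
                   levels = c("cluster_low", "cluster_high")))
}

#' Stratify samples by expression of one gene
#'
#' Splits samples into low/high expression of a gene by the mean (default),
#' the median, or two-group k-means on the single gene. The method and
#' threshold (where applicable) are recorded as attributes.
#'
#' @param cohort an [omics_cohort()].
#' @param gene gene symbol in the expression matrix.
#' @param method `"mean"`, `"median"` or `"kmeans"`.
#' @param seed seed for the k-means method.
#' @return Tibble `sample_id`, `label` in \{low, high\}, with attributes
#'   `method` and `threshold` (NA for k-means).
#' @export
stratify_expression <- function(cohort, gene,
                                method = c("mean", "median", "kmeans"),
                                seed = 1L) {
  stopifnot(inherits(cohort, "omics_cohort"))
  method <- match.arg(method)
  gene <- toupper(gene)
  if (!(gene %in% rownames(cohort$expression))) {
    rlang::abort(sprintf("gene %s not in the expression matrix", gene))
  }
  x <- cohort$expression[gene, ]
  if (method == "kmeans") {
    if (length(unique(x)) < 2) rlang::abort("degenerate clustering input: constant expression")
    out <- kmeans_stratify(cohort$expression[gene, , drop = FALSE], gene, seed = seed)
    out$label <- factor(ifelse(out$label == "cluster_high", "high", "low"),
                        levels = c("low", "high"))
    thr <- NA_real_
  } else {
    thr <- if (method == "mean") mean(x) else stats::median(x)
    if (length(unique(x)) == 1L) {
      rlang::warn("constant expression; every sample labeled 'high'")
    }
    out <- tibble::tibble(
      sample_id = cohort$sample_ids,
      label = factor(ifelse(x >= thr, "high", "low"), levels = c("low", "high")))
  }
  attr(out, "method") <- method
  attr(out, "threshold") <- thr
  out
}

#' Combined mutation-by-expression three-group stratification
#'
#' Reproduces the combined stratification of a mutation gene with an
#' expression gene (e.g. TP53 mutation status crossed with SCO2 expression):
#' `wt_low` = wild-type and low expression, `mut_high` = mutant and high
#' expression, `mixed` = exactly one of the two alterations.
#'
#' @param cohort an [omics_cohort()].
#' @param mut_gene gene in the mutation matrix.
#' @param expr_gene gene in the expression matrix.
#' @param expr_method expression split method, see [stratify_expression()].
#' @param seed seed for the k-means expression split.
#' @return Tibble `sample_id`, `label` in \{wt_low, mixed, mut_high\}; the
#'   group sizes are attached as attribute `"group_sizes"`.
#' @export
stratify_combined_mut_expr <- function(cohort, mut_gene, expr_gene,
                                       expr_method = "mean", seed = 1L) {
  mut <- stratify_mutation(cohort, mut_gene)
  expr <- stratify_expression(cohort, expr_gene, method = expr_method, seed = seed)
  is_mut <- mut$label == "mutation"
  is_high <- expr$label == "high"
  lab <- dplyr::case_when(
    !is_mut & !is_high ~ "wt_low",
    is_mut & is_high ~ "mut_high",
    TRUE ~ "mixed")
  out <- tibble::tibble(
    sample_id = mut$sample_id,
    label = factor(lab, levels = c("wt_low", "mixed", "mut_high")))
  attr(out, "group_sizes") <- as.list(table(out$label))
  out
}

#' Compare survival between stratified groups
#'
#' Joins a stratification table to the cohort clinical data, drops samples
#' with missing survival information (with a message), and returns per-group
#' Kaplan-Meier curves plus the log-rank test. Groups with zero usable
#' samples are dropped with a warning.
#'
#' @param cohort an [omics_cohort()].
#' @param strata tibble with columns `sample_id` and `label` (any of the
#'   `stratify_*` outputs).
#' @return A `survival_comparison`: list with `curves` (tibble of per-group
#'   KM curves), `logrank` ([logrank_test()] result) and `n_dropped`.
#' @export
survival_compare <- function(cohort, strata) {
  stopifnot(inherits(cohort, "omics_cohort"))
  d <- dplyr::inner_join(cohort$clinical, strata, by = "sample_id")
  usable <- !is.na(d$os_days) & !is.na(d$os_event) & !is.na(d$label)
  n_drop <- sum(!usable)
  if (n_drop > 0) {
    rlang::inform(sprintf("dropping %d sample(s) with missing survival data", n_drop))
  }
  d <- d[usable, , drop = FALSE]
  d$label <- droplevels(factor(d$label))
  if (nlevels(d$label) < 2) rlang::abort("need at least 2 non-empty groups with survival data")
  curves <- purrr::map_dfr(levels(d$label), function(l) {
    sub <- d[d$label == l, ]
    dplyr::mutate(km_estimate(sub$os_days, sub$os_event), group = l, .before = 1)
  })
  lr <- logrank_test(d$os_days, d$os_event, d$label)
  structure(list(curves = curves, logrank = lr, n_dropped = n_drop),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  print(x$logrank)
  invisible(x)
}
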