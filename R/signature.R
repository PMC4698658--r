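#' Per-cancer Pearson association of gene expression with the EMT score
#'
#' For each cancer type, correlates each gene's expression with the EMT
#' score (sample Pearson r; two-tailed p from the exact t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 df) and controls the family-wise
#' error rate by Bonferroni across the genes tested within that cancer type.
#' Genes with constant expression in a cancer type have undefined r and are
#' reported with `testable = FALSE`.
#'
#' @param cohort an [omics_cohort()].
#' @param emt_scores output of [compute_emt_score()] (or a tibble with
#'   `sample_id` and `emt_score`).
#' @param genes genes to test (intersected with the expression matrix).
#' @param by_cancer if `TRUE` (default) the screen runs within each cancer
#'   type; otherwise once over the whole cohort (`cancer_type = "PANCAN"`).
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @return Tibble with `cancer_type`, `gene`, `n`, `pearson_r`, `p_raw`,
#'   `p_adj`, `significant`, `sign` (`positive`/`negative`/`none`) and
#'   `testable`.
#' @export
pearson_emt_association <- function(cohort, emt_scores, genes,
                                    by_cancer = TRUE, alpha = 0.05) {
  stopifnot(inherits(cohort, "omics_cohort"))
  genes <- intersect(toupper(genes), rownames(cohort$expression))
  if (length(genes) == 0) rlang::abort("no listed gene is present in the expression matrix")
  d <- dplyr::inner_join(
    dplyr::select(cohort$clinical, "sample_id", "cancer_type"),
    dplyr::select(emt_scores, "sample_id", "emt_score"), by = "sample_id")
  if (!by_cancer) d$cancer_type <- "PANCAN"
  purrr::map_dfr(split(d, d$cancer_type), function(block) {
    n <- nrow(block)
    if (n < 3) rlang::abort(sprintf("cancer type %s has fewer than 3 scored samples",
                                    block$cancer_type[1]))
    score <- block$emt_score
    if (stats::sd(score) == 0) {
      rlang::abort(sprintf("EMT scores are constant in cancer type %s",
                           block$cancer_type[1]))
    }
    res <- purrr::map_dfr(genes, function(g) {
      x <- cohort$expression[g, block$sample_id]
      if (stats::sd(x) == 0) {
        return(tibble::tibble(cancer_type = block$cancer_type[1], gene = g,
                              n = n, pearson_r = NA_real_, p_raw = NA_real_,
                              testable = FALSE))
      }
      r <- stats::cor(x, score)
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      tibble::tibble(cancer_type = block$cancer_type[1], gene = g, n = n,
                     pearson_r = r,
                     p_raw = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
                     testable = TRUE)
    })
    m <- sum(res$testable)
    res$p_adj <- ifelse(res$testable, pmin(1, res$p_raw * m), NA_real_)
    res$significant <- !is.na(res$p_adj) & res$p_adj <= alpha
    res$sign <- dplyr::case_when(
      res$significant & res$pearson_r > 0 ~ "positive",
      res$significant & res$pearson_r < 0 ~ "negative",
      TRUE ~ "none")
    res
  })
}

# IRLS fit of a univariate logistic model; convergence/separation flags
# are reported rather than hidden behind warnings.
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L) {
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = tol,
                                                                  maxit = max_iter)))
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  fitted <- stats::fitted(fit)
  separation <- !fit$converged || abs(beta) > 20 ||
    all(fitted > 1 - 1e-8 | fitted < 1e-8)
  z <- beta / se
  p_wald <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  null_dev <- fit$null.deviance
  p_lr <- stats::pchisq(null_dev - stats::deviance(fit), df = 1,
                        lower.tail = FALSE)
  list(beta = beta, se = se, p_wald = p_wald, p_lr = p_lr,
       separation = separation, converged = fit$converged)
}

#' Per-cancer logistic regression of EMT class on gene expression
#'
#' Fits, per cancer type and per gene, a univariate logistic regression of
#' the binary EMT class (high = 1) on the gene's log2 expression by maximum
#' likelihood (IRLS, tolerance 1e-8, up to 100 iterations) and reports the
#' slope, the odds ratio (`exp(beta)`), the two-tailed Wald chi-square p
#' used for ranking, and a likelihood-ratio p for comparison. Complete or
#' quasi-complete separation is flagged and the Wald p replaced by the
#' smallest positive double so the gene ranks as maximally significant.
#'
#' @param cohort an [omics_cohort()].
#' @param emt_class tibble with `sample_id` and `emt_class` (from
#'   [classify_emt()]); samples with `NA` class are ignored.
#' @param genes genes to fit (intersected with the expression matrix).
#' @param by_cancer fit within each cancer type (default) or pooled.
#' @param standardize z-score expression within each block before fitting
#'   (for scale-free odds ratios); default `FALSE`, raw log2 units.
#' @return Tibble with `cancer_type`, `gene`, `n`, `beta`, `odds_ratio`,
#'   `p_wald`, `p_lr`, `separation`, `converged`.
#' @export
logistic_emt_or <- function(cohort, emt_class, genes, by_cancer = TRUE,
                            standardize = FALSE) {
  stopifnot(inherits(cohort, "omics_cohort"))
  genes <- intersect(toupper(genes), rownames(cohort$expression))
  if (length(genes) == 0) rlang::abort("no listed gene is present in the expression matrix")
  d <- dplyr::inner_join(
    dplyr::select(cohort$clinical, "sample_id", "cancer_type"),
    dplyr::select(emt_class, "sample_id", "emt_class"), by = "sample_id")
  d <- d[!is.na(d$emt_class), , drop = FALSE]
  if (!by_cancer) d$cancer_type <- "PANCAN"
  purrr::map_dfr(split(d, d$cancer_type), function(block) {
    y <- as.integer(block$emt_class == "high")
    if (length(unique(y)) < 2) {
      rlang::abort(sprintf("cancer type %s has only one EMT class",
                           block$cancer_type[1]))
    }
    purrr::map_dfr(genes, function(g) {
      x <- cohort$expression[g, block$sample_id]
      if (stats::sd(x) == 0) {
        return(tibble::tibble(cancer_type = block$cancer_type[1], gene = g,
                              n = length(y), beta = NA_real_,
                              odds_ratio = NA_real_, p_wald = NA_real_,
                              p_lr = NA_real_, separation = FALSE,
                              converged = FALSE))
      }
      if (standardize) x <- (x - mean(x)) / stats::sd(x)
      f <- fit_logistic(x, y)
      p_wald <- if (f$separation) .Machine$double.xmin else f$p_wald
      tibble::tibble(cancer_type = block$cancer_type[1], gene = g,
                     n = length(y), beta = f$beta,
                     odds_ratio = exp(f$beta), p_wald = p_wald,
                     p_lr = f$p_lr, separation = f$separation,
                     converged = f$converged)
    })
  })
}

#' Aggregate per-cancer significance ranks into a cross-cancer signature
#'
#' Within each cancer type, genes are ranked by `-log10(p)` in ascending
#' order: rank 1 = largest p (least significant), rank n = smallest p (most
#' significant); ties receive average ranks. Ranks are summed across cancer
#' types into a cumulative rank-sum per gene. Under the default
#' `rank_order = "significant_high"` the top signature is the `n_top` genes
#' with the LARGEST rank-sum (most consistently significant) and the bottom
#' signature the `n_bottom` with the smallest; `"significant_low"` flips the
#' rank direction. Genes absent from one cancer type's results receive that
#' type's midpoint rank `(n+1)/2` so they stay comparable. Rank-sum ties at
#' the selection boundary are broken alphabetically for determinism.
#'
#' @param logistic_table output of [logistic_emt_or()] (any tibble with
#'   `cancer_type`, `gene` and a p-value column).
#' @param p_col which p-value column ranks the genes (default `p_wald`).
#' @param rank_order `"significant_high"` (rank 1 = largest p; top = largest
#'   rank-sum) or `"significant_low"` (reversed).
#' @param n_top,n_bottom signature sizes (default 5; capped at half the
#'   gene count so the sets stay disjoint).
#' @return A `signature_result`: list with `ranks` (cancer_type, gene,
#'   rank), `rank_sums` (gene, rank_sum, n_types), `top_genes`,
#'   `bottom_genes`, `rank_order`.
#' @export
rank_and_aggregate <- function(logistic_table, p_col = "p_wald",
                               rank_order = c("significant_high", "significant_low"),
                               n_top = 5L, n_bottom = 5L) {
  rank_order <- match.arg(rank_order)
  types <- unique(logistic_table$cancer_type)
  if (length(types) < 2) {
    rlang::warn("fewer than 2 cancer types; aggregation degenerates to a single-type ranking")
  }
  all_genes <- sort(unique(logistic_table$gene))
  ranks <- purrr::map_dfr(types, function(ct) {
    block <- logistic_table[logistic_table$cancer_type == ct, ]
    block <- block[!is.na(block[[p_col]]), ]
    neglog <- -log10(block[[p_col]])
    r <- rank(neglog, ties.method = "average")  # 1 = largest p
    if (rank_order == "significant_low") r <- length(r) + 1 - r
    out <- tibble::tibble(cancer_type = ct, gene = block$gene, rank = r)
    missing <- setdiff(all_genes, block$gene)
    if (length(missing) > 0) {
      rlang::inform(sprintf(
        "cancer type %s: %d gene(s) without a result get the midpoint rank",
        ct, length(missing)))
      out <- dplyr::bind_rows(out, tibble::tibble(
        cancer_type = ct, gene = missing, rank = (nrow(block) + 1) / 2))
    }
    out
  })
  sums <- dplyr::summarise(dplyr::group_by(ranks, .data$gene),
                           rank_sum = sum(.data$rank),
                           n_types = dplyr::n(), .groups = "drop")
  k <- min(n_top, n_bottom, length(all_genes) %/% 2)
  ord <- order(-sums$rank_sum, sums$gene)
  top <- sums$gene[ord][seq_len(min(n_top, k))]
  ord_low <- order(sums$rank_sum, sums$gene)
  bottom <- sums$gene[ord_low][seq_len(min(n_bottom, k))]
  structure(list(ranks = ranks,
                 rank_sums = dplyr::arrange(sums, dplyr::desc(.data$rank_sum)),
                 top_genes = top, bottom_genes = bottom,
                 rank_order = rank_order, p_col = p_col),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result>\n")
  cat(sprintf("  rank order: %s (ranked on %s)\n", x$rank_order, x$p_col))
  cat(sprintf("  top genes:    %s\n", paste(x$top_genes, collapse = ", ")))
  cat(sprintf("  bottom genes: %s\n", paste(x$bottom_genes, collapse = ", ")))
  invisible(x)
}

#' Cluster samples by a gene signature and compare survival
#'
#' K-means (k = 2) clusters the samples on the expression profiles of a
#' signature gene set ([kmeans_stratify()]), then compares survival between
#' the high- and low-expression clusters with the log-rank test
#' ([survival_compare()]).
#'
#' @param cohort an [omics_cohort()] with survival data.
#' @param genes signature gene set.
#' @param seed seed for the k-means restarts.
#' @return List with `strata` (sample_id, label), `cluster_summary`
#'   (per-cluster n and mean signature expression), `curves` and `logrank`.
#' @export
signature_cluster_and_survive <- function(cohort, genes, seed = 1L) {
  strata <- kmeans_stratify(cohort$expression, genes, seed = seed)
  genes <- intersect(toupper(genes), rownames(cohort$expression))
  mean_expr <- colMeans(cohort$expression[genes, , drop = FALSE])
  summ <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(strata, mean_expr = mean_expr[.data$sample_id]),
      .data$label),
    n = dplyr::n(), mean_signature_expression = mean(.data$mean_expr),
    .groups = "drop")
  comp <- survival_compare(cohort, strata)
  list(strata = strata, cluster_summary = summ,
       curves = comp$curves, logrank = comp$logrank)
}
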