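#' Discretize GISTIC2-style copy-number calls
#'
#' Maps integer calls to `gain` (call >= 1), `loss` (call <= -1) or
#' `neutral` (call 0).
#'
#' @param cna integer gene-by-sample matrix with values in \[-2, 2\].
#' @return Character matrix of the same shape with entries
#'   `gain`/`loss`/`neutral`.
#' @export
discretize_cna <- function(cna) {
  if (!all(is.finite(cna)) || !all(cna == round(cna))) {
    rlang::abort("CNA calls must be integers")
  }
  out <- matrix("neutral", nrow = nrow(cna), ncol = ncol(cna),
                dimnames = dimnames(cna))
  out[cna >= 1] <- "gain"
  out[cna <= -1] <- "loss"
  out
}

#' Metastatic-vs-primary enrichment test for one alteration
#'
#' Tests whether the frequency of a binary alteration differs between
#' metastatic and primary samples. The default construction forms a 2x2
#' table of observed versus expected altered-sample counts: the expected
#' count per group is the pooled alteration frequency (over primary +
#' metastatic samples) times the group size, rounded to the nearest integer,
#' and the table `[[obs_met, obs_primary], [exp_met, exp_primary]]` is tested
#' with a two-tailed Fisher's exact test. `table_mode = "standard"` instead
#' uses the conventional altered/unaltered-by-group table.
#'
#' Genes altered in no sample of either group cannot deviate from
#' expectation; they are returned with `testable = FALSE` and `p_raw = 1`.
#'
#' @param altered binary (0/1) vector, one entry per sample.
#' @param group character/factor vector with values `primary`/`metastatic`.
#' @param table_mode `"observed_expected"` (default) or `"standard"`.
#' @return One-row tibble with observed and expected counts, group
#'   frequencies, `p_raw`, `direction` and `testable`.
#' @export
enrichment_test <- function(altered, group,
                            table_mode = c("observed_expected", "standard")) {
  table_mode <- match.arg(table_mode)
  group <- as.character(group)
  stopifnot(length(altered) == length(group))
  if (!all(altered %in% c(0, 1))) rlang::abort("altered must be 0/1")
  if (!all(group %in% c("primary", "metastatic"))) {
    rlang::abort("group must be 'primary' or 'metastatic'")
  }
  n_met <- sum(group == "metastatic"); n_pri <- sum(group == "primary")
  if (n_met == 0 || n_pri == 0) rlang::abort("both groups must be non-empty")
  obs_met <- sum(altered[group == "metastatic"])
  obs_pri <- sum(altered[group == "primary"])
  pooled <- (obs_met + obs_pri) / (n_met + n_pri)
  exp_met <- round(pooled * n_met); exp_pri <- round(pooled * n_pri)
  freq_met <- obs_met / n_met; freq_pri <- obs_pri / n_pri
  testable <- (obs_met + obs_pri) > 0
  p <- if (!testable) {
    1
  } else if (table_mode == "observed_expected") {
    stats::fisher.test(matrix(c(obs_met, obs_pri, exp_met, exp_pri),
                              nrow = 2, byrow = TRUE))$p.value
  } else {
    stats::fisher.test(matrix(c(obs_met, n_met - obs_met,
                                obs_pri, n_pri - obs_pri),
                              nrow = 2, byrow = TRUE))$p.value
  }
  tibble::tibble(
    n_metastatic = n_met, n_primary = n_pri,
    obs_metastatic = obs_met, obs_primary = obs_pri,
    exp_metastatic = exp_met, exp_primary = exp_pri,
    freq_metastatic = freq_met, freq_primary = freq_pri,
    p_raw = p, testable = testable, table_mode = table_mode)
}

#' Per-gene enrichment screen with Bonferroni control
#'
#' Applies [enrichment_test()] to every listed gene present in the relevant
#' matrix and controls the family-wise error rate by Bonferroni across the
#' testable genes (`p_adj = min(1, p_raw * m)`, `m` = number of testable
#' genes). Untestable genes (no alteration in either group) are reported but
#' excluded from `m`. For CNA kinds calls are discretized at >= 1 (gain)
#' and <= -1 (loss) first.
#'
#' @param cohort an [omics_cohort()] with the relevant matrix.
#' @param genes character vector of gene symbols to screen.
#' @param alteration_kind `"mutation"`, `"cna_gain"` or `"cna_loss"`.
#' @param table_mode passed to [enrichment_test()].
#' @param alpha significance level applied to `p_adj`.
#' @return Tibble sorted by `p_raw`, one row per gene, with columns `gene`,
#'   `alteration_kind`, the [enrichment_test()] fields, `p_adj`,
#'   `significant` and `direction` (`metastatic_enriched` /
#'   `primary_enriched` / `none`).
#' @export
run_enrichment_screen <- function(cohort, genes,
                                  alteration_kind = c("mutation", "cna_gain", "cna_loss"),
                                  table_mode = c("observed_expected", "standard"),
                                  alpha = 0.05) {
  stopifnot(inherits(cohort, "omics_cohort"))
  alteration_kind <- match.arg(alteration_kind)
  table_mode <- match.arg(table_mode)
  mat <- if (alteration_kind == "mutation") cohort$mutation else cohort$cna
  if (is.null(mat)) {
    rlang::abort(sprintf("cohort lacks the %s matrix",
                         if (alteration_kind == "mutation") "mutation" else "cna"))
  }
  genes <- intersect(toupper(genes), rownames(mat))
  if (length(genes) == 0) rlang::abort("no listed gene is present in the matrix")
  keep <- cohort$clinical$sample_type %in% c("primary", "metastatic")
  group <- cohort$clinical$sample_type[keep]
  res <- purrr::map_dfr(genes, function(g) {
    x <- mat[g, keep]
    altered <- switch(alteration_kind,
      mutation = as.numeric(x),
      cna_gain = as.numeric(x >= 1),
      cna_loss = as.numeric(x <= -1))
    dplyr::bind_cols(tibble::tibble(gene = g, alteration_kind = alteration_kind),
                     enrichment_test(altered, group, table_mode))
  })
  m <- sum(res$testable)
  res$p_adj <- ifelse(res$testable, pmin(1, res$p_raw * m), NA_real_)
  res$significant <- !is.na(res$p_adj) & res$p_adj <= alpha
  res$direction <- dplyr::case_when(
    res$significant & res$freq_metastatic > res$freq_primary ~ "metastatic_enriched",
    res$significant & res$freq_metastatic < res$freq_primary ~ "primary_enriched",
    TRUE ~ "none")
  res <- dplyr::arrange(res, .data$p_raw, .data$gene)
  attr(res, "n_tested") <- m
  class(res) <- c("enrichment_screen", class(res))
  res
}

#' Basal mutation frequency of a cohort
#'
#' The cumulative mutation count over all genes and samples divided by
#' (number of genes x number of samples), i.e. the mean of the binary
#' mutation matrix.
#'
#' @param mutation binary gene-by-sample matrix.
#' @return Scalar in \[0, 1\].
#' @export
basal_mutation_frequency <- function(mutation) {
  if (length(mutation) == 0) rlang::abort("empty mutation matrix")
  mean(mutation)
}

#' Mutation-burden strata over a gene category
#'
#' Sums each sample's mutations over the category genes and assigns the
#' stratum `none` (0 mutations), `single` (1) or `multiple` (>= 2).
#'
#' @param mutation binary gene-by-sample matrix.
#' @param genes category gene list; must intersect the matrix.
#' @return Tibble with `sample_id`, `n_mutations`, `stratum`.
#' @export
mutation_burden_strata <- function(mutation, genes) {
  genes <- intersect(toupper(genes), rownames(mutation))
  if (length(genes) == 0) rlang::abort("no category gene is present in the mutation matrix")
  s <- colSums(mutation[genes, , drop = FALSE])
  tibble::tibble(
    sample_id = colnames(mutation),
    n_mutations = as.integer(s),
    stratum = factor(dplyr::case_when(s == 0 ~ "none",
                                      s == 1 ~ "single",
                                      TRUE ~ "multiple"),
                     levels = c("none", "single", "multiple")))
}
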