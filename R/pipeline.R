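#' Run the full analysis pipeline on a cohort
#'
#' Executes every stage in sequence: EMT scoring and mean-split
#' classification, ANOVA/Tukey comparison of EMT scores across sample
#' types, mutation and copy-number gain/loss enrichment screens over the
#' gene-model genes, the per-cancer Pearson association and logistic
#' odds-ratio screens against the EMT class, rank-sum aggregation into
#' top/bottom signatures, and survival comparisons for the EMT split and
#' the two signature clusterings. With `out_dir` set, writes every result
#' table as TSV plus a JSON run summary; two runs with the same inputs and
#' seed produce byte-identical files.
#'
#' @param cohort an [omics_cohort()].
#' @param gene_model a [gene_model()]; default the shipped metabolic model.
#'   `NULL` screens every gene in the cohort except the EMT-score genes
#'   (useful for simulated cohorts with a generic gene universe).
#' @param emt_sets an [emt_gene_sets()]; default the shipped sets.
#' @param seed seed for the k-means stratifications.
#' @param table_mode contingency construction for the enrichment screens,
#'   see [enrichment_test()].
#' @param rank_order signature rank convention, see [rank_and_aggregate()].
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return A named list of all stage results (invisible when `out_dir` is
#'   set): `emt_scores`, `emt_anova`, `mutation_screen`, `cna_gain_screen`,
#'   `cna_loss_screen`, `association`, `logistic`, `signature`,
#'   `emt_survival`, `top_signature_survival`, `bottom_signature_survival`,
#'   `missing_genes`.
#' @export
run_pipeline <- function(cohort,
                         gene_model = default_gene_model(),
                         emt_sets = default_emt_gene_sets(),
                         seed = 1L,
                         table_mode = "observed_expected",
                         rank_order = "significant_high",
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "omics_cohort"))
  missing_report <- validate_gene_sets(cohort, gene_model, emt_sets)
  model_genes <- if (is.null(gene_model)) {
    setdiff(cohort$gene_universe, c(emt_sets$mesenchymal, emt_sets$epithelial))
  } else {
    unique(unlist(gene_model))
  }
  if (length(model_genes) == 0) rlang::abort("no genes to analyse")

  scores <- classify_emt(compute_emt_score(cohort, emt_sets))
  emt_anova <- compare_groups_anova(scores, "emt_score", "sample_type")

  screens <- list(
    mutation_screen = if (!is.null(cohort$mutation))
      run_enrichment_screen(cohort, model_genes, "mutation", table_mode),
    cna_gain_screen = if (!is.null(cohort$cna))
      run_enrichment_screen(cohort, model_genes, "cna_gain", table_mode),
    cna_loss_screen = if (!is.null(cohort$cna))
      run_enrichment_screen(cohort, model_genes, "cna_loss", table_mode))

  assoc <- pearson_emt_association(cohort, scores, model_genes)
  logistic <- logistic_emt_or(cohort, scores, model_genes)
  sig <- rank_and_aggregate(logistic, rank_order = rank_order)

  surv_ok <- any(!is.na(cohort$clinical$os_days) & !is.na(cohort$clinical$os_event))
  emt_surv <- top_surv <- bottom_surv <- NULL
  if (surv_ok) {
    emt_strata <- dplyr::transmute(scores[!is.na(scores$emt_class), ],
                                   sample_id = .data$sample_id,
                                   label = .data$emt_class)
    emt_surv <- survival_compare(cohort, emt_strata)
    top_surv <- signature_cluster_and_survive(cohort, sig$top_genes, seed = seed)
    bottom_surv <- signature_cluster_and_survive(cohort, sig$bottom_genes, seed = seed)
  }

  results <- c(list(emt_scores = scores, emt_anova = emt_anova),
               screens,
               list(association = assoc, logistic = logistic, signature = sig,
                    emt_survival = emt_surv,
                    top_signature_survival = top_surv,
                    bottom_signature_survival = bottom_surv,
                    missing_genes = missing_report))

  if (!is.null(out_dir)) {
    write_pipeline_outputs(results, out_dir, seed = seed,
                           table_mode = table_mode, rank_order = rank_order)
    return(invisible(results))
  }
  results
}

write_pipeline_outputs <- function(results, out_dir, seed, table_mode, rank_order) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) readr::write_tsv(df, file.path(out_dir, name))
  }
  w(results$emt_scores, "emt_scores.tsv")
  w(tidy(results$emt_anova), "emt_tukey.tsv")
  w(results$mutation_screen, "mutation_enrichment.tsv")
  w(results$cna_gain_screen, "cna_gain_enrichment.tsv")
  w(results$cna_loss_screen, "cna_loss_enrichment.tsv")
  w(results$association, "emt_association.tsv")
  w(results$logistic, "emt_logistic.tsv")
  w(results$signature$ranks, "signature_ranks.tsv")
  w(tidy(results$signature), "signature_rank_sums.tsv")
  w(results$missing_genes, "missing_genes.tsv")
  if (!is.null(results$emt_survival)) {
    w(results$emt_survival$curves, "emt_km_curves.tsv")
    w(results$top_signature_survival$curves, "top_signature_km_curves.tsv")
    w(results$bottom_signature_survival$curves, "bottom_signature_km_curves.tsv")
  }
  lr <- function(x) if (is.null(x) || is.null(x$logrank)) NULL else
    list(chi_square = x$logrank$chi_square, df = x$logrank$df,
         p_value = x$logrank$p_value, group_sizes = x$logrank$group_sizes)
  summary <- list(
    seed = seed,
    table_mode = table_mode,
    rank_order = rank_order,
    emt_threshold = attr(results$emt_scores, "threshold"),
    mesenchymal_genes_used = attr(results$emt_scores, "mesenchymal_used"),
    epithelial_genes_used = attr(results$emt_scores, "epithelial_used"),
    emt_anova = as.list(glance(results$emt_anova)),
    top_genes = results$signature$top_genes,
    bottom_genes = results$signature$bottom_genes,
    emt_survival = lr(results$emt_survival),
    top_signature_survival = lr(results$top_signature_survival),
    bottom_signature_survival = lr(results$bottom_signature_survival))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
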