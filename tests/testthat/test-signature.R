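assoc_cohort <- function(seed, n = 50, n_types = 1) {
  cfg <- simulation_config(seed = seed, n_cancer_types = n_types,
                           samples_per_type = n, n_genes = 6)
  generate_cohort(cfg)
}

test_that("Pearson association reproduces self- and anti-correlation exactly", {
  cohort <- assoc_cohort(40)
  scores <- compute_emt_score(cohort)
  # build two probe genes equal to +/- the EMT score
  expr <- rbind(cohort$expression,
                PROBEPOS = scores$emt_score,
                PROBENEG = -scores$emt_score)
  cohort2 <- omics_cohort(expr, clinical = cohort$clinical)
  res <- pearson_emt_association(cohort2, scores, c("PROBEPOS", "PROBENEG"))
  expect_equal(res$pearson_r[res$gene == "PROBEPOS"], 1)
  expect_equal(res$pearson_r[res$gene == "PROBENEG"], -1)
  expect_equal(res$sign[res$gene == "PROBEPOS"], "positive")
  expect_equal(res$sign[res$gene == "PROBENEG"], "negative")
})

test_that("Pearson r and p match the direct covariance-sum formula oracle", {
  cohort <- assoc_cohort(41)
  scores <- compute_emt_score(cohort)
  res <- pearson_emt_association(cohort, scores, paste0("G00", 1:6))
  for (i in seq_len(nrow(res))) {
    x <- cohort$expression[res$gene[i], ]
    y <- scores$emt_score
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    r <- (n * sum(x * y) - sx * sy) /
      sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    expect_equal(res$pearson_r[i], r, tolerance = 1e-10)
    expect_equal(res$p_raw[i], p, tolerance = 1e-10)
  }
  expect_equal(res$p_adj, pmin(1, res$p_raw * 6))
})

test_that("constant genes are flagged untestable, constant scores are fatal", {
  cohort <- assoc_cohort(42)
  expr <- rbind(cohort$expression, FLAT = rep(2, ncol(cohort$expression)))
  cohort2 <- omics_cohort(expr, clinical = cohort$clinical)
  scores <- compute_emt_score(cohort2)
  res <- pearson_emt_association(cohort2, scores, "FLAT")
  expect_false(res$testable)
  expect_equal(res$sign, "none")
  flat_scores <- scores; flat_scores$emt_score <- 1
  expect_error(pearson_emt_association(cohort2, flat_scores, "G001"), "constant")
})

test_that("logistic regression returns the no-information fit for class-balanced data", {
  genes <- c("VIM", "CDH1", "GX")
  expr <- matrix(c(1:8, -(1:8), 5, 5, 7, 7, 5, 5, 7, 7), nrow = 3, byrow = TRUE,
                 dimnames = list(genes, paste0("S", 1:8)))
  clin <- tibble::tibble(sample_id = paste0("S", 1:8), cancer_type = "AA",
                         sample_type = "primary", os_days = 1, os_event = 0)
  cohort <- omics_cohort(expr, clinical = clin)
  cls <- tibble::tibble(sample_id = paste0("S", 1:8),
                        emt_class = rep(c("low", "high"), 4))
  res <- logistic_emt_or(cohort, cls, "GX")
  expect_equal(res$beta, 0, tolerance = 1e-8)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-8)
  expect_gt(res$p_wald, 0.99)
})

test_that("logistic beta matches an independent IRLS oracle", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 60
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    expr <- rbind(matrix(rnorm(2 * n), 2, n,
                         dimnames = list(c("VIM", "CDH1"), sprintf("S%02d", 1:n))),
                  GX = x)
    clin <- tibble::tibble(sample_id = sprintf("S%02d", 1:n), cancer_type = "AA",
                           sample_type = "primary", os_days = 1, os_event = 0)
    cohort <- omics_cohort(expr, clinical = clin)
    cls <- tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                          emt_class = ifelse(y == 1, "high", "low"))
    res <- logistic_emt_or(cohort, cls, "GX")
    oracle <- irls_oracle(x, y)
    expect_equal(res$beta, unname(oracle[2]), tolerance = 1e-6)
  }
})

test_that("separation is flagged and ranked maximally significant", {
  n <- 20
  x <- c(rnorm(10, -5), rnorm(10, 5))
  expr <- rbind(matrix(rnorm(2 * n), 2, n,
                       dimnames = list(c("VIM", "CDH1"), sprintf("S%02d", 1:n))),
                GX = x)
  clin <- tibble::tibble(sample_id = sprintf("S%02d", 1:n), cancer_type = "AA",
                         sample_type = "primary", os_days = 1, os_event = 0)
  cohort <- omics_cohort(expr, clinical = clin)
  cls <- tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                        emt_class = rep(c("low", "high"), each = 10))
  res <- logistic_emt_or(cohort, cls, "GX")
  expect_true(res$separation)
  expect_equal(res$p_wald, .Machine$double.xmin)
})

test_that("ranking follows 'rank 1 = largest p' with ties averaged", {
  tab <- tibble::tibble(cancer_type = "CT01", gene = c("A", "B", "C"),
                        p_wald = c(0.5, 0.01, 0.2))
  sig <- rank_and_aggregate(tab, n_top = 1, n_bottom = 1) |>
    suppressWarnings()
  ranks <- sig$ranks
  expect_equal(ranks$rank[match(c("A", "C", "B"), ranks$gene)], c(1, 2, 3))
  expect_equal(sig$top_genes, "B")
  # two identical cancer types double every rank-sum
  tab2 <- dplyr::bind_rows(tab, dplyr::mutate(tab, cancer_type = "CT02"))
  sig2 <- rank_and_aggregate(tab2, n_top = 1, n_bottom = 1)
  rs1 <- sig$rank_sums$rank_sum[order(sig$rank_sums$gene)]
  rs2 <- sig2$rank_sums$rank_sum[order(sig2$rank_sums$gene)]
  expect_equal(rs2, 2 * rs1)
  # ties share the average rank
  tab3 <- tibble::tibble(cancer_type = "CT01", gene = c("A", "B", "C"),
                         p_wald = c(0.2, 0.2, 0.01))
  sig3 <- suppressWarnings(rank_and_aggregate(tab3, n_top = 1, n_bottom = 1))
  expect_equal(sort(sig3$ranks$rank[sig3$ranks$gene %in% c("A", "B")]),
               c(1.5, 1.5))
})

test_that("ranks are invariant to rescaling all p-values in one cancer type", {
  set.seed(44)
  tab <- tidyr::expand_grid(cancer_type = c("CT01", "CT02"),
                            gene = sprintf("G%02d", 1:8))
  tab$p_wald <- runif(nrow(tab))
  sig_a <- rank_and_aggregate(tab)
  tab2 <- tab
  scale_rows <- tab2$cancer_type == "CT01"
  tab2$p_wald[scale_rows] <- tab2$p_wald[scale_rows] * 0.01
  sig_b <- rank_and_aggregate(tab2)
  expect_equal(dplyr::arrange(sig_a$ranks, cancer_type, gene),
               dplyr::arrange(sig_b$ranks, cancer_type, gene))
})

test_that("genes missing from one cancer type receive the midpoint rank", {
  tab <- tibble::tibble(
    cancer_type = c(rep("CT01", 3), rep("CT02", 2)),
    gene = c("A", "B", "C", "A", "B"),
    p_wald = c(0.5, 0.01, 0.2, 0.3, 0.6))
  expect_message(sig <- rank_and_aggregate(tab, n_top = 1, n_bottom = 1),
                 "midpoint")
  missing_rank <- sig$ranks$rank[sig$ranks$cancer_type == "CT02" &
                                   sig$ranks$gene == "C"]
  expect_equal(missing_rank, 1.5)
})

test_that("the rank_order switch flips the selection", {
  tab <- tidyr::expand_grid(cancer_type = c("CT01", "CT02"), gene = c("A", "B"))
  tab$p_wald <- c(0.01, 0.9, 0.02, 0.8)  # A significant everywhere
  hi <- rank_and_aggregate(tab, n_top = 1, n_bottom = 1)
  lo <- rank_and_aggregate(tab, rank_order = "significant_low",
                           n_top = 1, n_bottom = 1)
  expect_equal(hi$top_genes, "A")
  expect_equal(lo$top_genes, "B")
})

test_that("signature clustering separates planted survival groups end to end", {
  cfg <- simulation_config(seed = 45, n_cancer_types = 1, samples_per_type = 400,
                           n_genes = 2, survival_effects = c("expr:G001" = 0.7))
  cohort <- generate_cohort(cfg)
  res <- signature_cluster_and_survive(cohort, "G001", seed = 7)
  expect_setequal(as.character(unique(res$strata$label)),
                  c("cluster_low", "cluster_high"))
  hi <- res$cluster_summary$mean_signature_expression[
    res$cluster_summary$label == "cluster_high"]
  lo <- res$cluster_summary$mean_signature_expression[
    res$cluster_summary$label == "cluster_low"]
  expect_gt(hi, lo)
  expect_lt(res$logrank$p_value, 0.01)
})
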