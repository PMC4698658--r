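test_that("KM product-limit matches hand-computed values", {
  # three deaths at distinct times: empirical survival steps
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))
  # censoring shrinks the risk set without a step
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$estimate[km2$time == 1], 2 / 3)
  expect_equal(km2$estimate[km2$time == 3], 2 / 3 * (1 - 1 / 1))
  # all censored: S stays 1
  km3 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km3$estimate == 1))
  expect_error(km_estimate(numeric(), numeric()), "empty")
})

test_that("without censoring KM equals one minus the empirical CDF", {
  set.seed(20)
  for (rep in 1:5) {
    times <- rexp(30)
    km <- km_estimate(times, rep(1, 30))
    ecdf_surv <- vapply(km$time, function(t) mean(times > t), numeric(1))
    expect_equal(km$estimate, ecdf_surv)
  }
})

test_that("log-rank chi-square matches the direct O-E/V oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    times <- round(rexp(n), 2) + 0.01
    events <- rbinom(n, 1, 0.8)
    groups <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(groups)) < 2 || sum(events) == 0) next
    got <- logrank_test(times, events, groups)
    expect_equal(got$chi_square, logrank_chisq_oracle(times, events, groups),
                 tolerance = 1e-8)
  }
})

test_that("identical groups give chi-square 0 and p 1", {
  times <- c(1, 2, 3, 4); events <- c(1, 0, 1, 1)
  res <- logrank_test(c(times, times), c(events, events),
                      rep(c("a", "b"), each = 4))
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_error(logrank_test(times, events, rep("a", 4)), "2 non-empty groups")
})

test_that("mutation stratification mirrors the indicator", {
  cohort <- tiny_cohort()
  strata <- stratify_mutation(cohort, "GB")
  expect_equal(as.character(strata$label),
               unname(ifelse(cohort$mutation["GB", ] == 1, "mutation", "no_mutation")))
  expect_error(stratify_mutation(cohort, "NOPE"), "NOPE")
  # an unmutated gene yields a single stratum; the log-rank step then
  # errors cleanly rather than fabricating a comparison
  strata0 <- stratify_mutation(cohort, "GA")
  expect_true(all(strata0$label == "no_mutation"))
  expect_error(survival_compare(cohort, strata0), "2 non-empty groups")
})

test_that("k-means stratification separates point masses and relabels by mean", {
  genes <- paste0("G", 1:3)
  low <- matrix(0, 3, 10); high <- matrix(10, 3, 10)
  m <- cbind(low, high)
  dimnames(m) <- list(genes, sprintf("S%02d", 1:20))
  strata <- kmeans_stratify(m, genes, seed = 3)
  expect_equal(as.character(strata$label),
               rep(c("cluster_low", "cluster_high"), each = 10))
  # negating the matrix swaps the labels
  neg <- kmeans_stratify(-m, genes, seed = 3)
  expect_equal(as.character(neg$label),
               rep(c("cluster_high", "cluster_low"), each = 10))
  # identical samples always co-cluster
  m2 <- m; m2[, 2] <- m2[, 1]
  s2 <- kmeans_stratify(m2, genes, seed = 3)
  expect_equal(as.character(s2$label[1]), as.character(s2$label[2]))
  expect_error(kmeans_stratify(matrix(1, 2, 5, dimnames = list(c("G1", "G2"),
                                                               paste0("S", 1:5))),
                               c("G1", "G2")),
               "degenerate")
})

test_that("k-means recovers a planted two-cluster mixture", {
  hits <- vapply(1:10, function(s) {
    set.seed(s + 100)
    truth <- rep(c(0, 1), each = 200)
    m <- t(sapply(1:4, function(i) truth * 4 + rnorm(400)))
    dimnames(m) <- list(paste0("G", 1:4), sprintf("S%03d", 1:400))
    strata <- kmeans_stratify(m, paste0("G", 1:4), seed = s)
    adjusted_rand(truth, as.character(strata$label)) >= 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("expression stratification honors the chosen split method", {
  genes <- c("VIM", "CDH1", "GX")
  expr <- matrix(c(5, 5, 5, 1, 1, 1, 1, 2, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(genes, paste0("S", 1:3)))
  clin <- tibble::tibble(sample_id = paste0("S", 1:3), cancer_type = "AA",
                         sample_type = "primary", os_days = 1, os_event = 0)
  cohort <- omics_cohort(expr, clinical = clin)
  strata <- stratify_expression(cohort, "GX", method = "mean")
  expect_equal(as.character(strata$label), c("low", "high", "high"))
  expect_equal(attr(strata, "threshold"), 2)
  # mean and median agree on symmetric data
  med <- stratify_expression(cohort, "GX", method = "median")
  expect_equal(strata$label, med$label)
  # constant gene: warning under mean, error under kmeans
  expect_warning(allhigh <- stratify_expression(cohort, "VIM"), "constant")
  expect_true(all(allhigh$label == "high"))
  expect_error(stratify_expression(cohort, "VIM", method = "kmeans"),
               "degenerate")
})

test_that("combined mutation-by-expression strata follow the exhaustive truth table", {
  set.seed(22)
  n <- 40
  genes <- c("VIM", "CDH1", "TP53", "SCO2")
  expr <- matrix(rnorm(4 * n), nrow = 4,
                 dimnames = list(genes, sprintf("S%02d", 1:n)))
  mut <- matrix(0, nrow = 4, ncol = n, dimnames = dimnames(expr))
  mut["TP53", ] <- rbinom(n, 1, 0.5)
  clin <- tibble::tibble(sample_id = colnames(expr), cancer_type = "AA",
                         sample_type = "primary", os_days = rexp(n) * 100,
                         os_event = rbinom(n, 1, 0.8))
  cohort <- omics_cohort(expr, mut, NULL, clin)
  strata <- stratify_combined_mut_expr(cohort, "TP53", "SCO2")
  is_mut <- cohort$mutation["TP53", ] == 1
  is_high <- cohort$expression["SCO2", ] >= mean(cohort$expression["SCO2", ])
  want <- ifelse(!is_mut & !is_high, "wt_low",
                 ifelse(is_mut & is_high, "mut_high", "mixed"))
  expect_equal(as.character(strata$label), unname(want))
  expect_equal(sum(unlist(attr(strata, "group_sizes"))), n)
})

test_that("survival comparison drops missing survival data and reports groups", {
  cohort <- tiny_cohort()
  clin <- cohort$clinical; clin$os_days[2] <- NA
  cohort2 <- omics_cohort(cohort$expression, cohort$mutation, cohort$cna, clin)
  strata <- tibble::tibble(sample_id = cohort2$sample_ids,
                           label = c("a", "a", "b", "b"))
  expect_message(comp <- survival_compare(cohort2, strata), "dropping 1")
  expect_equal(comp$n_dropped, 1)
  expect_s3_class(glance(comp$logrank), "tbl_df")
  expect_setequal(unique(comp$curves$group), c("a", "b"))
})

test_that("a planted survival effect is detected by the log-rank test", {
  cfg <- simulation_config(seed = 33, n_cancer_types = 1, samples_per_type = 500,
                           n_genes = 1, survival_effects = c("mutation:G001" = 0.7),
                           mutation_rates = c(G001 = 0.5))
  cohort <- generate_cohort(cfg)
  comp <- survival_compare(cohort, stratify_mutation(cohort, "G001"))
  expect_lt(comp$logrank$p_value, 0.001)
})
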