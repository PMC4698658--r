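# Independent oracle implementations used to cross-check the package.
# These are deliberately written from the defining formulas (enumeration,
# explicit loops) and share no code with the implementation paths they check.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins, summing probabilities <= the observed
# table's (with the standard relative guard against ties in floating point).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Two-group log-rank chi-square from the direct O-E / V formula over the
# pooled event times, with hypergeometric variance.
logrank_chisq_oracle <- function(times, events, groups) {
  g <- sort(unique(groups))
  stopifnot(length(g) == 2)
  O <- E <- V <- 0
  for (t in sort(unique(times[events == 1]))) {
    n1 <- sum(times >= t & groups == g[1])
    n2 <- sum(times >= t & groups == g[2])
    d1 <- sum(times == t & events == 1 & groups == g[1])
    d2 <- sum(times == t & events == 1 & groups == g[2])
    ntot <- n1 + n2; d <- d1 + d2
    if (ntot == 0 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / ntot
    if (ntot > 1) V <- V + d * (n1 / ntot) * (n2 / ntot) * (ntot - d) / (ntot - 1)
  }
  (O - E)^2 / V
}

# Univariate logistic regression by hand-rolled iteratively reweighted
# least squares; returns c(intercept, slope).
irls_oracle <- function(x, y, tol = 1e-12, max_iter = 200L) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(t(X) %*% (w * X), t(X) %*% (w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small hand-assembled cohort: 3 analysis genes plus one EMT gene per side
# so the cohort validates, 4 samples spanning both tumor groups.
tiny_cohort <- function() {
  genes <- c("VIM", "CDH1", "GA", "GB", "GC")
  samples <- sprintf("S%02d", 1:4)
  expr <- matrix(c(5, 6, 7, 8,
                   2, 1, 2, 1,
                   1.5, 2.5, 3.5, 4.5,
                   0, 1, 0, 1,
                   3, 3, 3, 3),
                 nrow = 5, byrow = TRUE, dimnames = list(genes, samples))
  mut <- matrix(c(0, 1, 0, 1,
                  1, 1, 0, 0,
                  0, 0, 0, 0,
                  1, 0, 1, 0,
                  0, 0, 1, 1),
                nrow = 5, byrow = TRUE, dimnames = list(genes, samples))
  cna <- matrix(c(0, 1, 2, -1,
                  -2, 0, 0, 1,
                  1, 1, 0, 0,
                  0, 0, 0, 0,
                  2, -2, 1, -1),
                nrow = 5, byrow = TRUE, dimnames = list(genes, samples))
  clinical <- tibble::tibble(
    sample_id = samples,
    cancer_type = c("AA", "AA", "BB", "BB"),
    sample_type = c("primary", "metastatic", "primary", "primary"),
    os_days = c(100, 250, 300, 80),
    os_event = c(1, 0, 1, 1))
  omics_cohort(expr, mut, cna, clinical)
}

tiny_emt_sets <- function() {
  suppressWarnings(emt_gene_sets("VIM", "CDH1"))
}
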