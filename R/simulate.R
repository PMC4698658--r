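#' Configure a synthetic pan-cancer cohort
#'
#' Defines the generative model for [generate_cohort()]: per-cancer-type
#' sample blocks with a minority metastatic fraction; a latent per-sample EMT
#' axis `z ~ N(0,1)` shifted upward by `emt_shift` in metastatic samples;
#' mesenchymal genes generated as `+z`, epithelial genes as `-z` (plus noise)
#' so the computed EMT score tracks `z`; optional genes correlated with `z`
#' at chosen strength; copy-number-gain genes with group-specific gain
#' frequencies; sparse Bernoulli mutations; and exponential survival with
#' proportional-hazards effects of chosen alterations plus independent
#' exponential censoring.
#'
#' @param seed integer seed; the simulation is fully reproducible given the
#'   config (independent substreams for expression/CNA/mutation/survival are
#'   derived from it, so adding genes does not perturb survival draws).
#' @param n_cancer_types,samples_per_type cohort block structure.
#' @param metastatic_fraction proportion of metastatic samples per type
#'   (remaining samples are primary tumors).
#' @param n_genes number of background genes beyond the EMT gene sets.
#' @param emt_shift upward shift of the latent EMT axis in metastatic
#'   samples, in latent SD units.
#' @param emt_assoc_genes named numeric vector: gene -> correlation `rho` in
#'   \[-1, 1\] with the latent EMT axis (expression is
#'   `rho*z + sqrt(1-rho^2)*noise`).
#' @param cna_gain_genes named list: gene -> `c(primary = pi_p,
#'   metastatic = pi_m)` per-sample gain probabilities; all other genes get
#'   call 0.
#' @param mutation_rates named numeric vector: gene -> per-sample mutation
#'   probability.
#' @param survival_effects named numeric vector of log hazard ratios; names
#'   use prefixes `"mutation:GENE"`, `"gain:GENE"`, `"expr:GENE"` (a planted
#'   bimodal high/low expression state for GENE), or the bare key
#'   `"metastatic"` (sample-type effect).
#' @param baseline_hazard,censoring_rate exponential rates per day; the
#'   defaults (1/1000 and 1/4000) give a median survival near 700 days and
#'   roughly 20% censoring under the null.
#' @param noise_sd expression noise standard deviation (log2 units).
#' @param expr_effect_delta expression separation, in log2 units, between the
#'   high and low states of `expr:` effect genes.
#' @param emt_sets [emt_gene_sets()] whose genes are always included in the
#'   expression matrix.
#' @param cna_full_range if `TRUE`, non-effect genes receive symmetric
#'   low-frequency calls across \{-2,...,2\} instead of all zeros.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_cancer_types = 5L,
                              samples_per_type = 200L,
                              metastatic_fraction = 0.15,
                              n_genes = 40L,
                              emt_shift = 1.5,
                              emt_assoc_genes = numeric(),
                              cna_gain_genes = list(),
                              mutation_rates = numeric(),
                              survival_effects = numeric(),
                              baseline_hazard = 1 / 1000,
                              censoring_rate = 1 / 4000,
                              noise_sd = 1,
                              expr_effect_delta = 4,
                              emt_sets = default_emt_gene_sets(),
                              cna_full_range = FALSE) {
  stopifnot(n_cancer_types >= 1, samples_per_type >= 2,
            metastatic_fraction > 0, metastatic_fraction < 1,
            n_genes >= 0, baseline_hazard > 0, censoring_rate > 0,
            noise_sd >= 0)
  if (length(emt_assoc_genes) > 0 &&
      (is.null(names(emt_assoc_genes)) || any(abs(emt_assoc_genes) > 1))) {
    rlang::abort("emt_assoc_genes must be a named vector of correlations in [-1,1]")
  }
  for (g in names(cna_gain_genes)) {
    p <- cna_gain_genes[[g]]
    if (length(p) != 2 || any(p < 0) || any(p > 1)) {
      rlang::abort(sprintf("cna_gain_genes[['%s']] must be two probabilities (primary, metastatic)", g))
    }
  }
  if (any(mutation_rates < 0) || any(mutation_rates > 1)) {
    rlang::abort("mutation_rates must be probabilities")
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_cancer_types = as.integer(n_cancer_types),
    samples_per_type = as.integer(samples_per_type),
    metastatic_fraction = metastatic_fraction, n_genes = as.integer(n_genes),
    emt_shift = emt_shift, emt_assoc_genes = emt_assoc_genes,
    cna_gain_genes = cna_gain_genes, mutation_rates = mutation_rates,
    survival_effects = survival_effects, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, noise_sd = noise_sd,
    expr_effect_delta = expr_effect_delta, emt_sets = emt_sets,
    cna_full_range = cna_full_range), class = "simulation_config")
  universe <- sim_gene_universe(cfg)
  eff_genes <- c(names(emt_assoc_genes), names(cna_gain_genes),
                 names(mutation_rates), sim_expr_effect_genes(cfg))
  surv_genes <- sub("^(mutation|gain|expr):", "",
                    setdiff(names(survival_effects), "metastatic"))
  unknown <- setdiff(unique(c(eff_genes, surv_genes)), universe)
  if (length(unknown) > 0) {
    rlang::abort(paste0("effect gene(s) not in the simulated universe: ",
                        paste(unknown, collapse = ", ")))
  }
  cfg
}

sim_gene_universe <- function(config) {
  bg <- if (config$n_genes > 0) sprintf("G%03d", seq_len(config$n_genes)) else character()
  unique(c(config$emt_sets$mesenchymal, config$emt_sets$epithelial, bg))
}

sim_expr_effect_genes <- function(config) {
  keys <- names(config$survival_effects)
  sub("^expr:", "", keys[grepl("^expr:", keys)])
}

# Derive independent substream seeds from the base seed so each component
# (layout/expression/cna/mutation/survival) has its own stream.
sim_substreams <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("layout", "expression", "cna", "mutation", "survival")
  s
}

#' Generate a synthetic cohort with planted effects
#'
#' Draws an [omics_cohort()] from the generative model described in
#' [simulation_config()]. Deterministic given the config (including seed).
#'
#' @param config a [simulation_config()].
#' @return An [omics_cohort()] with an extra attribute `"latent"`: a tibble
#'   holding the per-sample latent EMT axis and any planted expression-effect
#'   states (for recovery scoring; analyses never read it).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ss <- sim_substreams(config$seed)
  n_type <- config$samples_per_type
  types <- sprintf("CT%02d", seq_len(config$n_cancer_types))
  n <- n_type * config$n_cancer_types
  n_met_per_type <- max(1L, round(config$metastatic_fraction * n_type))

  clinical <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    cancer_type = rep(types, each = n_type),
    sample_type = unlist(lapply(types, function(t)
      c(rep("metastatic", n_met_per_type), rep("primary", n_type - n_met_per_type))))
  )
  is_met <- clinical$sample_type == "metastatic"
  universe <- sim_gene_universe(config)
  mes <- config$emt_sets$mesenchymal
  epi <- config$emt_sets$epithelial
  assoc <- config$emt_assoc_genes
  expr_eff <- sim_expr_effect_genes(config)

  set.seed(ss[["layout"]])
  z <- stats::rnorm(n) + config$emt_shift * is_met
  expr_state <- matrix(0L, nrow = length(expr_eff), ncol = n,
                       dimnames = list(expr_eff, clinical$sample_id))
  if (length(expr_eff) > 0) {
    expr_state[] <- stats::rbinom(length(expr_eff) * n, 1L, 0.5)
  }

  set.seed(ss[["expression"]])
  baseline <- 8
  expression <- matrix(NA_real_, nrow = length(universe), ncol = n,
                       dimnames = list(universe, clinical$sample_id))
  for (g in universe) {
    eps <- stats::rnorm(n)
    expression[g, ] <- baseline +
      if (g %in% mes) {
        z + config$noise_sd * eps
      } else if (g %in% epi) {
        -z + config$noise_sd * eps
      } else if (g %in% names(assoc)) {
        rho <- assoc[[g]]
        rho * z + sqrt(1 - rho^2) * eps
      } else if (g %in% expr_eff) {
        config$expr_effect_delta * expr_state[g, ] + config$noise_sd * eps
      } else {
        config$noise_sd * eps
      }
  }

  set.seed(ss[["cna"]])
  cna <- matrix(0L, nrow = length(universe), ncol = n,
                dimnames = list(universe, clinical$sample_id))
  if (config$cna_full_range) {
    probs <- c(0.02, 0.08, 0.80, 0.08, 0.02)  # calls -2..2
    cna[] <- sample(c(-2L, -1L, 0L, 1L, 2L), length(universe) * n,
                    replace = TRUE, prob = probs)
  }
  for (g in names(config$cna_gain_genes)) {
    p <- config$cna_gain_genes[[g]]
    pi_s <- ifelse(is_met, p[[2]], p[[1]])
    cna[g, ] <- stats::rbinom(n, 1L, pi_s)
  }

  set.seed(ss[["mutation"]])
  mutation <- matrix(0L, nrow = length(universe), ncol = n,
                     dimnames = list(universe, clinical$sample_id))
  for (g in names(config$mutation_rates)) {
    mutation[g, ] <- stats::rbinom(n, 1L, config$mutation_rates[[g]])
  }

  set.seed(ss[["survival"]])
  lp <- numeric(n)
  for (key in names(config$survival_effects)) {
    beta <- config$survival_effects[[key]]
    ind <- if (key == "metastatic") {
      as.numeric(is_met)
    } else if (grepl("^mutation:", key)) {
      mutation[sub("^mutation:", "", key), ]
    } else if (grepl("^gain:", key)) {
      as.numeric(cna[sub("^gain:", "", key), ] >= 1)
    } else if (grepl("^expr:", key)) {
      expr_state[sub("^expr:", "", key), ]
    } else {
      rlang::abort(sprintf("unknown survival effect key '%s'", key))
    }
    lp <- lp + beta * ind
  }
  t_death <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  t_cens <- stats::rexp(n, rate = config$censoring_rate)
  clinical$os_days <- round(pmin(t_death, t_cens), 2)
  clinical$os_event <- as.integer(t_death <= t_cens)

  cohort <- omics_cohort(expression, mutation, cna, clinical)
  attr(cohort, "latent") <- tibble::tibble(
    sample_id = clinical$sample_id, emt_axis = z,
    !!!stats::setNames(lapply(expr_eff, function(g) expr_state[g, ]),
                       if (length(expr_eff) > 0) paste0("state_", expr_eff) else character())
  )
  cohort
}

#' Ledger of planted effects
#'
#' Emits the exact genes and effect sizes a [simulation_config()] plants,
#' for automated recovery scoring against analysis output.
#'
#' @param config a [simulation_config()].
#' @return A list of tibbles: `emt_assoc` (gene, rho), `cna_gain`
#'   (gene, freq_primary, freq_metastatic), `mutation` (gene, rate),
#'   `survival` (covariate, log_hr), plus scalars `emt_shift` and `seed`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  list(
    emt_assoc = tibble::tibble(
      gene = names(config$emt_assoc_genes),
      rho = unname(config$emt_assoc_genes)),
    cna_gain = tibble::tibble(
      gene = names(config$cna_gain_genes),
      freq_primary = vapply(config$cna_gain_genes, function(p) p[[1]], numeric(1)),
      freq_metastatic = vapply(config$cna_gain_genes, function(p) p[[2]], numeric(1))),
    mutation = tibble::tibble(
      gene = names(config$mutation_rates),
      rate = unname(config$mutation_rates)),
    survival = tibble::tibble(
      covariate = names(config$survival_effects),
      log_hr = unname(config$survival_effects)),
    emt_shift = config$emt_shift,
    seed = config$seed
  )
}

#' Write a simulated cohort plus its truth ledger to disk
#'
#' Writes the four cohort TSVs via [write_cohort()] and a `truth.json`
#' holding [planted_truth()].
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  truth <- planted_truth(config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
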