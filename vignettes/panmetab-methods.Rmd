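---
title: "Methods: linking metabolic gene alterations to metastatic progression"
author: "panmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking metabolic gene alterations to metastatic progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmetab)
```

## Scope and scientific question

Metastatic tumor cells rewire their metabolism — the glycolytic switch
(Warburg effect), de novo lipogenesis, fatty-acid oxidation and cellular
fatty-acid uptake are all recurrently altered in cancer. `panmetab`
implements a reusable pipeline that asks, for a curated model of metabolic
genes: which of them are preferentially mutated or copy-number-gained in
metastatic versus primary tumors, which track the epithelial–mesenchymal
transition (EMT) program across cancer types, and whether those alterations
stratify patient survival. The pipeline is exercised end-to-end on synthetic
pan-cancer cohorts with planted, known effects, so every stage is validated
by parameter recovery rather than by eyeballing real-data output.

## The data model

An `omics_cohort` holds three gene-by-sample matrices — log2 expression,
binary non-synonymous mutation indicators, and integer GISTIC2-style
copy-number calls in $\{-2,\dots,2\}$ — plus a clinical table
(`sample_id`, `cancer_type`, `sample_type`, overall-survival days, event
indicator). All matrices are column-aligned to the clinical rows; samples
missing from the clinical table are dropped with a message, and matrices may
carry different gene sets. Matrix orientation is fixed as genes × samples
(the common cancer-browser convention); a file whose gene column looks like
multi-hyphen sample barcodes is rejected as transposed rather than silently
flipped, because a silent transpose is the most destructive parsing error
this format admits. Gene symbols are uppercased on both sides before
matching. Missing expression values are an error by default;
`drop_missing_genes = TRUE` drops the offending genes instead, since every
downstream statistic assumes complete per-gene vectors.

## EMT score

The per-sample EMT score is

$$\mathrm{EMT} = \sum_{g \in \mathrm{mes}} x_g \;-\; \sum_{g \in \mathrm{epi}} x_g,$$

on log2 expression, with the shipped default sets of 8 mesenchymal genes
(CDH2, FN1, SNAI1, SNAI2, VIM, TWIST1, TWIST2, ZEB2) and 5 epithelial genes
(CDH1, CLDN4, CLDN7, MUC1, TJP3). The commonly printed mesenchymal list
repeats ZEB2; the default config deduplicates it to 8 genes rather than
guessing that a different ZEB-family member was intended, and the loader
warns whenever a duplicate is removed. Samples are classified *high EMT*
when their score is at or above the arithmetic mean of the scores being
split (ties at the mean are high, per the `>=` rule) and *low EMT*
otherwise. The mean is computed over exactly the sample set being
stratified; by default `classify_emt()` restricts to tumor samples
(primary + metastatic), since survival analyses concern tumors — normals
and blood-derived samples would otherwise drag the threshold — and a flag
includes them when a pan-cohort split is wanted. Group comparisons of the
score use one-way ANOVA followed by Tukey's HSD, with the Tukey–Kramer
adjustment for unequal group sizes.

## Alteration enrichment in metastatic vs primary tumors

Copy-number calls are discretized at $\ge 1$ (gain) and $\le -1$ (loss).
For each gene the screen forms the pooled alteration frequency
$f = (a_m + a_p)/(n_m + n_p)$ over primary plus metastatic samples (other
sample types are excluded throughout), derives expected altered counts
$f\,n_m$ and $f\,n_p$ — rounded to the nearest integer, because an exact
test needs integer cells and the construction does not otherwise define
them — and applies a two-tailed Fisher's exact test to

$$\begin{pmatrix} a_m & a_p \\ \mathrm{round}(f n_m) & \mathrm{round}(f n_p) \end{pmatrix},$$

i.e. observed versus expected altered counts per group. This
observed-versus-expected construction is preserved as the default because
it is the procedure being reproduced, but it is statistically
unconventional, and its null behaviour is worth understanding: under the
null the expected row tracks the observed row almost exactly, so the
p-values pile up near 1 and the test is extremely conservative (in 500 null
replicates at cohort-scale group sizes, no p-value falls below 0.05). The
conventional altered/unaltered × group table is available as
`table_mode = "standard"`; on planted-effect screens the two modes agree on
well over 90% of significance calls, because genuine frequency shifts
dominate either construction. Family-wise error is controlled by Bonferroni
across the genes actually tested: genes with zero altered samples in both
groups cannot deviate from expectation in either direction, so they are
flagged untestable and excluded from the Bonferroni multiplier rather than
being allowed to dilute it. Direction (`metastatic_enriched` /
`primary_enriched`) is assigned from the sign of the frequency difference
when the adjusted p-value clears $\alpha = 0.05$.

Mutation burden over a gene category stratifies samples into
none / single / multiple (category sum 0, 1, $\ge 2$), and the basal
mutation frequency is the grand mean of the binary mutation matrix.

## Survival analysis

Survival curves are Kaplan–Meier product-limit estimates; group differences
use the log-rank (Mantel–Cox) chi-square over pooled event times with
hypergeometric variance, df = groups − 1. Deaths precede censorings at tied
times (the standard convention). Samples lacking survival data are dropped
from survival analyses only, with a logged count. Stratifiers provided:
single-gene mutation status; low/high single-gene expression (mean split by
default, consistent with the EMT convention; median and two-group k-means
as options); two-group k-means over a gene set's profiles (Euclidean
distance, 25 restarts, fixed seed); and the combined mutation × expression
three-group scheme (wild-type & low, exactly one altered, mutant & high),
as used for TP53 mutation crossed with SCO2 expression. K-means cluster
numbering is arbitrary, so clusters are relabeled deterministically:
`cluster_high` is the cluster with the larger mean value over the gene set.
All-identical profiles are a degenerate-input error rather than an
arbitrary split.

## Cross-cancer signature derivation

Within each cancer type, each model gene is (i) correlated with the EMT
score (Pearson r; two-tailed p from the exact t transform on $n-2$ df;
Bonferroni within the cancer type, matching per-dataset reporting) and
(ii) used as the single predictor in a logistic regression of the EMT class
(high = 1) on its log2 expression, fitted by IRLS to tolerance 1e-8. The
odds ratio is $e^{\beta}$, and the two-tailed Wald chi-square p is the
ranking statistic; a likelihood-ratio p is emitted alongside for
comparison. The regressions are univariate per gene — the reading most
consistent with gene-by-gene odds-ratio reporting — and unstandardized by
default, with a `standardize` flag for scale-free odds ratios. Complete or
quasi-complete separation (non-convergence or $|\beta| > 20$) is flagged
and the Wald p replaced by the smallest positive double so the gene ranks
as maximally significant instead of propagating a meaningless Wald
statistic.

Ranks are assigned within each cancer type on $-\log_{10} p$ in ascending
order — rank 1 is the *largest* p (least significant) — with ties averaged,
then summed across cancer types into a cumulative rank-sum per gene. Two
printed conventions for the selection step circulate that are mutually
inconsistent ("lowest rank = highest p-value" versus top genes having the
*lowest* cumulative rank-sum); this package treats the explicit rank
definition as authoritative and the other phrasing as a wording slip, so
the top signature is the 5 genes with the **largest** rank-sum (most
consistently significant) and the bottom signature the 5 smallest. A
`rank_order = "significant_low"` switch flips the convention, and the
choice is echoed in every output. Genes missing from one cancer type's
matrix receive that type's midpoint rank $(n+1)/2$ — neutral with respect
to the aggregate — rather than being dropped globally; rank-sum ties at a
selection boundary break alphabetically for determinism. Samples are then
k-means-clustered (k = 2) on each signature's expression profiles and the
clusters compared by log-rank.

## The synthetic-cohort generator

`simulation_config()` / `generate_cohort()` emulate the statistical
structure the analyses assume, with every effect planted at a known size:

- **Layout** — `n_cancer_types` blocks of `samples_per_type` samples, a
  deterministic `metastatic_fraction` of each block metastatic (default
  5 × 200 at 15%, a desk-scale stand-in for a pan-cancer cohort's minority
  of metastatic samples).
- **Latent EMT axis** — $z \sim N(0,1)$, shifted by `emt_shift`
  (default 1.5 SD) in metastatic samples. Mesenchymal genes are generated
  as $+z$, epithelial as $-z$, both plus $N(0, \sigma)$ noise
  ($\sigma = 1$ log2 unit, a typical within-gene spread for log-scale
  RNA-seq) around a baseline of 8 log2 units, so the computed EMT score
  correlates positively with $z$ by construction.
- **EMT-associated genes** — expression $\rho z + \sqrt{1-\rho^2}\,\epsilon$,
  giving exact control of the population correlation.
- **CNA gains** — Bernoulli calls in $\{0,1\}$ with group-specific
  probabilities $(\pi_p, \pi_m)$; non-effect genes stay 0 by default (the
  findings being emulated concern gains), with a flag for symmetric
  low-frequency calls over the full $\{-2,\dots,2\}$ range.
- **Mutations** — per-gene Bernoulli at configured rates.
- **Survival** — exponential death times with hazard
  $\lambda_0 e^{\sum_k \beta_k x_k}$ (the simplest model consistent with
  the KM/log-rank analyses) and independent exponential censoring; defaults
  $\lambda_0 = 1/1000$ per day and censoring rate $1/4000$ give a median
  survival near 700 days and roughly 20% censoring. Effect covariates are
  named `mutation:GENE`, `gain:GENE`, `expr:GENE` (a planted bimodal
  high/low expression state, separated by 4 log2 units so expression-based
  clustering can recover it), or `metastatic`.

A single base seed is split into named substreams
(layout / expression / CNA / mutation / survival), so enlarging the gene
universe leaves the survival draws untouched — important when comparing
configurations. `planted_truth()` emits the exact planted genes and effect
sizes for automated recovery scoring, and `simulate_to_dir()` writes the
four cohort TSVs plus `truth.json`.

What the generator does **not** emulate: real marginal expression
distributions, batch effects, inter-gene co-expression beyond the single
latent EMT axis, mutual exclusivity between alteration types, or
non-proportional hazards. Passing recovery tests therefore demonstrates
the pipeline's statistical correctness under its own assumptions, not
robustness to the full messiness of real tumor data.

## Numerical and design choices

- Expected enrichment counts are rounded half-even to integers before the
  exact test (R's `round`); the mode and rounding are recorded in output.
- Two-tailed exact p-values sum the probabilities of all tables with the
  observed margins whose probability does not exceed the observed table's
  (the standard two-sided definition).
- The mean split labels exact ties *high*; an all-constant vector labels
  every sample high with a warning, since the mean is attained everywhere.
- k-means uses 25 restarts under a fixed seed; stratification seeds are
  explicit arguments everywhere randomness enters, and `run_pipeline()`
  with the same cohort and seed writes byte-identical TSV/JSON output.
- The loss screen uses the $\le -1$ threshold stated by the discretization
  rule.
- The Bonferroni family for the Pearson screen is the genes tested within
  one cancer type; controlling across genes × types is stricter than the
  per-dataset reporting being mirrored.

## Validation strategy and problem sizes

The test suite checks each statistical routine against an independent
oracle implemented from the defining formula: exhaustive hypergeometric
enumeration for Fisher p-values (agreement to 1e-12), a direct O−E/V
log-rank computation (1e-8), a hand-rolled IRLS fit (1e-6), and
hand-computed product-limit values. Null calibration draws hundreds of
no-effect cohorts (5 types × 40 samples) and checks that raw p-values from
the Pearson and log-rank tests are uniform by Kolmogorov–Smirnov; the
enrichment screen's exact-test p-values are discrete and — in the
observed-vs-expected construction — extremely conservative, so their null
distribution is *not* uniform, which the suite documents by direct
measurement while confirming that the Bonferroni screen's family-wise
error stays below its nominal level. Parameter recovery runs 20 seeds per
scenario: a planted CNA gain ($\pi_p = 0.10$, $\pi_m = 0.45$, 500 per
group), five genes at $|\rho| = 0.7$ among 30 across 7 cancer types
recovered as the exact top-5 signature, and a planted log hazard ratio of
0.7 at n = 1000 detected by signature-cluster log-rank at p < 0.01. These
sizes keep the default test run to a few minutes while leaving each check
ample power.

## Known limitations

Headline numbers from full-scale pan-cancer cohorts (specific gene lists,
survival p-values of order $10^{-20}$) require the original multi-thousand
sample datasets and are out of reach of a self-contained synthetic
validation; the package validates the machinery, not those constants. The
observed-vs-expected enrichment construction should be interpreted with its
conservatism in mind — `table_mode = "standard"` is the statistically
conventional alternative. Cox regression and hazard-ratio estimation are
deliberately out of scope (the survival interface is KM + log-rank);
`survival::coxph()` is used only as an external cross-check in the
simulator's self-tests.
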