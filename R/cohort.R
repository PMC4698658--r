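#' Assemble an aligned multi-omics cohort
#'
#' Bundles gene-by-sample expression, mutation and copy-number matrices with a
#' clinical table into a validated `omics_cohort`. Matrices are column-aligned
#' to the intersection of their sample ids with the clinical table; samples
#' missing from the clinical table are dropped with a message. The three
#' matrices may carry different gene sets.
#'
#' @param expression numeric gene-by-sample matrix of log2-transformed,
#'   finite abundance values (rownames = gene symbols, colnames = sample ids).
#' @param mutation gene-by-sample matrix of 0/1 non-synonymous mutation
#'   indicators, or `NULL`.
#' @param cna gene-by-sample matrix of integer copy-number calls in
#'   \[-2, 2\] (GISTIC2-style), or `NULL`.
#' @param clinical data frame with columns `sample_id`, `cancer_type`,
#'   `sample_type` (one of normal/primary/metastatic/blood), `os_days`,
#'   `os_event`.
#' @return An `omics_cohort`: a list with elements `expression`, `mutation`,
#'   `cna`, `clinical` (tibble), `gene_universe` and `sample_ids`.
#' @export
omics_cohort <- function(expression, mutation = NULL, cna = NULL, clinical) {
  clinical <- validate_clinical(clinical)
  mats <- list(expression = expression, mutation = mutation, cna = cna)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!"expression" %in% names(mats)) {
    rlang::abort("an expression matrix is required")
  }
  mats <- lapply(names(mats), function(nm) validate_matrix(mats[[nm]], nm))
  names(mats) <- c("expression", if (!is.null(mutation)) "mutation",
                   if (!is.null(cna)) "cna")

  all_samples <- unique(unlist(lapply(mats, colnames)))
  keep <- intersect(clinical$sample_id, Reduce(intersect, lapply(mats, colnames)))
  if (length(keep) == 0L) {
    rlang::abort("no sample id is shared by all matrices and the clinical table")
  }
  dropped <- setdiff(all_samples, keep)
  if (length(dropped) > 0L) {
    rlang::inform(sprintf(
      "dropping %d sample(s) absent from the clinical table or some matrix",
      length(dropped)))
  }
  clinical <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  mats <- lapply(mats, function(m) m[, keep, drop = FALSE])

  structure(
    list(
      expression    = mats$expression,
      mutation      = mats$mutation,
      cna           = mats$cna,
      clinical      = tibble::as_tibble(clinical),
      gene_universe = unique(unlist(lapply(mats, rownames))),
      sample_ids    = keep
    ),
    class = "omics_cohort"
  )
}

sample_type_vocab <- c("normal", "primary", "metastatic", "blood")

validate_clinical <- function(clinical) {
  clinical <- tibble::as_tibble(clinical)
  req <- c("sample_id", "cancer_type", "sample_type", "os_days", "os_event")
  miss <- setdiff(req, names(clinical))
  if (length(miss) > 0L) {
    rlang::abort(paste0("clinical table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) {
    rlang::abort("clinical sample ids are not unique")
  }
  bad <- setdiff(unique(clinical$sample_type), sample_type_vocab)
  if (length(bad) > 0L) {
    rlang::abort(paste0(
      "unknown sample_type value(s): ", paste(bad, collapse = ", "),
      " (expected ", paste(sample_type_vocab, collapse = "/"),
      "; see load_cohort(sample_type_map=) for label normalization)"))
  }
  ok_days <- is.na(clinical$os_days) | clinical$os_days >= 0
  if (!all(ok_days)) rlang::abort("os_days must be >= 0 (or NA)")
  ok_ev <- is.na(clinical$os_event) | clinical$os_event %in% c(0, 1)
  if (!all(ok_ev)) rlang::abort("os_event must be 0 or 1 (or NA)")
  clinical
}

validate_matrix <- function(m, kind) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    rlang::abort(sprintf("%s matrix needs gene rownames and sample colnames", kind))
  }
  rownames(m) <- toupper(rownames(m))
  if (anyDuplicated(rownames(m))) {
    rlang::abort(sprintf("%s matrix has duplicated gene symbols", kind))
  }
  if (anyDuplicated(colnames(m))) {
    rlang::abort(sprintf("%s matrix has duplicated sample ids", kind))
  }
  if (kind == "expression" && !all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "expression has a non-finite value at gene %s, sample %s",
      rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (kind == "mutation" && !all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    idx <- arrayInd(bad, dim(m))
    rlang::abort(sprintf(
      "mutation value not in {0,1} at gene %s, sample %s",
      rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  if (kind == "cna") {
    ok <- is.finite(m) & m == round(m) & m >= -2 & m <= 2
    if (!all(ok)) {
      bad <- which(!ok)[1]
      idx <- arrayInd(bad, dim(m))
      rlang::abort(sprintf(
        "CNA call not an integer in [-2,2] at gene %s, sample %s",
        rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
    storage.mode(m) <- "integer"
  }
  m
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat("<omics_cohort>\n")
  cat(sprintf("  samples: %d  (%s)\n", length(x$sample_ids),
              paste(sprintf("%s=%d", names(table(x$clinical$sample_type)),
                            table(x$clinical$sample_type)), collapse = ", ")))
  for (nm in c("expression", "mutation", "cna")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %-10s %d genes x %d samples\n", nm,
                  nrow(x[[nm]]), ncol(x[[nm]])))
    }
  }
  cat(sprintf("  cancer types: %s\n",
              paste(sort(unique(x$clinical$cancer_type)), collapse = ", ")))
  invisible(x)
}

# Heuristic transpose guard: gene symbols are short uppercase tokens; sample
# ids in TCGA-style data are multi-hyphen barcodes. If the "gene" column looks
# like barcodes the file is almost surely transposed.
looks_like_sample_ids <- function(x) {
  x <- as.character(x)
  mean(grepl("^[A-Za-z0-9]+(-[A-Za-z0-9]+){2,}$", x)) > 0.5
}

read_matrix_tsv <- function(path, kind) {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_double(),
      gene = readr::col_character())),
    error = function(e) rlang::abort(sprintf("failed to parse %s: %s",
                                             path, conditionMessage(e))))
  prob <- readr::problems(df)
  if (nrow(prob) > 0L) {
    rlang::abort(sprintf("malformed TSV %s at line %d: %s",
                         path, prob$row[1] + 1L, prob$expected[1]))
  }
  if (names(df)[1] != "gene") {
    rlang::abort(sprintf("%s: first column must be named 'gene'", path))
  }
  if (looks_like_sample_ids(df$gene)) {
    rlang::abort(sprintf(
      "%s appears transposed (sample-id-like values in the gene column); supply genes as rows",
      path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Load a cohort from TSV files
#'
#' Reads the three omics matrices (genes as rows, first column `gene`,
#' remaining columns samples) and the clinical table, normalizes sample-type
#' labels, and assembles a validated [omics_cohort()].
#'
#' @param expression_path,mutation_path,cna_path,clinical_path TSV file paths;
#'   `mutation_path` and `cna_path` may be `NULL`.
#' @param log2_transform if `TRUE`, expression is transformed as
#'   `log2(x + 1)` on load (for inputs not already on log scale).
#' @param drop_missing_genes if `TRUE`, expression genes with any missing
#'   value are dropped (with a message); otherwise missing values are an error.
#' @param sample_type_map named character vector or YAML path mapping raw
#'   sample-type labels to the vocabulary normal/primary/metastatic/blood.
#'   Defaults to the table shipped with the package.
#' @return An [omics_cohort()].
#' @export
load_cohort <- function(expression_path, mutation_path = NULL, cna_path = NULL,
                        clinical_path, log2_transform = FALSE,
                        drop_missing_genes = FALSE,
                        sample_type_map = default_sample_type_map()) {
  if (is.character(sample_type_map) && length(sample_type_map) == 1 &&
      file.exists(sample_type_map)) {
    sample_type_map <- unlist(yaml::read_yaml(sample_type_map))
  }
  expr <- read_matrix_tsv(expression_path, "expression")
  if (anyNA(expr)) {
    if (drop_missing_genes) {
      bad <- rowSums(is.na(expr)) > 0
      rlang::inform(sprintf("dropping %d expression gene(s) with missing values",
                            sum(bad)))
      expr <- expr[!bad, , drop = FALSE]
    } else {
      rlang::abort("expression contains missing values (set drop_missing_genes = TRUE to drop those genes)")
    }
  }
  if (log2_transform) {
    if (any(expr < 0)) rlang::abort("negative expression values cannot be log2-transformed")
    expr <- log2(expr + 1)
  }
  mut <- if (!is.null(mutation_path)) read_matrix_tsv(mutation_path, "mutation")
  cna <- if (!is.null(cna_path)) read_matrix_tsv(cna_path, "cna")

  clin <- readr::read_tsv(clinical_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cancer_type = readr::col_character(),
    sample_type = readr::col_character(),
    os_days = readr::col_double(),
    os_event = readr::col_double()))
  idx <- match(tolower(clin$sample_type), tolower(names(sample_type_map)))
  clin$sample_type <- ifelse(is.na(idx),
                             tolower(clin$sample_type),
                             unname(sample_type_map)[idx])
  omics_cohort(expr, mut, cna, clin)
}

default_sample_type_map <- function() {
  unlist(yaml::read_yaml(system.file("extdata", "sample_type_map.yaml",
                                     package = "panmetab")))
}

#' Write a cohort to a directory of TSV files
#'
#' Inverse of [load_cohort()]: writes `expression.tsv`, `mutation.tsv`,
#' `cna.tsv` (those present) and `clinical.tsv` into `dir`. Writing then
#' reading reproduces every matrix entry exactly.
#'
#' @param cohort an [omics_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "omics_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_m <- function(m, path) {
    df <- tibble::as_tibble(m, rownames = "gene")
    readr::write_tsv(df, path)
  }
  write_m(cohort$expression, file.path(dir, "expression.tsv"))
  if (!is.null(cohort$mutation)) write_m(cohort$mutation, file.path(dir, "mutation.tsv"))
  if (!is.null(cohort$cna)) write_m(cohort$cna, file.path(dir, "cna.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

#' Gene model of metabolic pathway categories
#'
#' A named list of gene-symbol vectors for the four metabolic categories:
#' `warburg` (aerobic glycolysis regulators), `lipogenesis`, `fa_oxidation`
#' and `fa_uptake`. By default a gene may belong to only one category.
#'
#' @param categories named list of non-empty character vectors.
#' @param allow_overlap permit a gene in more than one category.
#' @return A `gene_model` (named list).
#' @export
gene_model <- function(categories, allow_overlap = FALSE) {
  if (length(categories) == 0 || is.null(names(categories)) ||
      any(names(categories) == "")) {
    rlang::abort("categories must be a non-empty named list")
  }
  if (anyDuplicated(names(categories))) {
    rlang::abort("category names must be unique")
  }
  categories <- lapply(categories, function(g) toupper(as.character(g)))
  if (any(lengths(categories) == 0)) {
    rlang::abort("every category must list at least one gene")
  }
  all_genes <- unlist(categories, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup) > 0 && !allow_overlap) {
    rlang::abort(paste0("gene(s) in more than one category: ",
                        paste(dup, collapse = ", "),
                        " (use allow_overlap = TRUE to permit)"))
  }
  structure(categories, class = c("gene_model", "list"))
}

#' @rdname gene_model
#' @param path YAML file mapping category names to gene lists.
#' @export
read_gene_model <- function(path, allow_overlap = FALSE) {
  gene_model(yaml::read_yaml(path), allow_overlap = allow_overlap)
}

#' @rdname gene_model
#' @export
default_gene_model <- function() {
  read_gene_model(system.file("extdata", "gene_model.yaml", package = "panmetab"))
}

#' EMT score gene sets
#'
#' The mesenchymal and epithelial gene lists defining the EMT score
#' (mesenchymal sum minus epithelial sum of log2 expression). Duplicates
#' within a list are removed with a warning naming the gene; the two lists
#' must be disjoint and non-empty.
#'
#' @param mesenchymal,epithelial character vectors of gene symbols.
#' @return An `emt_gene_sets` list with elements `mesenchymal`, `epithelial`.
#' @export
emt_gene_sets <- function(mesenchymal, epithelial) {
  mesenchymal <- toupper(as.character(mesenchymal))
  epithelial <- toupper(as.character(epithelial))
  for (nm in c("mesenchymal", "epithelial")) {
    g <- get(nm)
    dup <- unique(g[duplicated(g)])
    if (length(dup) > 0) {
      rlang::warn(paste0("duplicate ", nm, " gene(s) removed: ",
                         paste(dup, collapse = ", ")))
    }
  }
  mesenchymal <- unique(mesenchymal)
  epithelial <- unique(epithelial)
  if (length(mesenchymal) == 0 || length(epithelial) == 0) {
    rlang::abort("both EMT gene lists must be non-empty")
  }
  both <- intersect(mesenchymal, epithelial)
  if (length(both) > 0) {
    rlang::abort(paste0("gene(s) in both EMT lists: ", paste(both, collapse = ", ")))
  }
  structure(list(mesenchymal = mesenchymal, epithelial = epithelial),
            class = c("emt_gene_sets", "list"))
}

#' @rdname emt_gene_sets
#' @param path YAML file with keys `mesenchymal` and `epithelial`.
#' @export
read_emt_gene_sets <- function(path) {
  y <- yaml::read_yaml(path)
  emt_gene_sets(y$mesenchymal, y$epithelial)
}

#' @rdname emt_gene_sets
#' @export
default_emt_gene_sets <- function() {
  read_emt_gene_sets(system.file("extdata", "emt_gene_sets.yaml",
                                 package = "panmetab"))
}

#' Report genes of the configured sets missing from each cohort matrix
#'
#' Downstream analyses use only genes present in the relevant matrix; this
#' report makes the dropped genes explicit. All mesenchymal or all epithelial
#' genes missing from the expression matrix is fatal (the EMT score would be
#' undefined).
#'
#' @param cohort an [omics_cohort()].
#' @param gene_model a [gene_model()] (or `NULL` to check EMT sets only).
#' @param emt_sets an [emt_gene_sets()] (or `NULL`).
#' @return Tibble with columns `set`, `gene_list`, `matrix`, `gene`, one row
#'   per missing gene per matrix; zero rows when everything is present.
#' @export
validate_gene_sets <- function(cohort, gene_model = NULL, emt_sets = NULL) {
  stopifnot(inherits(cohort, "omics_cohort"))
  lists <- list()
  if (!is.null(gene_model)) {
    for (cat in names(gene_model)) {
      lists[[length(lists) + 1L]] <-
        list(set = "gene_model", gene_list = cat, genes = gene_model[[cat]])
    }
  }
  if (!is.null(emt_sets)) {
    for (side in c("mesenchymal", "epithelial")) {
      lists[[length(lists) + 1L]] <-
        list(set = "emt", gene_list = side, genes = emt_sets[[side]])
    }
  }
  mats <- c("expression", "mutation", "cna")
  mats <- mats[!vapply(mats, function(m) is.null(cohort[[m]]), logical(1))]
  report <- purrr::map_dfr(lists, function(l) {
    purrr::map_dfr(mats, function(m) {
      missing <- setdiff(l$genes, rownames(cohort[[m]]))
      if (length(missing) == 0) return(tibble::tibble())
      tibble::tibble(set = l$set, gene_list = l$gene_list,
                     matrix = m, gene = missing)
    })
  })
  if (nrow(report) == 0) {
    report <- tibble::tibble(set = character(), gene_list = character(),
                             matrix = character(), gene = character())
  }
  if (!is.null(emt_sets)) {
    for (side in c("mesenchymal", "epithelial")) {
      present <- intersect(emt_sets[[side]], rownames(cohort$expression))
      if (length(present) == 0) {
        rlang::abort(sprintf(
          "all %s genes are missing from the expression matrix; EMT score undefined",
          side))
      }
    }
  }
  report
}
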