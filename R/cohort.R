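#' Cohort construction and validation
#'
#' A cohort bundles, for `N` individuals, the clinical covariate table
#' (id, covariates, binary treatment, right-censored survival outcome) with
#' a binary gene-alteration matrix aligned by sample id. All discovery
#' functions in the package operate on this container.
#'
#' @param clinical A data frame with at least the columns `id`, `treatment`
#'   (0/1), `time` (non-negative), `event` (0/1), plus the clinical
#'   covariates named by `covariate_names`. Typically produced by
#'   [read_clinical_table()] and [filter_complete_cases()].
#' @param mutations Binary gene x sample matrix (rownames = gene symbols,
#'   colnames = sample ids), e.g. from [read_mutation_matrix()] or
#'   [maf_to_matrix()]. Every clinical sample must be present; a missing
#'   genetic profile is a hard error, never a silent zero. May be `NULL`
#'   for a clinical-only partial cohort.
#' @param covariate_names Character vector naming the clinical covariate
#'   columns (default: the `"covariate_names"` attribute of `clinical`,
#'   falling back to `c("age", "sex")`).
#'
#' @return An object of class `"csearch_cohort"`: a list with elements
#'   `clinical` (data frame, one row per individual), `G` (individuals x
#'   genes binary matrix, row order matching `clinical`), `gene_names` and
#'   `covariate_names`.
#' @export
#' @examples
#' clin <- data.frame(id = c("s1", "s2"), age = c(50, 60), sex = c(0, 1),
#'                    treatment = c(1, 0), time = c(12, 30), event = c(1, 0))
#' mut <- matrix(c(1L, 0L), 1, 2, dimnames = list("TP53", c("s1", "s2")))
#' make_cohort(clin, mut)
make_cohort <- function(clinical, mutations = NULL, covariate_names = NULL) {
  stopifnot(is.data.frame(clinical))
  if (is.null(covariate_names)) {
    covariate_names <- attr(clinical, "covariate_names")
  }
  if (is.null(covariate_names)) {
    covariate_names <- intersect(c("age", "sex"), names(clinical))
  }
  needed <- c("id", "treatment", "time", "event", covariate_names)
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  clinical$id <- as.character(clinical$id)
  if (anyDuplicated(clinical$id)) {
    stop("duplicated sample ids: ",
         paste(unique(clinical$id[duplicated(clinical$id)]), collapse = ", "))
  }
  if (!all(clinical$treatment %in% c(0, 1))) {
    stop("treatment must be coded 0/1")
  }
  if (!all(clinical$event %in% c(0, 1))) {
    stop("event must be coded 0/1")
  }
  if (any(!is.finite(clinical$time)) || any(clinical$time < 0)) {
    stop("survival times must be finite and non-negative")
  }

  G <- NULL
  gene_names <- character(0)
  if (!is.null(mutations)) {
    stopifnot(is.matrix(mutations))
    absent <- setdiff(clinical$id, colnames(mutations))
    if (length(absent)) {
      stop("sample id(s) in clinical table without genetic profile: ",
           paste(absent, collapse = ", "))
    }
    extra <- setdiff(colnames(mutations), clinical$id)
    if (length(extra)) {
      message("dropping ", length(extra),
              " mutation-matrix sample(s) absent from the clinical table")
    }
    # align by id, never by position
    G <- t(mutations[, clinical$id, drop = FALSE])
    storage.mode(G) <- "integer"
    if (anyNA(G)) stop("missing genetic values are not allowed")
    if (!all(G %in% c(0L, 1L))) stop("gene matrix must be binary 0/1")
    gene_names <- colnames(G)
    rownames(G) <- clinical$id
  }

  structure(
    list(clinical = clinical, G = G,
         gene_names = gene_names, covariate_names = covariate_names),
    class = "csearch_cohort"
  )
}

#' @export
print.csearch_cohort <- function(x, ...) {
  cl <- x$clinical
  cat(sprintf("C-search cohort: %d individuals, %d genes\n",
              nrow(cl), length(x$gene_names)))
  cat(sprintf("  treated %d / untreated %d; events %d (%.0f%%)\n",
              sum(cl$treatment == 1), sum(cl$treatment == 0),
              sum(cl$event == 1), 100 * mean(cl$event == 1)))
  cat("  covariates: ", paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort A `"csearch_cohort"`.
#' @return Integer count.
#' @export
n_individuals <- function(cohort) nrow(cohort$clinical)

#' Subset a cohort by individual
#'
#' Keeps the indicated rows of the clinical table and the matching rows of
#' the gene matrix; gene and covariate ordering is untouched.
#'
#' @param cohort A `"csearch_cohort"`.
#' @param idx Integer or logical index over individuals, or character ids.
#' @return A `"csearch_cohort"`.
#' @export
subset_cohort <- function(cohort, idx) {
  cl <- cohort$clinical
  if (is.character(idx)) idx <- match(idx, cl$id)
  cl2 <- cl[idx, , drop = FALSE]
  rownames(cl2) <- NULL
  G2 <- if (is.null(cohort$G)) NULL else cohort$G[idx, , drop = FALSE]
  structure(
    list(clinical = cl2, G = G2,
         gene_names = cohort$gene_names,
         covariate_names = cohort$covariate_names),
    class = "csearch_cohort"
  )
}

# Clinical covariate block as a numeric matrix (rows = individuals).
covariate_matrix <- function(cohort) {
  m <- as.matrix(cohort$clinical[, cohort$covariate_names, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$clinical$id
  m
}

# Either covariate block by name.
block_matrix <- function(cohort, block = c("clinical", "genetic")) {
  block <- match.arg(block)
  if (block == "clinical") return(covariate_matrix(cohort))
  if (is.null(cohort$G)) stop("cohort carries no gene matrix")
  m <- cohort$G
  storage.mode(m) <- "double"
  m
}

stop_if_single_arm <- function(cohort) {
  tr <- cohort$clinical$treatment
  if (!any(tr == 1) || !any(tr == 0)) {
    stop("cohort must contain both treated and untreated individuals")
  }
  invisible(NULL)
}

#' Write a cohort to delimited text files
#'
#' Inverse of loading via [read_clinical_table()], [read_mutation_matrix()]
#' and [make_cohort()]: the clinical table is written as TSV, the gene
#' matrix as a gene x sample TSV with the gene symbol in the first column.
#'
#' @param cohort A `"csearch_cohort"`.
#' @param clinical_path,mutations_path Output file paths; `mutations_path`
#'   may be `NULL` for a clinical-only cohort.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, clinical_path, mutations_path = NULL) {
  utils::write.table(cohort$clinical, clinical_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mutations_path)) {
    if (is.null(cohort$G)) stop("cohort carries no gene matrix")
    mat <- t(cohort$G)
    out <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    utils::write.table(out, mutations_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(cohort)
}
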