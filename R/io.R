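#' Read a clinical covariate table
#'
#' Loads a delimited clinical file (one row per patient) and standardizes
#' it to the column layout the package uses: `id`, covariates, `treatment`,
#' `time`, `event`. Missing values are preserved as `NA` -- rows are never
#' dropped here; use [filter_complete_cases()] for the complete-case step.
#'
#' Treatment and event codings are declared, never guessed: cBioPortal
#' files, for example, code vital status as `"1:DECEASED"` / `"0:LIVING"`,
#' which is handled by `event_map = c("1:DECEASED" = 1, "0:LIVING" = 0)`.
#' Plain 0/1 columns need no map.
#'
#' @param path Path to a TSV or CSV file with a header row. Fields equal to
#'   `""`, `"NA"` or `"[Not Available]"` are read as missing.
#' @param column_map Named list mapping the standard roles to the file's
#'   column names. Mandatory entries: `id`, `treatment`, `time`, `event`.
#'   Optional: `covariates`, a character vector of covariate columns (its
#'   names, if any, give the standardized covariate names). Default layout
#'   matches [write_cohort()] output.
#' @param treatment_map,event_map Optional named vectors translating raw
#'   values to 0/1 (names = raw strings, values = 0 or 1).
#' @param covariate_maps Optional named list of such vectors for individual
#'   covariates (e.g. `list(sex = c(Female = 0, Male = 1))`).
#' @param sep Field separator; by default inferred from the file extension
#'   (`.csv` = comma, otherwise tab).
#'
#' @return A data frame of class `"csearch_clinical"` with columns `id`,
#'   the covariates, `treatment`, `time`, `event`, and a
#'   `"covariate_names"` attribute. Feed it to [filter_complete_cases()]
#'   and [make_cohort()].
#' @export
read_clinical_table <- function(path,
                                column_map = list(
                                  id = "id",
                                  covariates = c(age = "age", sex = "sex"),
                                  treatment = "treatment",
                                  time = "time",
                                  event = "event"),
                                treatment_map = NULL,
                                event_map = NULL,
                                covariate_maps = NULL,
                                sep = NULL) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           na.strings = c("", "NA", "[Not Available]"))

  for (role in c("id", "treatment", "time", "event")) {
    if (is.null(column_map[[role]])) {
      stop("column_map lacks the mandatory role '", role, "'")
    }
  }
  covs <- column_map$covariates
  if (is.null(covs)) covs <- character(0)
  cov_std <- if (is.null(names(covs)) || any(names(covs) == "")) covs else names(covs)
  wanted <- c(column_map$id, unname(covs), column_map$treatment,
              column_map$time, column_map$event)
  absent <- setdiff(wanted, names(raw))
  if (length(absent)) {
    stop("clinical file lacks mandatory column(s): ",
         paste(absent, collapse = ", "))
  }

  out <- data.frame(id = raw[[column_map$id]], stringsAsFactors = FALSE)
  for (i in seq_along(covs)) {
    out[[cov_std[i]]] <- decode_column(raw[[covs[i]]], covariate_maps[[cov_std[i]]],
                                       cov_std[i], binary = FALSE)
  }
  out$treatment <- decode_column(raw[[column_map$treatment]], treatment_map,
                                 "treatment", binary = TRUE)
  out$time <- decode_column(raw[[column_map$time]], NULL, "time", binary = FALSE)
  out$event <- decode_column(raw[[column_map$event]], event_map,
                             "event", binary = TRUE)
  attr(out, "covariate_names") <- cov_std
  class(out) <- c("csearch_clinical", "data.frame")
  out
}

# Decode one raw character column to numeric, applying a declared value map
# if given. Binary roles must end up in {0, 1, NA}; a value that is neither
# mapped nor numeric is a parse error naming the first offending row.
decode_column <- function(x, map, role, binary = FALSE) {
  out <- rep(NA_real_, length(x))
  if (!is.null(map)) {
    hit <- x %in% names(map)
    out[hit] <- as.numeric(map[x[hit]])
    x[hit] <- NA_character_
  }
  rest <- !is.na(x)
  val <- suppressWarnings(as.numeric(x[rest]))
  bad <- which(rest)[is.na(val)]
  if (length(bad)) {
    stop("cannot parse ", role, " value '", x[bad[1]], "' at data row ",
         bad[1], if (is.null(map)) " (no value map declared)" else "")
  }
  out[rest] <- val
  if (binary && any(!is.na(out) & !(out %in% c(0, 1)))) {
    bad <- which(!is.na(out) & !(out %in% c(0, 1)))[1]
    stop(role, " value at data row ", bad, " is not codable to {0,1}")
  }
  out
}

#' Drop records with missing clinical data
#'
#' Complete-case filter: retains only individuals whose id, covariates,
#' treatment, time and event are all non-missing, and reports the
#' bookkeeping (input = omitted + retained).
#'
#' @param clinical A clinical data frame from [read_clinical_table()] (or
#'   any data frame with the standardized columns).
#' @return The filtered data frame, with attribute `"counts"` = named
#'   vector `(input, omitted, retained)`.
#' @export
filter_complete_cases <- function(clinical) {
  covs <- attr(clinical, "covariate_names")
  if (is.null(covs)) covs <- setdiff(names(clinical),
                                     c("id", "treatment", "time", "event"))
  cols <- c("id", covs, "treatment", "time", "event")
  keep <- stats::complete.cases(clinical[, cols, drop = FALSE])
  out <- clinical[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts <- c(input = nrow(clinical), omitted = sum(!keep),
              retained = sum(keep))
  if (counts["retained"] == 0L) {
    stop("complete-case filtering removed every record")
  }
  message(sprintf("complete-case filter: %d in, %d omitted, %d retained",
                  counts["input"], counts["omitted"], counts["retained"]))
  attr(out, "counts") <- counts
  attr(out, "covariate_names") <- covs
  class(out) <- c("csearch_clinical", "data.frame")
  out
}

#' Read a binary gene x sample mutation matrix
#'
#' The expected dialect is a TSV whose first column holds the gene symbol
#' and whose remaining columns are sample ids; entries are 0/1 alteration
#' indicators. Positive entries greater than 1 (e.g. mutation counts) are
#' coerced to 1 with a warning; negative or non-numeric entries are errors.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_mutation_matrix <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE)
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("mutation matrix contains missing values")
  if (any(mat < 0)) stop("mutation matrix contains negative entries")
  if (any(mat > 1)) {
    warning(sum(mat > 1), " entries > 1 coerced to 1")
    mat[mat > 1] <- 1
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  mat
}

#' Build a binary mutation matrix from MAF-like records
#'
#' Collapses a per-variant mutation list (one row per called mutation) into
#' a binary gene x sample matrix: an entry is 1 iff at least one record
#' pairs the gene with the sample, so duplicate records are idempotent.
#'
#' @param records A data frame with the columns `Tumor_Sample_Barcode` and
#'   `Hugo_Symbol` (extra columns ignored), or a path to such a TSV.
#' @param samples,genes Optional universes; by default the distinct values
#'   observed in `records`. Samples without records get all-zero columns.
#' @return Integer matrix, genes in rows, samples in columns. Malformed
#'   rows (missing gene or sample) are skipped with a message.
#' @export
maf_to_matrix <- function(records, samples = NULL, genes = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- utils::read.table(records, header = TRUE, sep = "\t",
                                 quote = "", comment.char = "#",
                                 check.names = FALSE,
                                 colClasses = "character")
  }
  stopifnot(is.data.frame(records))
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol")
  if (!all(need %in% names(records))) {
    stop("MAF-like input needs columns ", paste(need, collapse = " and "))
  }
  sid <- as.character(records$Tumor_Sample_Barcode)
  gid <- as.character(records$Hugo_Symbol)
  bad <- is.na(sid) | sid == "" | is.na(gid) | gid == ""
  if (any(bad)) message("skipped ", sum(bad), " malformed MAF record(s)")
  sid <- sid[!bad]; gid <- gid[!bad]
  if (!length(sid)) stop("no usable mutation records")
  if (is.null(samples)) samples <- sort(unique(sid))
  if (is.null(genes)) genes <- sort(unique(gid))
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  keep <- sid %in% samples & gid %in% genes
  mat[cbind(match(gid[keep], genes), match(sid[keep], samples))] <- 1L
  mat
}
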