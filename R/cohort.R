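#' Assemble an InflammCohort from its component tables
#'
#' Harmonizes sample identifiers across the expression matrix, the clinical
#' table and the optional stemness table (exact string match after
#' whitespace trimming), keeps the intersection, and reports how many
#' samples each table lost — unmatched samples are dropped with a message,
#' never silently.
#'
#' @param expression numeric matrix, genes in rows (rownames = gene
#'   symbols), samples in columns (colnames = sample ids); non-negative.
#' @param clinical data.frame as returned by [readClinical()]: columns
#'   `sample_id`, `age_years`, `survival_time_days`, `event`,
#'   `survival_known` plus any optional clinical fields.
#' @param stemness optional data.frame as returned by [readStemness()].
#' @param truth optional list of generator ground truth, stored in
#'   `metadata()$truth`.
#' @return An [InflammCohort-class] object.
#' @examples
#' expr <- matrix(1:6, 3, 2, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' clin <- data.frame(sample_id = c("s1", "s2"), age_years = c(50, 70),
#'                    survival_time_days = c(400L, 800L), event = c(1L, 0L),
#'                    survival_known = TRUE)
#' cohort <- InflammCohort(expr, clin)
#' ageYears(cohort)
#' @export
InflammCohort <- function(expression, clinical, stemness = NULL, truth = NULL) {
  expression <- validateExpressionMatrix(expression)
  clinical <- validateClinicalTable(clinical)
  colnames(expression) <- trimws(colnames(expression))
  clinical$sample_id <- trimws(clinical$sample_id)

  ids <- intersect(colnames(expression), clinical$sample_id)
  if (!is.null(stemness)) {
    stemness <- validateStemnessTable(stemness)
    stemness$sample_id <- trimws(stemness$sample_id)
  }
  nDropExpr <- ncol(expression) - length(ids)
  nDropClin <- nrow(clinical) - length(ids)
  if (nDropExpr > 0 || nDropClin > 0)
    message(sprintf(
      "dropping unmatched samples: %d expression-only, %d clinical-only; %d retained",
      nDropExpr, nDropClin, length(ids)))
  if (length(ids) == 0L)
    stop("no samples shared between expression and clinical tables")

  expression <- expression[, ids, drop = FALSE]
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(clinical[setdiff(names(clinical), "sample_id")],
                             row.names = ids)
  if (!is.null(stemness)) {
    idx <- match(ids, stemness$sample_id)
    for (col in c("mrnasi", "ereg_mrnasi", "mdnasi", "ereg_mdnasi"))
      cd[[col]] <- stemness[[col]][idx]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expression), colData = cd)
  obj <- methods::new("InflammCohort", se)
  if (!is.null(truth)) S4Vectors::metadata(obj)$truth <- truth
  obj
}

setValidity("InflammCohort", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is required")
  x <- SummarizedExperiment::assay(object, "expr")
  if (anyNA(x)) msg <- c(msg, "expression values must not be missing")
  else if (any(x < 0)) msg <- c(msg, "expression values must be non-negative")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicated sample ids")
  need <- c("age_years", "survival_time_days", "event", "survival_known")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing clinical columns: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn InflammCohort expression assay (genes x samples matrix).
#' @param x,object an `InflammCohort`.
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "expr")

#' @describeIn InflammCohort clinical table as a data.frame with a
#'   `sample_id` column (inverse of the constructor's `clinical` input).
#' @export
clinicalData <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  stemCols <- intersect(c("mrnasi", "ereg_mrnasi", "mdnasi", "ereg_mdnasi"),
                        names(cd))
  cd <- cd[setdiff(names(cd), stemCols)]
  cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE), cd,
        row.names = NULL)
}

#' @describeIn InflammCohort stemness-index table (`NULL` when absent).
#' @export
stemnessData <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  cols <- c("mrnasi", "ereg_mrnasi", "mdnasi", "ereg_mdnasi")
  if (!any(cols %in% colnames(cd))) return(NULL)
  out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
  for (col in cols) out[[col]] <- if (col %in% colnames(cd)) cd[[col]] else NA_real_
  out
}

#' @describeIn InflammCohort chronological ages in years.
#' @export
ageYears <- function(x) SummarizedExperiment::colData(x)$age_years

#' @describeIn InflammCohort observed survival times in days.
#' @export
survTimeDays <- function(x) SummarizedExperiment::colData(x)$survival_time_days

#' @describeIn InflammCohort event indicator (1 = dead, 0 = censored).
#' @export
eventStatus <- function(x) SummarizedExperiment::colData(x)$event

#' @describeIn InflammCohort generator ground truth (`NULL` for real data).
#' @export
cohortTruth <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn InflammCohort subset to the samples retained by a
#'   [FilterReport-class].
#' @param report a `FilterReport`.
#' @export
retainSamples <- function(x, report) {
  stopifnot(methods::is(report, "FilterReport"))
  x[, intersect(colnames(x), report@retainedIds)]
}

#' @export
setMethod("show", "InflammCohort", function(object) {
  cat("InflammCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  age (years): ", sprintf("%.1f +/- %.1f", mean(cd$age_years),
      stats::sd(cd$age_years)), "\n", sep = "")
  if (any(cd$survival_known))
    cat("  events: ", sum(cd$event[cd$survival_known]), "/",
        sum(cd$survival_known), " with known survival\n", sep = "")
  if ("mrnasi" %in% colnames(cd)) cat("  stemness indices: present\n")
  if (!is.null(cohortTruth(object))) cat("  synthetic truth: present\n")
  invisible(object)
})
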