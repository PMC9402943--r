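# Readers and validators for the three tabular inputs, plus the cohort
# inclusion/exclusion filters. All tables are plain delimited text; the
# delimiter is sniffed from the first line (tab beats comma).

sniffDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

validateExpressionMatrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicated gene ids: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicated sample ids: ", paste(unique(dup), collapse = ", "))
  bad <- which(is.na(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or missing expression at gene '%s', sample '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  x
}

validateClinicalTable <- function(x) {
  need <- c("sample_id", "age_years", "survival_time_days", "event",
            "survival_known")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample ids in clinical table")
  if (any(!is.na(x$event) & !x$event %in% c(0, 1)))
    stop("event must be coded 0/1")
  if (any(is.na(x$age_years) | x$age_years <= 0))
    stop("age_years must be positive and non-missing")
  known <- which(x$survival_known)
  if (any(is.na(x$survival_time_days[known])) ||
      any(x$survival_time_days[known] < 0))
    stop("survival_time_days must be >= 0 whenever survival_known")
  x
}

validateStemnessTable <- function(x) {
  cols <- c("mrnasi", "ereg_mrnasi", "mdnasi", "ereg_mdnasi")
  miss <- setdiff(c("sample_id", cols), names(x))
  if (length(miss))
    stop("stemness table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicated sample ids in stemness table")
  for (col in cols) {
    bad <- which(!is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 1))
    if (length(bad))
      stop(sprintf("stemness index '%s' outside [0,1] for sample '%s'",
                   col, x$sample_id[bad[1]]))
  }
  x
}

#' Read a genes-by-samples expression matrix
#'
#' Reads delimited text (TSV or CSV, sniffed) with gene symbols in the first
#' column and a header row of sample ids, validates it (no duplicates, no
#' negative or missing cells) and optionally restricts to a gene panel.
#' Panel genes absent from the file are reported via the `"missingGenes"`
#' attribute and a message, never dropped silently.
#'
#' @param path path to the delimited file.
#' @param geneSubset optional character vector of gene symbols to keep.
#' @return validated numeric matrix; attribute `missingGenes` lists requested
#'   genes not present in the file.
#' @export
readExpression <- function(path, geneSubset = NULL) {
  d <- utils::read.delim(path, sep = sniffDelim(path), check.names = FALSE,
                         stringsAsFactors = FALSE)
  genes <- trimws(as.character(d[[1]]))
  m <- as.matrix(d[-1])
  if (!is.numeric(m))
    stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  colnames(m) <- trimws(colnames(m))
  m <- validateExpressionMatrix(m)
  if (!is.null(geneSubset)) {
    missing <- setdiff(geneSubset, rownames(m))
    if (length(missing))
      message(length(missing), " requested gene(s) absent from file: ",
              paste(missing, collapse = ", "))
    m <- m[intersect(geneSubset, rownames(m)), , drop = FALSE]
    attr(m, "missingGenes") <- missing
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: genes in the first column (`gene_id`),
#' one column per sample. Values round-trip at full double precision.
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Required columns (after `columnMap` renaming) are `sample_id`, `age`,
#' `time` and `event`; optional columns (`sex`, `race`, `karnofsky`,
#' `tumor_dim_cm`, `is_recurrent_or_multiple`) are carried through with
#' missing values preserved. Survival times are stored internally in days;
#' times given in years are converted with 365.25 days/year and rounded to
#' the nearest day. A missing/blank time marks survival as unknown rather
#' than dropping the row.
#'
#' @param path path to the delimited file.
#' @param timeUnit `"days"` or `"years"` for the `time` column.
#' @param eventMap named vector mapping event codes to 0/1, e.g.
#'   `c(Dead = 1, Alive = 0)`; numeric 0/1 columns need no map.
#' @param columnMap optional named character vector mapping the canonical
#'   names to the file's column names, e.g. `c(age = "age_at_diagnosis")`.
#' @return data.frame with canonical columns (`sample_id`, `age_years`,
#'   `survival_time_days`, `event`, `survival_known`, optional fields).
#' @export
readClinical <- function(path, timeUnit = c("days", "years"),
                         eventMap = NULL, columnMap = NULL) {
  timeUnit <- match.arg(timeUnit)
  d <- utils::read.delim(path, sep = sniffDelim(path), check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(columnMap))
    for (canon in names(columnMap)) {
      j <- match(columnMap[[canon]], names(d))
      if (!is.na(j)) names(d)[j] <- canon
    }
  need <- c("sample_id", "age", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("clinical file missing required column(s): ",
         paste(miss, collapse = ", "))
  ev <- d$event
  if (!is.null(eventMap)) {
    unknown <- setdiff(unique(stats::na.omit(as.character(ev))), names(eventMap))
    if (length(unknown))
      stop("unmapped event code(s): ", paste(unknown, collapse = ", "))
    ev <- unname(eventMap[as.character(ev)])
  } else {
    ev <- suppressWarnings(as.numeric(ev))
    if (any(!is.na(ev) & !ev %in% c(0, 1)))
      stop("event codes must be 0/1 or covered by eventMap")
  }
  tm <- suppressWarnings(as.numeric(d$time))
  days <- if (timeUnit == "years") round(tm * 365.25) else round(tm)
  out <- data.frame(
    sample_id = trimws(as.character(d$sample_id)),
    age_years = as.numeric(d$age),
    survival_time_days = as.integer(days),
    event = as.integer(ev),
    survival_known = !is.na(days) & !is.na(ev),
    stringsAsFactors = FALSE
  )
  for (col in c("sex", "race", "karnofsky", "tumor_dim_cm",
                "is_recurrent_or_multiple"))
    if (col %in% names(d)) out[[col]] <- d[[col]]
  if ("is_recurrent_or_multiple" %in% names(out))
    out$is_recurrent_or_multiple <- as.logical(out$is_recurrent_or_multiple)
  validateClinicalTable(out)
}

#' Read a per-sample stemness-index table
#'
#' Expects columns `sample_id`, `mrnasi`, `ereg_mrnasi`, `mdnasi`,
#' `ereg_mdnasi`. Indices must lie in \[0, 1\]; missing cells are preserved
#' (downstream correlations are pairwise-complete).
#'
#' @param path path to the delimited file.
#' @return validated data.frame.
#' @export
readStemness <- function(path) {
  d <- utils::read.delim(path, sep = sniffDelim(path), check.names = FALSE,
                         stringsAsFactors = FALSE)
  d$sample_id <- trimws(as.character(d$sample_id))
  validateStemnessTable(d)
}

filterRules <- list(
  recurrent_or_multiple = function(cl) {
    if (is.null(cl$is_recurrent_or_multiple))
      stop("rule 'recurrent_or_multiple' needs column is_recurrent_or_multiple")
    !is.na(cl$is_recurrent_or_multiple) & cl$is_recurrent_or_multiple
  },
  survival_unknown = function(cl) !cl$survival_known,
  survival_lt_30d = function(cl)
    cl$survival_known & cl$survival_time_days < 30,
  incomplete_clinical = function(cl, fields = c("age_years",
                                                "survival_time_days", "event")) {
    miss <- rep(FALSE, nrow(cl))
    for (f in fields) {
      if (is.null(cl[[f]])) stop("rule 'incomplete_clinical' needs column ", f)
      miss <- miss | is.na(cl[[f]])
    }
    miss
  }
)

#' Apply ordered cohort inclusion/exclusion rules
#'
#' Rules are applied sequentially, each to the remainder left by the
#' previous one, so per-rule counts depend on the order while the retained
#' set does not. Available rules: `recurrent_or_multiple` (recurrent or
#' multifocal tumors), `survival_unknown` (no usable follow-up),
#' `survival_lt_30d` (survival strictly below 30 days; day 30 is retained),
#' `incomplete_clinical` (missing values in `incompleteFields`).
#'
#' @param clinical clinical data.frame ([readClinical()] output) or an
#'   [InflammCohort-class].
#' @param rules character vector of rule names, applied in order.
#' @param incompleteFields columns checked by `incomplete_clinical`.
#' @return a [FilterReport-class].
#' @examples
#' clin <- data.frame(sample_id = paste0("s", 1:4), age_years = 60,
#'                    survival_time_days = c(29L, 30L, 500L, NA),
#'                    event = c(1L, 1L, 0L, NA),
#'                    survival_known = c(TRUE, TRUE, TRUE, FALSE))
#' applyInclusionFilters(clin, c("survival_unknown", "survival_lt_30d"))
#' @export
applyInclusionFilters <- function(clinical, rules = character(),
                                  incompleteFields = c("age_years",
                                                       "survival_time_days",
                                                       "event")) {
  if (methods::is(clinical, "InflammCohort")) clinical <- clinicalData(clinical)
  clinical <- validateClinicalTable(clinical)
  bad <- setdiff(rules, names(filterRules))
  if (length(bad)) stop("unknown filter rule(s): ", paste(bad, collapse = ", "))
  remaining <- clinical
  excluded <- integer(0)
  for (r in rules) {
    drop <- if (r == "incomplete_clinical")
      filterRules[[r]](remaining, incompleteFields)
    else filterRules[[r]](remaining)
    excluded[r] <- sum(drop)
    remaining <- remaining[!drop, , drop = FALSE]
  }
  methods::new("FilterReport",
               nInput = nrow(clinical),
               excludedByRule = excluded,
               nRetained = nrow(remaining),
               retainedIds = remaining$sample_id)
}

#' @export
setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@nInput, "samples in\n")
  for (r in names(object@excludedByRule))
    cat(sprintf("  - %s: %d excluded\n", r, object@excludedByRule[[r]]))
  cat("  retained:", object@nRetained, "\n")
  invisible(object)
})

#' Serialize a FilterReport to JSON
#'
#' @param report a [FilterReport-class].
#' @param path optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
filterReportJSON <- function(report, path = NULL) {
  x <- list(n_input = report@nInput,
            n_excluded_by_rule = as.list(report@excludedByRule),
            n_retained = report@nRetained,
            retained_ids = report@retainedIds)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Descriptive cohort summary
#'
#' Mean +/- SD for the continuous clinical fields and counts with
#' percentages for the categorical ones, in the layout of a standard
#' baseline-characteristics table (percentages on the 0-100 scale).
#'
#' @param clinical clinical data.frame or [InflammCohort-class].
#' @return named list: `n`, `age_mean`, `age_sd`, `n_dead`, `pct_dead`,
#'   `surv_mean_years`, `surv_sd_years`, plus entries for any optional
#'   fields present.
#' @export
cohortSummary <- function(clinical) {
  if (methods::is(clinical, "InflammCohort")) clinical <- clinicalData(clinical)
  known <- clinical$survival_known
  out <- list(
    n = nrow(clinical),
    age_mean = mean(clinical$age_years),
    age_sd = stats::sd(clinical$age_years),
    n_dead = sum(clinical$event[known] == 1, na.rm = TRUE),
    pct_dead = 100 * sum(clinical$event[known] == 1, na.rm = TRUE) /
      nrow(clinical),
    surv_mean_years = mean(clinical$survival_time_days[known]) / 365.25,
    surv_sd_years = stats::sd(clinical$survival_time_days[known]) / 365.25
  )
  if (!is.null(clinical$sex)) {
    out$n_male <- sum(clinical$sex == "male", na.rm = TRUE)
    out$pct_male <- 100 * out$n_male / nrow(clinical)
  }
  if (!is.null(clinical$karnofsky)) {
    out$karnofsky_mean <- mean(clinical$karnofsky, na.rm = TRUE)
    out$karnofsky_sd <- stats::sd(clinical$karnofsky, na.rm = TRUE)
  }
  out
}
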