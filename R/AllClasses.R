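#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Cohort container: expression assay plus clinical and stemness annotation
#'
#' `InflammCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"expr"` assay (genes in rows, samples in columns, non-negative
#' normalized expression) and per-sample clinical fields in `colData`.
#' Required clinical columns are `age_years`, `survival_time_days`, `event`
#' and `survival_known`; optional columns (`sex`, `race`, `karnofsky`,
#' `tumor_dim_cm`, `is_recurrent_or_multiple`) and the four stemness indices
#' (`mrnasi`, `ereg_mrnasi`, `mdnasi`, `ereg_mdnasi`) are carried when
#' available. For synthetic cohorts, `metadata(x)$truth` holds the generator
#' ground truth (see [generateCohort()]).
#'
#' @seealso [InflammCohort()] for construction from separate tables,
#'   [exprMatrix()], [clinicalData()], [stemnessData()], [cohortTruth()].
#' @export
setClass("InflammCohort", contains = "SummarizedExperiment")

#' Audit trail of cohort inclusion/exclusion filtering
#'
#' Records, for an ordered list of exclusion rules applied sequentially to
#' the remainder of the previous rule, how many samples each rule removed and
#' which samples survived. The counts are conserved:
#' `nInput = sum(excludedByRule) + nRetained`.
#'
#' @slot nInput number of samples before filtering.
#' @slot excludedByRule named integer vector, one entry per applied rule.
#' @slot nRetained number of samples retained.
#' @slot retainedIds identifiers of the retained samples.
#' @seealso [applyInclusionFilters()], [filterReportJSON()]
#' @export
setClass("FilterReport",
  slots = c(
    nInput = "integer",
    excludedByRule = "integer",
    nRetained = "integer",
    retainedIds = "character"
  )
)

setValidity("FilterReport", function(object) {
  msg <- character()
  if (object@nInput != sum(object@excludedByRule) + object@nRetained)
    msg <- c(msg, "nInput must equal sum(excludedByRule) + nRetained")
  if (length(object@retainedIds) != object@nRetained)
    msg <- c(msg, "retainedIds length must equal nRetained")
  if (length(msg)) msg else TRUE
})

#' Fitted inflammatory aging clock
#'
#' Stores everything needed to replay iAge scoring on a new cohort with
#' frozen parameters: the per-gene Spearman weights and selection flags, the
#' per-gene normalization parameters estimated on the training cohort, the
#' score shift and cohort calibration constant, and the raw-score
#' standardization used by the per-patient calibration mode.
#'
#' @slot weights data.frame with columns `gene_id`, `beta`, `selected`.
#' @slot normalization list with `method` ("minmax01" or "zscore") and
#'   per-gene parameter vectors `p1`, `p2` (min/max or mean/sd) for the
#'   selected genes.
#' @slot shift non-negative score shift guaranteeing positive mean raw score.
#' @slot calibrationConstant cohort constant C with mean(iAge) = mean(age).
#' @slot calibrationMode "cohort_constant" or "per_patient".
#' @slot perPatientScale scale of the per-patient mode (default 0.25).
#' @slot rawCenter,rawScale training-cohort mean and sd of the raw score.
#' @slot threshold absolute-Spearman selection threshold used at fit time.
#' @seealso [fitIAgeClock()], [scoreCohort()], [writeIAgeModel()]
#' @export
setClass("IAgeModel",
  slots = c(
    weights = "data.frame",
    normalization = "list",
    shift = "numeric",
    calibrationConstant = "numeric",
    calibrationMode = "character",
    perPatientScale = "numeric",
    rawCenter = "numeric",
    rawScale = "numeric",
    threshold = "numeric"
  )
)

setValidity("IAgeModel", function(object) {
  msg <- character()
  need <- c("gene_id", "beta", "selected")
  if (!all(need %in% names(object@weights)))
    msg <- c(msg, "weights must have columns gene_id, beta, selected")
  if (!object@calibrationMode %in% c("cohort_constant", "per_patient"))
    msg <- c(msg, "calibrationMode must be cohort_constant or per_patient")
  if (length(object@shift) != 1L || object@shift < 0)
    msg <- c(msg, "shift must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors. `time` holds the
#' distinct event times in increasing order; `surv`, `nRisk`, `nEvent` and
#' `se` are aligned with it. The estimated survival function is the
#' right-continuous step function equal to 1 before the first event time
#' (see [survProb()]).
#'
#' @slot time increasing distinct event times.
#' @slot surv product-limit estimates at each event time.
#' @slot nRisk number at risk just before each event time.
#' @slot nEvent number of events at each event time.
#' @slot se Greenwood standard errors of `surv`.
#' @slot nTotal number of subjects the curve was estimated from.
#' @slot maxTime largest observed time (event or censored).
#' @slot obsTimes sorted observed times (events and censorings), kept so
#'   at-risk counts can be read off at arbitrary times.
#' @seealso [kmEstimate()], [survProb()], [conditionalSurvival()]
#' @export
setClass("KMCurve",
  slots = c(
    time = "numeric",
    surv = "numeric",
    nRisk = "numeric",
    nEvent = "numeric",
    se = "numeric",
    nTotal = "integer",
    maxTime = "numeric",
    obsTimes = "numeric"
  )
)

setValidity("KMCurve", function(object) {
  msg <- character()
  n <- length(object@time)
  if (any(lengths(list(object@surv, object@nRisk, object@nEvent, object@se)) != n))
    msg <- c(msg, "time, surv, nRisk, nEvent, se must have equal length")
  if (n > 1) {
    if (any(diff(object@time) <= 0)) msg <- c(msg, "event times must be strictly increasing")
    if (any(diff(object@surv) > 1e-12)) msg <- c(msg, "survival must be non-increasing")
    if (any(diff(object@nRisk) > 0)) msg <- c(msg, "number at risk must be non-increasing")
  }
  if (n > 0 && (any(object@surv < -1e-12) || any(object@surv > 1 + 1e-12)))
    msg <- c(msg, "survival values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
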