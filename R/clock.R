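# The inflammatory aging clock itself: Spearman screening of panel genes
# against chronological age, the calibrated iAge score
# iAge = C * (sum_j beta_j * X_j), train/test splitting and the median-split
# subtyping. The printed formula leaves C underdetermined for a weighted sum
# of arbitrary scale, so scoring supports two explicit calibrations (see
# fitIAgeClock); the default fixes one cohort-level constant so that
# mean(iAge) = mean(age), which preserves the raw-score ranking and hence
# the median split.

#' Chronological age groups
#'
#' Bins ages into the four standard groups: young (<= 44 years),
#' middle-aged (45-59), old-young (60-74) and old (>= 75). Non-integer ages
#' fall into the group whose integer bounds bracket them (e.g. 44.5 is
#' middle-aged).
#'
#' @param ageYears positive numeric vector of ages in years.
#' @return factor with levels `young`, `middle`, `old_young`, `old`.
#' @examples
#' assignAgeGroup(c(44, 45, 60, 75))
#' @export
assignAgeGroup <- function(ageYears) {
  if (any(is.na(ageYears)) || any(ageYears <= 0))
    stop("ages must be positive and non-missing")
  cut(ageYears, breaks = c(0, 44, 59, 74, Inf),
      labels = c("young", "middle", "old_young", "old"), right = TRUE)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Returns
#' `NA` — not an error — when either vector is constant, since a constant
#' gene carries no ordering information.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA_real_` for a constant input.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Screen panel genes for correlation with chronological age
#'
#' Computes the Spearman correlation of each gene's expression with age;
#' a gene is selected when `|beta| >= threshold` (inclusive boundary).
#' The correlation doubles as the gene's weight in the clock. Constant
#' genes get a missing beta and are never selected.
#'
#' @param cohort an [InflammCohort-class]; ages and expression are taken
#'   from it. The screening cohort is an explicit input: pass whichever
#'   cohort the weights should be estimated on.
#' @param threshold absolute-correlation selection cutoff in (0, 1\].
#' @return weight table: data.frame with `gene_id`, `beta`, `selected`.
#' @export
screenAgeGenes <- function(cohort, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  expr <- exprMatrix(cohort)
  age <- ageYears(cohort)
  beta <- apply(expr, 1L, spearmanRho, y = age)
  wt <- data.frame(
    gene_id = rownames(expr),
    beta = beta,
    # tiny slack so a rho that is exactly the threshold in exact arithmetic
    # is not lost to floating-point rounding of the rank correlation
    selected = !is.na(beta) & abs(beta) >= threshold - 1e-12,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!any(wt$selected))
    warning("no gene passed the |beta| >= ", threshold, " screen")
  wt
}

normalizationParams <- function(mat, method) {
  switch(method,
    minmax01 = list(method = method,
                    p1 = apply(mat, 1L, min), p2 = apply(mat, 1L, max)),
    zscore = list(method = method,
                  p1 = rowMeans(mat), p2 = apply(mat, 1L, stats::sd)),
    stop("unknown normalization method: ", method))
}

applyNormalization <- function(mat, params) {
  p1 <- params$p1[rownames(mat)]
  p2 <- params$p2[rownames(mat)]
  if (anyNA(p1)) stop("normalization parameters missing for some genes")
  out <- mat
  for (i in seq_len(nrow(mat))) {
    if (params$method == "minmax01") {
      out[i, ] <- if (p2[i] > p1[i]) (mat[i, ] - p1[i]) / (p2[i] - p1[i])
                  else rep(0.5, ncol(mat))
    } else {
      out[i, ] <- if (p2[i] > 0) (mat[i, ] - p1[i]) / p2[i]
                  else rep(0, ncol(mat))
    }
  }
  out
}

#' Per-gene expression normalization
#'
#' `minmax01` maps each gene to \[0, 1\] (constant genes to 0.5);
#' `zscore` centers and scales each gene (constant genes to 0). Gene and
#' sample ids are preserved.
#'
#' @param expr numeric genes x samples matrix.
#' @param method `"minmax01"` (default) or `"zscore"`.
#' @return normalized matrix of identical shape.
#' @export
normalizeExpression <- function(expr, method = c("minmax01", "zscore")) {
  method <- match.arg(method)
  applyNormalization(expr, normalizationParams(expr, method))
}

#' Fit the inflammatory aging clock on a training cohort
#'
#' Estimates (or accepts) the per-gene Spearman weights, freezes the
#' per-gene normalization parameters on the training cohort, computes the
#' raw score `sum_j beta_j * X_j` over the selected genes and fixes the
#' calibration:
#' \describe{
#'   \item{cohort_constant}{shift `s = max(0, 0.01 - min(raw))`, then one
#'     constant `C = mean(age) / mean(raw + s)` so that the mean iAge
#'     equals the mean chronological age; iAge is a positive affine map of
#'     the raw score, so rankings (and the median split) are unchanged.}
#'   \item{per_patient}{`iAge_i = age_i * (1 + scale * z(raw_i))` with the
#'     raw-score standardization frozen from the training cohort; offered
#'     as a sensitivity analysis that keeps each patient's own age as the
#'     multiplier.}
#' }
#' All frozen quantities live in the returned [IAgeModel-class], so scoring
#' a validation cohort with [scoreCohort()] replays them unchanged.
#'
#' @param cohort training [InflammCohort-class].
#' @param weights optional precomputed weight table ([screenAgeGenes()]
#'   output); screened internally when `NULL`.
#' @param threshold selection cutoff passed to [screenAgeGenes()].
#' @param normalization `"minmax01"` (default) or `"zscore"`.
#' @param calibrationMode `"cohort_constant"` (default) or `"per_patient"`.
#' @param perPatientScale scale of the per-patient mode (default 0.25).
#' @return an [IAgeModel-class].
#' @export
fitIAgeClock <- function(cohort, weights = NULL, threshold = 0.5,
                         normalization = c("minmax01", "zscore"),
                         calibrationMode = c("cohort_constant", "per_patient"),
                         perPatientScale = 0.25) {
  normalization <- match.arg(normalization)
  calibrationMode <- match.arg(calibrationMode)
  if (perPatientScale <= 0) stop("perPatientScale must be positive")
  if (is.null(weights)) weights <- screenAgeGenes(cohort, threshold)
  sel <- weights$gene_id[weights$selected]
  if (length(sel) == 0L) stop("cannot fit a clock with no selected gene")
  expr <- exprMatrix(cohort)[sel, , drop = FALSE]
  params <- normalizationParams(expr, normalization)
  xn <- applyNormalization(expr, params)
  beta <- weights$beta[match(sel, weights$gene_id)]
  raw <- as.numeric(beta %*% xn)

  if (calibrationMode == "cohort_constant" && stats::sd(raw) == 0)
    stop("all raw scores identical: cohort-constant calibration cannot rank")
  shift <- max(0, 0.01 - min(raw))
  konst <- mean(ageYears(cohort)) / mean(raw + shift)
  methods::new("IAgeModel",
               weights = weights,
               normalization = params,
               shift = shift,
               calibrationConstant = konst,
               calibrationMode = calibrationMode,
               perPatientScale = perPatientScale,
               rawCenter = mean(raw),
               rawScale = if (stats::sd(raw) > 0) stats::sd(raw) else 1,
               threshold = threshold)
}

#' Score a cohort with a fitted clock (frozen replay)
#'
#' Applies a fitted [IAgeModel-class] to a cohort, reusing the stored
#' weights, normalization parameters, shift and calibration constant
#' unchanged — the external-validation protocol. Scoring the training
#' cohort reproduces the fit-time scores.
#'
#' @param model an [IAgeModel-class].
#' @param cohort an [InflammCohort-class] containing all selected genes.
#' @return data.frame with `sample_id`, `raw_score`, `iage_years`;
#'   attribute `"calibration_constant"` carries the constant used.
#' @export
scoreCohort <- function(model, cohort) {
  stopifnot(methods::is(model, "IAgeModel"))
  sel <- model@weights$gene_id[model@weights$selected]
  miss <- setdiff(sel, rownames(cohort))
  if (length(miss))
    stop("cohort lacks selected gene(s): ", paste(miss, collapse = ", "))
  xn <- applyNormalization(exprMatrix(cohort)[sel, , drop = FALSE],
                           model@normalization)
  beta <- model@weights$beta[match(sel, model@weights$gene_id)]
  raw <- as.numeric(beta %*% xn)
  iage <- if (model@calibrationMode == "cohort_constant") {
    model@calibrationConstant * (raw + model@shift)
  } else {
    z <- (raw - model@rawCenter) / model@rawScale
    ageYears(cohort) * (1 + model@perPatientScale * z)
  }
  out <- data.frame(sample_id = colnames(cohort), raw_score = raw,
                    iage_years = iage, stringsAsFactors = FALSE)
  attr(out, "calibration_constant") <- model@calibrationConstant
  out
}

#' Screen, fit and score in one step
#'
#' Convenience wrapper: fits the clock on `cohort` and scores the same
#' cohort. In the default cohort-constant calibration, `mean(iage_years)`
#' equals `mean(age_years)` exactly.
#'
#' @inheritParams fitIAgeClock
#' @param ... passed to [fitIAgeClock()].
#' @return the [scoreCohort()] data.frame, with the fitted model in
#'   attribute `"model"`.
#' @export
computeIAge <- function(cohort, ...) {
  model <- fitIAgeClock(cohort, ...)
  out <- scoreCohort(model, cohort)
  attr(out, "model") <- model
  out
}

#' Random half-split into training and test groups
#'
#' Uniformly random, deterministic per seed; sizes differ by at most one;
#' disjoint and exhaustive. The global RNG state is untouched.
#'
#' @param sampleIds character vector of >= 2 identifiers.
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
splitTrainTest <- function(sampleIds, seed = 1L) {
  n <- length(sampleIds)
  if (n < 2L) stop("need at least 2 samples to split")
  withr::local_preserve_seed()
  set.seed(seed)
  perm <- sample(sampleIds)
  nTrain <- ceiling(n / 2)
  list(train = sort(perm[seq_len(nTrain)]), test = sort(perm[-seq_len(nTrain)]))
}

#' Median-split subtyping
#'
#' Dichotomizes the cohort at the median iAge (midpoint of the two central
#' order statistics for even n). A sample is `high_iage` iff its iAge
#' strictly exceeds the median; ties at the threshold go to `low_iage`
#' (deterministic and conservative). With distinct values and even n the
#' split is exactly n/2 / n/2.
#'
#' @param iage [scoreCohort()] data.frame, or a named numeric vector of
#'   iAge values.
#' @return data.frame with `sample_id`, `subtype` (factor `low_iage` /
#'   `high_iage`) and `threshold_value` (the cohort median).
#' @export
classifyByMedian <- function(iage) {
  if (is.data.frame(iage)) {
    values <- iage$iage_years
    ids <- iage$sample_id
  } else {
    values <- as.numeric(iage)
    ids <- names(iage)
  }
  if (length(values) < 2L) stop("need at least 2 samples")
  if (length(unique(values)) == 1L)
    stop("all iAge values identical: median split undefined")
  med <- stats::median(values)
  data.frame(
    sample_id = ids,
    subtype = factor(ifelse(values > med, "high_iage", "low_iage"),
                     levels = c("low_iage", "high_iage")),
    threshold_value = med,
    stringsAsFactors = FALSE
  )
}

#' Serialize a fitted clock to JSON
#'
#' Stores weights, normalization parameters, shift, calibration constant
#' and mode, so a model written on one machine replays identically on
#' another ([readIAgeModel()] is the inverse).
#'
#' @param model an [IAgeModel-class].
#' @param path output path.
#' @export
writeIAgeModel <- function(model, path) {
  x <- list(
    weights = model@weights,
    normalization = list(method = model@normalization$method,
                         gene_id = names(model@normalization$p1),
                         p1 = unname(model@normalization$p1),
                         p2 = unname(model@normalization$p2)),
    shift = model@shift,
    calibration_constant = model@calibrationConstant,
    calibration_mode = model@calibrationMode,
    per_patient_scale = model@perPatientScale,
    raw_center = model@rawCenter,
    raw_scale = model@rawScale,
    threshold = model@threshold
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeIAgeModel
#' @return `readIAgeModel()`: the restored [IAgeModel-class].
#' @export
readIAgeModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("IAgeModel",
               weights = as.data.frame(x$weights),
               normalization = list(
                 method = x$normalization$method,
                 p1 = stats::setNames(x$normalization$p1, x$normalization$gene_id),
                 p2 = stats::setNames(x$normalization$p2, x$normalization$gene_id)),
               shift = x$shift,
               calibrationConstant = x$calibration_constant,
               calibrationMode = x$calibration_mode,
               perPatientScale = x$per_patient_scale,
               rawCenter = x$raw_center,
               rawScale = x$raw_scale,
               threshold = x$threshold)
}

#' @export
setMethod("show", "IAgeModel", function(object) {
  nSel <- sum(object@weights$selected)
  cat("IAgeModel:", nSel, "of", nrow(object@weights),
      "genes selected (|beta| >=", object@threshold, ")\n")
  cat("  normalization:", object@normalization$method,
      "| calibration:", object@calibrationMode, "\n")
  cat(sprintf("  shift = %.4g, C = %.4g\n", object@shift,
              object@calibrationConstant))
  invisible(object)
})
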