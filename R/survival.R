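# First-principles survival machinery: product-limit estimation with
# Greenwood variance, the two-group log-rank test with hypergeometric
# variance, and univariate Cox regression maximized by Newton-Raphson with
# Breslow tie handling. These are deliberately implemented here rather than
# delegated, so their contracts (oracle equivalence, type-I error, partial-
# likelihood maximality) are testable primitives of the package.

#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct
#' event times, with Greenwood standard errors
#' `S(t) * sqrt(sum d_i / (n_i (n_i - d_i)))`. A subject censored exactly
#' at an event time is counted at risk for that time (the standard
#' right-continuous convention). With no censoring the curve equals the
#' empirical survival function exactly.
#'
#' @param times non-negative observed times.
#' @param events event indicator (1 = event, 0 = censored), same length.
#' @return a [KMCurve-class].
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
#' survProb(km, 3)   # (3/4) * (1/2)
#' @export
kmEstimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (length(times) < 1L) stop("need at least one observation")
  if (anyNA(times) || anyNA(events)) stop("missing values not allowed")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be coded 0/1")
  evTimes <- sort(unique(times[events == 1]))
  nRisk <- vapply(evTimes, function(t) sum(times >= t), numeric(1))
  nEvent <- vapply(evTimes, function(t) sum(times == t & events == 1),
                   numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  gwTerm <- ifelse(nRisk > nEvent, nEvent / (nRisk * (nRisk - nEvent)), 0)
  se <- surv * sqrt(cumsum(gwTerm))
  methods::new("KMCurve", time = evTimes, surv = surv, nRisk = nRisk,
               nEvent = nEvent, se = se, nTotal = length(times),
               maxTime = max(times), obsTimes = sort(times))
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step evaluation: `S(t)` is 1 before the first event
#' time and the product-limit value at the last event time `<= t`
#' otherwise.
#'
#' @param km a [KMCurve-class].
#' @param t numeric vector of times.
#' @return survival probabilities in \[0, 1\].
#' @export
survProb <- function(km, t) {
  if (any(t < 0)) stop("negative time")
  c(1, km@surv)[findInterval(t, km@time) + 1L]
}

#' @describeIn survProb number of subjects still under observation
#'   (observed time `>= t`).
#' @export
nAtRisk <- function(km, t) {
  vapply(t, function(tt) sum(km@obsTimes >= tt), numeric(1))
}

#' @export
setMethod("show", "KMCurve", function(object) {
  cat("KMCurve:", object@nTotal, "subjects,", sum(object@nEvent), "events,",
      length(object@time), "distinct event times\n")
  if (length(object@time)) {
    med <- object@time[object@surv <= 0.5][1]
    cat("  median survival:", if (is.na(med)) "not reached" else med, "\n")
  }
  invisible(object)
})

#' Two-group log-rank test
#'
#' At each distinct pooled event time, the observed number of events in
#' group 1 is compared with its hypergeometric expectation given the risk
#' sets; the statistic `(O1 - E1)^2 / V` is referred to a chi-square
#' distribution with 1 degree of freedom. Invariant to relabeling the
#' groups and to strictly increasing transforms of the time axis.
#'
#' @param times non-negative observed times.
#' @param events event indicator (1 = event, 0 = censored).
#' @param group two-level grouping (factor, character or binary).
#' @return list with `chi_square`, `df` (= 1), `p_value`, and per-group
#'   `observed` and `expected` event counts (which sum to equal totals).
#' @export
logrankTest <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("exactly two non-empty groups required")
  group <- droplevels(group)
  if (sum(events) < 1) stop("at least one event required")
  g1 <- group == levels(group)[1]
  evTimes <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in evTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  dTot <- sum(events == 1)
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  list(
    chi_square = chi,
    df = 1L,
    p_value = if (v > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1,
    observed = stats::setNames(c(o1, dTot - o1), levels(group)),
    expected = stats::setNames(c(e1, dTot - e1), levels(group))
  )
}

# Breslow partial log-likelihood and its first two derivatives at beta.
# Subjects sorted by decreasing time make every risk set a prefix; tied
# times share the cumulative sums at the last index of their tie group.
coxQuantities <- function(times, events, x, beta) {
  ord <- order(times, decreasing = TRUE)
  t <- times[ord]; d <- events[ord]; xs <- x[ord]
  w <- exp(beta * xs)
  s0 <- cumsum(w)
  s1 <- cumsum(w * xs)
  s2 <- cumsum(w * xs^2)
  last <- stats::ave(seq_along(t), match(t, unique(t)), FUN = max)
  ev <- d == 1
  r0 <- s0[last][ev]; r1 <- s1[last][ev]; r2 <- s2[last][ev]
  list(
    loglik = sum(beta * xs[ev] - log(r0)),
    score = sum(xs[ev] - r1 / r0),
    info = sum(r2 / r0 - (r1 / r0)^2)
  )
}

#' Breslow partial log-likelihood
#'
#' The Cox partial log-likelihood with Breslow tie handling at a given
#' coefficient value; useful for likelihood diagnostics.
#'
#' @inheritParams coxUnivariate
#' @param beta coefficient at which to evaluate.
#' @return log partial likelihood (a scalar).
#' @export
coxPartialLoglik <- function(times, events, x, beta) {
  coxQuantities(times, events, x, beta)$loglik
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood with Breslow tie handling by
#' Newton-Raphson from `beta = 0`; convergence when the absolute score
#' falls below `tol` or after `maxIter` iterations. The Wald 95% interval
#' is formed on the coefficient scale and exponentiated. A monotone
#' likelihood (|beta| drifting past 20) is flagged as non-converged and
#' the estimate is returned with a warning.
#'
#' @param times non-negative observed times.
#' @param events event indicator (1 = event, 0 = censored); >= 2 events.
#' @param x numeric covariate, non-constant.
#' @param id label for the covariate in the output.
#' @param tol score-convergence tolerance.
#' @param maxIter maximum Newton iterations.
#' @return list with `covariate_id`, `beta_hat`, `se`, `hr`, `ci95`
#'   (length-2 vector), `p_value` (two-sided Wald), `loglik`, `converged`,
#'   `n_iter`.
#' @export
coxUnivariate <- function(times, events, x, id = "x", tol = 1e-8,
                          maxIter = 50L) {
  if (length(unique(x)) < 2L) stop("covariate is constant")
  if (sum(events) < 2) stop("need at least 2 events")
  if (anyNA(times) || anyNA(events) || anyNA(x))
    stop("missing values not allowed")
  beta <- 0
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    q <- coxQuantities(times, events, x, beta)
    if (!is.finite(q$score) || !is.finite(q$info) || q$info <= 0) break
    if (abs(q$score) < tol) {
      converged <- TRUE
      break
    }
    beta <- beta + q$score / q$info
    if (abs(beta) > 20) break          # monotone-likelihood divergence
    if (iter >= maxIter) break
  }
  q <- coxQuantities(times, events, x, beta)
  se <- if (q$info > 0) 1 / sqrt(q$info) else NA_real_
  if (!converged)
    warning("Cox fit for '", id, "' did not converge; estimate unreliable")
  z <- beta / se
  list(
    covariate_id = id,
    beta_hat = beta,
    se = se,
    hr = exp(beta),
    ci95 = exp(beta + c(-1, 1) * 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    loglik = q$loglik,
    converged = converged,
    n_iter = iter
  )
}

#' Univariate Cox screen over a gene panel
#'
#' Runs [coxUnivariate()] on each gene's z-scored expression against
#' overall survival (samples with unknown survival are dropped). Genes are
#' ranked by p-value; a gene is flagged significant at `alpha` with no
#' multiplicity correction by default (a Benjamini-Hochberg option exists
#' behind `adjust = "BH"`). Genes whose fit fails (constant expression)
#' are reported in the `"failed"` attribute, not fatal.
#'
#' @param cohort an [InflammCohort-class].
#' @param alpha significance level for the flag (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` to flag on adjusted p-values.
#' @return data.frame sorted by p-value with `gene_id`, `beta_hat`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, (`q_value` when `adjust = "BH"`),
#'   `significant`, `converged`; attributes `n_flagged` and `failed`.
#' @export
screenPrognosticGenes <- function(cohort, alpha = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  cl <- clinicalData(cohort)
  keep <- cl$survival_known
  times <- cl$survival_time_days[keep]
  events <- cl$event[keep]
  xn <- normalizeExpression(exprMatrix(cohort)[, keep, drop = FALSE], "zscore")
  rows <- list()
  failed <- character(0)
  for (g in rownames(xn)) {
    fit <- tryCatch(
      suppressWarnings(coxUnivariate(times, events, xn[g, ], id = g)),
      error = function(e) NULL)
    if (is.null(fit)) {
      failed <- c(failed, g)
      next
    }
    rows[[g]] <- data.frame(gene_id = g, beta_hat = fit$beta_hat,
                            hr = fit$hr, ci_low = fit$ci95[1],
                            ci_high = fit$ci95[2], p_value = fit$p_value,
                            converged = fit$converged,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$q_value < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  attr(out, "n_flagged") <- sum(out$significant)
  attr(out, "failed") <- failed
  out
}

#' Conditional survival probability
#'
#' `P(T > target | T > given) = S(target) / S(given)` from a fitted
#' Kaplan-Meier curve, using right-continuous step values.
#'
#' @param km a [KMCurve-class] (fit on whatever time unit `givenT` and
#'   `targetT` are expressed in).
#' @param givenT time already survived.
#' @param targetT target time, `>= givenT`.
#' @return probability in \[0, 1\].
#' @export
conditionalSurvival <- function(km, givenT, targetT) {
  if (any(targetT < givenT)) stop("targetT must be >= givenT")
  sGiven <- survProb(km, givenT)
  if (any(sGiven <= 0)) stop("S(givenT) is zero: conditioning undefined")
  survProb(km, targetT) / sGiven
}

#' Annual conditional survival table
#'
#' For a curve fit on times in years, tabulates
#' `P(T > j | T > i)` for `0 <= i <= j <= maxYears` (diagonal 1; row
#' `i = 0` is the marginal annual survival), together with the median
#' survival (first observed event time with `S(t) <= 0.5`, no
#' interpolation) and the number of subjects still under observation at
#' each year. Cells that would condition on `S(i) = 0` are `NA`.
#'
#' @param km a [KMCurve-class] fit on times in years.
#' @param maxYears largest year in the grid (>= 1).
#' @return list with `probabilities` (square matrix, rows = given year,
#'   columns = target year), `median_survival` (`NA` when not reached) and
#'   `n_alive` (named vector over years 0..maxYears).
#' @export
annualSurvivalTable <- function(km, maxYears) {
  if (maxYears < 1) stop("maxYears must be >= 1")
  yrs <- 0:maxYears
  s <- survProb(km, yrs)
  p <- matrix(NA_real_, length(yrs), length(yrs),
              dimnames = list(given = yrs, target = yrs))
  for (i in seq_along(yrs))
    for (j in i:length(yrs))
      if (s[i] > 0) p[i, j] <- s[j] / s[i]
  med <- km@time[km@surv <= 0.5][1]
  list(
    probabilities = p,
    median_survival = med,
    n_alive = stats::setNames(nAtRisk(km, yrs), yrs)
  )
}
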