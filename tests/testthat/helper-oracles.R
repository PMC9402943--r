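# Independent brute-force oracles and tiny fixture builders shared across
# test files. Everything here is deliberately naive (O(n^2) loops, direct
# textbook definitions) and never calls the package code paths it checks.

# Spearman via explicitly counted mid-ranks and the raw Pearson sums
bruteSpearman <- function(x, y) {
  n <- length(x)
  midrank <- function(v) {
    vapply(seq_len(n), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  r <- midrank(x)
  s <- midrank(y)
  num <- sum((r - mean(r)) * (s - mean(s)))
  den <- sqrt(sum((r - mean(r))^2) * sum((s - mean(s))^2))
  if (den == 0) NA_real_ else num / den
}

# two-group log-rank O1, E1, V by direct subject-level loops
bruteLogrank <- function(times, events, g1) {
  evTimes <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in evTimes) {
    n <- 0; n1 <- 0; d <- 0; d1 <- 0
    for (i in seq_along(times)) {
      if (times[i] >= t) {
        n <- n + 1
        if (g1[i]) n1 <- n1 + 1
      }
      if (times[i] == t && events[i] == 1) {
        d <- d + 1
        if (g1[i]) d1 <- d1 + 1
      }
    }
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v > 0) (o1 - e1)^2 / v else 0
}

# Breslow partial log-likelihood by direct risk-set enumeration
bruteCoxLoglik <- function(times, events, x, beta) {
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# textbook Benjamini-Hochberg step-up: reject H_(1..k*) where k* is the
# largest k with p_(k) <= k/m * q
bhStepUpFlags <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * q)
  flags <- rep(FALSE, m)
  if (length(k)) flags[ord[seq_len(max(k))]] <- TRUE
  flags
}

# minimal valid clinical table
makeClinical <- function(n, ages = NULL, days = NULL, events = NULL,
                         ids = sprintf("s%03d", seq_len(n))) {
  data.frame(
    sample_id = ids,
    age_years = if (is.null(ages)) rep(60, n) else ages,
    survival_time_days = as.integer(if (is.null(days)) rep(365L, n) else days),
    event = as.integer(if (is.null(events)) rep(1L, n) else events),
    survival_known = TRUE,
    stringsAsFactors = FALSE
  )
}

# tiny cohort around a given expression matrix
makeCohort <- function(expr, ages, days = NULL, events = NULL,
                       stemness = NULL) {
  n <- ncol(expr)
  clin <- makeClinical(n, ages = ages, days = days, events = events,
                       ids = colnames(expr))
  InflammCohort(expr, clin, stemness = stemness)
}
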