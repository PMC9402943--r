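test_that("KM with no censoring equals the empirical survival function", {
  expect_equal(kmEstimate(c(1, 2, 3), c(1, 1, 1))@surv, c(2 / 3, 1 / 3, 0))
  set.seed(51)
  for (i in 1:10) {
    t <- round(rexp(40), 2)
    km <- kmEstimate(t, rep(1, 40))
    grid <- seq(0, max(t), length.out = 25)
    expect_equal(survProb(km, grid),
                 vapply(grid, function(g) mean(t > g), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("all-censored data yields a flat curve at 1", {
  km <- kmEstimate(c(2, 5, 9), c(0, 0, 0))
  expect_length(km@time, 0)
  expect_equal(survProb(km, c(0, 4, 100)), c(1, 1, 1))
})

test_that("censoring at an event time keeps the subject at risk", {
  # times (1, 2+, 3, 4), events (1,0,1,1): S(3) = (3/4) * (1/2)
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(survProb(km, 3), 0.375)
  expect_equal(km@nRisk, c(4, 2, 1))
})

test_that("KM survival and Greenwood errors match the survival package", {
  set.seed(52)
  for (i in 1:5) {
    t <- ceiling(rexp(60, 0.3) * 10)        # discrete times force ties
    ev <- rbinom(60, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- kmEstimate(t, ev)
    ref <- summary(survival::survfit(survival::Surv(t, ev) ~ 1))
    expect_equal(km@time, ref$time)
    expect_equal(km@surv, ref$surv, tolerance = 1e-12)
    expect_equal(km@nRisk, ref$n.risk)
    # where S = 0 survfit reports NaN se; we report 0 — compare elsewhere
    ok <- is.finite(ref$std.err)
    expect_equal(km@se[ok], ref$std.err[ok], tolerance = 1e-10)
  }
})

test_that("log-rank is null on duplicated groups and matches survdiff", {
  t <- c(1, 3, 5, 7, 9)
  ev <- c(1, 0, 1, 1, 0)
  dup <- logrankTest(rep(t, 2), rep(ev, 2), rep(c("a", "b"), each = 5))
  expect_equal(dup$chi_square, 0)
  expect_equal(dup$p_value, 1)
  set.seed(53)
  for (i in 1:5) {
    n <- 50
    tt <- ceiling(rexp(n, 0.2))
    ee <- rbinom(n, 1, 0.8)
    gg <- rep(c("a", "b"), n / 2)
    if (sum(ee) == 0) ee[1] <- 1
    mine <- logrankTest(tt, ee, gg)
    ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
    expect_equal(mine$chi_square, ref$chisq, tolerance = 1e-10)
    expect_equal(unname(mine$observed), unname(ref$obs))
    expect_equal(unname(mine$expected), unname(ref$exp), tolerance = 1e-10)
    expect_equal(sum(mine$observed), sum(mine$expected), tolerance = 1e-10)
  }
})

test_that("log-rank matches brute-force and permutation oracles at n = 8", {
  t <- c(2, 4, 5, 7, 8, 10, 12, 15)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  grp <- c(1, 1, 1, 1, 0, 0, 0, 0)
  mine <- logrankTest(t, ev, grp)
  expect_equal(mine$chi_square, bruteLogrank(t, ev, grp == 1),
               tolerance = 1e-12)
  # exact permutation reference: all 70 balanced relabelings
  combs <- utils::combn(8, 4)
  chiAll <- apply(combs, 2, function(idx) {
    g <- rep(0, 8); g[idx] <- 1
    bruteLogrank(t, ev, g == 1)
  })
  pPerm <- mean(chiAll >= mine$chi_square - 1e-12)
  expect_lt(abs(mine$p_value - pPerm), 0.1)
})

test_that("log-rank is invariant to relabeling and monotone time transforms", {
  set.seed(54)
  t <- rexp(30)
  ev <- rbinom(30, 1, 0.8)
  g <- rep(c("x", "y"), 15)
  a <- logrankTest(t, ev, g)
  b <- logrankTest(t, ev, ifelse(g == "x", "y", "x"))
  expect_equal(a$chi_square, b$chi_square, tolerance = 1e-12)
  d <- logrankTest(log1p(t), ev, g)     # strictly increasing transform
  expect_equal(a$chi_square, d$chi_square, tolerance = 1e-12)
})

test_that("log-rank keeps its nominal size under the null", {
  set.seed(55)
  reject <- 0L
  nrep <- 2000L
  for (i in seq_len(nrep)) {
    t <- rexp(100)
    g <- rep(0:1, each = 50)
    if (logrankTest(t, rep(1, 100), g)$p_value < 0.05) reject <- reject + 1L
  }
  rate <- reject / nrep
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("Cox estimate maximizes the partial likelihood (grid-scan oracle)", {
  set.seed(56)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    t <- sample(100, n)                  # no ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) ev[1:2] <- 1
    x <- rnorm(n)
    fit <- coxUnivariate(t, ev, x)
    if (!fit$converged) next
    grid <- seq(-3, 3, by = 0.01)
    llGrid <- vapply(grid, function(b) bruteCoxLoglik(t, ev, x, b),
                     numeric(1))
    expect_gte(bruteCoxLoglik(t, ev, x, fit$beta_hat) + 1e-10, max(llGrid))
    expect_equal(fit$loglik, bruteCoxLoglik(t, ev, x, fit$beta_hat),
                 tolerance = 1e-10)
  }
})

test_that("Cox matches coxph with Breslow ties on random data", {
  set.seed(57)
  for (i in 1:5) {
    n <- 80
    t <- ceiling(rexp(n, 0.2))
    x <- rnorm(n)
    ev <- rbinom(n, 1, 0.8)
    fit <- coxUnivariate(t, ev, x)
    ref <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "breslow")
    expect_equal(fit$beta_hat, unname(coef(ref)), tolerance = 1e-7)
    expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-7)
    expect_identical(fit$hr > 1, fit$beta_hat > 0)
    expect_lte(fit$ci95[1], fit$hr)
    expect_gte(fit$ci95[2], fit$hr)
  }
})

test_that("Cox recovers a two-group log-HR of 0.7 within 10%", {
  set.seed(58)
  est <- vapply(1:20, function(i) {
    n <- 500
    g <- rep(0:1, each = n / 2)
    t <- rexp(n, exp(0.7 * g))
    cens <- rexp(n, 0.25)
    coxUnivariate(pmin(t, cens), as.integer(t <= cens), g)$beta_hat
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7) / 0.7, 0.10)
})

test_that("Cox is equivariant under covariate scaling", {
  set.seed(59)
  t <- rexp(60)
  ev <- rbinom(60, 1, 0.8)
  x <- rnorm(60)
  b1 <- coxUnivariate(t, ev, x)$beta_hat
  b5 <- coxUnivariate(t, ev, 5 * x)$beta_hat
  expect_equal(b5, b1 / 5, tolerance = 1e-8)
})

test_that("degenerate Cox inputs are caught or flagged", {
  expect_error(coxUnivariate(1:5, rep(1, 5), rep(2, 5)), "constant")
  expect_error(coxUnivariate(1:5, c(1, 0, 0, 0, 0), rnorm(5)), "2 events")
  # perfectly separated covariate drives a monotone likelihood
  t <- c(1, 2, 3, 10, 11, 12)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- coxUnivariate(t, rep(1, 6), x), "converge")
  expect_false(fit$converged)
})

test_that("prognostic screen flags hazard-linked genes and respects alpha", {
  co <- generateCohort(simConfig(nSamples = 500, seed = 61))
  linked <- cohortTruth(co)$age_linked_gene_ids
  scr <- screenPrognosticGenes(co)
  expect_identical(order(scr$p_value), seq_len(nrow(scr)))
  sens <- mean(linked %in% scr$gene_id[scr$significant])
  expect_gte(sens, 0.8)
  expect_identical(attr(scr, "n_flagged"), sum(scr$significant))
  none <- screenPrognosticGenes(co, alpha = 0)
  expect_identical(sum(none$significant), 0L)
})

test_that("prognostic screen is calibrated on permuted survival times", {
  co <- generateCohort(simConfig(nSamples = 200, seed = 62))
  cl <- clinicalData(co)
  set.seed(63)
  perm <- sample(nrow(cl))
  cl$survival_time_days <- cl$survival_time_days[perm]
  cl$event <- cl$event[perm]
  null <- InflammCohort(exprMatrix(co), cl)
  scr <- screenPrognosticGenes(null, alpha = 0.05)
  # 200 genes at alpha 0.05: expect about 10 flags, binomial 2-sigma ~ 6
  expect_gte(sum(scr$significant), 1L)
  expect_lte(sum(scr$significant), 25L)
})

test_that("conditional survival follows S(target)/S(given)", {
  # 50 subjects, all events: 25 die by year 3, 7 more by 3.5, rest at 5
  t <- c(rep(1.5, 10), rep(2.5, 15), rep(3.5, 7), rep(5, 18))
  km <- kmEstimate(t, rep(1, 50))
  expect_equal(survProb(km, 3), 0.5)
  expect_equal(survProb(km, 4), 0.36)
  expect_equal(conditionalSurvival(km, 3, 4), 0.72, tolerance = 1e-12)
  expect_equal(conditionalSurvival(km, 0, 4), survProb(km, 4))
  expect_equal(conditionalSurvival(km, 3, 3), 1)
  expect_error(conditionalSurvival(km, 4, 3), "targetT")
  expect_error(conditionalSurvival(km, 6, 7), "zero")
})

test_that("conditional-survival chain rule holds to machine precision", {
  set.seed(64)
  for (i in 1:10) {
    t <- rexp(80, 0.4)
    ev <- rbinom(80, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- kmEstimate(t, ev)
    ts <- sort(runif(3, 0, max(t[ev == 1])))
    if (survProb(km, ts[1]) == 0 || survProb(km, ts[2]) == 0) next
    expect_equal(conditionalSurvival(km, ts[1], ts[3]),
                 conditionalSurvival(km, ts[2], ts[3]) *
                   conditionalSurvival(km, ts[1], ts[2]),
                 tolerance = 1e-12)
  }
})

test_that("annual table matches hand-computed fractions without censoring", {
  t <- c(rep(0.5, 4), rep(1.5, 3), rep(2.5, 2), rep(3.5, 1))
  km <- kmEstimate(t, rep(1, 10))
  tab <- annualSurvivalTable(km, 3)
  expect_equal(unname(diag(tab$probabilities)), rep(1, 4))
  # marginal row: S(1)=6/10, S(2)=3/10, S(3)=1/10
  expect_equal(unname(tab$probabilities["0", ]), c(1, 0.6, 0.3, 0.1))
  expect_equal(unname(tab$probabilities["1", "2"]), 0.5)
  expect_equal(unname(tab$probabilities["2", "3"]), 1 / 3)
  expect_equal(unname(tab$n_alive), c(10, 6, 3, 1))
  expect_equal(tab$median_survival, 1.5)   # first time with S <= 0.5
})
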