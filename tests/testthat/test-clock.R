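test_that("age groups follow the four-bin classification with its boundaries", {
  got <- assignAgeGroup(c(20, 44, 45, 59, 60, 74, 75, 90, 44.5))
  expect_identical(as.character(got),
                   c("young", "young", "middle", "middle", "old_young",
                     "old_young", "old", "old", "middle"))
  expect_error(assignAgeGroup(c(50, 0)), "positive")
  expect_error(assignAgeGroup(c(50, NA)), "positive")
})

test_that("spearmanRho handles perfect monotone, reversal and constants", {
  expect_equal(spearmanRho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearmanRho(1:4, c(40, 30, 20, 10)), -1)
  expect_true(is.na(spearmanRho(c(2, 2, 2), 1:3)))
  expect_error(spearmanRho(1:3, 1:4), "equal length")
  expect_error(spearmanRho(1:2, 1:2), "3 observations")
})

test_that("spearmanRho equals the brute-force mid-rank oracle with ties", {
  expect_equal(spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               bruteSpearman(c(1, 2, 2, 4), c(1, 3, 2, 4)), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties likely
    y <- sample(1:6, n, replace = TRUE)
    mine <- spearmanRho(x, y)
    ref <- bruteSpearman(x, y)
    if (is.na(ref)) expect_true(is.na(mine))
    else {
      expect_equal(mine, ref, tolerance = 1e-12)
      expect_equal(spearmanRho(y, x), mine, tolerance = 1e-12)  # symmetry
    }
  }
})

test_that("screening selects at the inclusive |beta| >= 0.5 boundary", {
  # gene ranks (2,4,1,3,5) against ordered ages: sum d^2 = 10, rho = 0.5
  expr <- rbind(ONBOUND = c(2, 4, 1, 3, 5), FLAT = rep(1, 5))
  colnames(expr) <- paste0("s", 1:5)
  co <- makeCohort(expr, ages = c(40, 50, 60, 70, 80))
  wt <- screenAgeGenes(co, threshold = 0.5)
  expect_equal(wt$beta[wt$gene_id == "ONBOUND"], 0.5)
  expect_true(wt$selected[wt$gene_id == "ONBOUND"])
  expect_true(is.na(wt$beta[wt$gene_id == "FLAT"]))
  expect_false(wt$selected[wt$gene_id == "FLAT"])
})

test_that("screening warns when no gene passes", {
  expr <- matrix(rep(1, 10), 2, 5,
                 dimnames = list(c("A", "B"), paste0("s", 1:5)))
  co <- makeCohort(expr, ages = c(40, 50, 60, 70, 80))
  expect_warning(wt <- screenAgeGenes(co), "no gene")
  expect_error(fitIAgeClock(co, weights = wt), "no selected gene")
})

test_that("screening recovers linked genes on a generated cohort", {
  co <- generateCohort(simConfig(nSamples = 300, nAgeLinked = 40, seed = 17))
  wt <- screenAgeGenes(co, threshold = 0.5)
  linked <- cohortTruth(co)$age_linked_gene_ids
  expect_gte(sum(wt$selected & wt$gene_id %in% linked), 36)
  expect_lte(sum(wt$selected & !wt$gene_id %in% linked), 8)
})

test_that("normalization maps genes to the stated ranges", {
  m <- rbind(A = c(0, 5, 10), B = c(3, 3, 3), C = c(1, 2, 4))
  colnames(m) <- paste0("s", 1:3)
  mm <- normalizeExpression(m, "minmax01")
  expect_equal(unname(mm["A", ]), c(0, 0.5, 1))
  expect_equal(unname(mm["B", ]), rep(0.5, 3))
  zz <- normalizeExpression(m, "zscore")
  expect_equal(unname(rowMeans(zz)[c("A", "C")]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zz, 1, sd)[c("A", "C")]), c(1, 1),
               tolerance = 1e-12)
  expect_equal(unname(zz["B", ]), rep(0, 3))
  expect_identical(dimnames(mm), dimnames(m))
})

test_that("iAge matches the hand-computed calibration on a two-sample cohort", {
  expr <- matrix(c(0, 5), 1, 2, dimnames = list("G1", c("s1", "s2")))
  co <- makeCohort(expr, ages = c(50, 70))
  wt <- data.frame(gene_id = "G1", beta = 1, selected = TRUE)
  ia <- scoreCohort(fitIAgeClock(co, weights = wt), co)
  # minmax X = (0, 1); shift = 0.01; C = 60 / mean(0.01, 1.01) = 60 / 0.51;
  # iage = C * (0.01, 1.01) = (60/51, 6060/51), whose mean is 60 = mean age
  expect_equal(ia$raw_score, c(0, 1))
  expect_equal(ia$iage_years, (60 / 0.51) * c(0.01, 1.01), tolerance = 1e-12)
  expect_equal(mean(ia$iage_years), 60, tolerance = 1e-12)
})

test_that("cohort-constant calibration fixes mean(iAge) = mean(age) exactly", {
  for (s in c(2, 8)) {
    co <- generateCohort(simConfig(nSamples = 80, seed = s))
    ia <- computeIAge(co)
    expect_equal(mean(ia$iage_years), mean(ageYears(co)), tolerance = 1e-10)
  }
})

test_that("iAge tracks chronological age on a default synthetic cohort", {
  co <- generateCohort(simConfig(nSamples = 300, seed = 33))
  ia <- computeIAge(co)
  expect_gte(spearmanRho(ia$iage_years, ageYears(co)), 0.5)
})

test_that("per-patient mode scales each patient's own age", {
  co <- generateCohort(simConfig(nSamples = 60, seed = 12))
  model <- fitIAgeClock(co, calibrationMode = "per_patient")
  ia <- scoreCohort(model, co)
  z <- (ia$raw_score - model@rawCenter) / model@rawScale
  expect_equal(ia$iage_years, ageYears(co) * (1 + 0.25 * z),
               tolerance = 1e-12)
})

test_that("degenerate identical raw scores are rejected", {
  expr <- matrix(rep(2, 4), 1, 4, dimnames = list("G1", paste0("s", 1:4)))
  co <- makeCohort(expr, ages = c(50, 55, 60, 65))
  wt <- data.frame(gene_id = "G1", beta = 1, selected = TRUE)
  expect_error(fitIAgeClock(co, weights = wt), "identical")
})

test_that("train/test split is balanced, disjoint, exhaustive, reproducible", {
  ids <- sprintf("P%03d", 1:168)
  sp <- splitTrainTest(ids, seed = 5)
  expect_identical(lengths(sp), c(train = 84L, test = 84L))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, splitTrainTest(ids, seed = 5))
  expect_false(identical(sp, splitTrainTest(ids, seed = 6)))
  sp5 <- splitTrainTest(letters[1:5], seed = 1)
  expect_identical(sort(unname(lengths(sp5))), c(2L, 3L))
  expect_error(splitTrainTest("a"), "at least 2")
})

test_that("median split yields equal subtypes for distinct even-n scores", {
  for (n in c(216L, 168L)) {
    co <- generateCohort(simConfig(nSamples = n, seed = n))
    ia <- computeIAge(co)
    expect_identical(anyDuplicated(ia$iage_years), 0L)
    sub <- classifyByMedian(ia)
    expect_identical(unname(table(sub$subtype)["high_iage"]), n %/% 2L)
    expect_identical(unname(table(sub$subtype)["low_iage"]), n %/% 2L)
  }
})

test_that("median-split ties at the threshold go to the low subtype", {
  sub <- classifyByMedian(c(a = 1, b = 2, c = 2, d = 3))
  expect_identical(sub$threshold_value, rep(2, 4))
  expect_identical(as.character(sub$subtype),
                   c("low_iage", "low_iage", "low_iage", "high_iage"))
  expect_error(classifyByMedian(c(a = 1, b = 1)), "identical")
})

test_that("median split commutes with the cohort-constant calibration", {
  co <- generateCohort(simConfig(nSamples = 101, seed = 44))
  ia <- computeIAge(co)
  fromIage <- classifyByMedian(ia)
  fromRaw <- classifyByMedian(stats::setNames(ia$raw_score, ia$sample_id))
  expect_identical(as.character(fromIage$subtype),
                   as.character(fromRaw$subtype))
})

test_that("reflecting a gene's expression negates its weight", {
  co <- generateCohort(simConfig(nSamples = 120, seed = 3))
  wt <- screenAgeGenes(co)
  expr <- exprMatrix(co)
  g <- cohortTruth(co)$age_linked_gene_ids[1]
  expr[g, ] <- max(expr[g, ]) - expr[g, ]   # order-reversing, non-negative
  wt2 <- screenAgeGenes(makeCohort(expr, ages = ageYears(co)))
  expect_equal(wt2$beta[wt2$gene_id == g], -wt$beta[wt$gene_id == g],
               tolerance = 1e-12)
  expect_identical(wt2$selected[wt2$gene_id == g],
                   wt$selected[wt$gene_id == g])
})

test_that("frozen-weight replay is deterministic and survives JSON round trip", {
  train <- generateCohort(simConfig(nSamples = 150, seed = 1))
  valid <- generateCohort(simConfig(nSamples = 90, seed = 2))
  model <- fitIAgeClock(train)
  a <- scoreCohort(model, valid)
  b <- scoreCohort(model, valid)
  expect_identical(a, b)
  f <- withr::local_tempfile(fileext = ".json")
  writeIAgeModel(model, f)
  restored <- readIAgeModel(f)
  expect_equal(scoreCohort(restored, valid)$iage_years, a$iage_years,
               tolerance = 1e-12)
  # training-cohort scores replay the fit-time calibration identity
  expect_equal(mean(scoreCohort(model, train)$iage_years),
               mean(ageYears(train)), tolerance = 1e-10)
})

test_that("scoring a cohort that lacks a selected gene fails loudly", {
  train <- generateCohort(simConfig(nSamples = 100, seed = 6))
  model <- fitIAgeClock(train)
  sel <- model@weights$gene_id[model@weights$selected]
  small <- train[setdiff(rownames(train), sel[1]), ]
  expect_error(scoreCohort(model, small), sel[1])
})
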