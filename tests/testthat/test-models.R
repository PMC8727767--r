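fixture <- loadCohort()
fx <- cohortData(fixture)

test_that("median split reproduces the published outcome counts", {
  yD <- medianSplit(fx$gose_discharge, "discharge")
  expect_equal(c(sum(yD), sum(1 - yD)), c(20, 12))

  yC <- medianSplit(fx$gose_chronic, "chronic")
  expect_identical(sum(is.na(yC)), 2L)
  expect_equal(c(sum(yC, na.rm = TRUE), sum(1 - yC, na.rm = TRUE)),
               c(15, 15))

  same <- medianSplit(rep(6L, 5), "discharge")
  expect_true(isTRUE(attr(same, "degenerate")))
  expect_error(medianSplit(c(1, 9), "discharge"), "1, 8")
  expect_error(medianSplit(1:3, "sixmonth"), "arg")
})

test_that("logistic fits reproduce the published fixture models", {
  yD <- medianSplit(fx$gose_discharge, "discharge")

  m0 <- fitLogistic(NULL, yD)
  expect_equal(m0@beta[["(Intercept)"]], log(20 / 12), tolerance = 1e-6)
  expect_equal(m0@logLik, 20 * log(20 / 32) + 12 * log(12 / 32),
               tolerance = 1e-8)

  m <- fitLogistic(cbind(maxBSR = fx$max_bsr, maxGCS = fx$max_gcs), yD)
  expect_equal(m@beta[["maxBSR"]], 13.866, tolerance = 5e-3)
  expect_equal(m@beta[["maxGCS"]], 1.572, tolerance = 5e-3)
  expect_equal(m@logLik, -5.366, tolerance = 2e-3)

  z <- fitLogistic(cbind(x = rnorm(10)), rep(0, 10))
  expect_true(z@degenerate)
})

test_that("logistic MLE matches dense grid-search maximization", {
  set.seed(99)
  x <- rnorm(10)
  y <- rbinom(10, 1, plogis(0.3 + 0.8 * x))
  fit <- fitLogistic(cbind(x = x), y)
  grid <- gridLogistic(x, y, fit@beta[1] + c(-2, 2), fit@beta[2] + c(-2, 2))
  expect_gte(fit@logLik, grid$logLik - 1e-9)
  expect_lt(abs(fit@beta[[1]] - grid$beta[1]), grid$step)
  expect_lt(abs(fit@beta[[2]] - grid$beta[2]), grid$step)
})

test_that("AICc follows the small-sample correction", {
  expect_equal(aicc(-5.366, 3, 32), 17.589, tolerance = 1e-3)
  expect_equal(aicc(-15.907, 2, 32), 36.228, tolerance = 1e-3)
  expect_equal(aicc(-7, 0, 20), 14)
  expect_error(aicc(-5, 4, 5), "n > k")
  # converges to AIC as n grows
  gap <- vapply(c(20, 100, 1000, 1e5), function(n)
    aicc(-10, 3, n) - (2 * 10 + 2 * 3), numeric(1))
  expect_true(all(diff(gap) < 0) && gap[4] < 1e-3)
})

test_that("Akaike weights renormalize over the selection window", {
  w <- akaikeWeights(c(0, 0.567, 2.826, 3.047))
  expect_equal(round(w, 3), c(0.452, 0.340, 0.110, 0.098))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  w2 <- akaikeWeights(c(0, 2, 30, 40))
  expect_identical(w2[3:4], c(0, 0))
  expect_equal(sum(w2), 1, tolerance = 1e-12)
})

test_that("model enumeration covers all 16 subsets with a sane window", {
  ms <- enumerateModels(fixture, "discharge")
  expect_length(ms@fits, 16)
  expect_identical(ms@n, 32L)
  expect_equal(sum(modelWeights(ms)), 1, tolerance = 1e-12)

  # every model in the selection window contains both maxBSR and maxGCS
  inw <- which(ms@delta <= ms@windowDelta)
  for (i in inw)
    expect_true(all(c("maxBSR", "maxGCS") %in% ms@fits[[i]]@terms))

  msC <- enumerateModels(fixture, "chronic")
  expect_identical(msC@n, 30L)  # missing chronic GOSe dropped
  tab <- modelTable(msC)
  expect_identical(nrow(tab), 16L)
  expect_true(all(diff(tab$AICc) >= 0))
})

test_that("a null generator leaves the intercept-only model in the window", {
  hits <- 0L
  for (rep in 1:20) {
    sim <- simulateCohort(simParams(nPatients = 500, seed = 1000 + rep,
                                    outcomeCoef = c(0, 0, 0)),
                          signals = FALSE)
    ms <- enumerateModels(sim$cohort, "chronic")
    i0 <- which(vapply(ms@fits, function(f) length(f@terms) == 0, logical(1)))
    if (ms@delta[i0] <= ms@windowDelta) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # >= 80% of replicates
})

test_that("conditional averaging reproduces the published averaged betas", {
  # chronic window: renormalized weighted means of the window coefficients
  expect_equal(conditionalAverage(c(8.083, 7.917, 8.444, 8.340),
                                  c(0.422, 0.284, 0.146, 0.146)),
               8.13, tolerance = 5e-3)
  expect_equal(conditionalAverage(c(-5.818, -6.289), c(0.422, 0.146)),
               -5.94, tolerance = 5e-3)
})

test_that("averaged parameters stay within the window coefficient range", {
  for (tp in c("discharge", "chronic")) {
    ms <- enumerateModels(fixture, tp)
    av <- averageParameters(ms)
    inw <- which(ms@delta <= ms@windowDelta)
    for (i in seq_len(nrow(av))) {
      tm <- av$term[i]
      bs <- unlist(lapply(ms@fits[inw], function(f)
        if (tm %in% names(f@beta)) f@beta[[tm]]))
      expect_gte(av$beta[i], min(bs))
      expect_lte(av$beta[i], max(bs))
      expect_gte(av$adj_se[i], av$se[i])  # df adjustment only inflates
    }
  }
})

test_that("a single-model window reduces averaging to that model", {
  ms <- enumerateModels(fixture, "discharge", windowDelta = 0.1)
  expect_identical(sum(ms@delta <= 0.1), 1L)
  av <- averageParameters(ms)
  f <- ms@fits[[1]]
  for (i in seq_len(nrow(av))) {
    expect_equal(av$beta[i], f@beta[[av$term[i]]])
    expect_equal(av$se[i], sqrt(f@vcov[av$term[i], av$term[i]]))
  }
})

test_that("association statistics reproduce the published values", {
  # published to two decimals
  rd <- pearsonR(fx$gose_discharge, fx$days_discharge)
  expect_equal(round(rd$r, 2), -0.24)
  expect_gt(rd$p, 0.05)
  rc <- pearsonR(fx$gose_chronic, fx$days_chronic)
  expect_equal(round(rc$r, 2), 0.05)
  expect_identical(rc$n, 28L)

  x <- rnorm(20)
  expect_equal(pearsonR(x, x)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_error(pearsonR(1:2, 2:3), "at least 3")
  expect_warning(z <- pearsonR(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(z$r))
})

test_that("2x2 chi-squared matches the published missing-data checks", {
  chi <- chiSquared2x2(rbind(c(20, 12), c(6, 2)))
  expect_equal(chi$chi2, 0.44, tolerance = 5e-3)
  expect_gt(chi$p, 0.5)

  expect_equal(chiSquared2x2(rbind(c(15, 15), c(4, 4)))$chi2, 0)
  expect_equal(chiSquared2x2(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  expect_error(chiSquared2x2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chiSquared2x2(rbind(c(-1, 2), c(1, 2))), "nonnegative")
})
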