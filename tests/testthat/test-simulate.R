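# generator sizes here are kept small (short sections, modest fs); statistical
# checks use seed loops rather than single long runs

test_that("state path hits the burst-only and isoelectric limits", {
  p <- simParams(sectionDurationS = 30, fs = 128)
  s0 <- simulateBSEEG(p, 0, seed = 1)
  expect_true(all(s0$truth@statePath == 0L))
  # rectified amplitude exceeds 1 uV on > 99% of each channel's samples
  # (the rare exceptions are the jittered per-channel deviations)
  expect_true(all(rowMeans(abs(s0$record@signal) > 1) > 0.99))

  s1 <- simulateBSEEG(p, 1, seed = 1)
  expect_true(all(s1$truth@statePath == 1L))
  expect_equal(bsr(computeBSR(makeSection(s1$record@signal, fs = 128))), 1.0)

  expect_error(simulateBSEEG(p, 1.5), "proportion")
  expect_error(simulateBSEEG(p, -0.1), "proportion")
})

test_that("suppression-state samples stay below 1 uV nearly always", {
  p <- simParams(sectionDurationS = 60, fs = 128)
  sim <- simulateBSEEG(p, 0.6, seed = 7)
  supp <- sim$truth@statePath == 1L
  # pool across channels; per-channel jitter is rare enough not to matter
  amps <- abs(sim$record@signal[, supp])
  expect_gt(mean(amps < 1), 0.999)
})

test_that("realized suppression fraction converges to the target", {
  p <- simParams(sectionDurationS = 600, fs = 64)
  for (target in c(0.3, 0.7)) {
    fr <- vapply(1:20, function(s)
      simulateBSEEG(p, target, seed = s)$truth@suppressionFraction, numeric(1))
    expect_lt(abs(mean(fr) - target), 0.02)
  }
})

test_that("signal kurtosis rises with suppression fraction below 1", {
  p <- simParams(sectionDurationS = 60, fs = 128)
  lk <- vapply(c(0, 0.3, 0.6, 0.9), function(tg) {
    sim <- simulateBSEEG(p, tg, seed = 11)
    logKurtosis(makeSection(sim$record@signal, fs = 128))
  }, numeric(1))
  expect_true(all(diff(lk) > 0))
  # a truly isoelectric record (no jittered burst excursions) collapses back
  # to a near-Gaussian kurtosis, far below the burst-suppression range
  iso <- simulateBSEEG(simParams(sectionDurationS = 60, fs = 128,
                                 jitterProb = 0), 1, seed = 11)
  expect_lt(logKurtosis(makeSection(iso$record@signal, fs = 128)), lk[2])
})

test_that("GCS trajectories respect sedation windows", {
  g0 <- simulateGCSSeries(96, list(), seed = 1)
  expect_gte(min(g0@scores), 7L)
  g1 <- simulateGCSSeries(48, list(c(0, 48)), seed = 1)
  expect_lte(max(g1@scores), 6L)
  # at least 2 assessments per simulated day
  expect_gte(length(g0@timestamps), 2 * 4)

  for (s in 1:50) {
    g <- simulateGCSSeries(96, list(c(24, 48)), seed = s)
    tmin <- g@timestamps[which.min(g@scores)]
    expect_true(tmin >= 24 && tmin <= 48)
  }

  expect_error(simulateGCSSeries(96, list(c(50, 40))), "malformed")
  expect_error(simulateGCSSeries(96, list(c(0, 30), c(20, 50))), "overlap")
  expect_error(simulateGCSSeries(96, list(c(80, 120))), "malformed")
})

test_that("null outcome model yields ~50% positive outcomes", {
  sim <- simulateCohort(simParams(nPatients = 1000, seed = 5,
                                  outcomeCoef = c(0, 0, 0)), signals = FALSE)
  expect_lt(abs(mean(sim$truth$outcome_chronic) - 0.5), 0.04)
})

test_that("refitting the generating model recovers the coefficients", {
  sim <- simulateCohort(simParams(nPatients = 500, seed = 42,
                                  outcomeCoef = c(-13, 8, 1)),
                        signals = FALSE)
  tr <- sim$truth
  fit <- fitLogistic(cbind(maxBSR = tr$target_max_bsr, maxGCS = tr$max_gcs),
                     tr$outcome_chronic)
  se <- sqrt(diag(fit@vcov))
  expect_lt(abs(fit@beta[["maxBSR"]] - 8), 3 * se[["maxBSR"]])
  expect_lt(abs(fit@beta[["maxGCS"]] - 1), 3 * se[["maxGCS"]])
})

test_that("simulation is byte-identical under a fixed seed", {
  p <- simParams(nPatients = 4, fs = 64, sectionDurationS = 20, seed = 9)
  a <- simulateCohort(p, signals = TRUE)
  b <- simulateCohort(p, signals = TRUE)
  expect_identical(cohortData(a$cohort), cohortData(b$cohort))
  expect_identical(a$truth, b$truth)
  expect_identical(a$sections[[1]][[1]]$section@signal,
                   b$sections[[1]][[1]]$section@signal)

  s1 <- simulateBSEEG(simParams(sectionDurationS = 5, fs = 64), 0.5, seed = 3)
  s2 <- simulateBSEEG(simParams(sectionDurationS = 5, fs = 64), 0.5, seed = 3)
  expect_identical(s1$record@signal, s2$record@signal)
})

test_that("synthetic cohorts carry the assumed clinical structure", {
  sim <- simulateCohort(simParams(nPatients = 400, seed = 12), signals = FALSE)
  r <- cohortData(sim$cohort)
  expect_s4_class(sim$cohort, "CohortTable")
  # about 31% burst-suppressed, barbiturates saturating with BSR
  expect_lt(abs(mean(r$max_bsr > 0.4) - 0.31), 0.08)
  expect_gt(mean(r$barbiturates[r$max_bsr > 0.45]), 0.85)
  # median split recovers the generated binary outcomes exactly
  expect_identical(medianSplit(r$gose_chronic, "chronic"),
                   sim$truth$outcome_chronic)
  expect_identical(medianSplit(r$gose_discharge, "discharge"),
                   sim$truth$outcome_discharge)
})

test_that("mediation test-bed generator honours its coefficients", {
  d <- simulateMediationData(5000, coefM = c(0.2, 0.7, 0), sigmaM = 0.5,
                             coefY = c(0, 0, 1, 0), seed = 3)
  m <- lm(mediator ~ treat, data = d)
  expect_lt(abs(coef(m)[["treat"]] - 0.7), 0.05)
  null <- simulateMediationData(5000, coefM = c(0, 0, 0), seed = 4)
  expect_lt(abs(coef(lm(mediator ~ treat, null))[["treat"]]), 0.06)
})
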