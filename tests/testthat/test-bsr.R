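test_that("binarization applies a strict rectified threshold", {
  z <- makeSection(matrix(0, 3, 10))
  expect_true(all(binarizeSuppression(z) == 1L))

  pm5 <- makeSection(matrix(c(5, -5, 5), 3, 10))
  expect_true(all(binarizeSuppression(pm5, 1) == 0L))
  expect_true(all(binarizeSuppression(pm5, 10) == 1L))
  # boundary samples equal to the threshold are non-suppressed
  expect_true(all(binarizeSuppression(pm5, 5) == 0L))

  expect_error(binarizeSuppression(z, 0), "positive")
  expect_error(binarizeSuppression(z, -1), "positive")

  # masked samples are excluded
  m <- makeSection(matrix(0, 2, 10), badMask = c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_identical(ncol(binarizeSuppression(m)), 6L)
})

test_that("consensus is the cross-channel mode with ties to suppression", {
  b <- matrix(c(rep(1L, 7), rep(0L, 6)), 13, 1)
  expect_identical(channelConsensus(b), 1L)
  b <- matrix(c(rep(1L, 6), rep(0L, 7)), 13, 1)
  expect_identical(channelConsensus(b), 0L)

  same <- matrix(rep(c(1L, 0L, 1L), each = 5), 5, 3, byrow = FALSE)
  expect_identical(channelConsensus(same), same[1, ])

  tie <- rbind(rep(1L, 4), rep(0L, 4))
  expect_identical(channelConsensus(tie), rep(1L, 4))
})

test_that("vectorized BSR equals the per-sample loop oracle exactly", {
  set.seed(31)
  for (trial in 1:20) {
    k <- sample(c(2, 3, 13), 1)
    n <- 100  # 1-s fixture at 100 Hz
    sig <- matrix(rnorm(k * n, sd = sample(c(0.3, 1, 3), 1)), k, n)
    mask <- runif(n) < 0.1
    if (all(mask)) mask[1] <- FALSE
    sec <- makeSection(sig, badMask = mask)
    th <- sample(c(0.5, 1, 2), 1)
    expect_identical(bsr(computeBSR(sec, th)), loopBSR(sig, mask, th))
  }
})

test_that("BSR recovers the generated suppression fraction", {
  p <- simParams(sectionDurationS = 120, fs = 128)
  err <- vapply(1:10, function(s) {
    sim <- simSection(0.7, seed = s, fs = 128, durationS = 120, params = p)
    bsr(computeBSR(sim$section)) - sim$truth@suppressionFraction
  }, numeric(1))
  expect_lt(max(abs(err)), 0.02)

  iso <- simSection(1, seed = 1, fs = 128, durationS = 30)
  expect_equal(bsr(computeBSR(iso$section)), 1.0)
  bo <- simSection(0, seed = 1, fs = 128, durationS = 30)
  expect_lte(bsr(computeBSR(bo$section)), 0.01)
})

test_that("BSR is monotone in the threshold and bracketed by channel fractions", {
  set.seed(17)
  sim <- simSection(0.5, seed = 23, fs = 128, durationS = 30)
  ths <- c(0.2, 0.5, 1, 2, 5, 10, 25)
  vals <- vapply(ths, function(th) bsr(computeBSR(sim$section, th)), numeric(1))
  expect_true(all(diff(vals) >= 0))

  res <- computeBSR(sim$section)
  expect_gte(bsr(res), min(res@perChannelFraction))
  expect_lte(bsr(res), max(res@perChannelFraction))
  expect_error(computeBSR(makeSection(matrix(0, 2, 4),
                                      badMask = rep(TRUE, 4))), "usable")
})

test_that("log kurtosis matches analytic references", {
  set.seed(5)
  x <- rnorm(150000)
  expect_equal(logKurtosis(x), log10(3), tolerance = 0.05)

  two <- rep(c(-2, 2), 50)
  expect_equal(logKurtosis(two), 0)

  expect_true(is.na(logKurtosis(rep(1, 100))))  # flat: flagged, not thrown
  expect_error(logKurtosis(c(1, 2)), "samples")

  lk <- vapply(c(0, 0.3, 0.6, 0.9), function(tg)
    logKurtosis(simSection(tg, seed = 3, fs = 128, durationS = 60)$section),
    numeric(1))
  expect_true(all(diff(lk) > 0))
})

test_that("channel ICC behaves as a one-way random agreement coefficient", {
  mixed <- matrix(rep(c(1L, 0L, 1L, 1L, 0L), each = 6), 6, 5, byrow = FALSE)
  expect_equal(channelICC(mixed), 1.0)

  set.seed(8)
  coins <- matrix(rbinom(5 * 10000, 1, 0.5), 5, 10000)
  expect_lt(abs(channelICC(coins)), 0.05)

  sim <- simSection(0.5, seed = 4, fs = 128, durationS = 60)
  expect_gte(computeBSR(sim$section)@icc, 0.99)

  expect_warning(v <- channelICC(matrix(1L, 3, 10)), "undefined")
  expect_true(is.na(v))
  expect_error(channelICC(matrix(1L, 1, 10)), "at least 2")
})

test_that("threshold sensitivity separates sound from unsound thresholds", {
  # suppression only at GCS 3; low-amplitude (~2-6 uV) continuous EEG at
  # higher GCS, which a 10 uV threshold misclassifies as suppressed
  pSupp <- simParams(sectionDurationS = 30, fs = 128)
  pLow <- simParams(sectionDurationS = 30, fs = 128, burstSd = 4,
                    burstFloor = 1.5)
  secs <- list()
  for (s in 1:4)
    secs[[s]] <- simSection(0.8, seed = s, fs = 128, durationS = 30,
                            params = pSupp, gcs = 3)$section
  for (s in 5:8)
    secs[[s]] <- simSection(0, seed = s, fs = 128, durationS = 30,
                            params = pLow, gcs = 4 + s)$section
  sens <- thresholdSensitivity(secs, thresholds = c(1, 10))
  high1 <- sens@results[["1uV"]]$highSections
  expect_true(all(high1$gcs == 3))
  high10 <- sens@results[["10uV"]]$highSections
  expect_true(any(high10$gcs > 3))

  two <- thresholdSensitivity(secs[1:2], thresholds = 5)
  expect_length(two@results, 1)
  expect_true(is.numeric(two@results[[1]]$r))
})

test_that("per-patient maxima ignore unusable sections and warn on empties", {
  tab <- data.frame(patient_id = c(1, 1, 1, 2), bsr = c(0.1, 0.7, 0.3, 0.5))
  m <- maxBSRPerPatient(tab)
  expect_equal(unname(m["1"]), 0.7)
  expect_equal(unname(m["2"]), 0.5)

  tab$usable <- c(TRUE, FALSE, TRUE, FALSE)
  expect_warning(m2 <- maxBSRPerPatient(tab), "no usable")
  expect_equal(unname(m2["1"]), 0.3)
  expect_false("2" %in% names(m2))
})
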