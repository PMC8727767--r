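## Default 13-channel montage common to all patients in the cohort.
.DEFAULT_CHANNELS <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                       "O1", "O2", "T3", "T4", "Cz")

## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stream child seeds, kept below 2^31 - 1.
.subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483646L) + 1L
}

#' Constructor for synthetic-generator parameters
#'
#' Convenience wrapper around the [SimParams-class] prototype; any slot can be
#' overridden by name.
#'
#' @param ... slot values to override (see [SimParams-class]).
#' @return a validated [SimParams-class].
#' @examples
#' simParams(nPatients = 8, fs = 128)
#' @export
simParams <- function(...) {
  obj <- do.call(new, c(list("SimParams"), list(...)))
  validObject(obj)
  obj
}

## Two-state alternating-renewal state path (1 = suppression), log-normal
## dwell times. The burst/suppression mean dwells are rescaled so their ratio
## yields the target suppression fraction while the mean cycle length is kept.
.simulateStatePath <- function(nSamples, fs, target, burstDwellS, suppDwellS,
                               sdLog) {
  if (target <= 0) return(integer(nSamples))
  if (target >= 1) return(rep(1L, nSamples))
  cycle <- burstDwellS + suppDwellS
  means <- c(burst = cycle * (1 - target), supp = cycle * target)
  state <- integer(0)
  cur <- as.integer(stats::runif(1) < target)
  while (length(state) < nSamples) {
    m <- if (cur == 1L) means["supp"] else means["burst"]
    dur <- stats::rlnorm(1, meanlog = log(m) - sdLog^2 / 2, sdlog = sdLog)
    state <- c(state, rep(cur, max(1L, round(dur * fs))))
    cur <- 1L - cur
  }
  state[seq_len(nSamples)]
}

## Band-limited unit-variance noise (zero-phase low-pass of white noise).
.bandNoise <- function(n, fs) {
  co <- min(30, 0.4 * fs) / (fs / 2)
  z <- signal::filtfilt(signal::butter(2, co, type = "low"), stats::rnorm(n))
  z / stats::sd(z)
}

## Burst-state waveform: band-limited noise with its rectified amplitude kept
## above `floor`, so a labeled burst sample can never masquerade as
## suppression at the 1 uV threshold. Realized sd is close to burstSd.
.burstWave <- function(n, fs, burstSd, floor) {
  z <- .bandNoise(n, fs) * max(burstSd - floor, 1)
  z + sign(z) * floor
}

#' Simulate a multichannel burst-suppression EEG section
#'
#' Generates a 13-channel EEG section from a two-state alternating-renewal
#' process: a common suppression/burst state path with log-normal dwell times,
#' near-isoelectric Gaussian noise during suppression (rectified amplitude
#' almost surely below 1 uV at the default 0.2 uV noise), and high-amplitude
#' band-limited activity during bursts. Each channel follows the common state
#' except at rare jittered samples, mirroring the near-perfect cross-channel
#' agreement seen clinically. The realized per-sample state path is returned
#' as ground truth for recovery tests.
#'
#' @param params a [SimParams-class].
#' @param targetSuppression desired long-run suppression fraction in \[0, 1\].
#' @param seed integer seed (defaults to `params@seed`).
#' @param channelLabels channel names; length defines the channel count.
#' @return list with elements `record` ([EEGRecording-class]) and `truth`
#'   ([BSGroundTruth-class]).
#' @examples
#' sim <- simulateBSEEG(simParams(sectionDurationS = 10, fs = 128), 0.5, seed = 1)
#' sim$truth@suppressionFraction
#' @export
simulateBSEEG <- function(params = simParams(), targetSuppression,
                          seed = params@seed,
                          channelLabels = .DEFAULT_CHANNELS) {
  stopifnot(is(params, "SimParams"))
  if (!is.numeric(targetSuppression) || length(targetSuppression) != 1L ||
      is.na(targetSuppression) || targetSuppression < 0 || targetSuppression > 1)
    stop("targetSuppression must be a proportion in [0, 1]")
  n <- round(params@sectionDurationS * params@fs)
  nCh <- length(channelLabels)
  .withSeed(seed, {
    state <- .simulateStatePath(n, params@fs, targetSuppression,
                                params@burstDwellS, params@suppDwellS,
                                params@dwellSdLog)
    sig <- matrix(0, nCh, n)
    for (c in seq_len(nCh)) {
      chState <- state
      jit <- stats::runif(n) < params@jitterProb
      chState[jit] <- 1L - chState[jit]
      x <- .burstWave(n, params@fs, params@burstSd, params@burstFloor)
      supp <- chState == 1L
      x[supp] <- stats::rnorm(sum(supp), sd = params@suppNoiseSd)
      sig[c, ] <- x
    }
    rec <- new("EEGRecording", signal = sig, fs = params@fs,
               channelLabels = channelLabels, startTime = 0,
               badMask = rep(FALSE, n))
    truth <- new("BSGroundTruth", statePath = state,
                 suppressionFraction = mean(state))
    list(record = rec, truth = truth)
  })
}

#' Simulate a GCS assessment series with sedation-linked minima
#'
#' Draws at least two assessments per day at uniform times. Scores inside the
#' supplied sedation windows are drawn from 3..6 (deep sedation), scores
#' outside from 7..15, so that the global GCS minimum falls inside a sedation
#' window whenever one exists.
#'
#' @param durationH total duration in hours.
#' @param sedationWindows list of `c(start_h, end_h)` windows; must lie within
#'   the record and not overlap.
#' @param seed integer seed.
#' @param assessmentsPerDay expected number of assessments per day (>= 2).
#' @return a [GCSSeries-class].
#' @export
simulateGCSSeries <- function(durationH, sedationWindows = list(), seed = 1,
                              assessmentsPerDay = 3) {
  stopifnot(durationH > 0, assessmentsPerDay >= 2)
  if (length(sedationWindows)) {
    w <- do.call(rbind, lapply(sedationWindows, function(x) x[1:2]))
    if (any(!is.finite(w)) || any(w[, 1] >= w[, 2]) ||
        any(w[, 1] < 0) || any(w[, 2] > durationH))
      stop("malformed sedation window(s): need 0 <= start < end <= duration")
    o <- order(w[, 1])
    if (any(w[o, 1][-1] < w[o, 2][-nrow(w)]))
      stop("malformed sedation window(s): windows overlap")
  }
  .withSeed(seed, {
    nDays <- ceiling(durationH / 24)
    ts <- unlist(lapply(seq_len(nDays) - 1L, function(d) {
      hi <- min(24, durationH - 24 * d)
      k <- max(2L, stats::rpois(1, assessmentsPerDay))
      24 * d + sort(stats::runif(k, 0, hi))
    }))
    ts <- sort(unique(ts))
    sedated <- vapply(ts, function(t)
      any(vapply(sedationWindows,
                 function(w) t >= w[1] && t <= w[2], logical(1))),
      logical(1))
    sc <- integer(length(ts))
    sc[sedated] <- sample(3:6, sum(sedated), replace = TRUE)
    sc[!sedated] <- sample(7:15, sum(!sedated), replace = TRUE)
    new("GCSSeries", timestamps = ts, scores = sc)
  })
}

#' Simulate a full synthetic cohort
#'
#' Builds a cohort with the statistical structure the downstream analysis
#' assumes. Per patient: a maximum GCS is drawn; about 31% of patients are
#' burst-suppressed (target maximum BSR uniform on \[0.4, 1\]), the rest have
#' near-continuous EEG (Beta(0.5, 8) targets); barbiturate exposure rises
#' steeply with BSR; binary chronic and discharge outcomes are drawn from a
#' logistic model on (max BSR, max GCS) with coefficients
#' `params@outcomeCoef`, and mapped onto GOSe halves (chronic: 5-8 vs 1-4,
#' discharge: 3-4 vs 1-2) so that a median split recovers them exactly. With
#' `signals = TRUE` each patient also gets a GCS series with sedation windows,
#' and one simulated EEG section per GCS-guided timepoint whose suppression
#' depends on the concurrent sedation state; ground truth is recorded for
#' recovery tests.
#'
#' @param params a [SimParams-class].
#' @param signals logical; generate EEG sections and GCS series (`TRUE`) or
#'   only the scalar cohort (`FALSE`, e.g. for large parameter-recovery runs).
#' @param channelLabels channel names for generated EEG.
#' @return list with elements `cohort` ([CohortTable-class]), `truth`
#'   (per-patient data.frame of generating values), and, when
#'   `signals = TRUE`, `gcs` (list of [GCSSeries-class]) and `sections` (list
#'   of per-patient lists of `list(section, truth)`), plus `seed`.
#' @export
simulateCohort <- function(params = simParams(), signals = TRUE,
                           channelLabels = .DEFAULT_CHANNELS) {
  stopifnot(is(params, "SimParams"))
  nP <- params@nPatients
  co <- params@outcomeCoef
  recs <- vector("list", nP)
  truth <- vector("list", nP)
  gcsList <- if (signals) vector("list", nP) else NULL
  secList <- if (signals) vector("list", nP) else NULL

  for (i in seq_len(nP)) {
    si <- .subSeed(params@seed, i)
    p <- .withSeed(si, {
      maxGCS <- sample(3:15, 1)
      bsPatient <- stats::runif(1) < 0.31
      targetMax <- if (bsPatient) stats::runif(1, 0.4, 1) else
        stats::rbeta(1, 0.5, 8)
      eta <- co[[1]] + co[[2]] * targetMax + co[[3]] * maxGCS
      outcomeChronic <- stats::rbinom(1, 1, stats::plogis(eta))
      outcomeDischarge <- stats::rbinom(1, 1, stats::plogis(eta))
      nSec <- sample(3:7, 1)
      list(maxGCS = maxGCS, targetMax = targetMax,
           outcomeChronic = outcomeChronic, outcomeDischarge = outcomeDischarge,
           nSec = nSec, eta = eta,
           goseChronic = if (outcomeChronic) sample(5:8, 1) else sample(1:4, 1),
           goseDischarge = if (outcomeDischarge) sample(3:4, 1) else sample(1:2, 1),
           daysDischarge = max(2, round(stats::rnorm(1, 22, 10))),
           daysChronic = round(stats::rnorm(1, 193, 34)),
           sex = if (stats::runif(1) < 0.16) "F" else "M",
           ageBin = sample(.AGE_BINS, 1, prob = c(0.2, 0.3, 0.2, 0.2, 0.1)),
           barb = stats::runif(1) < stats::plogis(-2.5 + 16 * targetMax),
           prop = stats::runif(1) < 0.5)
    })

    realizedMax <- p$targetMax
    if (signals) {
      durH <- 24 * (p$nSec + 1)
      wins <- lapply(seq_len(p$nSec), function(d) c(24 * (d - 1) + 6,
                                                    24 * (d - 1) + 18))
      gcs <- simulateGCSSeries(durH, wins, seed = .subSeed(si, 1))
      times <- selectSectionTimes(gcs, minSpacingH = 24)
      gcsAt <- gcs@scores[match(times, gcs@timestamps)]
      secTargets <- .withSeed(.subSeed(si, 2), {
        tg <- ifelse(gcsAt <= 6,
                     stats::runif(length(times), 0.3, 1) * p$targetMax,
                     stats::runif(length(times), 0, 0.02))
        if (any(gcsAt <= 6)) tg[which(gcsAt <= 6)[1]] <- p$targetMax
        tg
      })
      secs <- vector("list", length(times))
      fr <- numeric(length(times))
      for (j in seq_along(times)) {
        sim <- simulateBSEEG(params, secTargets[j], seed = .subSeed(si, 10 + j),
                             channelLabels = channelLabels)
        sec <- new("EEGSection", signal = sim$record@signal, fs = params@fs,
                   channelLabels = channelLabels, startTime = times[j],
                   badMask = sim$record@badMask, t0 = times[j],
                   durationS = params@sectionDurationS,
                   gcsAtExtraction = as.numeric(gcsAt[j]), usable = TRUE)
        secs[[j]] <- list(section = sec, truth = sim$truth)
        fr[j] <- sim$truth@suppressionFraction
      }
      realizedMax <- if (length(fr)) max(fr) else 0
      gcsList[[i]] <- gcs
      secList[[i]] <- secs
    }

    recs[[i]] <- data.frame(
      patient_id = i, age_bin = p$ageBin, sex = p$sex,
      max_bsr = realizedMax, max_gcs = p$maxGCS,
      gose_discharge = p$goseDischarge, days_discharge = p$daysDischarge,
      gose_chronic = p$goseChronic, days_chronic = p$daysChronic,
      barbiturates = p$barb, propofol = p$prop,
      usable_sections = p$nSec, total_sections = p$nSec,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      patient_id = i, target_max_bsr = p$targetMax,
      realized_max_bsr = realizedMax, max_gcs = p$maxGCS,
      linear_predictor = p$eta, p_outcome = stats::plogis(p$eta),
      outcome_chronic = p$outcomeChronic,
      outcome_discharge = p$outcomeDischarge)
  }

  r <- do.call(rbind, recs)
  r$age_bin <- factor(r$age_bin, levels = .AGE_BINS, ordered = TRUE)
  r$age_mid <- .AGE_MIDS[as.integer(r$age_bin)]
  r$gose_chronic <- as.integer(r$gose_chronic)
  r$gose_discharge <- as.integer(r$gose_discharge)
  r$max_gcs <- as.integer(r$max_gcs)
  r$patient_id <- as.integer(r$patient_id)
  r$usable_sections <- as.integer(r$usable_sections)
  r$total_sections <- as.integer(r$total_sections)
  r <- r[, c("patient_id", "age_bin", "age_mid", "sex", "max_bsr", "max_gcs",
             "gose_discharge", "days_discharge", "gose_chronic", "days_chronic",
             "barbiturates", "propofol", "usable_sections", "total_sections")]
  cohort <- new("CohortTable", records = r, provenance = "synthetic")
  out <- list(cohort = cohort, truth = do.call(rbind, truth),
              seed = params@seed)
  if (signals) {
    out$gcs <- gcsList
    out$sections <- secList
  }
  out
}

#' Simulate treatment / mediator / outcome data for mediation calibration
#'
#' Generates the linear-logistic structure the mediation machinery assumes: a
#' binary (or uniform continuous) treatment, a Gaussian mediator
#' `a0 + aT * treat + aG * gcs + N(0, sigmaM)`, and a Bernoulli outcome with
#' `logit p = c0 + cT * treat + cM * mediator + cG * gcs`. Setting `aT = 0`
#' yields a no-mediation null; setting `cT = 0` with strong `aT`, `cM` yields
#' pure mediation.
#'
#' @param n sample size.
#' @param coefM mediator-model coefficients `c(a0, aT, aG)`.
#' @param coefY outcome-model coefficients `c(c0, cT, cM, cG)`.
#' @param sigmaM mediator residual standard deviation.
#' @param binaryTreatment draw treatment as Bernoulli(0.5) (else Uniform(0,1)).
#' @param seed integer seed.
#' @return data.frame with columns `treat`, `gcs`, `mediator`, `outcome`.
#' @export
simulateMediationData <- function(n, coefM = c(0, 0.5, 0),
                                  coefY = c(0, 0, 1, 0), sigmaM = 1,
                                  binaryTreatment = TRUE, seed = 1) {
  .withSeed(seed, {
    treat <- if (binaryTreatment) stats::rbinom(n, 1, 0.5) else stats::runif(n)
    gcs <- sample(3:15, n, replace = TRUE)
    mediator <- coefM[1] + coefM[2] * treat + coefM[3] * gcs +
      stats::rnorm(n, sd = sigmaM)
    eta <- coefY[1] + coefY[2] * treat + coefY[3] * mediator + coefY[4] * gcs
    data.frame(treat = treat, gcs = gcs, mediator = mediator,
               outcome = stats::rbinom(n, 1, stats::plogis(eta)))
  })
}
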