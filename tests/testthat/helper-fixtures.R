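# shared helpers: small builders and independent oracles

makeSection <- function(signal, fs = 100, badMask = rep(FALSE, ncol(signal)),
                        gcs = NA_real_, t0 = 0) {
  new("EEGSection", signal = signal, fs = fs,
      channelLabels = paste0("ch", seq_len(nrow(signal))),
      startTime = t0, badMask = badMask, t0 = t0,
      durationS = ncol(signal) / fs, gcsAtExtraction = gcs, usable = TRUE)
}

simSection <- function(target, seed, fs = 256, durationS = 600, params = NULL,
                       gcs = NA_real_) {
  p <- if (is.null(params)) simParams(fs = fs, sectionDurationS = durationS)
       else params
  sim <- simulateBSEEG(p, target, seed = seed)
  list(section = makeSection(sim$record@signal, fs = p@fs, gcs = gcs),
       truth = sim$truth)
}

makeGCS <- function(hours, scores) {
  new("GCSSeries", timestamps = hours, scores = as.integer(scores))
}

# brute-force oracle for the greedy GCS-minimum selection: enumerate every
# spacing-feasible subset and take the lexicographically greatest one in the
# (score, timestamp) priority order
bruteForceSelect <- function(hours, scores, spacing = 24) {
  n <- length(hours)
  prio <- order(scores, hours)
  bestKey <- NULL
  bestIdx <- NULL
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) next
    tt <- hours[idx]
    if (length(tt) > 1L && min(dist(tt)) < spacing) next
    key <- as.integer(prio %in% idx)
    if (is.null(bestKey)) { bestKey <- key; bestIdx <- idx; next }
    d <- which(key != bestKey)
    if (length(d) && key[d[1]] == 1L) { bestKey <- key; bestIdx <- idx }
  }
  sort(hours[bestIdx])
}

# per-sample loop oracle for the consensus BSR
loopBSR <- function(signal, badMask, threshold) {
  k <- nrow(signal)
  cons <- integer(0)
  for (i in seq_len(ncol(signal))) {
    if (badMask[i]) next
    cnt <- 0L
    for (c in seq_len(k)) if (abs(signal[c, i]) < threshold) cnt <- cnt + 1L
    cons <- c(cons, as.integer(cnt >= k / 2))
  }
  mean(cons)
}

# dense grid-search oracle for 1-predictor logistic maximum likelihood
gridLogistic <- function(x, y, b0range, b1range, step = 0.05) {
  b0s <- seq(b0range[1], b0range[2], by = step)
  b1s <- seq(b1range[1], b1range[2], by = step)
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  best <- c(NA, NA, -Inf)
  for (b0 in b0s) for (b1 in b1s) {
    v <- ll(b0, b1)
    if (v > best[3]) best <- c(b0, b1, v)
  }
  list(beta = best[1:2], logLik = best[3], step = step)
}
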