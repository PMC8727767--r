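#' Median-split dichotomization of GOSe outcomes
#'
#' Discharge GOSe scores split 1-2 vs 3-4 (coded 1 when GOSe >= 3); chronic
#' scores split 1-4 vs 5-8 (coded 1 when GOSe >= 5). Missing scores stay
#' missing. When every non-missing score falls in one class, the result
#' carries attribute `degenerate = TRUE`.
#'
#' @param gose integer GOSe scores in 1..8 (NA allowed).
#' @param timepoint `"discharge"` or `"chronic"`.
#' @return integer 0/1 vector, same length as `gose`.
#' @export
medianSplit <- function(gose, timepoint = c("discharge", "chronic")) {
  timepoint <- match.arg(timepoint)
  if (any(gose < 1 | gose > 8, na.rm = TRUE))
    stop("GOSe scores must lie in [1, 8]")
  cut <- if (timepoint == "discharge") 3L else 5L
  y <- as.integer(gose >= cut)
  if (length(unique(y[!is.na(y)])) < 2L) attr(y, "degenerate") <- TRUE
  y
}

#' Maximum-likelihood logistic regression
#'
#' Fits a binomial GLM (logit link) by iteratively reweighted least squares,
#' with tight convergence (deviance change < 1e-10, up to 100 iterations),
#' returning the maximized log-likelihood and the inverse-information
#' coefficient covariance. Boundary cases (single-class outcome) and apparent
#' separation are flagged on the returned object rather than thrown.
#'
#' @param x numeric observations x terms matrix (no intercept column; an
#'   intercept is always included), or NULL for the intercept-only model.
#' @param y binary 0/1 outcomes.
#' @return a [ModelFit-class].
#' @examples
#' d <- cohortData(loadCohort())
#' y <- medianSplit(d$gose_discharge, "discharge")
#' fitLogistic(cbind(maxBSR = d$max_bsr, maxGCS = d$max_gcs), y)
#' @export
fitLogistic <- function(x, y) {
  y <- as.numeric(y)
  if (anyNA(y) || (!is.null(x) && anyNA(x)))
    stop("missing values are not allowed; subset to complete cases first")
  n <- length(y)
  terms <- if (is.null(x) || NCOL(x) == 0L) character(0) else colnames(x)
  if (!is.null(x) && NCOL(x) > 0L && is.null(terms))
    stop("x must have column names")
  X <- cbind(`(Intercept)` = rep(1, n),
             if (length(terms)) as.matrix(x) else NULL)
  k <- ncol(X)
  if (n <= k) stop("need more observations than parameters")
  degenerate <- length(unique(y)) < 2L
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  ll <- -fit$deviance / 2  # Bernoulli saturated log-likelihood is 0
  ## unpivoted inverse information
  R <- qr.R(fit$qr)
  V <- tryCatch(chol2inv(R), error = function(e) matrix(NA_real_, k, k))
  piv <- fit$qr$pivot
  vcov <- matrix(NA_real_, k, k, dimnames = list(names(beta), names(beta)))
  vcov[piv, piv] <- V
  mu <- fit$fitted.values
  separated <- !degenerate && all(mu < 1e-8 | mu > 1 - 1e-8)
  if (separated)
    warning("apparent complete separation; coefficients diverge")
  if (!fit$converged && !degenerate)
    warning("IRLS did not converge in 100 iterations")
  new("ModelFit", terms = as.character(terms), beta = beta, vcov = vcov,
      logLik = ll, k = as.integer(k), n = as.integer(n),
      aicc = aicc(ll, k, n), converged = fit$converged,
      degenerate = degenerate || separated)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`; requires `n > k + 1` (except
#' the trivial k = 0 case, where the correction vanishes).
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (k > 0 && n <= k + 1) stop("AICc requires n > k + 1")
  corr <- if (k > 0) 2 * k * (k + 1) / (n - k - 1) else 0
  -2 * logLik + 2 * k + corr
}

#' Akaike weights over a selection window
#'
#' `w_i = exp(-delta_i / 2)` renormalized over the models with
#' `delta <= windowDelta`; models outside the window receive weight 0.
#'
#' @param delta AICc differences to the leading model.
#' @param windowDelta selection window width (default 5).
#' @return numeric weights, summing to 1 over the window.
#' @examples
#' round(akaikeWeights(c(0, 0.567, 2.826, 3.047)), 3)
#' @export
akaikeWeights <- function(delta, windowDelta = 5) {
  inw <- delta <= windowDelta
  w <- numeric(length(delta))
  w[inw] <- exp(-delta[inw] / 2)
  w / sum(w)
}

## Candidate predictor matrix for a cohort (sex indicator: M = 0, F = 1;
## age as bin midpoint). Log-likelihoods, AICc, weights and non-sex
## coefficients are invariant to the sex dummy coding.
.designMatrix <- function(records) {
  cbind(maxBSR = records$max_bsr, maxGCS = records$max_gcs,
        sex = as.numeric(records$sex == "F"), age = records$age_mid)
}

#' Exhaustive logistic model enumeration with AICc ranking
#'
#' Fits all 2^4 = 16 logistic models over subsets of {maxBSR, maxGCS, sex,
#' age} (each with an intercept) predicting the median-split outcome at the
#' given timepoint, using complete cases (all 32 patients at discharge; the
#' patients with missing chronic GOSe are dropped for the chronic outcome).
#' Models are ranked by AICc; Akaike weights are renormalized over the
#' `delta <= windowDelta` selection window.
#'
#' @param cohort a [CohortTable-class] with >= 10 complete cases.
#' @param timepoint `"discharge"` or `"chronic"`.
#' @param windowDelta AICc selection window (default 5).
#' @return a [ModelSet-class], fits ordered by AICc.
#' @examples
#' ms <- enumerateModels(loadCohort(), "discharge")
#' head(modelTable(ms))
#' @export
enumerateModels <- function(cohort, timepoint = c("discharge", "chronic"),
                            windowDelta = 5) {
  stopifnot(is(cohort, "CohortTable"))
  timepoint <- match.arg(timepoint)
  r <- cohortData(cohort)
  gose <- if (timepoint == "discharge") r$gose_discharge else r$gose_chronic
  keep <- !is.na(gose)
  r <- r[keep, ]
  if (nrow(r) < 10L) stop("need at least 10 complete cases")
  y <- medianSplit(gose[keep], timepoint)
  X <- .designMatrix(r)
  termNames <- colnames(X)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(termNames)))
  fits <- lapply(seq_len(nrow(subsets)), function(i) {
    sel <- unlist(subsets[i, ])
    tryCatch(
      fitLogistic(if (any(sel)) X[, sel, drop = FALSE] else NULL, y),
      error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), "error")
  if (any(failed))
    warning(sum(failed), " model(s) failed to fit and were dropped: ",
            paste(vapply(fits[failed], conditionMessage, character(1)),
                  collapse = "; "))
  fits <- fits[!failed]
  aiccs <- vapply(fits, function(f) f@aicc, numeric(1))
  ord <- order(aiccs)
  fits <- fits[ord]
  delta <- aiccs[ord] - min(aiccs)
  new("ModelSet", fits = fits, delta = delta,
      weight = akaikeWeights(delta, windowDelta),
      windowDelta = windowDelta, timepoint = timepoint,
      n = fits[[1]]@n)
}

#' @rdname accessors
#' @aliases modelTable,ModelSet-method
setMethod("modelTable", "ModelSet", function(x) {
  terms <- c("(Intercept)", "maxBSR", "maxGCS", "sex", "age")
  rows <- lapply(seq_along(x@fits), function(i) {
    f <- x@fits[[i]]
    b <- stats::setNames(rep(NA_real_, length(terms)), terms)
    b[names(f@beta)] <- f@beta
    data.frame(t(b), df = f@k, logLik = f@logLik, AICc = f@aicc,
               delta = x@delta[i], weight = x@weight[i],
               check.names = FALSE)
  })
  do.call(rbind, rows)
})

#' Renormalized weighted mean of window coefficients
#'
#' The conditional (subset) model-averaged estimate: the Akaike weights of
#' the models containing a term are renormalized to sum to 1 and the
#' coefficient is averaged under them.
#'
#' @param beta coefficients of the term in the window models containing it.
#' @param weight the corresponding (unnormalized or window) Akaike weights.
#' @return the averaged coefficient.
#' @examples
#' conditionalAverage(c(8.083, 7.917, 8.444, 8.340),
#'                    c(0.422, 0.284, 0.146, 0.146))
#' @export
conditionalAverage <- function(beta, weight) {
  stopifnot(length(beta) == length(weight), length(beta) > 0)
  sum(beta * weight) / sum(weight)
}

#' Conditional model-averaged parameters
#'
#' Averages each parameter over the selection-window models that contain it
#' (conditional / subset averaging, weights renormalized within the subset).
#' The standard error is the revised unconditional estimator
#' `SE = sum_i w_i * sqrt(var_i + (beta_i - beta_avg)^2)`; the adjusted
#' standard error additionally inflates each model's variance by the
#' t-versus-normal quantile ratio at that model's residual degrees of freedom
#' (`SE_i * qt(0.975, n - k_i) / qnorm(0.975)`) before pooling, compensating
#' for small-sample normal approximation. z = |beta| / adjSE with a
#' two-sided normal p-value.
#'
#' @param set a [ModelSet-class] with a non-empty selection window.
#' @return data.frame with columns `term`, `beta`, `odds_ratio`, `se`,
#'   `adj_se`, `z`, `p`, and attribute `"n_models"` (window size).
#' @export
averageParameters <- function(set) {
  stopifnot(is(set, "ModelSet"))
  inw <- which(set@delta <= set@windowDelta)
  if (!length(inw)) stop("empty selection window")
  fits <- set@fits[inw]
  w <- set@weight[inw]
  terms <- unique(unlist(lapply(fits, function(f) names(f@beta))))
  zq <- stats::qnorm(0.975)
  rows <- lapply(terms, function(tm) {
    has <- vapply(fits, function(f) tm %in% names(f@beta), logical(1))
    wi <- w[has] / sum(w[has])
    bi <- vapply(fits[has], function(f) f@beta[[tm]], numeric(1))
    vi <- vapply(fits[has], function(f) f@vcov[tm, tm], numeric(1))
    dfi <- vapply(fits[has], function(f) f@n - f@k, numeric(1))
    bavg <- sum(wi * bi)
    se <- sum(wi * sqrt(vi + (bi - bavg)^2))
    viAdj <- vi * (stats::qt(0.975, dfi) / zq)^2
    adjSe <- sum(wi * sqrt(viAdj + (bi - bavg)^2))
    z <- abs(bavg) / adjSe
    data.frame(term = tm, beta = bavg, odds_ratio = exp(bavg), se = se,
               adj_se = adjSe, z = z, p = 2 * stats::pnorm(-z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_models") <- length(fits)
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors; incomplete pairs are dropped (>= 3 required).
#' @return list with `r`, `p` (two-sided, t transform on n - 2 df) and `n`.
#' @export
pearsonR <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom; used to compare the
#' proportion of outcomes above the median split between retained and
#' excluded patients.
#'
#' @param tab 2x2 matrix of nonnegative counts with no zero margin.
#' @return list with `chi2`, `p`, `df = 1`.
#' @export
chiSquared2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin; chi-squared undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, df = 1L)
}
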