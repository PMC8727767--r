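## Extract a named analysis variable from a cohort data.frame.
.medVar <- function(r, name) {
  switch(name,
    barbiturates = as.numeric(r$barbiturates),
    propofol = as.numeric(r$propofol),
    maxBSR = r$max_bsr,
    maxGCS = r$max_gcs,
    discharge = medianSplit(r$gose_discharge, "discharge"),
    chronic = medianSplit(r$gose_chronic, "chronic"),
    stop("unknown variable: ", name))
}

## Quasi-Bayesian potential-outcome simulation shared by both mediator types.
## Returns the J-vector of draws for each effect. Coefficient orders follow
## the fitted formulas: mediator model (intercept, treat, covariates);
## outcome model (intercept, treat, mediator, covariates[, treat:mediator]).
.mediationDraws <- function(mm, om, dat, nSims, binaryMediator, interaction,
                            fixTheta = FALSE) {
  if (fixTheta) {
    ## plug-in coefficients (bootstrap inner step): only mediator error varies
    thM <- matrix(stats::coef(mm), nSims, length(stats::coef(mm)), byrow = TRUE)
    thY <- matrix(stats::coef(om), nSims, length(stats::coef(om)), byrow = TRUE)
  } else {
    thM <- MASS::mvrnorm(nSims, stats::coef(mm), stats::vcov(mm))
    thY <- MASS::mvrnorm(nSims, stats::coef(om), stats::vcov(om))
    if (nSims == 1L) {
      thM <- matrix(thM, 1)
      thY <- matrix(thY, 1)
    }
  }
  n <- nrow(dat)
  covs <- setdiff(names(dat), c("treat", "mediator", "outcome"))
  Z <- as.matrix(dat[, covs, drop = FALSE])
  zM <- if (length(covs))
    Z %*% t(thM[, 2L + seq_along(covs), drop = FALSE]) else 0
  etaM <- function(t)
    matrix(thM[, 1] + thM[, 2] * t, n, nSims, byrow = TRUE) + zM
  sigma <- if (!binaryMediator) sqrt(sum(stats::residuals(mm)^2) /
                                       stats::df.residual(mm)) else NULL
  drawM <- function(t) {
    eta <- etaM(t)
    if (binaryMediator)
      matrix(stats::rbinom(length(eta), 1, stats::plogis(eta)), n)
    else eta + matrix(stats::rnorm(length(eta), sd = sigma), n)
  }
  M0 <- drawM(0); M1 <- drawM(1)
  zY <- if (length(covs))
    Z %*% t(thY[, 3L + seq_along(covs), drop = FALSE]) else 0
  bInt <- if (interaction) thY[, ncol(thY)] else 0
  pY <- function(t, M) {
    eta <- matrix(thY[, 1] + thY[, 2] * t, n, nSims, byrow = TRUE) +
      sweep(M, 2, thY[, 3] + bInt * t, "*") + zY
    stats::plogis(eta)
  }
  cm <- function(x) colMeans(x)
  list(acme0 = cm(pY(0, M1) - pY(0, M0)),
       acme1 = cm(pY(1, M1) - pY(1, M0)),
       ade0  = cm(pY(1, M0) - pY(0, M0)),
       ade1  = cm(pY(1, M1) - pY(0, M1)),
       total = cm(pY(1, M1) - pY(0, M0)))
}

#' Nonparametric quasi-Bayesian causal mediation analysis
#'
#' Tests whether a mediator transmits the effect of a treatment on a
#' dichotomized outcome, controlling for the maximum GCS. Two regressions are
#' fitted -- a mediator model on treatment + covariates (linear for a
#' continuous mediator such as maximum BSR, logistic for a binary medication
#' flag) and a logistic outcome model on treatment + mediator + covariates.
#' `nSims` parameter vectors are then drawn from each model's asymptotic
#' normal; per draw, potential mediator values are simulated under treatment
#' 0 and 1 and potential outcome probabilities under the four
#' treatment-by-mediator combinations. Average causal mediation effects
#' (ACME), average direct effects (ADE) and the total effect are reported on
#' the probability (risk-difference) scale with percentile intervals and
#' simulation p-values. A nonparametric bootstrap variant is available via
#' `method = "bootstrap"`.
#'
#' @param data a [CohortTable-class] (variables are looked up by role), or a
#'   data.frame with columns `treat`, `mediator`, `outcome` and covariates.
#' @param treatment,mediator for cohort input: one of `"barbiturates"`,
#'   `"propofol"`, `"maxBSR"` (treatment and mediator must differ).
#' @param outcome for cohort input: `"discharge"` or `"chronic"` (complete
#'   cases; patients missing the chronic GOSe are dropped).
#' @param covariates covariate names (cohort input; default `"maxGCS"`).
#' @param nSims number of Monte-Carlo draws (>= 100; 1000 by default).
#' @param seed integer seed.
#' @param interaction include a treatment-by-mediator interaction in the
#'   outcome model (off by default: additive models).
#' @param method `"quasibayes"` (default) or `"bootstrap"`.
#' @param conf confidence level of the percentile intervals.
#' @return a [MediationResult-class].
#' @examples
#' res <- runMediation(loadCohort(), "barbiturates", "maxBSR", "discharge",
#'                     nSims = 200, seed = 1)
#' effectEstimates(res)["acme"]
#' @export
runMediation <- function(data, treatment = "barbiturates", mediator = "maxBSR",
                         outcome = "discharge", covariates = "maxGCS",
                         nSims = 1000, seed = 1, interaction = FALSE,
                         method = c("quasibayes", "bootstrap"), conf = 0.95) {
  method <- match.arg(method)
  if (nSims < 100) stop("nSims must be at least 100")
  if (identical(treatment, mediator)) stop("treatment and mediator must differ")

  if (is(data, "CohortTable")) {
    r <- cohortData(data)
    dat <- data.frame(treat = .medVar(r, treatment),
                      mediator = .medVar(r, mediator),
                      outcome = .medVar(r, outcome))
    for (cv in covariates) dat[[cv]] <- .medVar(r, cv)
  } else {
    dat <- as.data.frame(data)
    stopifnot(all(c("treat", "mediator", "outcome") %in% names(dat)))
  }
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 10L) stop("insufficient complete cases for mediation")
  binaryMediator <- all(dat$mediator %in% c(0, 1))

  fitModels <- function(d) {
    covs <- setdiff(names(d), c("treat", "mediator", "outcome"))
    fM <- stats::reformulate(c("treat", covs), response = "mediator")
    fY <- stats::reformulate(c("treat", "mediator",
                               if (interaction) "treat:mediator", covs),
                             response = "outcome")
    mm <- if (binaryMediator)
      stats::glm(fM, data = d, family = stats::binomial())
    else stats::lm(fM, data = d)
    om <- stats::glm(fY, data = d, family = stats::binomial())
    list(mm = mm, om = om)
  }
  mods <- fitModels(dat)
  sep <- any(vapply(list(mods$om, if (binaryMediator) mods$mm), function(m) {
    if (is.null(m)) return(FALSE)
    mu <- stats::fitted(m)
    all(mu < 1e-8 | mu > 1 - 1e-8)
  }, logical(1)))
  if (sep) warning("apparent separation in a component model; ",
                   "interpret intervals with caution")

  draws <- .withSeed(seed, {
    if (method == "quasibayes") {
      .mediationDraws(mods$mm, mods$om, dat, nSims, binaryMediator, interaction)
    } else {
      eff <- replicate(nSims, {
        b <- dat[sample.int(nrow(dat), replace = TRUE), ]
        mb <- tryCatch(fitModels(b), error = function(e) NULL)
        if (is.null(mb)) return(rep(NA_real_, 5))
        d1 <- .mediationDraws(mb$mm, mb$om, b, 50, binaryMediator, interaction,
                              fixTheta = TRUE)
        vapply(d1, mean, numeric(1))
      })
      eff <- eff[, stats::complete.cases(t(eff)), drop = FALSE]
      list(acme0 = eff[1, ], acme1 = eff[2, ], ade0 = eff[3, ],
           ade1 = eff[4, ], total = eff[5, ])
    }
  })
  draws$acme <- (draws$acme0 + draws$acme1) / 2
  draws$ade <- (draws$ade0 + draws$ade1) / 2
  ord <- c("acme0", "acme1", "ade0", "ade1", "acme", "ade", "total")
  est <- vapply(draws[ord], mean, numeric(1))
  a <- (1 - conf) / 2
  ci <- t(vapply(draws[ord], stats::quantile, numeric(2), probs = c(a, 1 - a)))
  colnames(ci) <- c("lower", "upper")
  pv <- vapply(draws[ord], function(d)
    min(1, 2 * min(mean(d <= 0), mean(d >= 0))), numeric(1))
  new("MediationResult", estimates = est, ci = ci, pvalues = pv,
      nSims = nSims, seed = seed,
      spec = list(treatment = if (is(data, "CohortTable")) treatment else "treat",
                  mediator = if (is(data, "CohortTable")) mediator else "mediator",
                  outcome = if (is(data, "CohortTable")) outcome else "outcome",
                  covariates = covariates, method = method,
                  interaction = interaction, n = nrow(dat),
                  binary_mediator = binaryMediator, separation = sep))
}
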