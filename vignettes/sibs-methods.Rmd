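---
title: "Quantifying sedation-induced burst suppression and its prognostic value"
author: "sibsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sedation-induced burst suppression and its prognostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibsr)
```

## The problem

In the neuro-ICU, deep sedation with barbiturates or propofol is used to
lower cerebral metabolic demand and intracranial pressure after severe
traumatic brain injury. Deep sedation produces *burst suppression*: an EEG
that alternates between high-amplitude bursts and near-isoelectric
(suppressed) epochs. Whether sedation-induced burst suppression (SIBS)
carries prognostic information is the question this package operationalizes:
it quantifies the depth of burst suppression per patient from multichannel
ICU EEG and relates it to global outcome (Glasgow Outcome Scale extended,
GOSe) at hospital discharge and at a chronic (~6 month) follow-up.

The package ships a 32-patient clinical cohort table (`loadCohort()`) with
each patient's maximum burst suppression ratio, maximum Glasgow Coma Scale
(GCS) score, outcomes, medication indicators and EEG bookkeeping, and a
synthetic EEG/cohort generator so that every pipeline stage can be exercised
and validated without access to raw patient recordings.

## The measurement pipeline

**Section selection.** Burst suppression occurs during minimal behavioral
responsiveness, so EEG excerpts are anchored to GCS minima. The greedy rule
in `selectSectionTimes()` sorts a patient's assessments by ascending score
(ties broken toward earlier timestamps), seeds the selection with the lowest
score, then walks the sorted list adding every timestamp at least 24 h from
all already-selected ones. The tie rule is a package choice — the procedure
is otherwise fully specified — and earliest-first is deterministic and
favors earlier sedation epochs. The selection provably equals the
lexicographically-best spacing-feasible subset in the (score, time) priority
order; the test suite verifies this against exhaustive enumeration on all
short series. Sections of 600 s start *at* the selected timestamp
(configurable via `align` in `extractSections()`); whether the original
analysis started, centered or preceded the assessment is not documented.

**Preprocessing.** `rereferenceAverage()` subtracts the instantaneous
cross-channel mean; `bandpassFilter()` applies a 4th-order Butterworth
design per band edge (high-pass 0.5 Hz, low-pass 45 Hz) forward and
backward. Zero-phase application avoids displacing suppression boundaries in
time; the band attenuates drift, muscle artifact and line noise (a 60 Hz
sinusoid retains under 10% of its amplitude, a 10 Hz one at least 95%).
Artifact review and independent-component cleaning are *not* reimplemented:
they enter only through the per-sample `badMask` a user supplies, and masked
samples are dropped before any proportion is formed.

**Burst suppression ratio.** `computeBSR()` rectifies the signal, marks a
sample suppressed when its amplitude is strictly below 1 uV (a boundary
sample equal to the threshold is *not* suppressed), takes the modal value
across the 13 channels per sample (ties on even channel counts resolve to
suppression), and reports the fraction of suppressed consensus samples. BSR
is kept continuous throughout; no categorical burst-suppression label is
ever produced. Two diagnostics accompany it: the base-10 log of the Pearson
(non-excess) kurtosis of the pooled voltages — chosen over excess kurtosis
so the Gaussian reference is 3 and the logarithm is well defined — and the
one-way random-effects single-measure intraclass correlation ICC(1,1) of the
binary indicators across channels, the least-assumption ICC variant (the
variant is recorded in the result metadata). Kurtosis is pooled across
channels; a per-channel option exists. `thresholdSensitivity()` recomputes
BSR at candidate thresholds (1, 5, 10 uV) and reports, per threshold, the
BSR-vs-log10-kurtosis correlation and which high-BSR sections coincide with
which GCS scores — the two criteria by which 1 uV is the defensible working
threshold.

## The inference machinery

**Outcome coding.** GOSe scores are dichotomized at the sample median:
discharge 1–2 vs 3–4 (positive = GOSe >= 3) and chronic 1–4 vs 5–8
(positive = GOSe >= 5). Patients missing the chronic score are dropped from
chronic analyses (complete-case, n = 30), never imputed.

**Model enumeration and averaging.** `enumerateModels()` fits all 16
logistic regressions over subsets of {max BSR, max GCS, sex, age at injury}
by maximum likelihood (IRLS via the base GLM machinery, deviance tolerance
1e-10) and ranks them by the small-sample corrected Akaike criterion
AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1). Akaike weights are renormalized
over the models within 5 AICc units of the leader; models outside the window
get weight zero. `averageParameters()` performs *conditional* (subset)
averaging: a coefficient is averaged only over window models containing it,
with weights renormalized within that subset. Conditional averaging is the
variant consistent with the published averaged estimates (full-model
averaging with zeros cannot reproduce them). The standard error is the
revised unconditional estimator `sum_i w_i sqrt(var_i + (b_i - b_avg)^2)`;
the *adjusted* standard error first inflates each model's variance by the
t-versus-normal quantile ratio at that model's residual degrees of freedom.
The exact adjustment used by the original software is not documented
anywhere we know of, so this column is the one averaged quantity not
guaranteed to reproduce other implementations digit-for-digit; z-statistics
use the adjusted SE with a two-sided normal p-value and no multiple-testing
correction.

**Sex and age coding.** Sex enters as an indicator with M = 0, F = 1;
log-likelihoods, AICc, weights and all non-sex coefficients are invariant to
this choice. Patient ages are available only as bins (18–25 through 70–85),
so the numeric covariate is the bin midpoint (21.5, 32.5, 47.5, 62.5, 77.5).
This is a declared approximation, not a guess at the unpublished values:
model rows containing age, and therefore the averaged parameters that mix
them in, are reproduced only qualitatively (sign and rough magnitude). One
visible consequence: with midpoint ages the averaged discharge max-BSR
p-value lands near 0.05 rather than comfortably above it; the age-free rows,
which the package checks exactly, are unaffected.

**Mediation.** `runMediation()` implements quasi-Bayesian Monte-Carlo
mediation in the potential-outcomes framework: a mediator model (linear for
the continuous BSR, logistic for a binary medication flag) and a logistic
outcome model, both additive (a treatment-by-mediator interaction is
available but off by default, matching the additive published analysis);
1000 draws from each model's asymptotic normal; per draw, simulated
potential mediators under treatment and control and potential outcome
probabilities under the four combinations; ACME, ADE and total effect as
averaged risk differences with percentile intervals. Quasi-Bayesian
simulation (rather than bootstrap) matches the referenced Monte-Carlo
default; a nonparametric bootstrap is available via `method = "bootstrap"`.
Medications are coded on the day of the patient's maximum BSR; the packaged
table already carries that coding. The published finding is a *null* (no
significant mediation), so validation is calibration-based: on a
no-mediation generator the nominal 95% ACME intervals must cover zero at
nominal rate, and the four medication analyses on the packaged cohort must
yield ACME intervals containing zero.

## What the synthetic generator emulates

`simulateBSEEG()` draws a common two-state alternating-renewal path
(1 = suppression) with log-normal dwell times (default mean 5 s per state,
log-sd 0.5). No dwell-time statistics were published for this cohort;
log-normal right-skewed dwells are the standard burst-suppression
phenomenology choice, and the two dwell means are rescaled jointly so any
requested long-run suppression fraction is hit while the mean cycle length
is preserved. Suppression samples are Gaussian with sd 0.2 uV, so rectified
suppression amplitude is below 1 uV essentially always; burst samples are
band-limited noise (about 20 uV sd) whose rectified amplitude is kept above
a 5 uV floor. The floor is deliberate: with an instantaneous threshold, a
zero-mean Gaussian burst would spend roughly 4% of its samples below 1 uV,
which would both bias BSR upward and destroy cross-channel agreement; the
floor keeps the labeled state identifiable sample-by-sample, which is what
makes exact ground-truth recovery a fair test. Each channel follows the
common state except at jittered samples (probability 5e-4 per channel and
sample). That default is calibrated to the near-perfect cross-channel
agreement observed clinically (mean ICC ~ 0.999): for one-way single-measure
ICC on binary indicators, a flip probability gamma caps the ICC near
1 - 2*gamma*k/(k-1) at a 50/50 state mix, so 5e-4 yields ICC ~ 0.998-0.999
while 5e-3 could not exceed ~0.98.

`simulateGCSSeries()` draws at least two assessments per day, scoring 3–6
inside supplied sedation windows and 7–15 outside, which pins the global GCS
minimum inside a sedation window. `simulateCohort()` assembles patients:
about 31% burst-suppressed (matching the reported fraction), barbiturate
exposure rising steeply with BSR (reaching near-certainty above BSR 0.45),
and binary outcomes drawn from logit p = b0 + b_BSR * maxBSR +
b_GCS * maxGCS with chronic-scale defaults (-13, 8, 1). Outcomes are mapped
onto the corresponding GOSe half uniformly so a median split recovers them
exactly. All randomness flows from one seed through deterministic
per-patient child streams; a fixed seed reproduces a cohort byte for byte.

What the generator does *not* emulate: physiological spectra, artifacts,
electrode failures, recording discontinuities, or any dependence of dwell
statistics on sedative dose. Passing tests therefore demonstrate that the
estimators are correct under the assumed data-generating structure, not that
the clinical findings generalize.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS to deviance tolerance 1e-10 (at most 100 iterations);
  coefficient covariance from the inverse observed information. Single-class
  outcomes and separated fits are flagged (`degenerate`), not thrown;
  near-separation is intrinsic here (the strongest published model has a BSR
  log-odds above 13), so no penalization is applied — plain maximum
  likelihood is what the published coefficients are.
* AICc requires n > k + 1 and errors otherwise; the k = 0 correction
  vanishes.
* Flat signals make kurtosis and ICC undefined: both return NA with a
  warning rather than erroring, so batch runs continue.
* Zero-phase filtering at a 0.5 Hz high-pass has second-scale DC-recovery
  tails; immediately after a burst these can hold a few suppression samples
  above threshold. End-to-end (filtered) BSR is therefore validated to a
  looser bound (mean error < 0.03) than raw-section recovery (< 0.02).
* Section extraction failures (timestamp outside the recording) produce
  per-section error entries and a warning, never a global failure; the same
  isolation applies per patient in `runFullPipeline()`.

## Problem sizes used in validation

The test suite validates statistical properties at deliberately modest
sizes: ground-truth BSR recovery on twenty 10-minute 256 Hz sections and on
shorter 128 Hz sections elsewhere; the BSR-kurtosis correlation and ICC on
ten 300 s sections spanning suppression fractions 0–0.9; coefficient
recovery on 200 replicates of 500-patient scalar cohorts; mediation interval
calibration on 100 replicates of 100-observation datasets with 1000
quasi-Bayesian draws each; and an end-to-end synthetic pipeline at 12
patients, 64 Hz, 60 s sections. These sizes were chosen so the full
validation runs in minutes while keeping Monte-Carlo error well inside each
asserted tolerance.

## Known limitations

* Ages are bin midpoints; every quantity mixing age models is approximate.
* The adjusted-SE formula reproduces the published pattern but is not
  certified identical to the original software's.
* The cohort table cannot support re-deriving per-section BSR for the
  clinical patients (raw EEG is not public); EEG-level claims are validated
  on synthetic sections only.
* The two extra patients used only in the original threshold sensitivity
  analysis are not in the packaged table (their data were never printed);
  threshold sensitivity is exercised on synthetic sections.
* Recording discontinuities are not modeled; timestamps are taken at face
  value.

## A short tour

```{r tour, eval = FALSE}
cohort <- loadCohort()
summarizeCohort(cohort)$usable_sections

ms <- enumerateModels(cohort, "chronic")
head(modelTable(ms))
averageParameters(ms)

med <- runMediation(cohort, "barbiturates", "maxBSR", "chronic",
                    nSims = 1000, seed = 1)
med

sim <- simulateBSEEG(simParams(), targetSuppression = 0.7, seed = 1)
sec <- extractSections(sim$record, times = 0, durationS = 600)[[1]]
computeBSR(sec)
```
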