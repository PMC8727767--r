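# sibsr

Sedation-induced burst suppression (SIBS) as a prognostic EEG biomarker
after moderate-to-severe traumatic brain injury.

In the neuro-ICU, barbiturates and propofol are titrated to EEG burst
suppression to lower cerebral metabolic demand and intracranial pressure.
`sibsr` quantifies the depth of burst suppression per patient and asks
whether it predicts global outcome. The pipeline:

1. **GCS-guided EEG selection** — a greedy walk over each patient's Glasgow
   Coma Scale assessments (lowest scores first, selected timepoints >= 24 h
   apart) anchors 10-minute EEG sections to periods of minimal
   responsiveness.
2. **Preprocessing** — average re-reference and zero-phase 0.5–45 Hz
   Butterworth band-pass; externally reviewed bad segments enter as a mask.
3. **Burst suppression ratio (BSR)** — the fraction of unmasked samples
   whose rectified cross-channel consensus amplitude is below 1 uV,

   `BSR = mean_t [ mode_c 1(|x_c(t)| < 1 uV) ]`,

   with threshold-sensitivity diagnostics (1/5/10 uV vs concurrent GCS and
   log10 signal kurtosis) and cross-channel agreement (one-way ICC).
4. **Multi-model inference** — GOSe outcomes dichotomized by median split
   (discharge 1–2 vs 3–4; chronic 1–4 vs 5–8); all 16 logistic models over
   {max BSR, max GCS, sex, age}; AICc ranking,
   `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`; Akaike weights over the
   delta <= 5 window; conditional (subset) model averaging with revised
   unconditional and df-adjusted standard errors.
5. **Mediation** — quasi-Bayesian Monte-Carlo mediation (1000 draws):
   does BSR transmit sedative effects on outcome (and vice versa),
   controlling for max GCS? Effects on the risk-difference scale (ACME,
   ADE, total) with percentile intervals.

A 32-patient clinical cohort table ships with the package; a synthetic
multichannel burst-suppression EEG generator (alternating-renewal state
path, log-normal dwells, near-isoelectric suppression noise,
amplitude-floored bursts, per-channel jitter) provides labeled ground truth
for every estimator. See the methods vignette
(`vignettes/sibs-methods.Rmd`) for the model details and design choices.

## Worked example

```r
library(sibsr)

cohort <- loadCohort()
cohort
#> CohortTable (fixture): 32 patients
#>   max BSR: 0.0000 - 0.9997; max GCS: 4 - 15
#>   chronic GOSe missing: 2

summarizeCohort(cohort)$usable_sections   # 4.6 +/- 1.8 sections per patient

ms <- enumerateModels(cohort, "chronic")  # 30 complete cases
head(modelTable(ms), 4)
#>   (Intercept) maxBSR maxGCS    sex    age df logLik   AICc delta weight
#> 1     -13.416  8.083  1.084 -5.818     NA  4 -7.246 24.092 0.000  0.382
#> 2     -12.631  7.917  0.985     NA     NA  3 -8.980 24.883 0.791  0.257
#> 3     -12.947  9.193  1.320     NA -0.076  4 -7.969 25.538 1.446  0.185
#> 4     -13.827  9.343  1.408 -7.142 -0.072  5 -6.569 25.638 1.546  0.176

averageParameters(ms)
#>          term    beta odds_ratio    se adj_se     z     p
#> 1 (Intercept) -13.200      0.000 5.010  5.252 2.513 0.012
#> 2      maxBSR   8.468   4760.121 3.670  3.844 2.203 0.028
#> 3      maxGCS   1.159      3.188 0.473  0.493 2.349 0.019
#> 4         sex  -6.236      0.002 8.023  8.420 0.741 0.459
#> 5         age  -0.074      0.929 0.068  0.072 1.031 0.303
```

Every model in the chronic selection window contains max BSR: deeper
sedation-induced burst suppression is associated with *better* 6-month
outcome (log-odds 8.47 per unit BSR, p = 0.028 after model averaging),
controlling for the patient's best behavioral recovery (max GCS). Note that
age enters as a bin midpoint (ages are published only in bins), so rows
mixing age are approximate; the age-free rows reproduce the published
values to three decimals.

Mediation finds no evidence that BSR transmits a barbiturate effect:

```r
runMediation(cohort, "barbiturates", "maxBSR", "chronic", nSims = 1000, seed = 1)
#> MediationResult: barbiturates -> maxBSR -> chronic (quasibayes, 1000 sims)
#>       estimate   lower  upper     p
#> acme    0.2178 -0.2478 0.7442 0.624
#> ade     0.2903 -0.4114 0.8342 0.538
#> total   0.5081  0.0745 0.7352 0.034
```

The ACME interval straddles zero: no significant mediation.

On the EEG side, the generator provides labeled sections for recovery
checks:

```r
sim <- simulateBSEEG(simParams(), targetSuppression = 0.7, seed = 1)
sec <- extractSections(sim$record, times = 0, durationS = 600)[[1]]
bsr(computeBSR(sec))            # within 0.02 of sim$truth@suppressionFraction
```

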