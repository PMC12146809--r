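---
title: "Methods: TMTV quantification and prognostic modelling"
author: "tmtv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMTV quantification and prognostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtv)
```

## Scope and model

Baseline total metabolic tumor volume (TMTV) on FDG-PET — the summed
volume of all nodal and extranodal lesions segmented at a fixed absolute
threshold of SUV ≥ 4 — has emerged as a prognostic biomarker in follicular
lymphoma. This package implements the full analysis chain around that
biomarker for a two-arm randomized-trial setting:

1. **SUV quantification.** Body-weight SUV is computed voxel-wise as
   `SUV = C · w / D`, with `C` the activity concentration (Bq/mL), `w` the
   body weight in grams, and `D` the injected dose decay-corrected to scan
   time, `D = D0 · 2^(−Δt/T½)` (F-18 half-life 6586.2 s by default). Only
   the body-weight variant is provided; lean-body-mass scaling is out of
   scope. Vendor images already in SUV units are accepted through a
   passthrough flag.
2. **Segmentation.** Voxels with SUV ≥ 4 (inclusive — a voxel at exactly
   4.0 is foreground) are grouped into lesions by 26-connectivity by
   default (6 and 18 are available; the choice is recorded in the audit
   log). Physiological uptake is removed by a deterministic surrogate of
   the operator's judgement: a component is discarded when more than half
   of its voxels fall inside a supplied exclusion mask. The spleen counts
   as involved if it contains a focal thresholded component or if its mean
   SUV strictly exceeds 150% of the liver reference (mean SUV over a liver
   VOI); diffuse involvement contributes the whole spleen anatomical
   volume by default (configurable to thresholded voxels only). Bone
   marrow components contribute only when flagged focal; the flag belongs
   to the operator, and a heuristic auto-flagger (component smaller than a
   set fraction of the marrow mask) exists for simulation only. A legacy
   41%-of-SUVmax mode re-grows each detected lesion at its own relative
   threshold, for comparison against cutoffs derived historically with
   that method.
3. **Cutoff derivation.** Three survival-based methods, all stratified by
   randomization arm and adjusted for FLIPI2, sex and induction regimen:
   the maximally selected log-rank-type score statistic over candidate
   cutoffs; a time-dependent ROC at a fixed horizon with
   inverse-probability-of-censoring weights, selecting the cutoff that
   maximizes sensitivity × specificity (Liu's criterion); and a
   restricted-cubic-spline Cox model read off at a zero crossing of the
   fitted log hazard-ratio curve. A consensus step evaluates the candidate
   cutoffs in the reference treatment arm and picks the one with the
   largest log-rank statistic.
4. **Validation and combined models.** Bootstrap out-of-bag validation of
   the chosen cutoff (per-resample hazard ratios on the ~37% of records
   left out of each with-replacement resample), bootstrap inclusion
   fractions for the TMTV term, the combined TMTV × FLIPI2 three-group
   classification, early progression within 24 months (POD24) with
   Fisher's exact test, Harrell concordance comparison of nested models
   with jackknife confidence intervals, and Bland–Altman inter-reader
   agreement.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| SUV threshold | 4.0, inclusive | SUV | standardized fixed-threshold protocol |
| Connectivity | 26 | — | common for PET blobs; configurable, audited |
| Minimum lesion volume | 0 | mL | the protocol applies no size filter |
| Exclusion overlap rule | > 0.5 | fraction | deterministic stand-in for operator removal |
| Spleen diffuse rule | mean SUV > 1.5 × liver, strict | — | focal OR diffuse involvement definition |
| Candidate grid | unique TMTV in [q10, q90] | mL | protects group sizes at the extremes |
| ROC horizon | 36 (configurable 60) | months | 3-year progression horizon |
| Knot range | 3–7, Harrell quantiles | — | selected by bootstrap-averaged AIC |
| Cox ties | Efron | — | more accurate than Breslow under monthly ties |
| CI level | 95%, Wald on log scale | — | matches the reporting convention |
| Newton convergence | gradient max-norm < 1e-9, ≤ 100 iterations | — | with step-halving (via the survival engine) |

The Harrell knot placements are tabulated in `rcsKnots()` (e.g. k = 5 →
quantiles 0.05/0.275/0.50/0.725/0.95). The spline basis is the truncated
power form scaled by the squared knot span, linear beyond the boundary
knots with continuous first and second derivatives.

## The synthetic data: what it emulates, what it does not

The trial's patient-level data are not redistributable, so the package
ships a generator whose defaults are fixed to the study conditions and
treated as constants, not dials:

* **TMTV marginal.** A plain log-normal cannot match the reference
  quartile triple (50, 161, 388 mL): the log-scale quantile spacing is
  asymmetric (log 388 − log 161 = 0.88 vs log 161 − log 50 = 1.17), and a
  log-normal forced through the median and the log-IQR width lands the
  quartiles at ≈58 and ≈448 mL. We therefore use a three-parameter
  shifted log-normal solved exactly from the quartiles: shift
  `s = (m² − q1·q3)/(q1 + q3 − 2m) ≈ 56.2`, `µ = log(m + s)`, `σ` from
  the log-IQR. About 10% of raw draws fall below zero; they are redrawn
  uniformly on (0, q1), which leaves all three quartiles exactly at
  50/161/388 and emulates the low-burden tail. The implied fraction above
  180 mL is ≈47% and the (180, 240] band holds ≈8%, both consistent with
  the reference cohort.
* **Clinical factors.** The five FLIPI2 factors (age > 60, Hb < 12,
  B2M > ULN, marrow involvement, bulky node > 6 cm) are Bernoulli at the
  reference prevalences (0.50/0.16/0.55/0.55/0.55) with a Gaussian
  one-factor coupling (loading 0.25) to the TMTV deviate, so higher TMTV
  accompanies adverse features. This yields a FLIPI2 high-risk fraction
  of ≈43%; the reference cohort reports 40%, and the difference is the
  price of keeping the published marginals — the real factors share
  dependence structure the generator does not model.
* **Hazard model.** PFS times are exponential
  (`h = λ0 · exp(β'x)`, optional Weibull shape) with a change-point
  (step) effect of TMTV at τ = 180 mL, log-HR log 1.6, FLIPI2-high
  log 2.0, male log 1.2; λ0 = 0.0034062/month was solved once so the
  marginal 5-year PFS is 67%. A smooth log-linear TMTV form and a null
  form exist for spline and calibration tests. OS uses an analogous
  single-cause model (λ0 = 0.00068152/month, 5-year OS ≈ 93%); PFS and
  OS times are drawn independently, so joint PFS/OS properties of a
  single patient are not calibrated.
* **Censoring.** Uniform accrual over 64 months plus an administrative
  cutoff at 89 months gives censoring ~ Uniform(25, 89) months and a
  reverse-KM median follow-up of ≈57 months. Dropout is not modelled: no
  subject is censored before 25 months, so in synthetic cohorts everyone
  is POD24-evaluable, unlike real trials.
* **Phantoms.** Shapes are voxelized by the center-in-shape rule, which
  makes every volume exactly reproducible by enumerating voxel centers
  and gives the segmentation an exact oracle. Optional isotropic Gaussian
  blur emulates partial-volume effects (default off; the truth always
  refers to unblurred geometry). No anatomical atlas, scanner noise or
  reconstruction modelling is attempted — passing phantom tests
  demonstrates correctness of the geometry and rule logic, not clinical
  segmentation performance.
* **Readers.** Inter-reader variability is multiplicative log-normal
  noise with a set coefficient of variation (σ² = log(1 + cv²)),
  median-unbiased.

## Numerical and design choices

* **Adjusted maximally selected statistic.** For each candidate c the
  score statistic of the indicator 1{TMTV > c} is computed from a
  stratified Cox model evaluated at coefficient 0 for the indicator with
  the adjusters held at their null-model estimates (a zero-iteration fit
  from those starting values). The adjusters' score components vanish at
  their own MLE, so the joint score statistic is the efficient score test
  for the indicator; with no adjusters it equals the classical log-rank
  statistic exactly. Ties in the maximal statistic resolve to the
  smallest cutoff. Maximally selected statistics are noisy by nature —
  in repeated simulations at n ≈ 700 and HR 1.6 the maxstat estimate
  misses the true change point by more than 20% in roughly a quarter of
  replicates, with occasional extreme picks near the grid edges; the
  stability and out-of-bag machinery exists precisely because a single
  selected cutoff overstates certainty. No small-sample p-value
  correction for the selection (Lausen–Schumacher) is applied.
* **Liu ROC operationalization.** The cited method names a criterion, not
  an estimator; we use the cumulative/dynamic definition at the horizon
  with inverse-probability-of-censoring weights from the Kaplan–Meier
  estimate of the censoring distribution (cases weighted by 1/G(T−),
  controls by a constant that cancels), and maximize sensitivity ×
  specificity. With no censoring this reduces algebraically to the
  empirical binary-outcome ROC, which the tests assert.
* **Spline cutoff reading.** The fitted spline gives a log hazard-ratio
  curve only up to an additive constant, so "where the curve crosses
  zero" depends on the chosen reference. Centering at the cohort median
  makes the curve zero at the reference by construction, so for any
  monotone fitted curve the crossing degenerates to the reference itself;
  that option exists (`reference = "median"`) and flags its degeneracy.
  The default centers the curve at the cohort-average spline risk
  (`reference = "meanRisk"`): the cutoff is the smallest TMTV above the
  median where predicted risk rises from below to above the cohort
  average, located by bisection to 0.1 mL. For a right-skewed marker this
  crossing sits above the median, which is also how the reference
  cohort's numbers behave (median 161, spline cutoff 181). If the curve
  never crosses, "no cutpoint" is reported rather than an arbitrary
  value.
* **Concordance.** Harrell's c counts pairs in which the shorter observed
  time is an event (ties in time usable only when exactly one member is
  censored at the tie); tied scores count one half. The 95% CI is
  normal-theory with the leave-one-out jackknife variance, computed in
  closed form by removing each subject's pair contributions. Note that
  the in-sample gain Δc from adding even a pure-noise covariate carries a
  small positive optimism (≈ +0.01 for one added degree of freedom at
  n = 300); Δc near zero, not exactly zero, is the correct null
  expectation.
* **Bootstrap inclusion fraction.** The BIF is a stability diagnostic of
  one dataset, not a type-I error rate: under a true null, resampling
  noise adds to sampling noise and the expected fraction of resamples
  with a significant likelihood-ratio test is ≈ 0.17, not 0.05
  (the resampled estimate is approximately N(b̂, se²) around an observed
  b̂ that is itself N(0, se²)). Calibration at the nominal 5% level holds
  across independent null datasets, which is what the calibration tests
  measure.
* **Bland–Altman CV.** Bias and limits of agreement are reported on the
  measurement scale. The coefficient of variation is computed from
  relative paired differences, CV = SD(dᵢ/mᵢ)/√2: with measurements
  spanning two orders of magnitude and multiplicative error, an
  absolute-difference CV would be dominated by the largest volumes and
  overestimate the per-measurement variability roughly two-fold.
* **POD24.** The clock starts at registration; evaluable subjects have an
  event before 24 months or at least 24 months of potential follow-up.
  Fisher's exact test is the default comparison (chi-squared by flag).
* **Missing data.** Complete cases per analysis; degenerate covariates
  (no variation) are flagged in reports rather than silently dropped.
* **Determinism.** Every stochastic routine takes a seed, derives child
  seeds for sub-procedures, and restores the caller's RNG state. The full
  pipeline writes byte-identical reports for identical (cohort, config,
  seed).

## Problem sizes used in the checks

The packaged checks run at deliberately moderate sizes chosen to make
Monte-Carlo conclusions stable while keeping the suite quick: 10 phantoms
on 36³ grids; distributional checks at n = 10 000; Cox
coverage at 200 replicates of n = 300; cutoff recovery at 20 replicates
of n = 700 (with the error-vs-n comparison at n = 200 vs 2000); null
calibration on 200 independent null cohorts; the end-to-end pipeline at
the trial's size (n = 689) with B = 200 bootstrap resamples and 40
knot-selection resamples.

## Shape of the package

Imaging-side objects (volumes, acquisition metadata, phantom truth,
segmentation results) are S4 classes with validity methods and accessors,
in the Bioconductor idiom. Statistical results are lightweight S3
objects with print methods, in the idiom of the survival package that
powers the fits. Kaplan–Meier, log-rank, Cox and Fisher computations are
delegated to the survival engine and stats; the restricted-spline basis,
Harrell concordance with jackknife, maximally selected adjusted score
statistic, IPCW time-dependent ROC and 3-D connected-component labeling
are implemented here because no installed package provides them in the
required form — each is checked against an independent brute-force oracle
in the test suite.

## Known limitations

* No DICOM reader: volumes enter as NIfTI-1 with a JSON metadata sidecar.
* Organ masks are inputs; no automatic organ segmentation or registration.
* SUVpeak, TLG, time-varying coefficients, frailty and competing-risks
  models are out of scope.
* The synthetic cohort is a calibration target, not a patient-level
  reconstruction: passing checks demonstrates the machinery recovers
  known truth under the stated conditions, not that the trial's specific
  numbers are reproduced.
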