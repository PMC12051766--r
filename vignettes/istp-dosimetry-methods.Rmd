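---
title: "Methods: instant single-time-point dosimetry for Lu-177 radioligand therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instant single-time-point dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(istpdose)
```

## The problem

Absorbed-dose estimation after Lu-177 radioligand therapy needs each
organ's time-integrated activity (TIA): the integral of organ activity over
all time after injection. The reference workflow images the patient with
quantitative SPECT at several time points over roughly a week and fits a
pharmacokinetic model — impractical for outpatient treatment. Single-scan
alternatives exist, but the widely used Hänscheid approximation only works
when the scan lands within 0.75–2.5 effective half-lives of injection,
which reintroduces strict scheduling. The instant single-time-point (iSTP)
approach removes that constraint: each organ's effective half-life
$T_{\mathrm{eff}}$ is predicted *before* therapy from pretherapy PET and
clinical data, so that a single scan at any early time point suffices.

This package implements the full chain — reference multi-time-point (MTP)
fitting, both single-scan estimators, S-value dosimetry, the machine-learning
half-life predictor, and the benchmarking machinery — together with a
calibrated synthetic cohort generator, because the clinical cohort the
method was developed on is not public.

## Kinetic model

Organ activity is modeled as a biexponential with a shared physical decay
rate $\lambda_{\mathrm{phys}} = \ln 2 / 159.6\,\mathrm{h}^{-1}$ (Lu-177,
6.65 d, converted to hours once and stored in `lu177_decay()`):

$$A(t) = A_1 e^{-(\lambda_1 + \lambda_{\mathrm{phys}})t}
       - A_2 e^{-(\lambda_2 + \lambda_{\mathrm{phys}})t},$$

a washout term minus an uptake term. The model value may be negative for
small $t$ when $A_2 > A_1$ (uptake still in progress); the evaluator
returns the signed value and only the data generator clamps observations at
zero, keeping the mathematics of the model separate from the physics of a
measurement. The effective half-life and TIA follow in closed form:

$$T_{\mathrm{eff}} = \frac{\ln 2}{\lambda_1 + \lambda_{\mathrm{phys}}},
\qquad
\tilde A = \frac{A_1 T_{\mathrm{eff}}}{\ln 2}
         - \frac{A_2}{\lambda_2 + \lambda_{\mathrm{phys}}}.$$

`numeric_tia()` evaluates the same integral by adaptive quadrature
(`stats::integrate` on $[0,\infty)$) and serves as an independent oracle:
the two agree to better than $10^{-6}$ relative over the whole admissible
parameter range (the test suite checks 100 random parameter sets).

## Reference fitting

The uptake pair $(A_2, \lambda_2)$ is not identifiable from sparse
post-therapy sampling — the earliest scan (2 h) already sits past the
uptake peak — so it is fixed per organ to population values supplied as a
file (`population_prior`). The shipped prior is synthetic, calibrated only
so that uptake peaks before 2 h; real analyses must supply their own.
Whether such priors should be per-organ or global is not settled; the
per-organ table is the more general choice and a global prior is just a
table with repeated rows.

With $(A_2, \lambda_2)$ fixed, the fit has two free parameters and the
optimal $A_1$ given $\lambda_1$ is a one-line weighted least-squares
solution. `fit_mtp()` therefore profiles $A_1$ out and minimizes a 1-D
objective in $\lambda_1$ over $[0, 10]\,\mathrm h^{-1}$: a 60-point
log-spaced grid plus a log-linear tail initializer, each refined by Brent's
method (tolerance $10^{-10}$). There is no stochastic step, so fits are
reproducible by construction, and the returned optimum provably beats every
start. Unweighted least squares is the default; a relative
($1/\text{activity}$) weighting is available since the original analysis
does not state a weighting.

Two deliberate choices:

* $A_1 > A_2$ (positive modeled activity at $t=0$) is **not** enforced.
  Whether the clinical fits constrained it is unknown; leaving it free makes
  violations visible in the returned parameters instead of hiding them.
* The amplitude bound (10 × the largest observed activity) is applied to
  the *model value at the earliest sample time*, not to $A_1$ itself. For a
  curve sampled only late (say {69, 144, 168} h with
  $T_{\mathrm{eff}} \approx 13$ h) the true $A_1$ back-extrapolates to far
  more than ten times anything observed; bounding $A_1$ directly made such
  noiseless curves unrecoverable, bounding the predicted initial
  observation keeps the same intent without that artifact.

Noiseless in-model curves are recovered to well below 0.1%; at 5%
multiplicative noise the median half-life recovery error over 200
replicates is about 3%.

## Single-time-point estimators

**Hänscheid.** $\tilde A_H = \frac{1}{\ln 2}\,A(t_{sc})\cdot 2 t_{sc}$.
For mono-exponential truth the ratio to the true TIA is
$x\,2^{1-x}$ with $x = t_{sc}/T_{\mathrm{eff}}$: exact at $x=1$, at most
+6.1% high (at $x = 1/\ln 2$) and −11.6% low at the edges of the rated
window $x \in [0.75, 2.5]$, which the package treats as a closed interval.
Scans outside the window (notably 2 h) are still computed but flagged
`out_of_method`.

**iSTP.** Given a predicted half-life, the single measurement is
back-extrapolated to an initial activity
$A_0 = A(t_{sc})\, 2^{t_{sc}/T_{\mathrm{eff}}}$ and the implied
mono-exponential integrated analytically:
$\tilde A_{\mathrm{iSTP}} = A_0 T_{\mathrm{eff}} / \ln 2$. The
reconstruction is mono-exponential by definition of the estimator — its
integrand contains a single exponential — so the uptake term is
deliberately absent. When the predicted half-life equals the true one, the
estimate is independent of the scan time, which is the property that frees
scan scheduling; the test suite verifies it exactly. For users who want the
population uptake integral removed, `istp_tia_uptake_corrected()` provides
that variant behind an explicit call; it is never applied silently.

## Absorbed dose

`absorbed_dose()` is the MIRD sum
$D(r_T) = \sum_{r_S} \tilde A_{r_S}\, S(r_T \leftarrow r_S)$ with an
infinite dose-integration period, matching the TIA integrals. One concrete
unit convention is fixed — S-values in Gy per MBq·h, TIA in MBq·h, dose in
Gy — and the S-value file must declare it; a mismatching declaration is an
error rather than a conversion, which rules out silent $3.6\times10^6$-fold
mistakes. Cross-organ terms are included when present; `dose_table()`
treats absent cross pairs as zero (sparse matrices are the norm), while the
low-level function errors by default. The shipped 4-organ matrix is
synthetic, scaled so typical cohort TIAs give doses of clinically familiar
magnitude; it is not a phantom-derived reference.

## Predicting the effective half-life

One independent model per organ maps pretherapy features — age, weight,
PSA, LDH, creatinine, hemoglobin, per-organ PET SUV_mean including the
urinary tract (kidneys and bladder), injected PET activity, cycle index,
and a small categorical organ-condition grade (one-hot, explicit category
list, unknown labels rejected) — to the MTP-measured half-life.

The learner is ε-insensitive support vector regression with an RBF kernel
(`e1071`/libsvm). Features are standardized to zero mean and unit variance
with statistics computed on training rows only; the scaler travels with the
model, so validation rows can never leak into scaling. Zero-variance
columns are dropped and logged. `C` and ε are grid-searched by inner
cross-validation on the mean absolute percentage error, with ties broken
toward smaller `C`, then larger ε (stronger regularization). The kernel
width γ is not specified in the original description; it joins the grid
with the scale heuristic $1/p$ as default. Predictions are floored at 1 h —
a half-life of zero or below is unphysical and would break the
back-extrapolation.

Validation is 10-fold cross-validation. The reported error is the mean
*absolute* percentage error per fold, summarized as mean ± SD across folds:
reported MEs in this problem read as positive magnitudes with SDs, which a
signed mean would not produce; the signed bias is reported alongside. Fold
assignment is plain row-level by default, matching the original
description, with an optional `by_patient` grouping because rows from one
patient recur across cycles and the original grouping is unknown.

Two prediction modes mirror the two clinical workflows: `per_cycle` uses
each cycle's own pretherapy features; `first_cycle_only` substitutes the
patient's cycle-1 features for every cycle, excluding (and logging)
patients who lack a cycle-1 row.

## The synthetic cohort generator

The generator emulates the statistical shape of the development cohort so
the pipeline is testable end to end:

* 20 patients attriting 20/12/6/4 across cycle bins 1/2/3/≥4, plus two
  patients whose cycle-1 pretherapy data are missing (exercising the
  first-cycle-only exclusions); 44 patient-cycles in total.
* Organ half-lives truncated-normal — kidneys 35 ± 16 h on [7, 65] (34 for
  the right), liver 11 ± 4 h on [6, 25], spleen 9 ± 4 h on [5, 25]. The
  truncated normal is the simplest distribution honoring all four published
  numbers (mean, SD, min, max).
* The half-life is **patient-intrinsic**: one patient-level draw per organ,
  jittered per cycle by a lognormal with CV 0.15 and clamped to the organ
  bounds. This encodes the premise that makes pretherapy prediction
  possible at all; with independent per-cycle half-lives the
  first-cycle-only scenario would be structurally impossible rather than
  merely harder, which would test nothing.
* Injected activities 7.3 ± 0.3 GBq (therapy) and 119.0 ± 25.1 MBq (PET);
  washout amplitudes scale from the injected activity through per-organ
  uptake fractions (kidneys 1.5%, liver 2.5%, spleen 0.5%, ±15% lognormal
  inter-subject spread) chosen to give organ doses of clinically familiar
  magnitude through the synthetic S-values.
* Clinical covariates follow the published per-cycle means and global
  min–max ranges (PSA lognormal within [0.1, 2936] ng/mL; LDH, creatinine,
  hemoglobin truncated-normal within their ranges; age 69 ± 9 y and weight
  82.3 ± 10.6 kg fixed per patient).
* Sampling schedules draw 3–5 distinct points from {2, 20, 43, 69, 144,
  168} h; the ">165 h" scan is represented as 168 h (7 d), configurably.
* Measurement noise is multiplicative lognormal with unit mean (CV 5% by
  default) and observations clamp at zero.
* The feature link — organ SUV_mean $= a + 3\log T_{\mathrm{eff}} +
  \mathcal N(0, 0.25)$ with per-organ intercepts, bladder SUV decreasing in
  the mean kidney half-life as a clearance proxy, and an organ-condition
  grade cut from the kidney half-life with 10% misclassification — is an
  explicit invention required for testability. Its parameters live in the
  configuration and are not claimed to be clinical truth. Consequently,
  passing predictor tests show that the pipeline *can learn a present
  signal without leakage*, not that pretherapy PET predicts clinical
  half-lives.

Everything is a pure function of the seed; cohorts re-emitted to CSV are
byte-identical across runs.

What the generator does **not** emulate: image formation (reconstruction,
partial-volume, segmentation error), correlated multi-organ kinetics beyond
the kidney pair, tri-exponential or compartmental washout, lesions and
salivary glands, and any real covariance between clinical labs and organ
kinetics.

## Problem sizes and frozen bounds

The validation suite uses the cohort-shaped dataset (44 cycles) for
pipeline runs and a 210-cycle cohort (100 patients, 40/30/10/20 attrition)
for predictor characterization — large enough for stable 10-fold CV, small
enough that the full suite runs in minutes on one core. The predictor
acceptance bound was frozen from a 10-seed pilot at exactly those
conditions: left kidney ME 12.8% ± 0.9 (worst 14.3%), liver 10.3% (worst
11.6%); the bound is 16%, the pilot mean plus ≈3.5 SD, to cover
seed-to-seed variation. Noise-ablation checks (link noise 0.1 → 0.5 → 2.0,
20 seeds each) use a fixed SVR configuration so that the comparison
isolates the data, not the search.

## Statistical comparisons

The relative absolute difference
$\mathrm{RAD} = |\theta_{\mathrm{STP}}/\theta_{\mathrm{MTP}} - 1| \times
100\%$ is the benchmarking metric; the absolute value is applied
deliberately (the metric's name and reported magnitudes imply it), with the
signed version retained for bias analyses. Records whose reference TIA is
exactly zero are excluded with a logged count rather than producing
infinities. Paired comparisons use the Wilcoxon signed-rank test, unpaired
ones Mann–Whitney, both two-sided at 0.05, delegating to
`stats::wilcox.test` (exact when sample sizes permit and ties are absent,
normal approximation with corrections otherwise); a hand-written Pratt
variant handles zero differences by ranking them and discarding their
contribution, since base R only drops zeros. The test suite validates both
against exhaustive enumeration of sign assignments and labelings. No
multiple-testing correction is applied, matching the original analysis.

## Known limitations

* The iSTP error grows exponentially with
  $t_{sc}\,(1/T_{\mathrm{pred}} - 1/T_{\mathrm{true}})$, so late scans
  amplify prediction error — visible in the synthetic benchmarks for the
  short-half-life organs (liver, spleen) at 69 h, and the reason early
  scans are the method's target regime.
* Because the synthetic truth is exactly biexponential with one effective
  washout rate, the Hänscheid estimator degrades faster at late scan times
  here than real curves (with their slower late components) would suggest.
* The fixture prior and S-value matrix are synthetic stand-ins; every
  number downstream of them is method-validation output, not a clinical
  dose.
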