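# istpdose

Organ-level internal dosimetry for ¹⁷⁷Lu radioligand therapy, built around
**instant single-time-point (iSTP)** dose estimation: predicting each
organ's effective half-life from *pretherapy* PET and clinical data so that
a single post-therapy SPECT scan — taken at any early time point — suffices
for absorbed-dose estimation.

## Who this is for

Medical physicists and quantitative-imaging researchers who need a
reference implementation of the iSTP workflow and its benchmarks:
multi-time-point (MTP) pharmacokinetic fitting as the gold standard, the
Hänscheid single-scan approximation as the established comparator, and a
machine-learning half-life predictor that removes the comparator's strict
scan-timing requirement. Because the clinical development cohort is
private, the package ships a seeded synthetic cohort generator calibrated
to the published cohort statistics, so every stage is testable end to end.

## The model

Organ activity after injection follows a biexponential with physical decay
λ_phys = ln2/159.6 h⁻¹ (¹⁷⁷Lu, 6.65 d):

    A(t) = A₁·exp(−(λ₁+λ_phys)·t) − A₂·exp(−(λ₂+λ_phys)·t)

with (A₂, λ₂) fixed to per-organ population values. The effective
half-life and time-integrated activity (TIA) follow in closed form:

    T_eff = ln2 / (λ₁ + λ_phys),     Ã = A₁·T_eff/ln2 − A₂/(λ₂+λ_phys)

Three TIA estimators:

* **MTP** (reference): least-squares fit of A₁, λ₁ to ≥3 scans.
* **Hänscheid**: Ã_H = (1/ln2)·A(t_sc)·2·t_sc, rated for
  t_sc ∈ [0.75, 2.5]·T_eff.
* **iSTP**: Ã = A₀·T_pred/ln2 with A₀ = A(t_sc)·2^(t_sc/T_pred), where
  T_pred comes from RBF-kernel support vector regression on pretherapy
  features (10-fold cross-validated, leakage-safe scaling, grid-searched
  C/ε/γ).

Absorbed dose is the MIRD sum D(target) = Σ_source Ã_source ·
S(target←source) with S-values in Gy/(MBq·h). Estimators are benchmarked
with the relative absolute difference RAD = |Ã_STP/Ã_MTP − 1|·100% plus
Wilcoxon signed-rank / Mann–Whitney comparisons.

## Worked example

```r
library(istpdose)
decay  <- lu177_decay()
prior  <- fixture_prior()              # synthetic uptake prior (A2, lambda2)
cohort <- generate_cohort(cohort_config(seed = 42))

# 1. reference fit of one organ curve
curve <- cohort$curves[[1]]
curve
#> <time_activity_curve> patient P01, cycle 1, left_kidney: 5 samples over [2, 144] h
fit <- fit_mtp(curve, prior, decay)
fit
#> <kinetics_estimate> P01 c1 left_kidney: Teff=29.99 h, TIA=4746.0 MBq*h (5 pts, sse=23.3)

# 2. cross-validated half-life prediction from pretherapy features
targets <- cohort$truth[cohort$truth$organ == "left_kidney",
                        c("patient_id", "cycle", "teff_hours")]
rep <- kfold_validate(cohort$features, targets, k = 10, seed = 42, cfg = NULL)
rep
#> <cv_report> k=10 (plain folds): ME 14.2% +/- 5.3% (bias +3.5%)

# 3. single 20-h scan -> iSTP TIA -> dose
pred <- rep$predictions$teff_pred[rep$predictions$patient_id == "P01" &
                                  rep$predictions$cycle == 1]      # 27.0 h
m <- stp_measurement("P01", 1, "left_kidney", 20,
                     curve$activity_MBq[curve$t_hours == 20])
res <- istp_tia(m, pred)
res
#> <stp_result> P01 c1 left_kidney @ 20 h [istp]: TIA=4644.9 MBq*h
rad(res$tia_MBq_h, fit$tia_MBq_h)          # 2.1 % vs the MTP reference
absorbed_dose(c(left_kidney = res$tia_MBq_h), fixture_svalues(),
              "left_kidney")               # 3.11 Gy
```

Reading: the five-point reference fit gives this kidney a 30.0 h effective
half-life and 4746 MBq·h TIA. The predictor, trained only on out-of-fold
pretherapy features, estimates 27.0 h; plugging a single 20-h measurement
into the iSTP formula reproduces the reference TIA within 2.1%, and the
synthetic S-value turns it into a 3.1 Gy kidney dose. The cohort-wide CV
error (ME 14.2% ± 5.3%) is the quantity that governs how well this works on
average.

The two full workflows — per-cycle features with scan-time sweeps
(`run_scenario_1`) and first-cycle-only features with per-cycle dose
comparisons (`run_scenario_2`) — write complete, provenance-stamped,
byte-reproducible report bundles. A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","istp.R",package="istpdose"))')" \
    scenario1 --seed 7 --out-dir runs/s1
```

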