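#' Truncated-normal sampler (inverse-CDF)
#'
#' All "mean +/- SD (min-max)" cohort quantities are drawn truncated-normal:
#' the simplest distribution honoring all four published numbers.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal.
#' @param lower,upper Truncation bounds (`lower < upper`).
#' @return Numeric vector of n draws in `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, sd >= 0)
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate draw outside truncation bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Lognormal multiplier with unit mean and coefficient of variation cv.
rlnorm_unit_mean <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the statistical shape of the 22-patient Lu-177-PSMA
#' therapy cohort the method was developed on: per-cycle patient counts
#' 20/12/6/4 (plus two patients whose first-cycle pretherapy data are
#' missing), organ effective half-lives truncated-normal with kidneys
#' 35 +/- 16 h on [7, 65] (34 for the right), liver 11 +/- 4 h on [6, 25],
#' spleen 9 +/- 4 h on [5, 25], injected therapy activity 7.3 +/- 0.3 GBq,
#' pretherapy PET activity 119.0 +/- 25.1 MBq, and clinical covariates with
#' the published per-cycle means and min-max ranges. Sparse SPECT schedules
#' draw 3-5 points from \{2, 20, 43, 69, 144, 168\} h (the ">165 h" scan is
#' represented as 168 h). The feature link — organ SUV_mean as a log-linear
#' function of the organ's effective half-life, bladder SUV anti-correlated
#' with kidney half-life as a clearance proxy — is an explicit modeling
#' stand-in that gives the predictor a learnable signal; it is not claimed
#' to be clinical truth.
#'
#' @param n_patients Number of patients with complete cycle-1 data.
#' @param cycles_per_patient_counts Integer vector: how many of those
#'   patients have exactly 1, 2, 3, 4 cycles. Must sum to `n_patients`.
#' @param n_missing_cycle1 Extra patients contributing one cycle-2 row only
#'   (no cycle-1 features) — exercised by the first-cycle-only mode.
#' @param teff Per-organ list of `c(mean, sd, min, max)` in hours.
#' @param teff_cycle_cv Within-patient cycle-to-cycle lognormal variability
#'   of the organ half-life. The half-life is modeled as patient-intrinsic
#'   (the premise that makes pretherapy prediction possible): one
#'   patient-level value per organ, jittered per cycle by this CV and
#'   clamped to the organ's truncation bounds.
#' @param uptake_fraction Per-organ fraction of injected activity in the
#'   washout amplitude A1.
#' @param uptake_fraction_cv Lognormal inter-subject variability of that
#'   fraction.
#' @param injected_GBq,injected_pet_MBq `c(mean, sd)` of therapy and PET
#'   injected activities.
#' @param clinical Per-cycle means and global bounds of PSA, LDH,
#'   creatinine, hemoglobin; age and weight distributions.
#' @param suv_link Per-organ intercepts `a`, common slope `b` and noise SD of
#'   the link `SUV = a + b * log(Teff) + N(0, sd)`; bladder uses
#'   `a_bladder - b_bladder * log(mean kidney Teff)`.
#' @param condition_thresholds Kidney-half-life cutoffs (h) separating the
#'   organ-condition classes normal / mild_impairment / impaired.
#' @param condition_flip_prob Probability of random misclassification of the
#'   condition class.
#' @param noise_cv Multiplicative lognormal measurement noise CV.
#' @param schedule_pool Candidate scan times (h).
#' @param n_points_range `c(min, max)` scans per curve.
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 20L,
    cycles_per_patient_counts = c(8L, 6L, 2L, 4L),
    n_missing_cycle1 = 2L,
    teff = list(left_kidney  = c(mean = 35, sd = 16, min = 7, max = 65),
                right_kidney = c(mean = 34, sd = 16, min = 7, max = 65),
                liver        = c(mean = 11, sd = 4,  min = 6, max = 25),
                spleen       = c(mean = 9,  sd = 4,  min = 5, max = 25)),
    teff_cycle_cv = 0.15,
    uptake_fraction = c(left_kidney = 0.015, right_kidney = 0.015,
                        liver = 0.025, spleen = 0.005),
    uptake_fraction_cv = 0.15,
    injected_GBq = c(mean = 7.3, sd = 0.3),
    injected_pet_MBq = c(mean = 119.0, sd = 25.1),
    clinical = list(
      age = c(mean = 69, sd = 9, min = 45, max = 90),
      weight = c(mean = 82.3, sd = 10.6, min = 55, max = 120),
      psa_cycle_mean = c(714.59, 591.35, 611.67, 438.19),
      psa_bounds = c(0.1, 2936),
      psa_sdlog = 1.2,
      ldh_cycle_mean = c(328.05, 275.25, 270.83, 247.67),
      ldh_bounds = c(161, 664), ldh_sd = 80,
      creatinine_cycle_mean = c(1.0, 0.9, 0.9, 0.9),
      creatinine_bounds = c(0.5, 2.0), creatinine_sd = 0.25,
      hemoglobin_cycle_mean = c(11.52, 10.78, 10.45, 10.72),
      hemoglobin_bounds = c(8.7, 15.2), hemoglobin_sd = 1.2),
    suv_link = list(a = c(left_kidney = 1.3, right_kidney = 1.3,
                          liver = -1.2, spleen = 0.4),
                    b = 3,
                    noise_sd = 0.25,
                    a_bladder = 25, b_bladder = 3.5, bladder_noise_sd = 0.8),
    condition_thresholds = c(27, 43),
    condition_flip_prob = 0.1,
    noise_cv = 0.05,
    schedule_pool = c(2, 20, 43, 69, 144, 168),
    n_points_range = c(3L, 5L),
    seed = 1L) {
  stopifnot(sum(cycles_per_patient_counts) == n_patients,
            length(cycles_per_patient_counts) == 4L,
            noise_cv >= 0,
            n_points_range[1] >= 3L,
            n_points_range[2] <= length(schedule_pool))
  for (org in dosimetry_organs()) {
    p <- teff[[org]]
    if (is.null(p)) stop("teff config missing organ ", org)
    if (p[["min"]] >= p[["max"]]) stop("teff truncation bounds violated for ", org)
    if (p[["sd"]] < 0) stop("teff sd must be >= 0")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' Draw one organ's true kinetics
#'
#' Effective half-life truncated-normal per the organ's config; the
#' biological washout rate is back-solved against physical decay; A1 scales
#' from the injected activity through an organ uptake fraction; the uptake
#' pair (A2, lambda2) comes from the prior. Uses the current RNG state
#' (callers seed via [generate_cohort()]).
#'
#' @param cfg A `cohort_config`.
#' @param organ One of [dosimetry_organs()].
#' @param injected_MBq Injected therapy activity (MBq).
#' @param prior A `population_prior`.
#' @param decay A `physical_decay`.
#' @param teff_hours Optional half-life to use instead of drawing one (the
#'   cohort generator supplies the patient-intrinsic, cycle-jittered value).
#' @return List: `params` (`biexp_params`), `teff_hours`, `tia_MBq_h`.
#' @export
sample_kinetics <- function(cfg, organ, injected_MBq, prior = fixture_prior(),
                            decay = lu177_decay(), teff_hours = NULL) {
  p <- cfg$teff[[organ]]
  teff <- teff_hours %||%
    rtruncnorm(1, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]])
  teff <- min(teff, decay$half_life_hours * 0.999)  # biological rate >= 0
  lam1 <- lambda1_from_teff(teff, decay)
  frac <- cfg$uptake_fraction[[organ]] * rlnorm_unit_mean(1, cfg$uptake_fraction_cv)
  pe <- prior_entry(prior, organ)
  params <- biexp_params(frac * injected_MBq, lam1, pe$A2_MBq, pe$lambda2_per_h)
  list(params = params,
       teff_hours = teff_from_rates(lam1, decay),
       tia_MBq_h = closed_form_tia(params, decay))
}

#' Draw a sparse SPECT sampling schedule
#'
#' 3-5 distinct times from the configured pool, sorted ascending.
#'
#' @param cfg A `cohort_config`.
#' @return Sorted numeric vector of scan times (h).
#' @export
sample_schedule <- function(cfg) {
  k <- sample(seq(cfg$n_points_range[1], cfg$n_points_range[2]), 1L)
  sort(sample(cfg$schedule_pool, k))
}

#' Observe a noisy time-activity curve
#'
#' Evaluates the signed biexponential model on the schedule, applies
#' multiplicative lognormal noise with unit mean and CV `noise_cv`, and
#' clamps at zero (measured activities cannot be negative; clamping lives
#' here, not in the model evaluator).
#'
#' @param params A `biexp_params`.
#' @param schedule Scan times (h), strictly increasing.
#' @param noise_cv Noise coefficient of variation, >= 0.
#' @param decay A `physical_decay`.
#' @param patient_id,cycle,organ Curve identifiers.
#' @return A `time_activity_curve`.
#' @export
observe_curve <- function(params, schedule, noise_cv, decay = lu177_decay(),
                          patient_id = "p", cycle = 1L, organ = "liver") {
  truth <- evaluate_biexponential(params, decay, schedule)
  obs <- pmax(0, truth * rlnorm_unit_mean(length(schedule), noise_cv))
  time_activity_curve(patient_id, cycle, organ, schedule, obs)
}

# Condition class from mean kidney half-life, with misclassification noise.
condition_class <- function(kidney_teff_mean, cfg) {
  cls <- cut(kidney_teff_mean, c(-Inf, cfg$condition_thresholds, Inf),
             labels = c("normal", "mild_impairment", "impaired"))
  cls <- as.character(cls)
  if (stats::runif(1) < cfg$condition_flip_prob) {
    cls <- sample(setdiff(c("normal", "mild_impairment", "impaired"), cls), 1L)
  }
  cls
}

#' Generate the pretherapy feature row for one patient cycle
#'
#' Organ SUV_mean is a log-linear function of the organ's true effective
#' half-life plus Gaussian noise; the urinary-bladder SUV decreases with the
#' mean kidney half-life (fast clearance fills the bladder). Clinical
#' covariates come from the published per-cycle means and bounds and carry
#' no half-life information.
#'
#' @param cfg A `cohort_config`.
#' @param patient Per-patient list with `age`, `weight`.
#' @param cycle Cycle index (clinical means use bin min(cycle, 4)).
#' @param teff_by_organ Named numeric: true effective half-life per organ (h).
#' @param patient_id Identifier.
#' @return One-row data frame (a feature row).
#' @export
generate_features <- function(cfg, patient, cycle, teff_by_organ, patient_id) {
  cl <- cfg$clinical
  bin <- min(cycle, 4L)
  psa <- exp(rtruncnorm(1, log(cl$psa_cycle_mean[bin]) - cl$psa_sdlog^2 / 2,
                        cl$psa_sdlog, log(cl$psa_bounds[1]), log(cl$psa_bounds[2])))
  ldh <- rtruncnorm(1, cl$ldh_cycle_mean[bin], cl$ldh_sd,
                    cl$ldh_bounds[1], cl$ldh_bounds[2])
  crea <- rtruncnorm(1, cl$creatinine_cycle_mean[bin], cl$creatinine_sd,
                     cl$creatinine_bounds[1], cl$creatinine_bounds[2])
  hb <- rtruncnorm(1, cl$hemoglobin_cycle_mean[bin], cl$hemoglobin_sd,
                   cl$hemoglobin_bounds[1], cl$hemoglobin_bounds[2])
  lk <- cfg$suv_link
  suv <- vapply(dosimetry_organs(), function(org) {
    max(0, lk$a[[org]] + lk$b * log(teff_by_organ[[org]]) +
          stats::rnorm(1, 0, lk$noise_sd))
  }, numeric(1))
  kid_mean <- mean(c(teff_by_organ[["left_kidney"]], teff_by_organ[["right_kidney"]]))
  suv_bladder <- max(0, lk$a_bladder - lk$b_bladder * log(kid_mean) +
                       stats::rnorm(1, 0, lk$bladder_noise_sd))
  data.frame(
    patient_id = patient_id, cycle = as.integer(cycle),
    age = patient$age, weight = patient$weight,
    psa = psa, ldh = ldh, creatinine = crea, hemoglobin = hb,
    suv_left_kidney = suv[["left_kidney"]],
    suv_right_kidney = suv[["right_kidney"]],
    suv_liver = suv[["liver"]], suv_spleen = suv[["spleen"]],
    suv_urinary_bladder = suv_bladder,
    organ_condition_class = condition_class(kid_mean, cfg),
    injected_pet_activity_MBq = max(1, stats::rnorm(1, cfg$injected_pet_MBq[["mean"]],
                                                    cfg$injected_pet_MBq[["sd"]])),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `cfg$seed`: curves, pretherapy features, and the
#' generating truth (per patient-cycle-organ parameters, effective
#' half-life, and time-integrated activity) are all returned, so fitting,
#' prediction and benchmarking can be validated against known ground truth.
#'
#' @param cfg A `cohort_config`.
#' @param prior A `population_prior` (defaults to the synthetic fixture).
#' @param decay A `physical_decay`.
#' @return Object of class `synthetic_cohort`: list with `curves` (list of
#'   `time_activity_curve`), `features` (data frame), `truth` (data frame),
#'   `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), prior = fixture_prior(),
                            decay = lu177_decay()) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)

  n_cycles_vec <- rep(1:4, times = cfg$cycles_per_patient_counts)
  patients <- lapply(seq_along(n_cycles_vec), function(i) {
    list(id = sprintf("P%02d", i), cycles = seq_len(n_cycles_vec[i]),
         missing_cycle1 = FALSE)
  })
  # Patients contributing one later cycle but no cycle-1 pretherapy data.
  for (j in seq_len(cfg$n_missing_cycle1)) {
    patients[[length(patients) + 1L]] <- list(
      id = sprintf("P%02d", length(patients) + 1L),
      cycles = 2L, missing_cycle1 = TRUE)
  }

  curves <- list(); truth <- list(); features <- list()
  cl <- cfg$clinical
  for (p in patients) {
    age <- rtruncnorm(1, cl$age[["mean"]], cl$age[["sd"]],
                      cl$age[["min"]], cl$age[["max"]])
    weight <- rtruncnorm(1, cl$weight[["mean"]], cl$weight[["sd"]],
                         cl$weight[["min"]], cl$weight[["max"]])
    pinfo <- list(age = age, weight = weight)
    # patient-intrinsic organ half-lives, jittered per cycle below
    teff_patient <- vapply(dosimetry_organs(), function(org) {
      tp <- cfg$teff[[org]]
      rtruncnorm(1, tp[["mean"]], tp[["sd"]], tp[["min"]], tp[["max"]])
    }, numeric(1))
    for (cy in p$cycles) {
      injected <- stats::rnorm(1, cfg$injected_GBq[["mean"]],
                               cfg$injected_GBq[["sd"]]) * 1000
      teff_by_organ <- numeric(0)
      for (org in dosimetry_organs()) {
        tp <- cfg$teff[[org]]
        teff_cy <- min(max(teff_patient[[org]] *
                             rlnorm_unit_mean(1, cfg$teff_cycle_cv),
                           tp[["min"]]), tp[["max"]])
        kin <- sample_kinetics(cfg, org, injected, prior, decay,
                               teff_hours = teff_cy)
        teff_by_organ[[org]] <- kin$teff_hours
        schedule <- sample_schedule(cfg)
        curves[[length(curves) + 1L]] <-
          observe_curve(kin$params, schedule, cfg$noise_cv, decay,
                        patient_id = p$id, cycle = cy, organ = org)
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = p$id, cycle = as.integer(cy), organ = org,
          A1_MBq = kin$params$A1_MBq, lambda1_bio = kin$params$lambda1_bio,
          A2_MBq = kin$params$A2_MBq, lambda2_bio = kin$params$lambda2_bio,
          teff_hours = kin$teff_hours, tia_MBq_h = kin$tia_MBq_h,
          injected_MBq = injected, stringsAsFactors = FALSE)
      }
      features[[length(features) + 1L]] <-
        generate_features(cfg, pinfo, cy, teff_by_organ, p$id)
    }
  }
  structure(list(curves = curves,
                 features = do.call(rbind, features),
                 truth = do.call(rbind, truth),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d curves, %d patient-cycles, seed %d\n",
              length(x$curves), nrow(x$features), x$config$seed))
  invisible(x)
}

#' Single-time-point measurements derived from cohort truth
#'
#' Evaluates each patient-cycle-organ truth curve at the requested scan
#' times, with the same multiplicative noise model as [observe_curve()]
#' (clamped at zero). Used to feed the single-time-point estimators during
#' benchmarking.
#'
#' @param cohort A `synthetic_cohort`.
#' @param t_sc Scan times (h).
#' @param noise_cv Measurement noise CV (default: the cohort's own).
#' @param decay A `physical_decay`.
#' @param seed Integer seed for the measurement noise.
#' @return Data frame `patient_id, cycle, organ, t_sc_hours, activity_MBq`.
#' @export
stp_measurements_from_truth <- function(cohort, t_sc = c(2, 20, 43, 69),
                                        noise_cv = cohort$config$noise_cv,
                                        decay = lu177_decay(),
                                        seed = cohort$config$seed + 1L) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  tr <- cohort$truth
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    params <- biexp_params(tr$A1_MBq[i], tr$lambda1_bio[i],
                           tr$A2_MBq[i], tr$lambda2_bio[i])
    a <- evaluate_biexponential(params, decay, t_sc)
    data.frame(patient_id = tr$patient_id[i], cycle = tr$cycle[i],
               organ = tr$organ[i], t_sc_hours = t_sc,
               activity_MBq = pmax(0, a * rlnorm_unit_mean(length(t_sc), noise_cv)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a synthetic cohort to a directory of CSVs
#'
#' Emits `cohort.csv` (long sample table), `features.csv`, `truth.csv`, and
#' `config.json` (the generating configuration, for provenance). Output is
#' byte-identical across runs with the same cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_with_provenance(cohort_to_samples(cohort$curves),
                        file.path(dir, "cohort.csv"), cohort$config$seed)
  write_with_provenance(cohort$features, file.path(dir, "features.csv"),
                        cohort$config$seed)
  write_with_provenance(cohort$truth, file.path(dir, "truth.csv"),
                        cohort$config$seed)
  cfg <- cohort$config
  cfg_plain <- lapply(unclass(cfg), function(x) x)
  jsonlite::write_json(cfg_plain, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
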