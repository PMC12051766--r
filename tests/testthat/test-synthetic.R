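test_that("truncated-normal draws honor bounds, degenerate SD, and moments", {
  set.seed(1)
  x <- rtruncnorm(1e4, 35, 16, 7, 65)
  expect_true(all(x >= 7 & x <= 65))
  # moments of the truncated distribution (not the parent): compare against
  # the analytic truncated-normal mean
  a <- (7 - 35) / 16; b <- (65 - 35) / 16
  mu_trunc <- 35 + 16 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu_trunc), 3 * se)

  expect_equal(rtruncnorm(5, 11, 0, 6, 25), rep(11, 5))
  expect_error(rtruncnorm(1, 50, 0, 6, 25), "degenerate")
})

test_that("organ kinetics draws stay inside the configured half-life ranges", {
  cfg <- cohort_config(seed = 2)
  set.seed(2)
  for (i in 1:200) {
    kin <- sample_kinetics(cfg, "liver", 7300)
    expect_true(kin$teff_hours >= 6 && kin$teff_hours <= 25)
  }
  set.seed(3)
  kid <- replicate(2000, sample_kinetics(cfg, "left_kidney", 7300)$teff_hours)
  expect_true(all(kid >= 7 & kid <= 65))
  # sample mean within 3 SE of the truncated-normal mean
  a <- (7 - 35) / 16; b <- (65 - 35) / 16
  mu_trunc <- 35 + 16 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(kid) - mu_trunc), 3 * sd(kid) / sqrt(length(kid)))

  cfg0 <- cohort_config(seed = 4)
  cfg0$teff$spleen["sd"] <- 0
  set.seed(4)
  expect_equal(sample_kinetics(cfg0, "spleen", 7300)$teff_hours, 9)
})

test_that("schedules have 3-5 sorted distinct points from the pool", {
  cfg <- cohort_config(seed = 5)
  set.seed(5)
  for (i in 1:300) {
    s <- sample_schedule(cfg)
    expect_true(length(s) >= 3 && length(s) <= 5)
    expect_true(all(s %in% cfg$schedule_pool))
    expect_false(is.unsorted(s, strictly = TRUE))
  }
  set.seed(6); s1 <- sample_schedule(cfg)
  set.seed(6); s2 <- sample_schedule(cfg)
  expect_identical(s1, s2)
})

test_that("observation noise is multiplicative, unit-mean, and clamped at zero", {
  d <- lu177_decay()
  p <- biexp_params(100, 0.02, A2_MBq = 20, lambda2_bio = 2.5)
  sched <- c(2, 20, 43, 69, 144)
  set.seed(7)
  noiseless <- observe_curve(p, sched, 0, d)
  expect_equal(noiseless$activity_MBq,
               evaluate_biexponential(p, d, sched), tolerance = 1e-12)

  set.seed(8)
  ratios <- replicate(3000, {
    cv <- observe_curve(p, 43, 0.1, d)
    cv$activity_MBq / evaluate_biexponential(p, d, 43)
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))

  # uptake-dominated curve is negative early; observations clamp to 0
  pneg <- biexp_params(10, 0.01, A2_MBq = 50, lambda2_bio = 0.5)
  expect_lt(evaluate_biexponential(pneg, d, 0.5), 0)
  set.seed(9)
  cv <- observe_curve(pneg, c(0.5, 20, 69), 0.05, d)
  expect_equal(cv$activity_MBq[1], 0)
})

test_that("generated cohorts are self-consistent and seed-reproducible", {
  cfg <- small_cohort_config(seed = 10)
  co <- generate_cohort(cfg)
  # structure: 10 full patients (4+3+1+2 with 1..4 cycles) + 1 missing-cycle1
  expect_equal(length(unique(co$features$patient_id)), 11)
  expect_equal(nrow(co$features), 4 + 3 * 2 + 1 * 3 + 2 * 4 + 1)
  expect_equal(nrow(co$truth), nrow(co$features) * 4)
  expect_equal(length(co$curves), nrow(co$truth))

  # truth TIA equals the closed form of the truth parameters
  d <- lu177_decay()
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    p <- biexp_params(tr$A1_MBq, tr$lambda1_bio, tr$A2_MBq, tr$lambda2_bio)
    expect_equal(tr$tia_MBq_h, closed_form_tia(p, d), tolerance = 1e-9)
  }

  # byte-identical CSV output for the same seed
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(co, d1)
  write_cohort(generate_cohort(small_cohort_config(seed = 10)), d2)
  for (f in c("cohort.csv", "features.csv", "truth.csv", "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  co_diff <- generate_cohort(small_cohort_config(seed = 11))
  expect_false(identical(co$truth$teff_hours, co_diff$truth$teff_hours))
})

test_that("clinical covariates respect the published ranges", {
  co <- generate_cohort(cohort_config(seed = 12))
  f <- co$features
  expect_true(all(f$psa >= 0.1 & f$psa <= 2936))
  expect_true(all(f$ldh >= 161 & f$ldh <= 664))
  expect_true(all(f$creatinine >= 0.5 & f$creatinine <= 2.0))
  expect_true(all(f$hemoglobin >= 8.7 & f$hemoglobin <= 15.2))
  expect_true(all(f$organ_condition_class %in% condition_levels()))
  # age and weight constant within patient
  for (p in unique(f$patient_id)) {
    expect_equal(length(unique(f$age[f$patient_id == p])), 1)
  }
})

test_that("the cohort's per-cycle patient counts match the configured attrition", {
  co <- generate_cohort(cohort_config(seed = 13))
  counts <- table(co$features$cycle)
  # 20 complete patients attriting 20/12/6/4, plus 2 missing-cycle1 patients
  # contributing one cycle-2 row each
  expect_equal(as.integer(counts[c("1", "2", "3", "4")]), c(20, 14, 6, 4))
  expect_equal(nrow(co$features), 44)
})

test_that("measurements derived from truth follow the same noise contract", {
  co <- generate_cohort(small_cohort_config(seed = 14))
  m0 <- stp_measurements_from_truth(co, t_sc = c(2, 20), noise_cv = 0)
  d <- lu177_decay()
  tr <- co$truth[1, ]
  p <- biexp_params(tr$A1_MBq, tr$lambda1_bio, tr$A2_MBq, tr$lambda2_bio)
  got <- m0[m0$patient_id == tr$patient_id & m0$cycle == tr$cycle &
              m0$organ == tr$organ, ]
  expect_equal(got$activity_MBq,
               pmax(0, evaluate_biexponential(p, d, c(2, 20))),
               tolerance = 1e-12)
  m1 <- stp_measurements_from_truth(co, seed = 99)
  m2 <- stp_measurements_from_truth(co, seed = 99)
  expect_identical(m1, m2)
})
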