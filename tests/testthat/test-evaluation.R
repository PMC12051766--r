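test_that("RAD matches hand arithmetic and is scale-invariant", {
  expect_equal(rad(1, 1), 0)
  expect_equal(rad(1.27, 1.00), 27, tolerance = 1e-12)
  expect_equal(rad(0.8, 1.0), 20, tolerance = 1e-12)
  expect_equal(rad(0.8, 1.0, signed = TRUE), -20, tolerance = 1e-12)
  expect_error(rad(1, 0), "theta_mtp")
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10); c_ <- runif(1, 0.1, 10)
    expect_equal(rad(c_ * a, c_ * b), rad(a, b), tolerance = 1e-9)
  }
})

test_that("comparison_records joins on keys and drops unmatched or zero references", {
  stp <- data.frame(patient_id = c("a", "a", "b", "c"), cycle = 1L,
                    organ = "liver", t_sc_hours = 20,
                    method = "istp", tia_MBq_h = c(110, 90, 50, 70))
  stp$organ[2] <- "spleen"
  mtp <- data.frame(patient_id = c("a", "a", "b"), cycle = 1L,
                    organ = c("liver", "spleen", "liver"),
                    tia_MBq_h = c(100, 100, 0))
  cmp <- comparison_records(stp, mtp)
  expect_equal(nrow(cmp$records), 2)           # c unmatched, b zero-ref
  expect_equal(cmp$dropped_no_reference, 1)
  expect_equal(cmp$dropped_zero_reference, 1)
  expect_equal(cmp$records$rad_percent, c(10, 10))
})

test_that("timepoint table groups per organ/method/scan time with window flags", {
  d <- lu177_decay()
  # noiseless mono-exponential truth, oracle half-life: iSTP RAD must be 0
  set.seed(12)
  recs <- list()
  for (p in 1:5) {
    teff <- runif(1, 8, 60)
    params <- biexp_params(100, lambda1_from_teff(teff, d))
    true_tia <- closed_form_tia(params, d)
    for (tsc in c(2, 20, 43, 69)) {
      a <- evaluate_biexponential(params, d, tsc)
      m <- stp_measurement(paste0("p", p), 1, "left_kidney", tsc, a)
      recs[[length(recs) + 1L]] <- data.frame(
        patient_id = paste0("p", p), cycle = 1L, organ = "left_kidney",
        t_sc_hours = tsc, method = "istp",
        tia_MBq_h = istp_tia(m, teff)$tia_MBq_h)
      recs[[length(recs) + 1L]] <- data.frame(
        patient_id = paste0("p", p), cycle = 1L, organ = "left_kidney",
        t_sc_hours = tsc, method = "hanscheid",
        tia_MBq_h = hanscheid_tia(m)$tia_MBq_h)
    }
    # Hanscheid scanned exactly at one half-life is exact (checked directly)
    mh <- stp_measurement(paste0("p", p), 1, "left_kidney", teff,
                          evaluate_biexponential(params, d, teff))
    expect_equal(hanscheid_tia(mh)$tia_MBq_h, true_tia, tolerance = 1e-12)
    recs[[length(recs) + 1L]] <- data.frame(
      patient_id = paste0("p", p), cycle = 1L, organ = "left_kidney",
      t_sc_hours = NA, method = "mtp_ref", tia_MBq_h = true_tia)
  }
  all_rec <- do.call(rbind, recs)
  mtp <- all_rec[all_rec$method == "mtp_ref", ]
  stp <- all_rec[all_rec$method != "mtp_ref", ]
  cmp <- comparison_records(stp, mtp)
  expect_true(all(cmp$records$rad_percent[cmp$records$method == "istp"] < 1e-6))

  tab <- timepoint_dependency_table(cmp$records)
  istp_rows <- tab[tab$method == "istp", ]
  expect_equal(nrow(istp_rows), 4)
  expect_equal(istp_rows$n, rep(5, 4))
  expect_true(all(istp_rows$mean_rad < 1e-6))
  # Hanscheid at 2 h is flagged out of method; later scans are in-method
  hans <- tab[tab$method == "hanscheid", ]
  expect_true(hans$out_of_method[hans$t_sc_hours == 2])
  expect_false(hans$out_of_method[hans$t_sc_hours == 43])

  # single-record group reports SD 0 with n = 1
  one <- cmp$records[1, ]
  t1 <- timepoint_dependency_table(one, t_sc_set = one$t_sc_hours)
  expect_equal(t1$sd_rad, 0)
  expect_equal(t1$n, 1)
})

test_that("cycle table respects the 1/2/3/>=4 binning and key checks", {
  expect_equal(as.character(cycle_group(c(1, 2, 3, 4, 5, 9))),
               c("1", "2", "3", ">=4", ">=4", ">=4"))
  a <- data.frame(patient_id = rep(c("p1", "p2"), each = 3),
                  cycle = rep(1:3, 2), organ = "liver",
                  rad_percent = c(10, 12, 14, 11, 13, 15))
  tab <- cycle_dependency_table(a, a)
  expect_equal(sort(unique(tab$cycle_group)), sort(c("1", "2", "3")))
  expect_equal(tab$mean_per_cycle, tab$mean_first_cycle)

  b <- a; b$cycle[6] <- 4L
  expect_error(cycle_dependency_table(a, b), "key mismatch")
})

test_that("signed-rank p-values match exhaustive sign enumeration", {
  set.seed(33)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    x <- round(rnorm(n, 10, 3), 3)
    y <- round(rnorm(n, 10, 3), 3)
    d <- x - y
    if (any(d == 0) || any(duplicated(abs(d)))) next
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, enum_signed_rank_p(x, y), tolerance = 1e-12)
    # symmetry
    expect_equal(wilcoxon_signed_rank(y, x)$p_value, got$p_value,
                 tolerance = 1e-12)
  }
  deg <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("Pratt zero handling gives a finite approximate p", {
  x <- c(5, 7, 3, 9, 4, 6, 8, 2, 10, 5)
  y <- c(5, 6, 4, 7, 4, 5, 6, 3, 8, 5)
  res <- wilcoxon_signed_rank(x, y, zero_method = "pratt")
  expect_equal(res$method, "pratt_normal_approx")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("Mann-Whitney p-values match exhaustive labeling enumeration", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$statistic, 0)               # U for x
  expect_equal(got$p_value, 0.1, tolerance = 1e-12)
  expect_equal(got$p_value, enum_mann_whitney_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  set.seed(44)
  for (i in 1:6) {
    x <- round(rnorm(sample(4:8, 1), 0, 5), 3)
    y <- round(rnorm(sample(4:8, 1), 1, 5), 3)
    if (any(duplicated(c(x, y)))) next
    expect_equal(mann_whitney(x, y)$p_value, enum_mann_whitney_p(x, y),
                 tolerance = 1e-12)
    # shift invariance
    expect_equal(mann_whitney(x + 3.7, y + 3.7)$p_value,
                 mann_whitney(x, y)$p_value, tolerance = 1e-12)
  }
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})
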