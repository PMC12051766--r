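#' Relative absolute difference (percent)
#'
#' The benchmarking metric: `|theta_stp / theta_mtp - 1| * 100`. The
#' reference must be strictly positive; records with a zero reference are
#' excluded upstream rather than producing infinities.
#'
#' @param theta_stp Estimated quantity (TIA or dose) from a
#'   single-time-point method.
#' @param theta_mtp Reference quantity from the multi-time-point fit, > 0.
#' @param signed If `TRUE`, return the signed relative difference instead
#'   (for bias analyses).
#' @return Percent difference(s), vectorized.
#' @export
rad <- function(theta_stp, theta_mtp, signed = FALSE) {
  if (any(theta_mtp <= 0)) stop("undefined reference: theta_mtp must be > 0")
  d <- (theta_stp / theta_mtp - 1) * 100
  if (signed) d else abs(d)
}

#' Match single-time-point results to the multi-time-point reference
#'
#' Joins on (patient_id, cycle, organ), computes the RAD per record, drops
#' records without a reference or with a zero reference, and reports the
#' drops.
#'
#' @param stp Data frame with `patient_id, cycle, organ, t_sc_hours, method`
#'   and the compared value in `value_col`.
#' @param mtp Data frame with `patient_id, cycle, organ` and the reference
#'   value in `ref_col`.
#' @param value_col,ref_col Column names of the compared quantities.
#' @return List: `records` (comparison rows with `theta_stp, theta_mtp,
#'   rad_percent, signed_percent`), `dropped_no_reference`,
#'   `dropped_zero_reference` (counts).
#' @export
comparison_records <- function(stp, mtp, value_col = "tia_MBq_h",
                               ref_col = "tia_MBq_h") {
  key_s <- paste(stp$patient_id, stp$cycle, stp$organ)
  key_m <- paste(mtp$patient_id, mtp$cycle, mtp$organ)
  idx <- match(key_s, key_m)
  no_ref <- is.na(idx)
  rec <- stp[!no_ref, , drop = FALSE]
  ref <- mtp[[ref_col]][idx[!no_ref]]
  zero_ref <- ref <= 0
  rec <- rec[!zero_ref, , drop = FALSE]
  ref <- ref[!zero_ref]
  rec$theta_stp <- rec[[value_col]]
  rec$theta_mtp <- ref
  rec$rad_percent <- rad(rec$theta_stp, rec$theta_mtp)
  rec$signed_percent <- rad(rec$theta_stp, rec$theta_mtp, signed = TRUE)
  list(records = rec,
       dropped_no_reference = sum(no_ref),
       dropped_zero_reference = sum(zero_ref))
}

#' RAD summaries per organ and scan time
#'
#' Groups comparison records by (organ, method, t_sc) over the early scan
#' times and reports mean, SD, and n of the RAD. Hanscheid rows at scan
#' times outside the method's rated window relative to the typical organ
#' half-life (notably 2 h) are flagged `out_of_method` — computed for
#' reference, as in the underlying study design.
#'
#' @param records Comparison records from [comparison_records()].
#' @param t_sc_set Scan times to tabulate (h).
#' @param hanscheid_reference_teff Named per-organ half-life (h) used only
#'   for the out-of-method flag; defaults to the cohort-typical means.
#' @return Data frame `organ, method, t_sc_hours, mean_rad, sd_rad, n,
#'   out_of_method` (single-record groups report SD 0 with n = 1).
#' @export
timepoint_dependency_table <- function(records, t_sc_set = c(2, 20, 43, 69),
                                       hanscheid_reference_teff =
                                         c(left_kidney = 35, right_kidney = 34,
                                           liver = 11, spleen = 9)) {
  rec <- records[records$t_sc_hours %in% t_sc_set, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records at the requested scan times")
  grp <- interaction(rec$organ, rec$method, rec$t_sc_hours, drop = TRUE)
  rows <- lapply(split(rec, grp), function(g) {
    out <- g$method[1] == "hanscheid" &&
      !hanscheid_window_check(g$t_sc_hours[1],
                              hanscheid_reference_teff[[g$organ[1]]])
    data.frame(organ = g$organ[1], method = g$method[1],
               t_sc_hours = g$t_sc_hours[1],
               mean_rad = mean(g$rad_percent),
               sd_rad = if (nrow(g) > 1L) stats::sd(g$rad_percent) else 0,
               n = nrow(g), out_of_method = out,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$organ, res$method, res$t_sc_hours), ]
  rownames(res) <- NULL
  res
}

#' Bin therapy cycles as 1, 2, 3, >=4
#' @param cycle Integer cycle indices.
#' @return Factor with levels `"1", "2", "3", ">=4"`.
#' @export
cycle_group <- function(cycle) {
  factor(ifelse(cycle >= 4, ">=4", as.character(cycle)),
         levels = c("1", "2", "3", ">=4"))
}

#' Per-cycle RAD summaries and cross-scenario comparison
#'
#' Compares a quantity (RAD in dose, or predicted half-life) between the
#' per-cycle and first-cycle-only prediction scenarios, grouped by organ and
#' cycle bin (1, 2, 3, >=4). Both inputs must cover identical
#' (patient, cycle, organ) keys; a mismatch is an error listing offenders.
#' Group comparisons use the unpaired Mann-Whitney test. Empty cycle groups
#' are omitted.
#'
#' @param per_cycle,first_cycle Data frames with `patient_id, cycle, organ`
#'   and the compared value in `value_col`.
#' @param value_col Name of the compared column.
#' @return Data frame `organ, cycle_group, n, mean_per_cycle, sd_per_cycle,
#'   mean_first_cycle, sd_first_cycle, mw_p`.
#' @export
cycle_dependency_table <- function(per_cycle, first_cycle,
                                   value_col = "rad_percent") {
  key_a <- sort(paste(per_cycle$patient_id, per_cycle$cycle, per_cycle$organ))
  key_b <- sort(paste(first_cycle$patient_id, first_cycle$cycle, first_cycle$organ))
  if (!identical(key_a, key_b)) {
    off <- union(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop("key mismatch between scenarios: ",
         paste(utils::head(off, 5), collapse = "; "))
  }
  per_cycle$cycle_group <- cycle_group(per_cycle$cycle)
  first_cycle$cycle_group <- cycle_group(first_cycle$cycle)
  rows <- list()
  for (org in sort(unique(per_cycle$organ))) {
    for (cg in levels(per_cycle$cycle_group)) {
      a <- per_cycle[[value_col]][per_cycle$organ == org &
                                    per_cycle$cycle_group == cg]
      b <- first_cycle[[value_col]][first_cycle$organ == org &
                                      first_cycle$cycle_group == cg]
      if (length(a) == 0L) next
      mw <- if (length(a) >= 1L && length(b) >= 1L &&
                (stats::sd(c(a, b)) > 0)) {
        mann_whitney(a, b)$p_value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, cycle_group = cg, n = length(a),
        mean_per_cycle = mean(a),
        sd_per_cycle = if (length(a) > 1) stats::sd(a) else 0,
        mean_first_cycle = mean(b),
        sd_first_cycle = if (length(b) > 1) stats::sd(b) else 0,
        mw_p = mw, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test; exact null distribution when the retained differences
#' are at most `exact_limit` with no ties, normal approximation (with
#' continuity correction) otherwise. Zero differences are dropped by
#' default; the Pratt variant ranks them with the rest and then discards
#' their rank contribution (normal approximation only).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_limit Largest n for the exact path.
#' @return List: `statistic` (V, sum of positive ranks), `p_value`,
#'   `method`, `degenerate` (TRUE when every difference is zero, in which
#'   case p is 1).
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("drop", "pratt"),
                                 exact_limit = 25L) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  if (zero_method == "drop") {
    nz <- d != 0
    n <- sum(nz)
    use_exact <- n <= exact_limit && !any(duplicated(abs(d[nz])))
    res <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = use_exact,
                         correct = TRUE))
    list(statistic = unname(res$statistic), p_value = res$p.value,
         method = if (use_exact) "exact" else "normal_approx",
         degenerate = FALSE)
  } else {
    # Pratt: rank |d| including zeros, drop zero ranks from the statistic,
    # adjust the null moments accordingly.
    r <- rank(abs(d))
    n <- length(d); n0 <- sum(d == 0)
    W <- sum(r[d > 0])
    E <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
    ties <- table(r[d != 0])
    V <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - E - sign(W - E) * 0.5) / sqrt(V)
    list(statistic = W, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "pratt_normal_approx", degenerate = FALSE)
  }
}

#' Mann-Whitney (Wilcoxon rank-sum) test for unpaired samples
#'
#' Two-sided; exact when both samples are at most `exact_limit` with no
#' ties, normal approximation with continuity and tie correction otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_limit Largest per-group n for the exact path.
#' @return List: `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  use_exact <- length(x) <= exact_limit && length(y) <= exact_limit &&
    !any(duplicated(c(x, y)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}
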