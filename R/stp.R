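#' A single-time-point activity measurement
#'
#' One quantitative SPECT measurement of organ activity at scan time `t_sc`
#' post-injection, the sole input of the single-time-point estimators.
#'
#' @param patient_id Patient identifier.
#' @param cycle Positive integer cycle index.
#' @param organ One of [dosimetry_organs()].
#' @param t_sc_hours Scan time post-injection (h), >= 0 (Hanscheid
#'   additionally requires > 0).
#' @param activity_MBq Measured activity (MBq), >= 0.
#' @return Object of class `stp_measurement`.
#' @export
stp_measurement <- function(patient_id, cycle, organ, t_sc_hours, activity_MBq) {
  organ <- match.arg(organ, dosimetry_organs())
  if (!is.finite(t_sc_hours) || t_sc_hours < 0) stop("t_sc_hours must be >= 0")
  if (!is.finite(activity_MBq) || activity_MBq < 0) stop("activity_MBq must be >= 0")
  structure(list(patient_id = as.character(patient_id), cycle = as.integer(cycle),
                 organ = organ, t_sc_hours = t_sc_hours,
                 activity_MBq = activity_MBq),
            class = "stp_measurement")
}

#' Hanscheid single-time-point TIA estimate
#'
#' The time-integrated activity is approximated from one measurement as
#' \deqn{\tilde A_H = \frac{1}{\ln 2} A(t_{sc}) \cdot 2 t_{sc},}
#' which is exact when the organ clears mono-exponentially and the scan
#' happens exactly one effective half-life after injection. The method is
#' rated for scan times between 0.75 and 2.5 effective half-lives; use
#' [hanscheid_window_check()] to flag scans outside that window (such as the
#' 2 h time point, which this package computes but marks out-of-method).
#'
#' @param m An `stp_measurement`.
#' @param teff_ref Optional reference effective half-life (h) used only to
#'   set the validity-window flag; `NA` if unknown.
#' @return Object of class `stp_result` with fields `tia_MBq_h`, `method`,
#'   and `in_validity_window` (NA when no reference was given).
#' @export
hanscheid_tia <- function(m, teff_ref = NA_real_) {
  stopifnot(inherits(m, "stp_measurement"))
  if (m$t_sc_hours <= 0) stop("Hanscheid estimate requires t_sc > 0")
  tia <- (1 / log(2)) * m$activity_MBq * 2 * m$t_sc_hours
  window <- if (is.na(teff_ref)) NA else {
    hanscheid_window_check(m$t_sc_hours, teff_ref)
  }
  structure(list(patient_id = m$patient_id, cycle = m$cycle, organ = m$organ,
                 t_sc_hours = m$t_sc_hours, tia_MBq_h = tia,
                 method = "hanscheid", a0_MBq = NA_real_,
                 in_validity_window = window),
            class = "stp_result")
}

#' Validity window of the Hanscheid approximation
#'
#' The approximation is rated for scan times within 0.75 to 2.5 times the
#' organ's effective half-life; the interval is treated as closed.
#'
#' @param t_sc Scan time (h), > 0.
#' @param teff_ref Reference effective half-life (h), > 0.
#' @return Logical: is `t_sc / teff_ref` inside `[0.75, 2.5]`?
#' @export
hanscheid_window_check <- function(t_sc, teff_ref) {
  if (any(t_sc <= 0) || any(teff_ref <= 0)) stop("t_sc and teff_ref must be > 0")
  ratio <- t_sc / teff_ref
  ratio >= 0.75 & ratio <= 2.5
}

#' Initial activity reconstructed from a single measurement
#'
#' Mono-exponential back-extrapolation to t = 0 along the predicted
#' effective half-life: `A0 = A(t_sc) * 2^(t_sc / Teff)`.
#'
#' @param m An `stp_measurement`.
#' @param teff_pred Predicted effective half-life (h), > 0.
#' @return Initial activity A0 (MBq).
#' @export
istp_a0 <- function(m, teff_pred) {
  stopifnot(inherits(m, "stp_measurement"))
  if (!is.finite(teff_pred) || teff_pred <= 0) stop("teff_pred must be > 0")
  m$activity_MBq * 2^(m$t_sc_hours / teff_pred)
}

#' Instant single-time-point (iSTP) TIA estimate
#'
#' Characterizes the organ curve by a predicted effective half-life and the
#' initial activity reconstructed by [istp_a0()], then integrates the
#' implied mono-exponential analytically:
#' \deqn{\tilde A_{iSTP} = \int_0^\infty A_0\, e^{-(\ln 2 / T_{eff}) t}\,dt
#'   = A_0 T_{eff} / \ln 2.}
#' Because the reconstruction and the integral use the same single
#' exponential, the estimate is independent of the scan time whenever the
#' predicted half-life equals the true one — the property that frees scan
#' scheduling. The uptake term of the full biexponential model is omitted
#' from the integrand by design (the estimator is defined on a single
#' exponential); [istp_tia_uptake_corrected()] offers a variant that
#' subtracts the population uptake integral.
#'
#' @inheritParams istp_a0
#' @return Object of class `stp_result` with fields `tia_MBq_h`, `a0_MBq`,
#'   `method = "istp"`.
#' @export
istp_tia <- function(m, teff_pred) {
  a0 <- istp_a0(m, teff_pred)
  structure(list(patient_id = m$patient_id, cycle = m$cycle, organ = m$organ,
                 t_sc_hours = m$t_sc_hours,
                 tia_MBq_h = a0 * teff_pred / log(2),
                 method = "istp", a0_MBq = a0,
                 in_validity_window = NA),
            class = "stp_result")
}

#' iSTP estimate with population uptake correction
#'
#' Variant of [istp_tia()] that subtracts the analytic integral of the
#' population uptake term `A2 exp(-(lambda2 + lambda_phys) t)`. Off by
#' default throughout the package; provided for sensitivity analyses.
#'
#' @inheritParams istp_a0
#' @param prior A `population_prior`.
#' @param decay A `physical_decay`.
#' @return An `stp_result` (TIA floored at 0).
#' @export
istp_tia_uptake_corrected <- function(m, teff_pred, prior, decay = lu177_decay()) {
  res <- istp_tia(m, teff_pred)
  pe <- prior_entry(prior, m$organ)
  res$tia_MBq_h <- max(0, res$tia_MBq_h -
                         pe$A2_MBq / (pe$lambda2_per_h + decay$lambda_phys))
  res$method <- "istp_uptake_corrected"
  res
}

#' @export
print.stp_result <- function(x, ...) {
  cat(sprintf("<stp_result> %s c%d %s @ %g h [%s]: TIA=%.1f MBq*h\n",
              x$patient_id, x$cycle, x$organ, x$t_sc_hours, x$method,
              x$tia_MBq_h))
  invisible(x)
}

#' Apply a single-time-point estimator to a table of measurements
#'
#' @param measurements Data frame with columns
#'   `patient_id, cycle, organ, t_sc_hours, activity_MBq`.
#' @param method `"hanscheid"` or `"istp"`.
#' @param teff Data frame of half-lives with columns
#'   `patient_id, cycle, organ, teff_hours`. Required for `"istp"`
#'   (predicted values); optional for `"hanscheid"` (reference values for
#'   the validity-window flag).
#' @return Data frame: one row per measurement with `tia_MBq_h`, `method`,
#'   `a0_MBq`, `in_validity_window`.
#' @export
stp_batch <- function(measurements, method = c("hanscheid", "istp"), teff = NULL) {
  method <- match.arg(method)
  need <- c("patient_id", "cycle", "organ", "t_sc_hours", "activity_MBq")
  missing <- setdiff(need, names(measurements))
  if (length(missing)) stop("measurements missing columns: ",
                            paste(missing, collapse = ", "))
  teff_lookup <- function(p, cy, org) {
    if (is.null(teff)) return(NA_real_)
    i <- which(teff$patient_id == p & teff$cycle == cy & teff$organ == org)
    if (length(i) != 1L) NA_real_ else teff$teff_hours[i]
  }
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    r <- measurements[i, ]
    m <- stp_measurement(r$patient_id, r$cycle, r$organ, r$t_sc_hours,
                         r$activity_MBq)
    th <- teff_lookup(r$patient_id, r$cycle, r$organ)
    res <- if (method == "istp") {
      if (is.na(th)) stop("istp requires a teff entry for (",
                          r$patient_id, ", ", r$cycle, ", ", r$organ, ")")
      istp_tia(m, th)
    } else {
      hanscheid_tia(m, teff_ref = th)
    }
    data.frame(patient_id = res$patient_id, cycle = res$cycle,
               organ = res$organ, t_sc_hours = res$t_sc_hours,
               tia_MBq_h = res$tia_MBq_h, method = res$method,
               a0_MBq = res$a0_MBq,
               in_validity_window = res$in_validity_window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
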