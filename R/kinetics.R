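#' Physical decay description of an isotope
#'
#' Bundles an isotope's physical half-life (hours) with the derived decay
#' constant. All kinetic computations in the package take one of these so the
#' unit convention (hours) is fixed in a single place.
#'
#' @param half_life_hours Positive physical half-life in hours.
#' @return An object of class `physical_decay` with fields `half_life_hours`
#'   and `lambda_phys` (1/h).
#' @examples
#' physical_decay(159.6)          # Lu-177
#' lu177_decay()$lambda_phys
#' @export
physical_decay <- function(half_life_hours) {
  if (!is.numeric(half_life_hours) || length(half_life_hours) != 1L ||
      !is.finite(half_life_hours) || half_life_hours <= 0) {
    stop("half_life_hours must be a single positive finite number (hours)")
  }
  structure(
    list(half_life_hours = half_life_hours,
         lambda_phys = log(2) / half_life_hours),
    class = "physical_decay"
  )
}

#' Lu-177 physical decay (6.65 d = 159.6 h)
#'
#' The therapy isotope's half-life, converted once from days to hours and
#' reused everywhere.
#'
#' @return A `physical_decay` object.
#' @export
lu177_decay <- function() physical_decay(6.65 * 24)

#' Organs supported for dosimetric analysis
#' @return Character vector of organ identifiers.
#' @export
dosimetry_organs <- function() {
  c("left_kidney", "right_kidney", "liver", "spleen")
}

#' Organs segmented on pretherapy PET (dosimetry organs + urinary bladder)
#' @return Character vector of organ identifiers.
#' @export
pet_organs <- function() c(dosimetry_organs(), "urinary_bladder")

#' Biexponential time-activity model parameters
#'
#' Organ kinetics are modeled as a washout term minus an uptake term, each
#' decaying with its biological rate plus the physical rate:
#' \deqn{A(t) = A_1 e^{-(\lambda_1+\lambda_{phys})t} -
#'       A_2 e^{-(\lambda_2+\lambda_{phys})t}.}
#'
#' @param A1_MBq Amplitude of the washout term (MBq), > 0.
#' @param lambda1_bio Biological rate of the washout term (1/h), >= 0.
#' @param A2_MBq Amplitude of the uptake term (MBq), >= 0.
#' @param lambda2_bio Biological rate of the uptake term (1/h), >= 0.
#' @return An object of class `biexp_params`.
#' @export
biexp_params <- function(A1_MBq, lambda1_bio, A2_MBq = 0, lambda2_bio = 0) {
  stopifnot(is.numeric(A1_MBq), is.numeric(lambda1_bio),
            is.numeric(A2_MBq), is.numeric(lambda2_bio))
  if (A1_MBq <= 0) stop("A1_MBq must be > 0")
  if (A2_MBq < 0) stop("A2_MBq must be >= 0")
  if (lambda1_bio < 0) stop("lambda1_bio must be >= 0")
  if (lambda2_bio < 0) stop("lambda2_bio must be >= 0")
  structure(
    list(A1_MBq = A1_MBq, lambda1_bio = lambda1_bio,
         A2_MBq = A2_MBq, lambda2_bio = lambda2_bio),
    class = "biexp_params"
  )
}

#' Evaluate the biexponential model at given times
#'
#' Returns the signed model value; it can be negative near t = 0 during the
#' uptake phase when `A2 > A1`. Clamping to physical (non-negative) activity
#' is deliberately left to the caller; the synthetic generator clamps, the
#' fitting machinery does not.
#'
#' @param params A `biexp_params` object.
#' @param decay A `physical_decay` object.
#' @param t Vector of times post-injection (h), all >= 0.
#' @return Activity in MBq, same length as `t`.
#' @export
evaluate_biexponential <- function(params, decay, t) {
  stopifnot(inherits(params, "biexp_params"), inherits(decay, "physical_decay"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  lp <- decay$lambda_phys
  params$A1_MBq * exp(-(params$lambda1_bio + lp) * t) -
    params$A2_MBq * exp(-(params$lambda2_bio + lp) * t)
}

#' Effective half-life from a biological washout rate
#'
#' The effective rate is the sum of biological and physical rates; the
#' effective half-life is `ln 2` over that sum.
#'
#' @param lambda1_bio Biological washout rate (1/h).
#' @param decay A `physical_decay` object.
#' @return Effective half-life in hours.
#' @export
teff_from_rates <- function(lambda1_bio, decay) {
  stopifnot(inherits(decay, "physical_decay"))
  rate <- lambda1_bio + decay$lambda_phys
  if (any(rate <= 0)) stop("effective rate lambda1_bio + lambda_phys must be > 0")
  log(2) / rate
}

#' Biological washout rate implied by an effective half-life
#'
#' Inverse of [teff_from_rates()]; used by the synthetic generator to
#' back-solve `lambda1` from a drawn effective half-life.
#'
#' @param teff_hours Effective half-life (h), must not exceed the physical
#'   half-life (biological rates are non-negative).
#' @param decay A `physical_decay` object.
#' @return Biological rate (1/h), >= 0.
#' @export
lambda1_from_teff <- function(teff_hours, decay) {
  stopifnot(inherits(decay, "physical_decay"))
  if (any(teff_hours <= 0)) stop("teff_hours must be > 0")
  lam <- log(2) / teff_hours - decay$lambda_phys
  if (any(lam < -1e-12)) {
    stop("teff_hours exceeds the physical half-life; biological rate would be negative")
  }
  pmax(lam, 0)
}

#' Closed-form time-integrated activity of the biexponential model
#'
#' Analytic value of the integral of the model over `[0, Inf)`:
#' `A1 * Teff / ln2 - A2 / (lambda2 + lambda_phys)`, with
#' `Teff = ln2 / (lambda1 + lambda_phys)`.
#'
#' @inheritParams evaluate_biexponential
#' @return Time-integrated activity (MBq*h).
#' @seealso [numeric_tia()] for the quadrature cross-check.
#' @export
closed_form_tia <- function(params, decay) {
  stopifnot(inherits(params, "biexp_params"), inherits(decay, "physical_decay"))
  lp <- decay$lambda_phys
  r1 <- params$lambda1_bio + lp
  r2 <- params$lambda2_bio + lp
  if (r1 <= 0 || (params$A2_MBq > 0 && r2 <= 0)) {
    stop("divergent integral: effective rates must be > 0")
  }
  params$A1_MBq / r1 - if (params$A2_MBq > 0) params$A2_MBq / r2 else 0
}

#' Time-integrated activity by adaptive quadrature
#'
#' Independent numerical evaluation of the same integral as
#' [closed_form_tia()], via [stats::integrate()] on `[0, Inf)` (which maps the
#' semi-infinite domain through a rational transform internally). Serves as the
#' oracle for the closed form; the two must agree to `rel_tol`.
#'
#' @inheritParams evaluate_biexponential
#' @param rel_tol Requested relative accuracy (default 1e-8).
#' @return Time-integrated activity (MBq*h).
#' @export
numeric_tia <- function(params, decay, rel_tol = 1e-8) {
  stopifnot(inherits(params, "biexp_params"), inherits(decay, "physical_decay"))
  lp <- decay$lambda_phys
  if (params$lambda1_bio + lp <= 0 ||
      (params$A2_MBq > 0 && params$lambda2_bio + lp <= 0)) {
    stop("divergent integral: effective rates must be > 0")
  }
  res <- stats::integrate(
    function(t) evaluate_biexponential(params, decay, t),
    lower = 0, upper = Inf, rel.tol = rel_tol, abs.tol = 0,
    subdivisions = 500L
  )
  if (res$message != "OK") {
    stop("quadrature failed: ", res$message,
         " (abs.error=", format(res$abs.error), ")")
  }
  res$value
}
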