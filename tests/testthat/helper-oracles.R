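# Brute-force enumeration oracles for the nonparametric tests, independent
# of the implementation under test.

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
# Assumes no zero differences and no ties in |d|.
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.vector(signs %*% r)
  p_le <- mean(dist <= W)
  p_ge <- mean(dist >= W)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Mann-Whitney p by enumerating all C(n+m, n) labelings.
# Assumes no ties across the pooled sample.
enum_mann_whitney_p <- function(x, y) {
  stopifnot(!any(duplicated(c(x, y))))
  n <- length(x); m <- length(y)
  pooled_ranks <- rank(c(x, y))
  U_obs <- sum(pooled_ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  all_ranks <- rank(c(x, y))
  dist <- apply(combos, 2, function(idx) sum(all_ranks[idx]) - n * (n + 1) / 2)
  p_le <- mean(dist <= U_obs)
  p_ge <- mean(dist >= U_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small cohort configuration used by the scenario tests (fast).
small_cohort_config <- function(seed = 1L) {
  cohort_config(n_patients = 10L,
                cycles_per_patient_counts = c(4L, 3L, 1L, 2L),
                n_missing_cycle1 = 1L,
                seed = seed)
}

# Noiseless mono-exponential curve in the model class of the fitter when
# paired with a zero-uptake prior.
mono_curve <- function(A1 = 10, teff = 35, times = c(2, 20, 43, 69, 144),
                       decay = lu177_decay(), organ = "left_kidney",
                       patient = "p1", cycle = 1L) {
  params <- biexp_params(A1, lambda1_from_teff(teff, decay))
  time_activity_curve(patient, cycle, organ, times,
                      pmax(0, evaluate_biexponential(params, decay, times)))
}

zero_uptake_prior <- function() {
  population_prior(dosimetry_organs(), A2_MBq = rep(0, 4),
                   lambda2_per_h = rep(0, 4))
}
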