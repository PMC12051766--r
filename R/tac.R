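#' Time-activity curve for one organ in one therapy cycle
#'
#' Holds the sampled organ activity versus time post-injection for a single
#' (patient, cycle, organ) combination. Times must be strictly increasing and
#' non-negative; activities non-negative. A curve needs at least one sample
#' to exist; multi-time-point fitting additionally requires three.
#'
#' @param patient_id Patient identifier (coerced to character).
#' @param cycle Positive integer therapy cycle index.
#' @param organ One of [dosimetry_organs()].
#' @param t_hours Numeric vector of sample times post-injection (h).
#' @param activity_MBq Numeric vector of measured activities (MBq).
#' @return An object of class `time_activity_curve`.
#' @export
time_activity_curve <- function(patient_id, cycle, organ, t_hours, activity_MBq) {
  cycle <- as.integer(cycle)
  if (is.na(cycle) || cycle < 1L) stop("cycle must be a positive integer")
  organ <- match.arg(organ, dosimetry_organs())
  if (length(t_hours) != length(activity_MBq)) {
    stop("t_hours and activity_MBq must have equal length")
  }
  if (length(t_hours) < 1L) stop("a curve needs at least one sample")
  if (any(!is.finite(t_hours)) || any(t_hours < 0)) stop("times must be finite and >= 0")
  if (any(diff(t_hours) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(activity_MBq)) || any(activity_MBq < 0)) {
    stop("activities must be finite and >= 0")
  }
  structure(
    list(patient_id = as.character(patient_id), cycle = cycle, organ = organ,
         t_hours = as.numeric(t_hours), activity_MBq = as.numeric(activity_MBq)),
    class = "time_activity_curve"
  )
}

#' @export
print.time_activity_curve <- function(x, ...) {
  cat(sprintf("<time_activity_curve> patient %s, cycle %d, %s: %d samples over [%g, %g] h\n",
              x$patient_id, x$cycle, x$organ, length(x$t_hours),
              min(x$t_hours), max(x$t_hours)))
  invisible(x)
}

#' Read a cohort of time-activity curves from CSV
#'
#' Expected columns: `patient_id, cycle, organ, t_hours, activity_MBq`, one
#' row per sample. Lines starting with `#` are treated as comments
#' (provenance headers written by this package).
#'
#' @param path Path to the cohort CSV.
#' @return A list of `time_activity_curve` objects, one per
#'   (patient, cycle, organ).
#' @export
read_cohort_csv <- function(path) {
  df <- read_table_csv(path,
    required = c("patient_id", "cycle", "organ", "t_hours", "activity_MBq"))
  cohort_from_samples(df)
}

#' Build curves from a long sample table
#'
#' @param df Data frame with columns
#'   `patient_id, cycle, organ, t_hours, activity_MBq`.
#' @return List of `time_activity_curve` objects.
#' @export
cohort_from_samples <- function(df) {
  key <- interaction(df$patient_id, df$cycle, df$organ, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$t_hours), , drop = FALSE]
    time_activity_curve(g$patient_id[1], g$cycle[1], g$organ[1],
                        g$t_hours, g$activity_MBq)
  })
}

#' Flatten curves to a long sample table
#'
#' @param curves List of `time_activity_curve` objects.
#' @return Data frame with one row per sample.
#' @export
cohort_to_samples <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(patient_id = cv$patient_id, cycle = cv$cycle, organ = cv$organ,
               t_hours = cv$t_hours, activity_MBq = cv$activity_MBq,
               stringsAsFactors = FALSE)
  }))
}

# Shared CSV reader: '#' comment lines allowed, header required.
read_table_csv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  df
}
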