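#' Known organ-condition categories
#'
#' The categorical clinical evaluation of organ condition is one-hot encoded
#' against this explicit list; unknown categories are rejected rather than
#' silently absorbed.
#'
#' @return Character vector of category labels.
#' @export
condition_levels <- function() c("normal", "mild_impairment", "impaired")

feature_numeric_cols <- function() {
  c("age", "weight", "psa", "ldh", "creatinine", "hemoglobin",
    "suv_left_kidney", "suv_right_kidney", "suv_liver", "suv_spleen",
    "suv_urinary_bladder", "injected_pet_activity_MBq", "cycle")
}

#' Assemble the per-organ feature matrix and aligned target vector
#'
#' One row per patient cycle; columns are the pretherapy features (basic
#' patient characteristics, clinical labs, per-organ PET SUV_mean including
#' the urinary tract, injected PET activity, cycle index) with the
#' organ-condition category one-hot encoded. Missing numeric entries are
#' median-imputed (median of the supplied rows) with an imputation log.
#'
#' @param features Data frame of feature rows (schema of
#'   [generate_features()]).
#' @param targets Data frame `patient_id, cycle, teff_hours` — the measured
#'   effective half-life of the organ this matrix is built for.
#' @return List: `X` (numeric matrix), `y` (targets aligned to rows), `ids`
#'   (data frame `patient_id, cycle`), `imputed` (data frame log, possibly
#'   empty).
#' @export
build_feature_matrix <- function(features, targets) {
  if (anyDuplicated(paste(features$patient_id, features$cycle))) {
    stop("duplicated (patient_id, cycle) in feature rows")
  }
  key_f <- paste(features$patient_id, features$cycle)
  key_t <- paste(targets$patient_id, targets$cycle)
  idx <- match(key_f, key_t)
  if (anyNA(idx)) {
    stop("missing target for feature rows: ",
         paste(utils::head(key_f[is.na(idx)], 5), collapse = "; "))
  }
  y <- targets$teff_hours[idx]

  num_cols <- intersect(feature_numeric_cols(), names(features))
  X <- as.matrix(features[, num_cols, drop = FALSE])
  mode(X) <- "numeric"

  imputed <- list()
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (all(nas)) stop("feature column entirely missing: ", colnames(X)[j])
    if (any(nas)) {
      med <- stats::median(X[, j], na.rm = TRUE)
      X[nas, j] <- med
      imputed[[length(imputed) + 1L]] <- data.frame(
        column = colnames(X)[j], n_imputed = sum(nas), value = med,
        stringsAsFactors = FALSE)
    }
  }

  if ("organ_condition_class" %in% names(features)) {
    cls <- features$organ_condition_class
    unknown <- setdiff(unique(cls), condition_levels())
    if (length(unknown)) stop("unknown organ-condition categories: ",
                              paste(unknown, collapse = ", "))
    onehot <- sapply(condition_levels(),
                     function(lv) as.numeric(cls == lv))
    colnames(onehot) <- paste0("condition_", condition_levels())
    X <- cbind(X, onehot)
  }

  list(X = X, y = y,
       ids = data.frame(patient_id = features$patient_id,
                        cycle = features$cycle, stringsAsFactors = FALSE),
       imputed = if (length(imputed)) do.call(rbind, imputed) else
         data.frame(column = character(), n_imputed = integer(),
                    value = numeric(), stringsAsFactors = FALSE))
}

#' Support-vector-regression configuration
#'
#' RBF-kernel epsilon-regression with feature standardization (zero mean,
#' unit variance, fit on training rows only). `gamma = NULL` uses the scale
#' heuristic `1 / (p * var(standardized X)) = 1/p`.
#'
#' @param C Regularization weight, > 0.
#' @param epsilon Insensitive-tube half-width, >= 0.
#' @param gamma RBF kernel width, > 0, or `NULL` for the scale heuristic.
#' @param teff_floor Predictions are clamped below at this half-life (h).
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(C = 10, epsilon = 0.1, gamma = NULL, teff_floor = 1) {
  stopifnot(C > 0, epsilon >= 0, is.null(gamma) || gamma > 0, teff_floor > 0)
  structure(list(C = C, epsilon = epsilon, gamma = gamma,
                 teff_floor = teff_floor),
            class = "svr_config")
}

#' Default hyperparameter grid
#'
#' @return Data frame over `C`, `epsilon`, `gamma` (NA = scale heuristic).
#' @export
default_svr_grid <- function() {
  expand.grid(C = c(1, 10, 100), epsilon = c(0.5, 2), gamma = c(NA, 0.05),
              KEEP.OUT.ATTRS = FALSE)
}

#' Train an RBF-kernel support vector regressor
#'
#' Standardizes features on the supplied rows (zero-variance columns are
#' dropped and logged in the model object), then fits epsilon-SVR with an
#' RBF kernel. The scaler travels with the model so that prediction on new
#' rows reuses the training-fold statistics — the pipeline never rescales on
#' validation data.
#'
#' @param X Numeric feature matrix (rows >= 2).
#' @param y Positive targets (effective half-life, h).
#' @param cfg An `svr_config`.
#' @return Object of class `teff_svr`.
#' @export
train_svr <- function(X, y, cfg = svr_config()) {
  stopifnot(inherits(cfg, "svr_config"), nrow(X) >= 2L, all(y > 0))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- which(scl > 0)
  if (length(keep) == 0L) stop("all feature columns are constant")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  gamma <- cfg$gamma %||% (1 / ncol(Xs))
  fit <- e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                    cost = cfg$C, epsilon = cfg$epsilon, gamma = gamma,
                    scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, center = ctr[keep], scale = scl[keep],
                 keep = keep, dropped = colnames(X)[-keep],
                 cfg = cfg, gamma = gamma),
            class = "teff_svr")
}

#' Predict effective half-lives with a fitted SVR
#'
#' @param object A `teff_svr`.
#' @param newdata Numeric matrix with the training-time columns.
#' @param ... Unused.
#' @return Numeric predictions (h), clamped at the configured floor.
#' @export
predict.teff_svr <- function(object, newdata, ...) {
  Xs <- sweep(sweep(newdata[, object$keep, drop = FALSE], 2, object$center),
              2, object$scale, "/")
  raw <- if (object$fit$tot.nSV == 0L) {
    # every training point sits inside the epsilon tube: the SVR is the
    # constant -rho (libsvm's intercept) with no support vectors
    rep(-object$fit$rho, nrow(Xs))
  } else {
    as.numeric(stats::predict(object$fit, Xs))
  }
  pmax(raw, object$cfg$teff_floor)
}

mape <- function(pred, truth) mean(abs(pred / truth - 1)) * 100
signed_mpe <- function(pred, truth) mean(pred / truth - 1) * 100

make_folds <- function(n, k, ids = NULL, grouping = "plain") {
  if (grouping == "by_patient") {
    pats <- unique(ids$patient_id)
    fold_of_patient <- stats::setNames(
      sample(rep(seq_len(k), length.out = length(pats))), pats)
    as.integer(fold_of_patient[ids$patient_id])
  } else {
    sample(rep(seq_len(k), length.out = n))
  }
}

#' Grid search for SVR hyperparameters by inner cross-validation
#'
#' Selects the grid point minimizing inner-CV mean absolute percentage
#' error. Ties are broken toward smaller `C`, then larger `epsilon`
#' (stronger regularization). Fully deterministic given the seed.
#'
#' @param X,y Training matrix and targets.
#' @param grid Data frame with columns `C, epsilon, gamma` (NA gamma = scale
#'   heuristic).
#' @param inner_k Inner fold count (capped at `nrow(X)`).
#' @param seed Integer seed for the inner fold assignment.
#' @param teff_floor Passed through to the selected config.
#' @return The selected `svr_config`.
#' @export
optimize_hyperparameters <- function(X, y, grid = default_svr_grid(),
                                     inner_k = 5L, seed = 1L, teff_floor = 1) {
  stopifnot(nrow(grid) >= 1L)
  if (nrow(grid) == 1L) {
    g <- grid[1, ]
    return(svr_config(g$C, g$epsilon,
                      if (is.na(g$gamma)) NULL else g$gamma, teff_floor))
  }
  k <- min(inner_k, nrow(X))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  folds <- make_folds(nrow(X), k)
  score <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- svr_config(g$C, g$epsilon,
                      if (is.na(g$gamma)) NULL else g$gamma, teff_floor)
    errs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (sum(tr) < 2L || sum(!tr) < 1L) return(NA_real_)
      model <- train_svr(X[tr, , drop = FALSE], y[tr], cfg)
      mape(predict(model, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  # order: best score, then smaller C, then larger epsilon
  best <- order(score, grid$C, -grid$epsilon)[1]
  g <- grid[best, ]
  svr_config(g$C, g$epsilon, if (is.na(g$gamma)) NULL else g$gamma, teff_floor)
}

#' k-fold cross-validation of the half-life predictor
#'
#' Partitions the patient cycles into `k` folds (sizes differing by at most
#' one), and for each fold trains on the remainder and predicts the held-out
#' rows. Standardization and (optional) hyperparameter search happen
#' strictly inside the training folds — there is no leakage path from
#' validation rows into scaling or model selection. The per-fold error is
#' the mean absolute percentage error between predicted and measured
#' half-life; the report carries the mean and SD across folds plus the
#' signed bias.
#'
#' @param features,targets As in [build_feature_matrix()].
#' @param k Fold count (default 10); requires `nrow >= k`.
#' @param grouping `"plain"` row-level folds (default) or `"by_patient"`
#'   (all cycles of a patient share a fold, preventing cross-cycle leakage).
#' @param seed Integer seed controlling fold assignment (and the inner
#'   search, when used).
#' @param cfg An `svr_config` used as-is, or `NULL` to run
#'   [optimize_hyperparameters()] inside every training fold.
#' @param grid Grid for the inner search when `cfg` is `NULL`.
#' @param predict_fn Optional override of the learner, for diagnostics:
#'   `function(X, y, train_idx, val_idx)` returning predictions for
#'   `val_idx`. When supplied, `cfg`/`grid` are ignored.
#' @return Object of class `cv_report`: `k`, `fold_mape`, `me_mean`,
#'   `me_sd`, `bias_mean`, `predictions` (data frame with ids, truth,
#'   prediction, fold), `fold_assignment`, `seed`.
#' @export
kfold_validate <- function(features, targets, k = 10L,
                           grouping = c("plain", "by_patient"),
                           seed = 1L, cfg = NULL, grid = default_svr_grid(),
                           predict_fn = NULL) {
  grouping <- match.arg(grouping)
  fm <- build_feature_matrix(features, targets)
  n <- nrow(fm$X)
  if (n < k) stop("need at least k = ", k, " rows, got ", n,
                  "; use a smaller k")
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  folds <- make_folds(n, k, fm$ids, grouping)

  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (length(va) == 0L) next
    if (!is.null(predict_fn)) {
      pred[va] <- predict_fn(fm$X, fm$y, tr, va)
    } else {
      use_cfg <- cfg %||% optimize_hyperparameters(
        fm$X[tr, , drop = FALSE], fm$y[tr], grid = grid,
        seed = seed + f)
      model <- train_svr(fm$X[tr, , drop = FALSE], fm$y[tr], use_cfg)
      pred[va] <- predict(model, fm$X[va, , drop = FALSE])
    }
  }
  fold_mape <- vapply(seq_len(k), function(f) {
    va <- folds == f
    if (!any(va)) NA_real_ else mape(pred[va], fm$y[va])
  }, numeric(1))
  structure(list(
    k = k,
    fold_mape = fold_mape,
    me_mean = mean(fold_mape, na.rm = TRUE),
    me_sd = stats::sd(fold_mape, na.rm = TRUE),
    bias_mean = signed_mpe(pred, fm$y),
    predictions = data.frame(fm$ids, teff_true = fm$y, teff_pred = pred,
                             fold = folds, stringsAsFactors = FALSE),
    fold_assignment = folds, seed = seed, grouping = grouping),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> k=%d (%s folds): ME %.1f%% +/- %.1f%% (bias %+.1f%%)\n",
              x$k, x$grouping, x$me_mean, x$me_sd, x$bias_mean))
  invisible(x)
}

#' Substitute first-cycle features for all cycles of each patient
#'
#' Implements the single-pretherapy-scan workflow: every cycle of a patient
#' reuses the patient's cycle-1 feature row (the `cycle` column keeps the
#' actual cycle index). Patients without a cycle-1 row cannot enter this
#' mode; their rows are excluded and logged.
#'
#' @param features Feature data frame.
#' @return List: `features` (substituted rows), `excluded` (data frame of
#'   dropped rows with reasons).
#' @export
substitute_first_cycle_features <- function(features) {
  first <- features[features$cycle == 1L, , drop = FALSE]
  has1 <- features$patient_id %in% first$patient_id
  excluded <- features[!has1, c("patient_id", "cycle"), drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "no cycle-1 feature row"
  kept <- features[has1, , drop = FALSE]
  sub <- first[match(kept$patient_id, first$patient_id), , drop = FALSE]
  sub$cycle <- kept$cycle
  rownames(sub) <- NULL
  list(features = sub, excluded = excluded)
}

#' Predict half-lives for feature rows with a fitted model
#'
#' @param model A `teff_svr`.
#' @param features Feature rows.
#' @param mode `"per_cycle"` uses each cycle's own features;
#'   `"first_cycle_only"` substitutes cycle-1 features for every cycle
#'   (patients lacking cycle 1 are excluded and reported).
#' @return List: `predictions` (data frame `patient_id, cycle,
#'   teff_pred_hours`), `excluded` (data frame, empty in per_cycle mode).
#' @export
predict_teff <- function(model, features, mode = c("per_cycle", "first_cycle_only")) {
  mode <- match.arg(mode)
  excluded <- data.frame(patient_id = character(), cycle = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  if (mode == "first_cycle_only") {
    sub <- substitute_first_cycle_features(features)
    features <- sub$features
    excluded <- sub$excluded
  }
  dummy_targets <- data.frame(patient_id = features$patient_id,
                              cycle = features$cycle,
                              teff_hours = 1, stringsAsFactors = FALSE)
  fm <- build_feature_matrix(features, dummy_targets)
  list(predictions = data.frame(fm$ids,
                                teff_pred_hours = predict(model, fm$X),
                                stringsAsFactors = FALSE),
       excluded = excluded)
}
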