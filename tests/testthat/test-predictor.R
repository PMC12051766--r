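make_feature_fixture <- function(n = 30, seed = 1) {
  set.seed(seed)
  teff <- exp(runif(n, log(7), log(65)))
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)), cycle = 1L,
    age = round(rnorm(n, 69, 9)), weight = rnorm(n, 82, 10),
    psa = exp(rnorm(n, 5, 1)), ldh = rnorm(n, 300, 60),
    creatinine = rnorm(n, 1, 0.2), hemoglobin = rnorm(n, 11, 1),
    suv_left_kidney = 1.3 + 3 * log(teff) + rnorm(n, 0, 0.2),
    suv_right_kidney = 1.3 + 3 * log(teff) + rnorm(n, 0, 0.2),
    suv_liver = rnorm(n, 6, 1), suv_spleen = rnorm(n, 7, 1),
    suv_urinary_bladder = 25 - 3.5 * log(teff) + rnorm(n, 0, 0.5),
    organ_condition_class = sample(condition_levels(), n, replace = TRUE),
    injected_pet_activity_MBq = rnorm(n, 119, 25),
    teff = teff,
    stringsAsFactors = FALSE)
}

targets_of <- function(feat) {
  data.frame(patient_id = feat$patient_id, cycle = feat$cycle,
             teff_hours = feat$teff, stringsAsFactors = FALSE)
}

test_that("feature matrix has the schema-fixed shape and one-hot encoding", {
  feat <- make_feature_fixture(5)
  fm <- build_feature_matrix(feat, targets_of(feat))
  expect_equal(nrow(fm$X), 5)
  expect_equal(ncol(fm$X), 13 + 3)  # numeric schema + 3 condition levels
  expect_true(all(paste0("condition_", condition_levels()) %in% colnames(fm$X)))
  expect_equal(rowSums(fm$X[, paste0("condition_", condition_levels())]),
               rep(1, 5), ignore_attr = TRUE)
  expect_equal(fm$y, feat$teff)

  dup <- rbind(feat, feat[1, ])
  expect_error(build_feature_matrix(dup, targets_of(dup)), "duplicated")

  bad <- feat; bad$organ_condition_class[2] <- "excellent"
  expect_error(build_feature_matrix(bad, targets_of(bad)), "unknown organ-condition")
})

test_that("missing numeric entries are median-imputed and logged", {
  feat <- make_feature_fixture(7)
  feat$ldh[3] <- NA
  fm <- build_feature_matrix(feat, targets_of(feat))
  expect_equal(fm$X[3, "ldh"], median(feat$ldh, na.rm = TRUE),
               ignore_attr = TRUE)
  expect_equal(fm$imputed$column, "ldh")
  expect_equal(fm$imputed$n_imputed, 1L)

  feat$creatinine <- NA
  expect_error(build_feature_matrix(feat, targets_of(feat)),
               "entirely missing")
})

test_that("SVR fits a flat function exactly inside the epsilon tube", {
  feat <- make_feature_fixture(12)
  fm <- build_feature_matrix(feat, targets_of(feat))
  y_const <- rep(20, 12)
  model <- train_svr(fm$X, y_const, svr_config(C = 10, epsilon = 0.5))
  expect_equal(predict(model, fm$X), rep(20, 12), tolerance = 1e-8)
})

test_that("SVR training is invariant to row permutation and deterministic", {
  feat <- make_feature_fixture(25)
  fm <- build_feature_matrix(feat, targets_of(feat))
  model <- train_svr(fm$X, fm$y)
  set.seed(3)
  perm <- sample(25)
  model_p <- train_svr(fm$X[perm, ], fm$y[perm])
  expect_equal(predict(model, fm$X), predict(model_p, fm$X), tolerance = 1e-8)
  expect_identical(predict(model, fm$X),
                   predict(train_svr(fm$X, fm$y), fm$X))
})

test_that("SVR learns a strong single-feature link to within 10% training error", {
  set.seed(6)
  n <- 80
  teff <- exp(runif(n, log(7), log(65)))
  X <- cbind(suv = 1.3 + 3 * log(teff))
  model <- train_svr(X, teff, svr_config(C = 100, epsilon = 0.5))
  pred <- predict(model, X)
  expect_lt(mean(abs(pred / teff - 1)) * 100, 10)
})

test_that("zero-variance columns are dropped, not fatal", {
  set.seed(9)
  X <- cbind(a = rnorm(20), b = rep(5, 20))
  y <- 10 + 2 * X[, "a"] + rnorm(20, 0, 0.1)
  model <- train_svr(X, pmax(y, 1))
  expect_equal(model$dropped, "b")
  expect_length(predict(model, X), 20)
})

test_that("hyperparameter search honors the grid and is deterministic", {
  feat <- make_feature_fixture(40, seed = 2)
  fm <- build_feature_matrix(feat, targets_of(feat))

  single <- data.frame(C = 7, epsilon = 0.3, gamma = NA)
  cfg <- optimize_hyperparameters(fm$X, fm$y, grid = single)
  expect_equal(cfg$C, 7)
  expect_equal(cfg$epsilon, 0.3)
  expect_null(cfg$gamma)

  # a sensible config must beat a clearly degenerate one
  grid <- data.frame(C = c(10, 1e-4), epsilon = c(0.5, 50), gamma = c(NA, NA))
  best <- optimize_hyperparameters(fm$X, fm$y, grid = grid, seed = 5)
  expect_equal(best$C, 10)

  a <- optimize_hyperparameters(fm$X, fm$y, seed = 11)
  b <- optimize_hyperparameters(fm$X, fm$y, seed = 11)
  expect_identical(a, b)
})

test_that("k-fold partition is balanced and exhaustive", {
  feat <- make_feature_fixture(23)
  rep <- kfold_validate(feat, targets_of(feat), k = 10, seed = 4,
                        cfg = svr_config())
  sizes <- table(rep$fold_assignment)
  expect_equal(length(sizes), 10L)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 23)
  expect_false(anyNA(rep$predictions$teff_pred))
})

test_that("fold error is the mean absolute percentage error", {
  feat <- make_feature_fixture(2)
  targ <- targets_of(feat)
  targ$teff_hours <- c(10, 10)
  rep <- kfold_validate(feat, targ, k = 1, seed = 1,
                        predict_fn = function(X, y, tr, va) c(12, 8)[va])
  expect_equal(rep$fold_mape, 20)
})

test_that("an oracle predictor scores zero error in every fold", {
  feat <- make_feature_fixture(30)
  rep <- kfold_validate(feat, targets_of(feat), k = 10, seed = 2,
                        predict_fn = function(X, y, tr, va) y[va])
  expect_equal(rep$fold_mape, rep(0, 10))
  expect_equal(rep$me_mean, 0)
})

test_that("cross-validation reports are reproducible and leakage-safe by construction", {
  feat <- make_feature_fixture(30)
  a <- kfold_validate(feat, targets_of(feat), k = 5, seed = 7, cfg = svr_config())
  b <- kfold_validate(feat, targets_of(feat), k = 5, seed = 7, cfg = svr_config())
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$fold_mape, b$fold_mape)

  # by_patient grouping keeps all cycles of a patient in one fold
  feat2 <- rbind(make_feature_fixture(12),
                 transform(make_feature_fixture(12), cycle = 2L))
  g <- kfold_validate(feat2, targets_of(feat2), k = 4, seed = 3,
                      grouping = "by_patient", cfg = svr_config())
  pf <- tapply(g$fold_assignment, feat2$patient_id, function(f) length(unique(f)))
  expect_true(all(pf == 1))

  # validation rows do not influence the training-fold scaler: a fold's
  # predictions are unchanged when the held-out rows are replaced
  fm <- build_feature_matrix(feat, targets_of(feat))
  set.seed(7); folds <- sample(rep(1:5, length.out = 30))
  tr <- which(folds != 1); va <- which(folds == 1)
  m1 <- train_svr(fm$X[tr, ], fm$y[tr], svr_config())
  X_alt <- fm$X; X_alt[va, ] <- X_alt[va, ] * 100
  m2 <- train_svr(X_alt[tr, ], fm$y[tr], svr_config())
  expect_identical(predict(m1, fm$X[va, , drop = FALSE]),
                   predict(m2, fm$X[va, , drop = FALSE]))
})

test_that("first-cycle-only mode substitutes features and logs exclusions", {
  feat <- rbind(make_feature_fixture(6),
                transform(make_feature_fixture(6, seed = 99), cycle = 2L))
  # drop P01's cycle-1 row: that patient cannot enter the mode
  feat <- feat[!(feat$patient_id == "P01" & feat$cycle == 1L), ]
  sub <- substitute_first_cycle_features(feat)
  expect_equal(sub$excluded$patient_id, "P01")
  expect_equal(sub$excluded$cycle, 2L)
  # every remaining cycle-2 row now carries the patient's cycle-1 features
  c2 <- sub$features[sub$features$cycle == 2L, ]
  c1 <- sub$features[sub$features$cycle == 1L, ]
  for (p in c2$patient_id) {
    expect_equal(c2$suv_left_kidney[c2$patient_id == p],
                 c1$suv_left_kidney[c1$patient_id == p])
  }

  fm <- build_feature_matrix(make_feature_fixture(10),
                             targets_of(make_feature_fixture(10)))
  model <- train_svr(fm$X, fm$y, svr_config())
  res <- predict_teff(model, feat, mode = "first_cycle_only")
  expect_equal(nrow(res$excluded), 1)
  expect_equal(nrow(res$predictions), nrow(feat) - 1)
  res_pc <- predict_teff(model, feat, mode = "per_cycle")
  expect_equal(nrow(res_pc$predictions), nrow(feat))
  expect_error(predict_teff(model, feat, mode = "bogus"))
})
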