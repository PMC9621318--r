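test_that("evaluation metrics match hand computation", {
  m <- regression_metrics(c(10, 20), c(12, 18))
  expect_equal(m$MAE, 2)
  expect_equal(m$RMSE, 2)
  expect_equal(m$IR, 100)
  expect_equal(m$MRE, ((-2 / 12) + (2 / 18)) / 2 * 100)  # signed: -2.78%
  perfect <- regression_metrics(c(5, 7), c(5, 7))
  expect_equal(unlist(perfect[c("MAE", "RMSE", "MRE")]), c(MAE = 0, RMSE = 0, MRE = 0))
  expect_equal(perfect$IR, 100)
  # boundary: exactly 20% relative error counts as inside
  expect_equal(regression_metrics(12, 10)$IR, 100)
  expect_error(regression_metrics(1:3, 1:2), "length")
  expect_error(regression_metrics(1:2, c(1, -1)), "positive")
})

test_that("RMSE dominates MAE and MRE keeps its sign", {
  set.seed(21)
  for (i in 1:50) {
    y <- runif(20, 10, 100)
    yh <- y + rnorm(20, 0, 5)
    m <- regression_metrics(yh, y)
    expect_gte(m$RMSE, m$MAE)
    expect_gte(m$IR, 0); expect_lte(m$IR, 100)
  }
  # systematic over-prediction gives positive MRE, under-prediction negative
  y <- runif(20, 10, 100)
  expect_gt(regression_metrics(y * 1.1, y)$MRE, 0)
  expect_lt(regression_metrics(y * 0.9, y)$MRE, 0)
})

test_that("every registry model fits and predicts on a small table", {
  ft <- small_table()
  X <- scaled_features(ft, "derivation")
  y <- ft$css[ft$split == "derivation"]
  for (nm in model_registry()) {
    m <- fit_regressor(model_spec(nm), X, y, seed = 1)
    p <- m$predict(X)
    expect_length(p, length(y))
    expect_true(all(is.finite(p)))
    # every learner beats the intercept-only baseline on its training data
    expect_lt(mean(abs(p - y)), mean(abs(mean(y) - y)))
  }
})

test_that("cross-validation reports seeded folds and optimism gap", {
  ft <- small_table()
  specs <- lapply(c("xgboost", "decision_tree", "linear"), model_spec)
  cv1 <- crossval_compare(ft, specs, folds = 5, seed = 9)
  cv2 <- crossval_compare(ft, specs, folds = 5, seed = 9)
  expect_identical(cv1, cv2)
  expect_equal(cv1$model, c("xgboost", "decision_tree", "linear"))
  expect_true(all(cv1$test_ci >= 0))
  # the unpruned tree memorises its training folds (up to split rounding)
  expect_lt(cv1$train_mae[cv1$model == "decision_tree"], 1e-3)
  # held-out error exceeds training error for the flexible learners
  expect_gt(cv1$test_mae[1], cv1$train_mae[1])
  expect_gt(cv1$test_mae[2], cv1$train_mae[2])
})

test_that("final bundle predicts its training cohort and round-trips to disk", {
  ft <- small_table()
  bundle <- fit_final(ft, seed = 2)
  rows <- ft$features[ft$split == "derivation", ]
  pred <- predict(bundle, rows)
  expect_lt(mean(abs(pred - ft$css[ft$split == "derivation"])),
            evaluate_bundle(bundle, ft)$MAE)  # optimism on own training rows
  dir <- file.path(tempdir(), "bundle-roundtrip")
  save_model_bundle(bundle, dir)
  back <- load_model_bundle(dir)
  expect_equal(predict(back, rows), pred)
  expect_identical(back$schema, bundle$schema)
  expect_equal(back$scaler$min, bundle$scaler$min)
})

test_that("feature ablation drops exactly the named columns", {
  ft <- small_table()
  simp <- ablate_features(ft)
  expect_equal(ncol(simp$features), 12)
  expect_false(any(c("Single Dose", "ALB", "t", "tau") %in% names(simp$features)))
  expect_equal(simp$css, ft$css)
  expect_identical(simp$split, ft$split)
  expect_identical(ablate_features(ft, character()), ft)
  expect_error(ablate_features(ft, "no-such-feature"), "unknown")
})

test_that("grid search returns the CV-optimal lattice point", {
  ft <- small_table()
  single <- data.frame(n_estimators = 15, max_depth = 3, learning_rate = 0.3)
  gs <- grid_search_xgb(ft, single, folds = 3, seed = 1)
  expect_equal(gs$best$params$n_estimators, 15)
  grid <- expand.grid(n_estimators = c(2, 60), max_depth = c(1, 6))
  gs2 <- grid_search_xgb(ft, grid, folds = 3, seed = 1)
  # the richer configuration wins on this signal-dominated data
  expect_equal(gs2$best$params$n_estimators, 60)
  expect_equal(gs2$best$params$max_depth, 6)
  expect_equal(nrow(gs2$results), 4)
  expect_error(grid_search_xgb(ft, NULL), "empty")
})
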