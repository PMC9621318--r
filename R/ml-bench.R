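#' Regression evaluation metrics
#'
#' The four metrics used throughout: mean absolute error, root-mean-squared
#' error, mean relative error and the "ideal rate".  MRE is *signed*
#' (`mean((pred - actual) / actual) * 100`): a value near zero indicates an
#' unbiased model, not an accurate one.  IR is the percentage of predictions
#' whose absolute relative error is at most 20% (the boundary counts as
#' inside).
#'
#' @param predicted,actual numeric vectors of equal nonzero length; `actual`
#'   must be strictly positive (relative metrics divide by it).
#' @return A list with elements `MAE`, `RMSE` (mg/L), `MRE`, `IR` (%).
#' @export
#' @examples
#' regression_metrics(c(10, 20), c(12, 18))
regression_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) == 0) {
    stop("predicted and actual must have equal nonzero length")
  }
  if (any(actual <= 0)) stop("actual values must be positive for MRE/IR")
  err <- predicted - actual
  list(MAE = mean(abs(err)),
       RMSE = sqrt(mean(err^2)),
       MRE = mean(err / actual) * 100,
       IR = 100 * mean(abs(err) / actual <= 0.20))
}

#' Registry of benchmarked regressors
#'
#' @return Character vector of the seven model names understood by
#'   [model_spec()].
#' @export
model_registry <- function() {
  c("xgboost", "random_forest", "bagging", "gradient_boosting",
    "decision_tree", "adaboost", "linear")
}

#' Specify a regressor
#'
#' @param name one of [model_registry()].
#' @param params named list of hyperparameter overrides; empty means the
#'   package defaults for that model (see [fit_regressor()]).
#' @return A list of class `ppk_model_spec`.
#' @export
model_spec <- function(name, params = list()) {
  name <- match.arg(name, model_registry())
  structure(list(name = name, params = params), class = "ppk_model_spec")
}

default_xgb_params <- function() {
  list(n_estimators = 100, learning_rate = 0.3, max_depth = 6,
       min_child_weight = 1, gamma = 0, subsample = 1, colsample_bytree = 1)
}

fit_xgb <- function(X, y, params, seed) {
  p <- utils::modifyList(default_xgb_params(), params)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = p$learning_rate, max_depth = p$max_depth,
                  min_child_weight = p$min_child_weight, gamma = p$gamma,
                  subsample = p$subsample, colsample_bytree = p$colsample_bytree,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = p$n_estimators, verbose = 0)
  list(fit = booster, params = p,
       predict = function(newX) stats::predict(booster, newX))
}

# AdaBoost.R2 with linear loss and depth-3 regression-tree base learners;
# prediction is the weighted median of the base predictions
fit_adaboost_r2 <- function(X, y, params, seed) {
  p <- utils::modifyList(list(n_estimators = 50, max_depth = 3), params)
  set.seed(seed)
  n <- length(y)
  df <- data.frame(X, check.names = TRUE)
  feat_names <- names(df)
  df$.y <- y
  w <- rep(1 / n, n)
  trees <- list()
  beta <- numeric(0)
  for (m in seq_len(p$n_estimators)) {
    # resample by weight (rpart's `weights` interact poorly with surrogate
    # splits; bootstrap-by-weight is the standard alternative)
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tr <- rpart::rpart(.y ~ ., data = df[idx, ],
                       control = rpart::rpart.control(
                         maxdepth = p$max_depth, cp = 0, xval = 0,
                         minsplit = 20, minbucket = 7))
    pred <- stats::predict(tr, df)
    e <- abs(pred - y)
    emax <- max(e)
    if (emax <= 0) { trees[[m]] <- tr; beta[m] <- 1e-10; break }
    L <- e / emax
    ebar <- sum(w * L)
    if (ebar >= 0.5) break
    b <- ebar / (1 - ebar)
    trees[[m]] <- tr
    beta[m] <- b
    w <- w * b^(1 - L)
    w <- w / sum(w)
  }
  if (length(trees) == 0) stop("adaboost failed to fit any base learner")
  lw <- log(1 / beta)
  predict_fn <- function(newX) {
    nd <- data.frame(newX, check.names = TRUE)[feat_names]
    P <- vapply(trees, function(tr) stats::predict(tr, nd),
                numeric(nrow(nd)))
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    apply(P, 1, function(pr) {
      o <- order(pr)
      cw <- cumsum(lw[o])
      pr[o][which(cw >= 0.5 * sum(lw))[1]]
    })
  }
  list(fit = trees, params = p, predict = predict_fn)
}

#' Fit one regressor from the registry
#'
#' Internal defaults per model: `xgboost` uses 100 trees of depth 6 with
#' learning rate 0.3; `gradient_boosting` is the classic slow-learning
#' configuration (100 trees, depth 3, learning rate 0.1); `random_forest`
#' and `bagging` use 200 trees (`bagging` sets `mtry` to all features, which
#' is exactly bagged unpruned trees); `decision_tree` is a fully grown,
#' unpruned tree (it memorises its training data); `adaboost` is AdaBoost.R2
#' with 50 depth-3 trees and linear loss; `linear` is ordinary least squares.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (scaled).
#' @param y numeric target.
#' @param seed integer seed for the stochastic learners.
#' @return List with elements `fit`, `params` and `predict` (a function of a
#'   feature matrix).
#' @export
fit_regressor <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "ppk_model_spec"))
  switch(spec$name,
    xgboost = fit_xgb(X, y, spec$params, seed),
    gradient_boosting = fit_xgb(X, y, utils::modifyList(
      list(learning_rate = 0.1, max_depth = 3), spec$params), seed),
    random_forest = {
      p <- utils::modifyList(list(num.trees = 200, min.node.size = 5), spec$params)
      rf <- ranger::ranger(x = X, y = y, num.trees = p$num.trees,
                           min.node.size = p$min.node.size,
                           num.threads = 1, seed = seed)
      list(fit = rf, params = p,
           predict = function(newX)
             stats::predict(rf, data = newX, num.threads = 1)$predictions)
    },
    bagging = {
      p <- utils::modifyList(list(num.trees = 200, min.node.size = 5), spec$params)
      rf <- ranger::ranger(x = X, y = y, num.trees = p$num.trees,
                           mtry = ncol(X), min.node.size = p$min.node.size,
                           num.threads = 1, seed = seed)
      list(fit = rf, params = p,
           predict = function(newX)
             stats::predict(rf, data = newX, num.threads = 1)$predictions)
    },
    decision_tree = {
      df <- data.frame(X, check.names = TRUE)
      feat_names <- names(df)
      df$.y <- y
      tr <- rpart::rpart(.y ~ ., data = df,
                         control = rpart::rpart.control(
                           cp = 0, minsplit = 2, minbucket = 1,
                           maxdepth = 30, xval = 0))
      list(fit = tr, params = list(),
           predict = function(newX)
             stats::predict(tr, data.frame(newX, check.names = TRUE)[feat_names]))
    },
    adaboost = fit_adaboost_r2(X, y, spec$params, seed),
    linear = {
      fit <- stats::lm.fit(cbind(1, X), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      list(fit = fit, params = list(),
           predict = function(newX) drop(cbind(1, newX) %*% cf))
    })
}

#' 10-fold cross-validated model comparison
#'
#' Partitions the derivation cohort into `folds` seed-deterministic folds;
#' each model is fitted on the remaining folds and scored (MAE) on both the
#' held-out fold and its own training folds.  Confidence intervals across
#' folds use the normal approximation `1.96 * sd / sqrt(folds)`.
#'
#' @param ft a `ppk_feature_table` (derivation rows are used).
#' @param specs list of [model_spec()] objects.
#' @param folds number of folds (default 10).
#' @param seed fold-partition seed.
#' @return data.frame with one row per model: mean `train_mae`, `test_mae`
#'   and their 95% CI half-widths, ordered as given.
#' @export
crossval_compare <- function(ft, specs = lapply(model_registry(), model_spec),
                             folds = 10L, seed = 1L) {
  X <- scaled_features(ft, "derivation")
  y <- ft$css[ft$split == "derivation"]
  n <- nrow(X)
  if (n < folds) stop("fewer derivation rows than folds")
  set.seed(as.integer(seed) * 2L + 201L)
  fold_id <- sample(rep_len(seq_len(folds), n))
  out <- lapply(specs, function(spec) {
    tr_mae <- te_mae <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- fit_regressor(spec, X[tr, , drop = FALSE], y[tr], seed = seed + f)
      tr_mae[f] <- mean(abs(m$predict(X[tr, , drop = FALSE]) - y[tr]))
      te_mae[f] <- mean(abs(m$predict(X[!tr, , drop = FALSE]) - y[!tr]))
    }
    data.frame(model = spec$name,
               train_mae = mean(tr_mae),
               train_ci = 1.96 * stats::sd(tr_mae) / sqrt(folds),
               test_mae = mean(te_mae),
               test_ci = 1.96 * stats::sd(te_mae) / sqrt(folds))
  })
  do.call(rbind, out)
}

#' Train the final model bundle
#'
#' Fits `spec` on the derivation cohort and packages everything needed to
#' use the model downstream: the fitted regressor, the table's scaler, the
#' ordered feature schema and the seeds/hyperparameters in force.
#'
#' @inheritParams crossval_compare
#' @param spec a [model_spec()] (default: the gradient-boosted tree model
#'   with implementation defaults).
#' @return An object of class `ppk_model_bundle`.
#' @export
fit_final <- function(ft, spec = model_spec("xgboost"), seed = 1L) {
  X <- scaled_features(ft, "derivation")
  y <- ft$css[ft$split == "derivation"]
  m <- fit_regressor(spec, X, y, seed = seed)
  structure(list(model = m, spec = spec, scaler = ft$scaler,
                 schema = colnames(X), seed = as.integer(seed),
                 params_used = m$params,
                 versions = list(
                   R = as.character(getRversion()),
                   xgboost = as.character(utils::packageVersion("xgboost")))),
            class = "ppk_model_bundle")
}

#' Predict steady-state concentration from a model bundle
#'
#' @param object a `ppk_model_bundle`.
#' @param newdata data.frame of *raw* (unscaled) features containing the
#'   bundle's schema columns; the stored scaler is applied internally.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (mg/L).
#' @export
predict.ppk_model_bundle <- function(object, newdata, ...) {
  if (!all(object$schema %in% names(newdata))) {
    stop("newdata lacks schema columns: ",
         paste(setdiff(object$schema, names(newdata)), collapse = ", "))
  }
  X <- apply_minmax_scaler(newdata[object$schema], object$scaler)
  unname(object$model$predict(as.matrix(X)))
}

#' Evaluate a bundle on a cohort of a feature table
#'
#' @param bundle a `ppk_model_bundle`.
#' @param ft a `ppk_feature_table` with the bundle's schema.
#' @param cohort `"validation"` (default) or `"derivation"`.
#' @return [regression_metrics()] of the bundle on that cohort.
#' @export
evaluate_bundle <- function(bundle, ft, cohort = "validation") {
  rows <- ft$split == cohort
  pred <- predict(bundle, ft$features[rows, , drop = FALSE])
  regression_metrics(pred, ft$css[rows])
}

#' Drop features from a feature table
#'
#' Returns a copy of the table restricted to the remaining features, with a
#' refitted scaler over the remaining continuous columns.  Rows, target and
#' split assignment are unchanged.  Dropping the four clinic-unfriendly
#' features (Single Dose, ALB, t, tau) yields the 12-feature simplified
#' schema.
#'
#' @param ft a `ppk_feature_table`.
#' @param drop character vector of feature names to remove (subset of the
#'   schema).
#' @return A `ppk_feature_table` with `ncol - length(drop)` features.
#' @export
ablate_features <- function(ft, drop = simplified_drop_features()) {
  unknown <- setdiff(drop, names(ft$features))
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  if (length(drop) == 0) return(ft)
  keep <- setdiff(names(ft$features), drop)
  ft$features <- ft$features[keep]
  ft$scaler <- fit_minmax_scaler(ft$features,
                                 intersect(continuous_features(), keep))
  ft
}

#' Grid-search gradient-boosted hyperparameters by cross-validated MAE
#'
#' Evaluates every point of a hyperparameter lattice by k-fold CV on the
#' derivation cohort and returns the point with the lowest mean test MAE.
#' Ties break to the lexicographically first lattice point.
#'
#' @inheritParams crossval_compare
#' @param grid data.frame lattice whose columns are xgboost hyperparameter
#'   names (`n_estimators`, `max_depth`, `min_child_weight`, `gamma`,
#'   `colsample_bytree`, `subsample`, `learning_rate`); see
#'   [default_xgb_grid()].
#' @return List with `best` (a [model_spec()]), `best_mae`, and `results`
#'   (the lattice with its CV MAE column).
#' @export
grid_search_xgb <- function(ft, grid, folds = 10L, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  X <- scaled_features(ft, "derivation")
  y <- ft$css[ft$split == "derivation"]
  set.seed(as.integer(seed) * 2L + 201L)
  fold_id <- sample(rep_len(seq_len(folds), nrow(X)))
  cv_mae <- vapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    mae <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- fit_xgb(X[tr, , drop = FALSE], y[tr], params, seed = seed + f)
      mean(abs(m$predict(X[!tr, , drop = FALSE]) - y[!tr]))
    }, numeric(1))
    mean(mae)
  }, numeric(1))
  best_i <- which.min(cv_mae)
  grid$cv_mae <- cv_mae
  list(best = model_spec("xgboost", as.list(grid[best_i, setdiff(names(grid), "cv_mae")])),
       best_mae = cv_mae[best_i], results = grid)
}

#' Default hyperparameter lattice
#'
#' Brackets each reference value of the optimised simplified model
#' (20 trees, depth 6, minimum child weight 5, gamma 0, full column and row
#' sampling, learning rate 0.3) with one smaller and one larger candidate.
#' The full lattice is large (1,458 points); restrict it before searching if
#' compute is a concern.
#'
#' @return data.frame lattice for [grid_search_xgb()].
#' @export
default_xgb_grid <- function() {
  expand.grid(n_estimators = c(10, 20, 40), max_depth = c(3, 6, 9),
              min_child_weight = c(1, 5, 10), gamma = c(0, 0.1, 1),
              colsample_bytree = c(0.8, 1.0), subsample = c(0.8, 1.0),
              learning_rate = c(0.1, 0.3, 0.5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Persist / restore a model bundle
#'
#' Writes the bundle to a directory: the booster in xgboost's native format
#' (other learners via `saveRDS`), plus JSON files for the scaler, schema and
#' metadata (seeds, hyperparameters, package versions).
#'
#' @param bundle a `ppk_model_bundle`.
#' @param dir target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (bundle$spec$name %in% c("xgboost", "gradient_boosting")) {
    xgboost::xgb.save(bundle$model$fit, file.path(dir, "model.ubj"))
  } else {
    saveRDS(bundle$model, file.path(dir, "model.rds"))
  }
  jsonlite::write_json(list(min = as.list(bundle$scaler$min),
                            max = as.list(bundle$scaler$max),
                            cols = bundle$scaler$cols),
                       file.path(dir, "scaler.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$schema, file.path(dir, "schema.json"))
  jsonlite::write_json(list(spec = bundle$spec$name, seed = bundle$seed,
                            params = bundle$params_used,
                            versions = bundle$versions),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  sc <- jsonlite::read_json(file.path(dir, "scaler.json"), simplifyVector = TRUE)
  scaler <- structure(list(min = unlist(sc$min), max = unlist(sc$max),
                           cols = sc$cols), class = "minmax_scaler")
  schema <- unlist(jsonlite::read_json(file.path(dir, "schema.json"),
                                       simplifyVector = TRUE))
  model <- if (file.exists(file.path(dir, "model.ubj"))) {
    booster <- xgboost::xgb.load(file.path(dir, "model.ubj"))
    list(fit = booster, params = meta$params,
         predict = function(newX) stats::predict(booster, newX))
  } else {
    readRDS(file.path(dir, "model.rds"))
  }
  structure(list(model = model, spec = model_spec(meta$spec),
                 scaler = scaler, schema = schema, seed = meta$seed,
                 params_used = meta$params, versions = meta$versions),
            class = "ppk_model_bundle")
}
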