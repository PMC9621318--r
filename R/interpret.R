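# Shapley-value interpretation of the trained tree ensemble.
#
# The value function is interventional: features outside the coalition are
# marginalised over an explicit background sample, so an attribution answers
# "how much does knowing this feature's value move the prediction away from
# the background average".  The tree algorithm in src/itshap.cpp computes
# these attributions exactly (no sampling) per background point.

# Parse an xgboost booster's JSON dump into flat per-tree arrays (0-based
# children indices by position), mapping split feature names onto `schema`.
parse_xgb_trees <- function(booster, schema) {
  dump <- xgboost::xgb.dump(booster, dump_format = "json", with_stats = FALSE)
  trees <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                              simplifyVector = FALSE)
  lapply(trees, function(root) {
    feat <- integer(0); thr <- numeric(0); yes <- integer(0)
    no <- integer(0); val <- numeric(0); id2pos <- new.env()
    flatten <- function(node) {
      pos <- length(feat)  # 0-based position of this node
      assign(as.character(node$nodeid), pos, envir = id2pos)
      if (!is.null(node$leaf)) {
        feat[pos + 1] <<- -1L; thr[pos + 1] <<- 0
        yes[pos + 1] <<- -1L; no[pos + 1] <<- -1L
        val[pos + 1] <<- node$leaf
        return(invisible())
      }
      fi <- match(node$split, schema) - 1L
      if (is.na(fi)) stop("split feature not in schema: ", node$split)
      feat[pos + 1] <<- fi; thr[pos + 1] <<- node$split_condition
      yes[pos + 1] <<- NA_integer_; no[pos + 1] <<- NA_integer_
      val[pos + 1] <<- 0
      for (ch in node$children) flatten(ch)
      yes[pos + 1] <<- get(as.character(node$yes), envir = id2pos)
      no[pos + 1] <<- get(as.character(node$no), envir = id2pos)
      invisible()
    }
    flatten(root)
    list(feat = feat, thr = thr, yes = yes, no = no, val = val)
  })
}

#' Interventional Shapley attributions for a model bundle
#'
#' Computes exact interventional Shapley values of the bundle's
#' gradient-boosted model for each row, marginalising absent features over a
#' background sample.  Attributions are on the model-output (mg/L) scale and
#' satisfy local accuracy: `base_value + rowSums(phi)` equals the model
#' prediction for every row.
#'
#' @param bundle a `ppk_model_bundle` whose model is a gradient-boosted tree
#'   ensemble.
#' @param rows data.frame of raw features to explain (bundle schema columns).
#' @param background data.frame of raw background rows; typically a
#'   fixed-seed subsample of the derivation cohort (see
#'   [background_sample()]).
#' @return A list of class `ppk_attribution`: `phi` (matrix rows x features),
#'   `base_value` (mean background prediction), `prediction` (per-row model
#'   output), `schema`.
#' @export
shap_attributions <- function(bundle, rows, background) {
  if (!bundle$spec$name %in% c("xgboost", "gradient_boosting")) {
    stop("attributions require a gradient-boosted tree bundle")
  }
  if (!all(bundle$schema %in% names(rows)) ||
      !all(bundle$schema %in% names(background))) {
    stop("rows/background lack schema columns")
  }
  X <- as.matrix(apply_minmax_scaler(rows[bundle$schema], bundle$scaler))
  Z <- as.matrix(apply_minmax_scaler(background[bundle$schema], bundle$scaler))
  trees <- parse_xgb_trees(bundle$model$fit, bundle$schema)
  phi <- itshap_cpp(trees, X, Z)
  colnames(phi) <- bundle$schema
  structure(list(phi = phi,
                 base_value = mean(bundle$model$predict(Z)),
                 prediction = unname(bundle$model$predict(X)),
                 schema = bundle$schema),
            class = "ppk_attribution")
}

#' Fixed-seed background subsample for attribution
#'
#' @param ft a `ppk_feature_table`.
#' @param size background size (default 512).
#' @param seed subsample seed.
#' @return data.frame of raw feature rows drawn from the derivation cohort.
#' @export
background_sample <- function(ft, size = 512L, seed = 1L) {
  idx <- which(ft$split == "derivation")
  set.seed(as.integer(seed) * 2L + 301L)
  ft$features[sample(idx, min(size, length(idx))), , drop = FALSE]
}

#' Exact Shapley values by exhaustive coalition enumeration
#'
#' Brute-force oracle: enumerates all `2^p` feature coalitions with the
#' combinatorial weights `|S|! (p - |S| - 1)! / p!`, using the interventional
#' value function (coalition features from `x`, the rest from each background
#' row, averaged).  Intended for testing against the tree algorithm;
#' restricted to `p <= 12`.
#'
#' @param predictor function mapping a numeric feature matrix to predictions.
#' @param x numeric vector, the point to explain.
#' @param background numeric matrix of background rows (same column count).
#' @return Numeric vector of per-feature Shapley values.
#' @export
shapley_exact <- function(predictor, x, background) {
  p <- length(x)
  if (p > 12) stop("exhaustive enumeration limited to 12 features")
  background <- as.matrix(background)
  stopifnot(ncol(background) == p)
  nS <- bitwShiftL(1L, p)
  # value of every coalition
  nu <- vapply(seq_len(nS) - 1L, function(mask) {
    M <- background
    for (j in seq_len(p)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) M[, j] <- x[j]
    }
    mean(predictor(M))
  }, numeric(1))
  sizes <- vapply(seq_len(nS) - 1L, function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0L), numeric(1))
  w <- lfactorial(0:p) + lfactorial(p - 1 - (0:p)) - lfactorial(p)  # log weights by |S|
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(nS) - 1L, bit) == 0L)
    for (m in without) {
      s <- sizes[m]
      phi[j] <- phi[j] + exp(w[s + 1]) * (nu[m + bit] - nu[m])
    }
  }
  phi
}

#' Global feature importance from attributions
#'
#' Mean absolute attribution per feature over all explained rows, sorted
#' descending.
#'
#' @param attr a `ppk_attribution`.
#' @return data.frame with columns `feature` and `mean_abs_phi`.
#' @export
shap_importance <- function(attr) {
  stopifnot(inherits(attr, "ppk_attribution"))
  imp <- colMeans(abs(attr$phi))
  out <- data.frame(feature = names(imp), mean_abs_phi = unname(imp))
  out[order(-out$mean_abs_phi), , drop = FALSE]
}

#' Dependence profile of one feature
#'
#' Per-row `(feature value, attribution)` pairs for plotting how a feature's
#' value drives its contribution; no aggregation is applied.
#'
#' @param attr a `ppk_attribution`.
#' @param rows the data.frame that was explained (raw feature values).
#' @param feature feature name from the schema.
#' @return data.frame with columns `value` and `phi`, one row per explained
#'   sample.
#' @export
shap_dependence <- function(attr, rows, feature) {
  if (!feature %in% attr$schema) stop("unknown feature: ", feature)
  data.frame(value = rows[[feature]], phi = attr$phi[, feature])
}
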