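#' Merge the two filtered virtual populations
#'
#' Stacks filtered Dataset-A and Dataset-B records into one table.  Dataset-A
#' rows carry the co-medication placeholder level `"None"`; Dataset-B rows
#' carry genotype `"unknown"` and missing gender/albumin.  These placeholder
#' levels are legitimate categories, not missing values — only gender and
#' albumin are treated as missing (and later imputed).
#'
#' @param a,b filtered data.frames from [simulate_populations()].
#' @return The row-bound data.frame.
#' @export
merge_with_placeholders <- function(a, b) {
  required <- c("genotype", "gender", "BW", "ALB", "comed", "X0", "tau", "t",
                "daily_dose", "ka", "Vd", "CL", "css", "source")
  if (!all(required %in% names(a)) || (nrow(b) > 0 && !all(required %in% names(b)))) {
    stop("schema mismatch: expected simulation record columns")
  }
  if (nrow(b) == 0) return(a)
  rbind(a[required], b[required])
}

# distance design for the imputation: min-max scaled dosing/weight columns
# plus co-medication indicators; albumin and the target concentration are
# excluded so neither drives its own imputation
impute_distance_matrix <- function(merged) {
  num <- merged[c("BW", "X0", "daily_dose", "t", "tau")]
  num <- vapply(num, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }, numeric(nrow(merged)))
  combos <- setdiff(comed_levels(), "None")
  ind <- vapply(combos, function(cm) as.numeric(merged$comed == cm),
                numeric(nrow(merged)))
  cbind(num, ind)
}

#' k-nearest-neighbour imputation of gender and albumin
#'
#' Completes the merged table: rows missing gender/albumin receive the
#' unweighted mean albumin and the majority-vote gender of their `k` nearest
#' complete rows (Euclidean distance on min-max-scaled body weight, single
#' dose, daily dose, sampling time and dosing interval, plus the
#' co-medication indicators).  Complete rows are returned unchanged.  Gender
#' votes that tie (possible for even `k`) resolve to `"female"`.
#'
#' @param merged data.frame from [merge_with_placeholders()].
#' @param k number of neighbours (default 5).
#' @return `merged` with no missing `gender`/`ALB` cells.
#' @export
knn_impute <- function(merged, k = 5L) {
  stopifnot(k >= 1)
  donors <- which(!is.na(merged$gender) & !is.na(merged$ALB))
  recips <- setdiff(seq_len(nrow(merged)), donors)
  if (length(recips) == 0) return(merged)
  if (k > length(donors)) stop("k exceeds the number of complete donor rows")
  Xd <- impute_distance_matrix(merged)
  D <- Xd[donors, , drop = FALSE]
  d2 <- rowSums(D^2)
  alb_d <- merged$ALB[donors]
  male_d <- as.numeric(merged$gender[donors] == "male")
  block <- 2000L
  for (start in seq(1L, length(recips), by = block)) {
    idx <- recips[start:min(start + block - 1L, length(recips))]
    R <- Xd[idx, , drop = FALSE]
    # squared Euclidean distances recipients x donors
    dist2 <- outer(rowSums(R^2), d2, "+") - 2 * tcrossprod(R, D)
    for (j in seq_along(idx)) {
      nn <- order(dist2[j, ])[seq_len(k)]
      merged$ALB[idx[j]] <- mean(alb_d[nn])
      merged$gender[idx[j]] <-
        if (sum(male_d[nn]) > k / 2) "male" else "female"
    }
  }
  merged
}

#' One-hot encode and assemble the 16-feature matrix
#'
#' Builds the fixed feature schema: six continuous columns (Single Dose, BW,
#' ALB, t, tau, Daily Dose), two genotype indicators, the Male indicator and
#' seven co-medication combination indicators.  The reference levels
#' `"Unknown"` (genotype), `"None"` (co-medication) and `"Female"` are
#' dropped, so unknown-genotype rows have both genotype indicators zero.
#' Latent pharmacokinetic columns (`ka`, `Vd`, `CL`) are deliberately
#' omitted: they are not observable in the clinic.
#'
#' @param completed data.frame from [knn_impute()] (no missing gender/ALB).
#' @return data.frame of 16 raw (unscaled) feature columns in schema order.
#' @export
encode_features <- function(completed) {
  if (anyNA(completed$gender) || anyNA(completed$ALB)) {
    stop("encode_features() requires a completed table (run knn_impute first)")
  }
  if (!all(completed$genotype %in% c("wildtype", "variant", "unknown"))) {
    stop("unexpected genotype category")
  }
  if (!all(completed$comed %in% comed_levels())) {
    stop("unexpected co-medication category")
  }
  X <- data.frame(
    `Single Dose` = completed$X0,
    BW = completed$BW,
    ALB = completed$ALB,
    t = completed$t,
    tau = completed$tau,
    `Daily Dose` = completed$daily_dose,
    `CYP2C19*1/*1` = as.numeric(completed$genotype == "wildtype"),
    `CYP2C19*2 and/or *3 variants` = as.numeric(completed$genotype == "variant"),
    Male = as.numeric(completed$gender == "male"),
    check.names = FALSE)
  for (cm in setdiff(comed_levels(), "None")) {
    X[[paste0("Co-administered ", cm)]] <- as.numeric(completed$comed == cm)
  }
  stopifnot(identical(names(X), feature_schema()))
  X
}

#' Fit a min-max scaler
#'
#' Records the observed minimum and maximum of each named column.
#'
#' @param X data.frame of features.
#' @param cols columns to scale (default: the six continuous features).
#' @return An object of class `minmax_scaler`.
#' @export
fit_minmax_scaler <- function(X, cols = continuous_features()) {
  stopifnot(all(cols %in% names(X)))
  rng <- lapply(X[cols], range)
  if (any(vapply(rng, diff, numeric(1)) <= 0)) {
    stop("degenerate feature (max == min) cannot be min-max scaled")
  }
  structure(list(min = vapply(rng, `[`, numeric(1), 1),
                 max = vapply(rng, `[`, numeric(1), 2),
                 cols = cols),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each scaled column through `(x - min) / (max - min)` using the bounds
#' stored at fit time.  At prediction time values outside the fitting range
#' map outside `[0, 1]`; that is intentional.
#'
#' @param X data.frame containing the scaler's columns.
#' @param scaler a `minmax_scaler`.
#' @return `X` with scaled columns.
#' @export
apply_minmax_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"), all(scaler$cols %in% names(X)))
  for (cl in scaler$cols) {
    X[[cl]] <- (X[[cl]] - scaler$min[[cl]]) / (scaler$max[[cl]] - scaler$min[[cl]])
  }
  X
}

#' Invert a min-max scaling
#'
#' @inheritParams apply_minmax_scaler
#' @return `X` with scaled columns mapped back to their original units.
#' @export
invert_minmax_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"), all(scaler$cols %in% names(X)))
  for (cl in scaler$cols) {
    X[[cl]] <- X[[cl]] * (scaler$max[[cl]] - scaler$min[[cl]]) + scaler$min[[cl]]
  }
  X
}

#' Random derivation/validation split
#'
#' Assigns each row to the derivation (model building) or validation cohort
#' uniformly at random, with `floor(fraction * n)` derivation rows.
#'
#' @param n number of rows.
#' @param fraction derivation fraction (default 0.8).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return Character vector of `"derivation"` / `"validation"`, length `n`.
#' @export
split_derivation_validation <- function(n, fraction = 0.8, seed = 1L) {
  stopifnot(n > 0, fraction > 0, fraction < 1)
  set.seed(as.integer(seed) * 2L + 101L)
  out <- rep("validation", n)
  out[sample.int(n, floor(fraction * n))] <- "derivation"
  out
}

#' Build the fused feature table
#'
#' End-to-end fusion: merge the filtered populations, impute gender/albumin,
#' one-hot encode into the 16-feature schema, fit the min-max scaler and
#' assign the 8:2 derivation/validation split.  The scaler is fitted on the
#' full merged table before splitting by default, mirroring a preprocessing-
#' before-split order; pass `scaler_scope = "derivation"` to fit on the
#' derivation rows only (avoids the mild information leak of full-data
#' scaling bounds).
#'
#' @param pops list from [simulate_populations()] (elements `a`, `b`).
#' @param k neighbours for [knn_impute()].
#' @param split_fraction derivation fraction.
#' @param seed split seed.
#' @param scaler_scope `"full"` or `"derivation"`.
#' @return An object of class `ppk_feature_table`: list with `features`
#'   (raw 16-column data.frame), `css` (target, mg/L), `split`, `scaler`,
#'   `source` and `merged` (the completed pre-encoding records).
#' @export
build_feature_table <- function(pops, k = 5L, split_fraction = 0.8,
                                seed = 1L, scaler_scope = c("full", "derivation")) {
  scaler_scope <- match.arg(scaler_scope)
  merged <- merge_with_placeholders(pops$a, pops$b)
  completed <- knn_impute(merged, k = k)
  X <- encode_features(completed)
  split <- split_derivation_validation(nrow(X), split_fraction, seed)
  scaler <- if (scaler_scope == "full") {
    fit_minmax_scaler(X)
  } else {
    fit_minmax_scaler(X[split == "derivation", , drop = FALSE])
  }
  structure(list(features = X, css = completed$css, split = split,
                 scaler = scaler, source = completed$source,
                 merged = completed),
            class = "ppk_feature_table")
}

#' Scaled feature matrix of a feature table
#'
#' @param ft a `ppk_feature_table`.
#' @param rows optional row filter (`"derivation"`, `"validation"` or
#'   indices).
#' @return Numeric matrix of scaled features.
#' @export
scaled_features <- function(ft, rows = NULL) {
  stopifnot(inherits(ft, "ppk_feature_table"))
  X <- apply_minmax_scaler(ft$features, ft$scaler)
  if (is.character(rows)) rows <- which(ft$split == rows)
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  as.matrix(X)
}
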