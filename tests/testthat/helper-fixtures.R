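# Shared fixtures.  Heavy default-scale results are computed once per test
# run and memoised here; module tests use small configurations instead.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# full study-scale populations (20,000 + 14,000 simulated, filtered)
default_pops <- function(seed = 1) {
  memo(paste0("pops", seed), simulate_populations(sim_config(seed = seed)))
}

# fused 16-feature table at study scale
default_table <- function(seed = 1) {
  memo(paste0("table", seed), build_feature_table(default_pops(seed), seed = seed))
}

# default-hyperparameter gradient-boosted bundle on the derivation cohort
default_bundle <- function(seed = 1) {
  memo(paste0("bundle", seed), fit_final(default_table(seed), seed = seed))
}

# small populations for fast module tests
small_pops <- function(seed = 42) {
  memo(paste0("small", seed),
       simulate_populations(sim_config(seed = seed, n_per_scenario_a = 250,
                                       n_per_combo_b = 100)))
}

small_table <- function(seed = 42) {
  memo(paste0("smalltab", seed), build_feature_table(small_pops(seed), seed = seed))
}

# tiny trained xgboost regressor for interpretation tests
tiny_xgb <- function(n = 80, p = 3, depth = 2, rounds = 3, seed = 5) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 5 * (X[, 1] > 0.5) + 3 * X[, 2] + stats::rnorm(n, 0, 0.01)
  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = depth,
                  eta = 1, nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = rounds, verbose = 0)
  list(booster = bst, X = X, y = y)
}
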