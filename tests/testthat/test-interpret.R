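# predictor closure over a booster for the enumeration oracle
booster_predictor <- function(booster, schema) {
  function(M) {
    colnames(M) <- schema
    predict(booster, M)
  }
}

test_that("exhaustive Shapley recovers the closed form for additive models", {
  set.seed(31)
  Z <- matrix(runif(20), 10, 2)
  f <- function(M) M[, 1] + M[, 2]
  x <- c(0.9, 0.2)
  phi <- shapley_exact(f, x, Z)
  expect_equal(phi, x - colMeans(Z))
})

test_that("exhaustive Shapley is symmetric for duplicated features", {
  set.seed(32)
  zc <- runif(8)
  Z <- cbind(zc, zc)  # identical background columns
  f <- function(M) 3 * M[, 1] + 3 * M[, 2]
  phi <- shapley_exact(f, c(0.7, 0.7), Z)
  expect_equal(phi[1], phi[2])
})

test_that("tree attribution matches exhaustive enumeration on small models", {
  # depth <= 2 trees, <= 4 features, <= 8 background points
  for (p in c(2, 3, 4)) {
    fix <- tiny_xgb(n = 70, p = p, depth = 2, rounds = 3, seed = 40 + p)
    trees <- ppkfuse:::parse_xgb_trees(fix$booster, colnames(fix$X))
    Z <- fix$X[1:8, , drop = FALSE]
    Xq <- fix$X[9:14, , drop = FALSE]
    phi_tree <- ppkfuse:::itshap_cpp(trees, Xq, Z)
    fpred <- booster_predictor(fix$booster, colnames(fix$X))
    for (i in seq_len(nrow(Xq))) {
      phi_ex <- shapley_exact(fpred, Xq[i, ], Z)
      expect_equal(unname(phi_tree[i, ]), phi_ex, tolerance = 1e-6)
    }
  }
})

test_that("a single-split stump attributes everything to its split feature", {
  # stump on feature 1 with two leaves; hand enumeration of the coalition
  # formula gives phi_1 = f(x) - mean_z f(z), phi_2 = 0
  tree <- list(feat = c(0L, -1L, -1L), thr = c(0.5, 0, 0),
               yes = c(1L, -1L, -1L), no = c(2L, -1L, -1L),
               val = c(0, 10, 20))
  X <- matrix(c(0.2, 0.9, 0.8, 0.1), 2, 2)
  Z <- matrix(c(0.2, 0.9, 0.4, 0.6), 2, 2)   # one background point per side
  phi <- ppkfuse:::itshap_cpp(list(tree), X, Z)
  fx <- c(10, 20)
  expect_equal(phi[, 1], fx - mean(c(10, 20)))
  expect_equal(phi[, 2], c(0, 0))
})

test_that("attributions satisfy additivity and the null-player axiom", {
  ft <- small_table()
  bundle <- fit_final(ft, seed = 3)
  bg <- background_sample(ft, 64, seed = 3)
  rows <- ft$features[which(ft$split == "validation")[1:40], ]
  at <- shap_attributions(bundle, rows, bg)
  # local accuracy: base + sum(phi) = prediction (float32 leaf storage
  # limits agreement to ~1e-6 relative)
  expect_equal(at$base_value + rowSums(at$phi), at$prediction,
               tolerance = 1e-5)
  expect_equal(at$base_value, mean(predict(bundle, bg)), tolerance = 1e-6)
  # a feature constant in training is never split on, hence never attributed
  ft2 <- ft
  ft2$features[["Co-administered CBZ"]] <- 0
  expect_error(fit_minmax_scaler(ft2$features, "Co-administered CBZ"))
  bundle2 <- fit_final(ft2, seed = 3)
  rows2 <- ft2$features[which(ft2$split == "validation")[1:20], ]
  at2 <- shap_attributions(bundle2, rows2, background_sample(ft2, 32, seed = 3))
  expect_true(all(at2$phi[, "Co-administered CBZ"] == 0))
})

test_that("importance ranking sorts mean absolute attribution descending", {
  at <- structure(list(
    phi = cbind(a = c(-1, 1), b = c(5, -5), c = c(0, 0)),
    base_value = 0, prediction = c(0, 0), schema = c("a", "b", "c")),
    class = "ppk_attribution")
  imp <- shap_importance(at)
  expect_equal(imp$feature, c("b", "a", "c"))
  expect_equal(imp$mean_abs_phi, c(5, 1, 0))
})

test_that("dependence profiles pair each sample with its attribution", {
  ft <- small_table()
  bundle <- fit_final(ft, seed = 4)
  rows <- ft$features[which(ft$split == "derivation")[1:60], ]
  at <- shap_attributions(bundle, rows, background_sample(ft, 32, seed = 4))
  dp <- shap_dependence(at, rows, "Daily Dose")
  expect_equal(nrow(dp), nrow(rows))
  expect_equal(dp$value, rows[["Daily Dose"]])
  expect_error(shap_dependence(at, rows, "nope"), "unknown")
})

test_that("dependence directions reflect the clearance covariates", {
  # higher albumin lowers clearance (higher concentration): positive rank
  # correlation with its attribution; body weight acts the opposite way
  ft <- small_table()
  bundle <- fit_final(ft, seed = 42)
  rows <- ft$features[which(ft$split == "derivation")[1:300], ]
  at <- shap_attributions(bundle, rows, background_sample(ft, 64, seed = 42))
  alb <- shap_dependence(at, rows, "ALB")
  bw <- shap_dependence(at, rows, "BW")
  expect_gt(cor(alb$value, alb$phi, method = "spearman"), 0)
  expect_lt(cor(bw$value, bw$phi, method = "spearman"), 0)
})
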