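test_that("merge keeps placeholder semantics of both sources", {
  pops <- small_pops()
  merged <- merge_with_placeholders(pops$a, pops$b)
  expect_equal(nrow(merged), nrow(pops$a) + nrow(pops$b))
  isB <- merged$source == "B"
  expect_equal(mean(is.na(merged$gender)), mean(isB))
  expect_equal(mean(is.na(merged$ALB)), mean(isB))
  expect_true(all(merged$genotype[isB] == "unknown"))
  expect_true(all(merged$comed[!isB] == "None"))
  # empty second input is the identity
  expect_identical(merge_with_placeholders(pops$a, pops$b[0, ]),
                   pops$a)
  expect_error(merge_with_placeholders(pops$a, data.frame(x = 1)), "schema")
})

test_that("kNN imputation averages neighbours and leaves donors unchanged", {
  # three complete donors; the incomplete row is equidistant to the first
  # two only, so with k = 2 its albumin is their mean
  toy <- data.frame(
    genotype = c("wildtype", "wildtype", "wildtype", "unknown"),
    gender = c("male", "female", "male", NA),
    BW = c(60, 60, 90, 60), ALB = c(30, 40, 50, NA),
    comed = c("None", "None", "None", "CBZ"),
    X0 = 500, tau = 12, t = c(2, 2, 2, 2), daily_dose = 1000,
    ka = 2.38, Vd = 22, CL = 0.6, css = 70, source = c("A", "A", "A", "B"),
    stringsAsFactors = FALSE)
  out <- knn_impute(toy, k = 2)
  expect_equal(out$ALB[4], 35)
  expect_identical(out[1:3, ], toy[1:3, ])
  expect_false(anyNA(out$gender))
  # tie between one male and one female vote resolves to female
  expect_equal(out$gender[4], "female")
  expect_error(knn_impute(toy, k = 5), "donor")
})

test_that("imputation completes the merged table deterministically", {
  pops <- small_pops()
  merged <- merge_with_placeholders(pops$a, pops$b)
  done <- knn_impute(merged, k = 5)
  expect_false(anyNA(done$ALB))
  expect_false(anyNA(done$gender))
  expect_equal(nrow(done), nrow(merged))
  expect_identical(done, knn_impute(merged, k = 5))
  # imputed albumin lies within the donor range
  expect_true(all(done$ALB >= min(pops$a$ALB) & done$ALB <= max(pops$a$ALB)))
})

test_that("encoding produces the 16-column schema with exclusive indicators", {
  ft <- small_table()
  X <- ft$features
  expect_identical(names(X), c(
    "Single Dose", "BW", "ALB", "t", "tau", "Daily Dose",
    "CYP2C19*1/*1", "CYP2C19*2 and/or *3 variants", "Male",
    "Co-administered CBZ", "Co-administered PHT", "Co-administered PB",
    "Co-administered CBZ+PHT", "Co-administered CBZ+PB",
    "Co-administered PHT+PB", "Co-administered CBZ+PHT+PB"))
  ind <- X[7:16]
  expect_true(all(unlist(ind) %in% c(0, 1)))
  expect_true(all(X[["CYP2C19*1/*1"]] + X[["CYP2C19*2 and/or *3 variants"]] <= 1))
  expect_true(all(rowSums(X[10:16]) <= 1))
  # dataset-A wildtype male rows encode as in the schema definition
  pops <- small_pops()
  merged <- knn_impute(merge_with_placeholders(pops$a, pops$b), 5)
  i <- which(merged$genotype == "wildtype" & merged$gender == "male")[1]
  expect_equal(unname(unlist(X[i, 7:16])), c(1, 0, 1, rep(0, 7)))
  # unknown-genotype rows drop to the all-zero reference
  j <- which(merged$source == "B")[1]
  expect_equal(unname(unlist(X[j, 7:8])), c(0, 0))
})

test_that("min-max scaling round-trips and reuses stored bounds", {
  ft <- small_table()
  sc <- ft$scaler
  scaled <- apply_minmax_scaler(ft$features, sc)
  for (cl in sc$cols) {
    expect_gte(min(scaled[[cl]]), 0)
    expect_lte(max(scaled[[cl]]), 1)
  }
  back <- invert_minmax_scaler(scaled, sc)
  expect_equal(back, ft$features, tolerance = 1e-12)
  # reuse on own fitting data is idempotent
  expect_equal(apply_minmax_scaler(ft$features, sc), scaled)
  # dose endpoints map to 0 and 1
  expect_equal(range(scaled[["Single Dose"]]), c(0, 1))
  expect_error(fit_minmax_scaler(data.frame(x = rep(1, 5)), "x"), "degenerate")
})

test_that("derivation/validation split is disjoint, sized and seeded", {
  s1 <- split_derivation_validation(26173, 0.8, seed = 1)
  expect_equal(sum(s1 == "validation"), 5235)
  expect_equal(sum(s1 == "derivation"), 20938)
  expect_identical(s1, split_derivation_validation(26173, 0.8, seed = 1))
  expect_false(identical(s1, split_derivation_validation(26173, 0.8, seed = 2)))
})

test_that("fused features show no perfect collinearity and near-normal target", {
  ft <- small_table()
  cm <- suppressWarnings(cor(as.matrix(ft$features)))
  off <- abs(cm[upper.tri(cm)])
  expect_true(all(off[!is.na(off)] < 1))
  # normal probability plot linearity of the concentration distribution
  q <- qnorm(ppoints(length(ft$css)))
  r2 <- cor(sort(ft$css), q)^2
  expect_gt(r2, 0.9)
})
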