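test_that("steady-state concentration matches term-by-term evaluation", {
  # independent high-precision evaluation of the closed form
  ka <- 2.38; Vd <- 22.15; CL <- 0.64; X0 <- 500; tau <- 12; t <- 2
  expected <- ka * X0 / (Vd * ka - CL) *
    (exp(-CL * t / Vd) / (1 - exp(-CL * tau / Vd)) -
       exp(-ka * t) / (1 - exp(-ka * tau)))
  expect_equal(css_steady_state(ka, 1, X0, Vd, CL, tau, t), expected)
  expect_equal(round(expected, 1), 73.4)
  expect_equal(css_steady_state(ka, 1, 0, Vd, CL, tau, t), 0)
})

test_that("steady state is periodic and nonnegative over the interval", {
  set.seed(11)
  for (i in 1:50) {
    ka <- runif(1, 0.5, 5); Vd <- runif(1, 5, 80); CL <- runif(1, 0.1, 2)
    tau <- sample(c(6, 8, 12, 24), 1)
    expect_equal(css_steady_state(ka, 1, 500, Vd, CL, tau, 0),
                 css_steady_state(ka, 1, 500, Vd, CL, tau, tau))
    tgrid <- seq(0, tau, length.out = 101)
    expect_true(all(css_steady_state(ka, 1, 500, Vd, CL, tau, tgrid) >= 0))
  }
})

test_that("mean concentration over the interval equals F*X0/(CL*tau)", {
  set.seed(12)
  for (i in 1:100) {
    ka <- runif(1, 0.5, 5); Vd <- runif(1, 5, 80); CL <- runif(1, 0.1, 2)
    tau <- runif(1, 6, 24); X0 <- runif(1, 125, 900)
    q <- stats::integrate(function(tt) css_steady_state(ka, 1, X0, Vd, CL, tau, tt),
                          0, tau, rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(q / tau, X0 / (CL * tau), tolerance = 1e-6)
  }
})

test_that("concentration increases with dose and decreases with clearance", {
  set.seed(13)
  for (i in 1:100) {
    Vd <- runif(1, 5, 80); tau <- sample(c(12, 24), 1)
    ka <- runif(1, 10 / tau, 5 + 10 / tau)  # accumulation-dominated: ka*tau > 10
    CL <- runif(1, 0.1, 2); t <- runif(1, 0, tau)
    expect_lt(css_steady_state(ka, 1, 400, Vd, CL, tau, t),
              css_steady_state(ka, 1, 500, Vd, CL, tau, t))
    expect_gt(css_steady_state(ka, 1, 500, Vd, CL * 0.8, tau, t),
              css_steady_state(ka, 1, 500, Vd, CL, tau, t))
  }
})

test_that("time of peak concentration lies between 1 and 2 hours", {
  tgrid <- seq(0, 12, by = 0.001)
  conc <- css_steady_state(2.38, 1, 500, 22.15, 0.64, 12, tgrid)
  tpeak <- tgrid[which.max(conc)]
  expect_gte(tpeak, 1)
  expect_lte(tpeak, 2)
})

test_that("invalid parameters are rejected", {
  expect_error(css_steady_state(2, 1, 500, 10, 20, 12, 2), "singular")
  expect_error(css_steady_state(-1, 1, 500, 10, 0.5, 12, 2))
  expect_error(css_steady_state(2, 1, 500, 10, 0.5, 12, 13))  # t > tau
  expect_error(css_steady_state(2, 1.2, 500, 10, 0.5, 12, 2)) # F > 1
})

test_that("clearance submodel A matches its covariate formula", {
  expect_equal(clearance_model_a(38.7, "wildtype"), 0.64)
  expect_equal(clearance_model_a(38.7, "variant"), 0.64 * exp(-0.45))
  expect_equal(clearance_model_a(30, "wildtype"), 0.64 * (30 / 38.7)^(-1.06))
  expect_error(clearance_model_a(38.7, "unknown"))
  expect_error(clearance_model_a(-1, "wildtype"))
})

test_that("volume submodel A encodes the gender effect", {
  expect_equal(volume_model_a("female"), 22.15)
  expect_equal(volume_model_a("male"), 22.15 * exp(0.78))
  expect_equal(volume_model_a("male") / volume_model_a("female"), exp(0.78))
  expect_error(volume_model_a(NA))
})

test_that("clearance submodel B combines weight, dose and inducer multipliers", {
  expect_equal(clearance_model_b(60, 1000), 0.1 * 1000^0.2)
  expect_equal(clearance_model_b(60, 1000, c("CBZ", "PHT", "PB")),
               0.1 * 1000^0.2 * 1.36 * 1.25 * 1.11)
  expect_equal(clearance_model_b(60, 1000, "CBZ") / clearance_model_b(60, 1000),
               1.36)
  # order independence
  expect_equal(clearance_model_b(70, 900, c("PB", "CBZ")),
               clearance_model_b(70, 900, c("CBZ", "PB")))
  expect_error(clearance_model_b(60, 1000, "TPM"))
})

test_that("volume submodel B is linear in body weight", {
  expect_equal(volume_model_b(60), 8.4)
  expect_equal(volume_model_b(100), 14.0)
  expect_equal(volume_model_b(2 * 73), 2 * volume_model_b(73))
})

test_that("analytic steady-state AUC equals the integral of the profile", {
  expect_equal(steady_state_auc_analytic(500, 1, 0.64), 781.25)
  expect_equal(steady_state_auc_analytic(0, 1, 0.64), 0)
  tgrid <- seq(0, 12, length.out = 10001)
  conc <- css_steady_state(2.38, 1, 500, 22.15, 0.64, 12, tgrid)
  quad <- sum(diff(tgrid) * (head(conc, -1) + tail(conc, -1)) / 2)
  expect_equal(quad, 781.25, tolerance = 1e-6)
})

test_that("no covariate combination approaches the singular prefactor", {
  # for any single patient, Vd*ka stays well above CL in both submodels
  cl_max_a <- clearance_model_a(10, "wildtype")        # very low albumin
  expect_gt(22.15 * 2.38, 5 * cl_max_a)
  for (BW in c(20, 40, 60, 100, 200)) {
    cl_b <- clearance_model_b(BW, 3600, c("CBZ", "PHT", "PB"))
    expect_gt(volume_model_b(BW) * 1.90, 5 * cl_b)
  }
})
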