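# Study-design constants shared across the simulation, fusion and scenario
# stages.  Kept in one place so an alternative pair of covariate models can be
# plugged in without touching the pipeline code.

#' Dosing design and population constants
#'
#' Returns the fixed design of the virtual-patient study: the discrete single
#' dose set and dosing-interval set (both sampled uniformly), the covariate
#' distribution moments of the two source populations, the absorption rate
#' constants of the two submodels, the concentration retention bound, and the
#' moments of the merged cohort used by the exposure scenarios.
#'
#' @return A nested list of constants (units: mg, kg, g/L, h, mg/L).
#' @export
vpa_defaults <- function() {
  list(
    dose_set = c(125, 250, 300, 350, 400, 450, 500, 550, 600, 650,
                 700, 750, 800, 850, 900),
    tau_set = c(6, 8, 12, 24),
    css_max = 150,
    model_a = list(ka = 2.38, BW_mean = 66.5, BW_sd = 12.1,
                   ALB_mean = 38.9, ALB_sd = 6.4),
    model_b = list(ka = 1.90, BW_mean = 60.2, BW_sd = 12.5),
    # covariate moments of the merged filtered cohort, used when simulating
    # exposure-scenario patients
    merged = list(BW_mean = 64.3, BW_sd = 12.4, ALB_mean = 37.9, ALB_sd = 5.6),
    comed_combos = list("CBZ", "PHT", "PB", c("CBZ", "PHT"), c("CBZ", "PB"),
                        c("PHT", "PB"), c("CBZ", "PHT", "PB"))
  )
}

# canonical feature schema of the fused table, in column order
feature_schema <- function() {
  c("Single Dose", "BW", "ALB", "t", "tau", "Daily Dose",
    "CYP2C19*1/*1", "CYP2C19*2 and/or *3 variants", "Male",
    "Co-administered CBZ", "Co-administered PHT", "Co-administered PB",
    "Co-administered CBZ+PHT", "Co-administered CBZ+PB",
    "Co-administered PHT+PB", "Co-administered CBZ+PHT+PB")
}

continuous_features <- function() {
  c("Single Dose", "BW", "ALB", "t", "tau", "Daily Dose")
}

simplified_drop_features <- function() {
  c("Single Dose", "ALB", "t", "tau")
}

comed_levels <- function() {
  c("None", "CBZ", "PHT", "PB", "CBZ+PHT", "CBZ+PB", "PHT+PB", "CBZ+PHT+PB")
}
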