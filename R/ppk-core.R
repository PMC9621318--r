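#' One-compartment oral steady-state concentration
#'
#' Concentration at time `t` within a dosing interval at steady state after
#' repeated first-order oral absorption, for a one-compartment disposition
#' model:
#'
#' \deqn{C_{ss}(t) = \frac{k_a F X_0}{V_d k_a - CL}\left(
#'   \frac{e^{-CL\,t/V_d}}{1 - e^{-CL\,\tau/V_d}} -
#'   \frac{e^{-k_a t}}{1 - e^{-k_a \tau}}\right)}
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param ka first-order absorption rate constant (1/h), > 0.
#' @param F_bio absolute bioavailability (fraction in (0, 1]); valproic acid
#'   oral formulations are essentially completely absorbed, so the default
#'   is 1.
#' @param X0 single dose (mg), >= 0.
#' @param Vd apparent volume of distribution (L), > 0.
#' @param CL total clearance (L/h), > 0.
#' @param tau dosing interval (h), > 0.
#' @param t time since the last dose (h), in `[0, tau]`.
#' @return Steady-state concentration (mg/L), same length as the recycled
#'   inputs.  The function is periodic in `t` with period `tau`:
#'   `t = 0` and `t = tau` give identical values.
#' @details The prefactor is singular at `Vd * ka == CL` ("flip-flop"
#'   coincidence); that parameter combination is rejected rather than handled
#'   by its analytic limit, because it cannot arise from either covariate
#'   submodel (absorption is fast relative to elimination for this drug).
#' @seealso [clearance_model_a()], [clearance_model_b()],
#'   [steady_state_auc_analytic()]
#' @export
#' @examples
#' css_steady_state(ka = 2.38, X0 = 500, Vd = 22.15, CL = 0.64, tau = 12, t = 2)
css_steady_state <- function(ka, F_bio = 1, X0, Vd, CL, tau, t) {
  stopifnot(all(ka > 0), all(CL > 0), all(Vd > 0),
            all(F_bio > 0), all(F_bio <= 1),
            all(X0 >= 0), all(tau > 0), all(t >= 0), all(t <= tau))
  if (any(abs(Vd * ka - CL) < 1e-10)) {
    stop("singular parameter combination: Vd * ka == CL")
  }
  ka * F_bio * X0 / (Vd * ka - CL) *
    (exp(-CL * t / Vd) / (1 - exp(-CL * tau / Vd)) -
       exp(-ka * t) / (1 - exp(-ka * tau)))
}

#' Clearance submodel A: albumin and CYP2C19 genotype
#'
#' Typical-value clearance for the albumin/genotype covariate model:
#' `CL = 0.64 * (ALB / 38.7)^(-1.06)`, multiplied by `exp(-0.45)` for
#' carriers of loss-of-function CYP2C19 variant alleles (*2 and/or *3).
#' Lower albumin means a larger unbound fraction and faster clearance;
#' variant carriers clear the drug more slowly.
#'
#' @param ALB serum albumin (g/L), > 0.
#' @param genotype `"wildtype"` (\*1/\*1) or `"variant"` (any \*2/\*3
#'   carrier).  This submodel requires a known genotype.
#' @return Clearance (L/h).
#' @export
#' @examples
#' clearance_model_a(38.7, "wildtype")  # 0.64 by construction
#' clearance_model_a(30, "variant")
clearance_model_a <- function(ALB, genotype) {
  stopifnot(all(ALB > 0))
  genotype <- match.arg2(genotype, c("wildtype", "variant"), length(ALB))
  0.64 * (ALB / 38.7)^(-1.06) * ifelse(genotype == "variant", exp(-0.45), 1)
}

#' Volume submodel A: gender
#'
#' Typical apparent volume of distribution: 22.15 L for females,
#' `22.15 * exp(0.78)` L for males.
#'
#' @param gender `"male"` or `"female"`; missing values are rejected.
#' @return Apparent volume of distribution (L).
#' @export
volume_model_a <- function(gender) {
  gender <- match.arg2(gender, c("male", "female"))
  ifelse(gender == "male", 22.15 * exp(0.78), 22.15)
}

#' Clearance submodel B: body weight, daily dose, enzyme inducers
#'
#' Typical-value clearance with allometric body-weight scaling, a dose
#' effect reflecting saturable protein binding, and multiplicative
#' induction factors for co-administered enzyme-inducing antiepileptics:
#' `CL = 0.1 * (BW / 60)^0.7 * DailyDose^0.2`, times 1.36 for
#' carbamazepine (CBZ), 1.25 for phenytoin (PHT) and 1.11 for
#' phenobarbital (PB).  The multipliers are order-independent.
#'
#' @param BW body weight (kg), > 0.
#' @param daily_dose total daily dose (mg), > 0.
#' @param comeds character vector (or list of character vectors, one per
#'   patient) drawn from `c("CBZ", "PHT", "PB")`; empty means no inducer.
#' @return Clearance (L/h).
#' @export
#' @examples
#' clearance_model_b(60, 1000, character())
#' clearance_model_b(60, 1000, c("CBZ", "PHT", "PB"))
clearance_model_b <- function(BW, daily_dose, comeds = character()) {
  stopifnot(all(BW > 0), all(daily_dose > 0))
  if (!is.list(comeds)) comeds <- list(comeds)
  bad <- setdiff(unique(unlist(comeds)), c("CBZ", "PHT", "PB"))
  if (length(bad)) stop("unknown co-medication: ", paste(bad, collapse = ", "))
  mult <- vapply(comeds, function(cm) {
    prod(c(1, 1.36, 1.25, 1.11)[c(TRUE, c("CBZ", "PHT", "PB") %in% cm)])
  }, numeric(1))
  0.1 * (BW / 60)^0.7 * daily_dose^0.2 * mult
}

#' Volume submodel B: body weight
#'
#' `Vd = 0.14 * BW` (L).
#'
#' @inheritParams clearance_model_b
#' @return Apparent volume of distribution (L).
#' @export
volume_model_b <- function(BW) {
  stopifnot(all(BW > 0))
  0.14 * BW
}

#' Closed-form steady-state AUC over one dosing interval
#'
#' At steady state the area under the concentration-time curve over one
#' dosing interval equals `F * X0 / CL`, independent of `ka`, `Vd` and
#' `tau`.  Used throughout the test suite as the analytic oracle for the
#' trapezoidal integrator and the simulator.
#'
#' @inheritParams css_steady_state
#' @return AUC over one interval (mg h/L).
#' @export
#' @examples
#' steady_state_auc_analytic(500, 1, 0.64)  # 781.25
steady_state_auc_analytic <- function(X0, F_bio = 1, CL) {
  stopifnot(all(CL > 0), all(X0 >= 0))
  F_bio * X0 / CL
}

# vectorised match.arg with NA rejection
match.arg2 <- function(x, choices, n = length(x)) {
  x <- as.character(x)
  if (length(x) == 1L && n > 1L) x <- rep(x, n)
  if (anyNA(x) || !all(x %in% choices)) {
    stop("value must be one of: ", paste(choices, collapse = ", "))
  }
  x
}
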