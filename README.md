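# ppkfuse

Different published population-pharmacokinetic (popPK) models of the same
drug explain its variability through different covariates, and none of them
can answer questions that cross covariate sets.  `ppkfuse` implements a
covariate-integration pipeline for valproic acid (VPA): it simulates large
virtual patient populations from two published one-compartment covariate
models — one driven by serum albumin and CYP2C19 genotype, one by body
weight, daily dose and enzyme-inducing co-medication — fuses the simulated
cohorts into a single 16-feature machine-learning dataset, trains and
benchmarks tree-ensemble regressors of steady-state concentration,
interprets the chosen model with exact interventional Shapley attributions,
and simulates genotype × co-medication exposure scenarios via trapezoidal
AUC.  It is aimed at pharmacometricians and clinical-pharmacology data
scientists exploring ML-assisted model-informed precision dosing.

## The model

Simulated concentrations follow the steady-state one-compartment oral model

    Css(t) = ka·F·X0 / (Vd·ka − CL) · [ e^(−CL·t/Vd) / (1 − e^(−CL·τ/Vd))
                                        − e^(−ka·t) / (1 − e^(−ka·τ)) ]

with typical-value clearance and volume from two covariate submodels
(albumin/genotype/gender, and allometric body weight/daily dose/inducer
multipliers 1.36 × 1.25 × 1.11 for carbamazepine/phenytoin/phenobarbital).
Virtual patients (20,000 + 14,000) are drawn from the published covariate
distributions, filtered at Css ≤ 150 mg/L, completed by k-nearest-neighbour
imputation, one-hot encoded, min-max scaled and split 8:2 into derivation
and validation cohorts.  A gradient-boosted tree regressor (xgboost,
library defaults) predicts Css from the 16 fused features; Shapley values
are computed exactly with an interventional tree algorithm implemented in
C++ and cross-checked against exhaustive coalition enumeration.

## Worked example

```r
library(ppkfuse)

pops <- simulate_populations(sim_config(seed = 1))
nrow(pops$a); nrow(pops$b)
#> [1] 14489
#> [1] 11706

ft <- build_feature_table(pops, seed = 1)      # 26,195 rows, 16 features
mean(ft$css)
#> [1] 73.78006

bundle <- fit_final(ft, seed = 1)              # default xgboost on 8/10 of rows
evaluate_bundle(bundle, ft)[c("MAE", "RMSE", "IR")]
#> $MAE   2.406802
#> $RMSE  3.328835
#> $IR    98.81657
```

So the fused virtual population retains 14,489 + 11,706 of 34,000 simulated
records after the concentration filter, the merged mean concentration is
73.8 mg/L, and the default gradient-boosted model predicts held-out
concentrations with a mean absolute error of 2.4 mg/L, 98.8% of them within
±20% of the simulated value.  Interpretation and scenario simulation:

```r
imp <- shap_importance(shap_attributions(
  bundle, ft$features[1:500, ], background_sample(ft, 512, seed = 1)))
head(imp, 3)
#>        feature mean_abs_phi
#>     Daily Dose       25.59
#>              t        8.66
#>  CYP2C19*2 ...        7.67

expo <- run_scenarios(bundle, canonical_scenarios(1))
expo$summary[3, c("scenario", "auc_mean", "cbar_mean")]
#>   scenario auc_mean cbar_mean
#>  scenario3   1174.8      97.9
```

Daily dose dominates the attribution ranking, and variant carriers without
inducer co-medication (scenario 3) reach a mean 12-hour AUC near
1,175 mg·h/L — the highest-exposure cell of the genotype × co-medication
grid.  See `vignettes/covariate-fusion.Rmd` for the science, the design
decisions and the known extrapolation limitation of the
out-of-support scenarios.

A thin command-line wrapper is installed at `inst/cli/ppkfuse.R`
(`Rscript ppkfuse.R --stage all --outdir out`, plus a `predict` stage that
scores a user CSV against a persisted model bundle).

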