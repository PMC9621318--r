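#' Pipeline configuration
#'
#' Assembles the configuration for an end-to-end run.  Every stage seed is
#' derived deterministically from the global `seed`, so a configuration
#' reproduces its data artifacts bit-identically.
#'
#' @param seed global integer seed.
#' @param n_per_scenario_a,n_per_combo_b,css_max see [sim_config()].
#' @param impute_k neighbours for [knn_impute()].
#' @param scaler_scope `"full"` or `"derivation"` (see
#'   [build_feature_table()]).
#' @param split_fraction derivation fraction.
#' @param cv_folds folds for [crossval_compare()].
#' @param background_size background rows for [shap_attributions()].
#' @param shap_sample number of rows to explain.
#' @param scenario_n_patients,scenario_n_times scenario cohort size.
#' @param grid optional hyperparameter lattice for [grid_search_xgb()]
#'   (`NULL` skips the search).
#' @return A nested list of class `ppk_config`.
#' @export
pipeline_config <- function(seed = 1L, n_per_scenario_a = 5000L,
                            n_per_combo_b = 2000L, css_max = 150,
                            impute_k = 5L, scaler_scope = "full",
                            split_fraction = 0.8, cv_folds = 10L,
                            background_size = 512L, shap_sample = 1000L,
                            scenario_n_patients = 1000L,
                            scenario_n_times = 200L, grid = NULL) {
  structure(list(
    seed = as.integer(seed),
    sim = sim_config(seed, n_per_scenario_a, n_per_combo_b, css_max),
    fusion = list(k = as.integer(impute_k), scaler_scope = scaler_scope,
                  split_fraction = split_fraction),
    training = list(cv_folds = as.integer(cv_folds), grid = grid),
    interpretation = list(background_size = as.integer(background_size),
                          shap_sample = as.integer(shap_sample)),
    scenarios = list(n_patients = as.integer(scenario_n_patients),
                     n_times = as.integer(scenario_n_times)),
    external = external_cohort_spec(seed = seed)),
    class = "ppk_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML document override the defaults of
#' [pipeline_config()]; unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return A `ppk_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(..., collapse = " ")))
}

#' Run the end-to-end pipeline
#'
#' Chains the stages simulate -> fuse -> train -> evaluate -> explain ->
#' scenarios -> external, writing CSV/JSON artifacts for each into `outdir`
#' and returning the in-memory results.  Individual stages can be selected;
#' later stages reuse earlier in-memory results when run together.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param stages character vector of stages to run (default all, in order).
#' @return Invisibly, a list with the stage results (`pops`, `table`,
#'   `bundle`, `metrics`, `cv`, `importance`, `exposure`, `external`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "ppkfuse-output",
                         stages = c("simulate", "fuse", "train", "evaluate",
                                    "explain", "scenarios", "external")) {
  stopifnot(inherits(config, "ppk_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  if ("simulate" %in% stages) {
    res$pops <- simulate_populations(config$sim)
    log_stage("simulate", "retained", nrow(res$pops$a), "+", nrow(res$pops$b),
              "of", sum(res$pops$raw_n), "records; seed", config$seed)
    utils::write.csv(rbind(res$pops$a, res$pops$b),
                     file.path(outdir, "simulated_records.csv"),
                     row.names = FALSE)
  }
  if ("fuse" %in% stages) {
    if (is.null(res$pops)) stop("fuse requires the simulate stage")
    res$table <- build_feature_table(res$pops, k = config$fusion$k,
                                     split_fraction = config$fusion$split_fraction,
                                     seed = config$seed,
                                     scaler_scope = config$fusion$scaler_scope)
    log_stage("fuse", nrow(res$table$features), "rows,",
              ncol(res$table$features), "features")
    fused <- cbind(res$table$features, Css = res$table$css,
                   split = res$table$split)
    utils::write.csv(fused, file.path(outdir, "fused_dataset.csv"),
                     row.names = FALSE)
    write_stage_json(list(min = as.list(res$table$scaler$min),
                          max = as.list(res$table$scaler$max)),
                     file.path(outdir, "scaler.json"))
  }
  if ("train" %in% stages) {
    if (is.null(res$table)) stop("train requires the fuse stage")
    res$cv <- crossval_compare(res$table, folds = config$training$cv_folds,
                               seed = config$seed)
    res$bundle <- fit_final(res$table, seed = config$seed)
    log_stage("train", "best CV model:",
              res$cv$model[which.min(res$cv$test_mae)])
    utils::write.csv(res$cv, file.path(outdir, "cv_comparison.csv"),
                     row.names = FALSE)
    save_model_bundle(res$bundle, file.path(outdir, "model_bundle"))
  }
  if ("evaluate" %in% stages) {
    if (is.null(res$bundle)) stop("evaluate requires the train stage")
    res$metrics <- evaluate_bundle(res$bundle, res$table)
    simp <- ablate_features(res$table)
    res$bundle_simplified <- fit_final(simp, seed = config$seed)
    res$metrics_simplified <- evaluate_bundle(res$bundle_simplified, simp)
    log_stage("evaluate", sprintf("validation MAE %.2f (full) / %.2f (simplified)",
                                  res$metrics$MAE, res$metrics_simplified$MAE))
    write_stage_json(list(full = res$metrics, simplified = res$metrics_simplified),
                     file.path(outdir, "validation_metrics.json"))
  }
  if ("explain" %in% stages) {
    if (is.null(res$bundle)) stop("explain requires the train stage")
    bg <- background_sample(res$table, config$interpretation$background_size,
                            seed = config$seed)
    idx <- which(res$table$split == "derivation")
    set.seed(config$seed * 2L + 302L)
    rows <- res$table$features[sample(idx, min(config$interpretation$shap_sample,
                                               length(idx))), , drop = FALSE]
    res$attr <- shap_attributions(res$bundle, rows, bg)
    res$importance <- shap_importance(res$attr)
    log_stage("explain", "top feature:", res$importance$feature[1])
    utils::write.csv(cbind(as.data.frame(res$attr$phi, check.names = FALSE)),
                     file.path(outdir, "shap_attributions.csv"), row.names = FALSE)
    write_stage_json(res$importance, file.path(outdir, "shap_importance.json"))
  }
  if ("scenarios" %in% stages) {
    if (is.null(res$bundle)) stop("scenarios requires the train stage")
    specs <- canonical_scenarios(config$seed, config$scenarios$n_patients,
                                 config$scenarios$n_times)
    res$exposure <- run_scenarios(res$bundle, specs)
    log_stage("scenarios", sprintf("AUC ratio 3:2 = %.3f",
                                   res$exposure$auc_ratio_3_2))
    utils::write.csv(do.call(rbind, lapply(names(res$exposure$patients),
      function(nm) cbind(scenario = nm, res$exposure$patients[[nm]]))),
      file.path(outdir, "exposure_per_patient.csv"), row.names = FALSE)
    write_stage_json(list(summary = res$exposure$summary,
                          auc_ratio_3_2 = res$exposure$auc_ratio_3_2),
                     file.path(outdir, "exposure_summary.json"))
  }
  if ("external" %in% stages) {
    if (is.null(res$bundle_simplified)) stop("external requires the evaluate stage")
    cohort <- generate_external_cohort(config$external)
    res$external <- evaluate_simplified(res$bundle_simplified, cohort)
    log_stage("external", sprintf("synthetic TDM cohort MAE %.2f",
                                  res$external$metrics$MAE))
    utils::write.csv(cohort, file.path(outdir, "external_cohort_synthetic.csv"),
                     row.names = FALSE)
    write_stage_json(res$external, file.path(outdir, "external_metrics.json"))
  }
  invisible(res)
}

#' Predict concentrations for user-supplied records
#'
#' Loads a persisted model bundle and predicts steady-state concentrations
#' for a CSV of records matching the bundle's feature schema (raw units; the
#' stored scaler is applied).  This is the batch counterpart of a bedside
#' dosing tool.
#'
#' @param bundle_dir directory written by [save_model_bundle()].
#' @param csv_in input CSV path with the schema columns.
#' @param csv_out optional output path; when given, the input plus a
#'   `predicted_css` column is written there.
#' @return data.frame: the input with `predicted_css` (mg/L).
#' @export
predict_css <- function(bundle_dir, csv_in, csv_out = NULL) {
  bundle <- load_model_bundle(bundle_dir)
  df <- utils::read.csv(csv_in, check.names = FALSE)
  missing_cols <- setdiff(bundle$schema, names(df))
  if (length(missing_cols)) {
    stop("input lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  df$predicted_css <- predict(bundle, df)
  if (!is.null(csv_out)) utils::write.csv(df, csv_out, row.names = FALSE)
  df
}
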