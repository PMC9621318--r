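# Default end-to-end configuration.  Any field of pipeline_config() may be
# overridden here; stage seeds derive from the global seed.
seed: 1
n_per_scenario_a: 5000
n_per_combo_b: 2000
css_max: 150
impute_k: 5
scaler_scope: full
split_fraction: 0.8
cv_folds: 10
background_size: 512
shap_sample: 1000
scenario_n_patients: 1000
scenario_n_times: 200
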