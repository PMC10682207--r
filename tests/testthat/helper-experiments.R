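# Heavy shared fixtures, computed lazily once per test run and cached.
#
# Problem sizes are scaled for a routine test run (documented in the methods
# vignette): band selection uses a 19-point alpha grid and 5 CV folds, the SVR
# grid search uses a 5 x 7 (C, gamma) grid with 3 folds on a 400-sample
# subsample.  All seeds fixed.

.lcc_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .lcc_cache)) {
    assign(name, force(expr), envir = .lcc_cache)
  }
  get(name, envir = .lcc_cache)
}

test_experiment_config <- function(target, split_counts = NULL, seed = 1) {
  experiment_config(
    target = target, split_counts = split_counts, seed = seed,
    selection_folds = 5, alpha_grid = seq(0.05, 0.95, by = 0.05),
    svr = svr_config(
      c_grid = 2^seq(0, 12, by = 3), gamma_grid = 2^seq(-14, -2, by = 2),
      k_folds = 3, seed = seed, search_max_n = 400
    )
  )
}

simulated_dataset <- function() {
  cached("sim_data", simulate_dataset())
}

simulated_report <- function() {
  cached("sim_report", {
    run_experiment(
      simulated_dataset(),
      test_experiment_config("cab", split_counts = c(1569, 531))
    )
  })
}

field_dataset <- function() {
  cached("field_data", generate_field_campaign(n = 69, seed = 7))
}

field_report <- function() {
  cached("field_report", {
    suppressWarnings(run_experiment(
      field_dataset(),
      test_experiment_config("spad", seed = 7)
    ))
  })
}
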