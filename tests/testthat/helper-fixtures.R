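# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# long-format observation rows for hand-built patients
make_obs <- function(patient_id, variable, t, value) {
  data.frame(patient_id = patient_id, variable = variable, t = t,
             value = value, stringsAsFactors = FALSE)
}

make_static <- function(patient_id, sex = "female", race = "white",
                        age_at_start = 60) {
  data.frame(patient_id = patient_id, sex = sex, race = race,
             age_at_start = age_at_start, stringsAsFactors = FALSE)
}

# small default-structure cohort shared across module tests
small_cohort <- function() memo("small_cohort", {
  generate_cohort(generator_config(n_patients = 250, seed = 101))
})

small_matched <- function() memo("small_matched", {
  build_matched_dataset(small_cohort(), spec = match_spec(seed = 5))
})

# a fast LSTM configuration for functional tests
tiny_lstm_cfg <- function(max_epochs = 5, ...) {
  lstm_config("essential_variables", lstm_units = 8, dense_layer_sizes = 8L,
              dropout_grid = 0, max_epochs = max_epochs, patience = 5,
              batch_size = 32, ...)
}
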