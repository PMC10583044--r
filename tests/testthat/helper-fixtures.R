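# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture_bundle <- function(scale = 1e6) {
  key <- sprintf("bundle_%g", scale)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <-
      generate_bundle(synthetic_spec(population_scale = scale))
  }
  fixture_env[[key]]
}

fixture_null_bundle <- function(scale = 1e6) {
  if (is.null(fixture_env$null_bundle)) {
    fixture_env$null_bundle <-
      generate_null_bundle(synthetic_spec(population_scale = scale))
  }
  fixture_env$null_bundle
}

fixture_result <- function() {
  if (is.null(fixture_env$result)) {
    fixture_env$result <- run_analysis(fixture_bundle())
  }
  fixture_env$result
}

fixture_null_result <- function() {
  if (is.null(fixture_env$null_result)) {
    fixture_env$null_result <- run_analysis(fixture_null_bundle())
  }
  fixture_env$null_result
}

summary_value <- function(res, horizon, measure) {
  s <- res$economics$summary
  s$value[s$horizon == horizon & s$measure == measure]
}
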