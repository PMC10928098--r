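# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small model-ready table: 33 settings x 7 concentrations x 2 replicates,
# raw renders (ROI fast path)
fixture_table <- function() {
  memo("small_table", function() {
    simulate_feature_table(phantom_design(n_replicates = 2, seed = 202),
                           wb_correct = "none")
  })
}

# the default full dataset (3465 rows), Gray-World-corrected full-frame
# renders: the model dataset of the headline experiments
fixture_full_table <- function() {
  memo("full_table", function() {
    simulate_feature_table(phantom_design(n_replicates = 15, seed = 101),
                           wb_correct = "gw")
  })
}

fixture_split <- function() {
  memo("full_split", function() split_dataset(fixture_full_table(),
                                              seed = 11))
}

expect_rgb_equal <- function(got, want, tol = 1e-9) {
  expect_equal(unname(as.numeric(got)), unname(as.numeric(want)),
               tolerance = tol)
}
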