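test_that("classify_nrs partitions [0, 10] with the stated cut-offs", {
  expect_equal(as.character(classify_nrs(c(2.5, 3.3, 6.6, 8.1))),
               c("mild", "moderate", "moderate", "severe"))
  expect_equal(as.character(classify_nrs(c(0, 10))), c("mild", "severe"))
  # every score maps to exactly one state, with no gaps at the boundaries
  grid <- seq(0, 10, by = 0.01)
  states <- classify_nrs(grid)
  expect_false(anyNA(states))
  expect_equal(sum(states == "mild") + sum(states == "moderate") +
                 sum(states == "severe"), length(grid))
  expect_true(all(states[grid < 3.3] == "mild"))
  expect_true(all(states[grid >= 3.3 & grid <= 6.6] == "moderate"))
  expect_true(all(states[grid > 6.6] == "severe"))
  expect_error(classify_nrs(10.5), "0, 10")
  expect_error(classify_nrs(-0.1), "0, 10")
})

test_that("transition estimator matches the hand count on four patients", {
  trial <- make_trial(list(c("mild", "mild"),
                           c("mild", "moderate"),
                           c("moderate", "moderate"),
                           c("severe", "severe")))
  est <- estimate_transition_matrix(trial, 1)
  expect_equal(unname(est$matrix),
               matrix(c(0.5, 0.5, 0,
                        0,   1,   0,
                        0,   0,   1), 3, 3, byrow = TRUE))
  expect_equal(est$n_at_risk, 4)
  expect_false(any(est$identity_rows))
})

test_that("a dataset without severity changes estimates the identity matrix", {
  trial <- make_trial(list(c("mild", "mild", "mild"),
                           c("moderate", "moderate", "moderate"),
                           c("severe", "severe", "severe")))
  for (cy in 1:2) {
    est <- estimate_transition_matrix(trial, cy)
    expect_equal(unname(est$matrix), diag(3))
  }
})

test_that("patients missing an endpoint are excluded; empty rows flagged as identity", {
  trial <- make_trial(list(c("mild", "moderate"),
                           c("mild", NA),          # excluded from the mild row
                           c(NA, "severe"),        # excluded entirely
                           c("moderate", "moderate")))
  est <- suppressWarnings(estimate_transition_matrix(trial, 1))
  expect_equal(unname(est$matrix[1, ]), c(0, 1, 0))
  expect_equal(est$n_at_risk, 2)
  expect_true(est$identity_rows[["severe"]])
  expect_equal(unname(est$matrix[3, ]), c(0, 0, 1))
  expect_warning(estimate_transition_matrix(trial, 1),
                 class = "markovboot_empty_row")
  # requesting transitions beyond the observed window is an error,
  # distinct from the per-row identity flag
  expect_error(estimate_transition_matrix(trial, 5), "beyond")
})

test_that("estimated matrices are always row-stochastic", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 3)
  for (cy in 1:5) {
    est <- suppressWarnings(estimate_transition_matrix(trial, cy))
    expect_true(all(est$matrix >= 0 & est$matrix <= 1))
    expect_equal(rowSums(est$matrix), c(mild = 1, moderate = 1, severe = 1),
                 tolerance = 1e-12)
  }
})

test_that("estimator is consistent for a known chain (pooled n = 5000)", {
  chain <- matrix(c(0.70, 0.25, 0.05,
                    0.15, 0.70, 0.15,
                    0.05, 0.35, 0.60), 3, 3, byrow = TRUE)
  trial <- simulate_chain_trial(chain, n = 5000, n_steps = 5, seed = 11)
  ests <- lapply(1:5, function(cy) estimate_transition_matrix(trial, cy)$matrix)
  pooled <- Reduce(`+`, ests) / length(ests)
  expect_lt(max(abs(pooled - chain)), 0.02)
})

test_that("estimate_utilities equals the brute-force pooled mean", {
  trial <- simulate_chain_trial(diag(3), n = 60, n_steps = 3, seed = 5)
  df <- as.data.frame(trial)
  # independent oracle: group-by mean over all observations
  oracle <- tapply(df$utility, classify_nrs(df$nrs), mean)
  est <- estimate_utilities(trial)
  expect_equal(unname(est$u), unname(as.numeric(oracle)), tolerance = 1e-12)

  # two moderate observations 0.4 and 0.6 average to 0.5
  two <- trial_dataset(data.frame(
    patient_id = c("A", "A", "B", "B"), stratum = "db_sativex",
    cycle = c(1, 2, 1, 2), nrs = c(5, 5, 2, 8),
    utility = c(0.4, 0.6, 0.7, 0.3)))
  est2 <- estimate_utilities(two)
  expect_equal(unname(est2$u[["moderate"]]), 0.5)
  expect_equal(unname(est2$u[["mild"]]), 0.7)
  expect_equal(unname(est2$u[["severe"]]), 0.3)

  # a state with no utility observations is an error naming the state
  onestate <- trial_dataset(data.frame(
    patient_id = "A", stratum = "db_sativex", cycle = 1, nrs = 2,
    utility = 0.7))
  expect_error(estimate_utilities(onestate), "moderate, severe")
})

test_that("trial dataset validates its invariants and round-trips CSV", {
  expect_error(trial_dataset(data.frame(patient_id = "A", stratum = "foo",
                                        cycle = 1, nrs = 5, utility = NA)),
               "stratum")
  expect_error(trial_dataset(data.frame(patient_id = "A",
                                        stratum = "db_sativex",
                                        cycle = 0, nrs = 5, utility = NA)),
               "positive")
  expect_error(trial_dataset(data.frame(patient_id = "A",
                                        stratum = "db_sativex",
                                        cycle = 1, nrs = 11, utility = NA)),
               "NRS")
  expect_error(trial_dataset(data.frame(patient_id = "A",
                                        stratum = "db_sativex",
                                        cycle = 1, nrs = 5, utility = 1.2)),
               "utility")
  expect_error(trial_dataset(data.frame(patient_id = c("A", "A"),
                                        stratum = "db_sativex",
                                        cycle = c(1, 1), nrs = 5,
                                        utility = NA)),
               "duplicate")

  cfg <- generator_config()
  trial <- generate_trial(cfg, 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(trial, path)
  back <- read_trial_csv(path)
  expect_equal(stratum_counts(back), stratum_counts(trial))
  expect_equal(back$nrs, trial$nrs)
  expect_equal(back$utility, trial$utility)
})

test_that("transition matrices round-trip through the long CSV dialect", {
  mats <- default_sativex_matrices()
  names(mats) <- seq_along(mats)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(mats, path)
  back <- read_matrix_csv(path)
  expect_equal(unname(back), unname(mats), tolerance = 1e-12)
})
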