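test_that("bootstrap replicates preserve stratum sizes and expert count", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 21)
  dp <- generate_delphi_panel(cfg, 22)
  set.seed(99)
  for (i in 1:10) {
    rep_i <- draw_bootstrap_replicate(trial, dp$panel)
    expect_equal(stratum_counts(rep_i$trial), stratum_counts(trial))
    expect_length(panel_experts(rep_i$panel), 8)
  }
})

test_that("a single-patient stratum resamples to that patient repeated", {
  trial <- make_trial(list(c("mild", "mild"), c("moderate", "severe"),
                           c("severe", "severe")),
                      strata = c("single_blind_only", "db_sativex",
                                 "db_placebo"))
  cfg <- generator_config()
  dp <- generate_delphi_panel(cfg, 1)
  set.seed(1)
  rep1 <- draw_bootstrap_replicate(trial, dp$panel)
  expect_equal(stratum_counts(rep1$trial), stratum_counts(trial))
  expect_equal(rep1$trial$nrs, trial$nrs[match(rep1$trial$patients$stratum,
                                               trial$patients$stratum), ])
})

test_that("identical seeds give bit-identical bootstrap results", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 31)
  dp <- generate_delphi_panel(cfg, 32)
  p1 <- run_bootstrap_psa(trial, dp$panel, dp$tariffs,
                          psa_config = bootstrap_config(12, seed = 7))
  p2 <- run_bootstrap_psa(trial, dp$panel, dp$tariffs,
                          psa_config = bootstrap_config(12, seed = 7))
  expect_identical(p1$replicates, p2$replicates)
  p3 <- run_bootstrap_psa(trial, dp$panel, dp$tariffs,
                          psa_config = bootstrap_config(12, seed = 8))
  expect_false(identical(p3$replicates$delta_qalys,
                         p1$replicates$delta_qalys))
})

test_that("identity-resample hook reduces the PSA to the point-estimate run", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 41)
  dp <- generate_delphi_panel(cfg, 42)
  point <- evaluate_cua(trial, dp$panel, dp$tariffs)
  psa <- run_bootstrap_psa(trial, dp$panel, dp$tariffs,
                           psa_config = bootstrap_config(1, seed = 5),
                           identity_resample = TRUE)
  expect_equal(psa$replicates$delta_costs, point$increments$delta_costs)
  expect_equal(psa$replicates$delta_qalys, point$increments$delta_qalys)
  expect_equal(psa$replicates$icer, point$increments$icer)
})

test_that("degenerate inputs give a zero-variance PSA", {
  inputs <- degenerate_inputs()
  psa <- run_bootstrap_psa(inputs$trial, inputs$panel, inputs$tariffs,
                           psa_config = bootstrap_config(20, seed = 3))
  for (h in 1:5) {
    s <- summarize_psa(psa$replicates, h)
    expect_equal(stats::sd(s$ce_plane$delta_qalys), 0)
    expect_equal(stats::sd(s$ce_plane$delta_costs), 0)
    expect_equal(s$ci_delta_qalys[[1]], s$ci_delta_qalys[[2]])
    expect_equal(s$ci_delta_costs[[1]], s$ci_delta_costs[[2]])
  }
})

test_that("PSA summary counts quadrants and interpolates percentiles", {
  mk_reps <- function(dc, dq) {
    data.frame(replicate_id = seq_along(dc), horizon = 1,
               delta_costs = dc, delta_qalys = dq,
               icer = ifelse(dq != 0, dc / dq, NA_real_))
  }
  # 4 of 10 replicates in the dominant (SE) quadrant
  reps <- mk_reps(c(-1, -2, -3, -4, 1, 2, 3, 4, -5, 5),
                  c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1))
  s <- summarize_psa(reps, 1)
  expect_equal(s$dominance_probability, 0.4)
  expect_equal(sum(s$quadrant_counts), 10)
  expect_equal(as.vector(s$quadrant_counts), c(2, 4, 1, 3))  # ne, se, sw, nw
  expect_equal(s$prob_qaly_gain, 0.6)

  all_dom <- mk_reps(rep(-1, 10), rep(0.1, 10))
  expect_equal(summarize_psa(all_dom, 1)$dominance_probability, 1)

  # interpolated 2.5 / 97.5 percentiles of 1..100 (independent hand
  # computation: h = 0.025 * 99 + 1 = 3.475 and h = 0.975 * 99 + 1 = 97.525)
  reps100 <- mk_reps(as.numeric(1:100), rep(1, 100))
  s100 <- summarize_psa(reps100, 1)
  expect_equal(unname(s100$ci_delta_costs), c(3.475, 97.525))

  expect_error(summarize_psa(reps, 3), "no replicates")
})

test_that("Monte Carlo engine: degenerate dispersion reproduces the point run", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 51)
  dp <- generate_delphi_panel(cfg, 52)
  point <- evaluate_cua(trial, dp$panel, dp$tariffs)
  disp <- mc_dispersion(point, sample_transitions = FALSE,
                        sample_utilities = FALSE, sample_costs = FALSE)
  mc <- run_monte_carlo_psa(point, disp, n_replicates = 4, seed = 9)
  for (b in 1:4) {
    r <- mc$replicates[mc$replicates$replicate_id == b, ]
    expect_equal(r$delta_costs, point$increments$delta_costs)
    expect_equal(r$delta_qalys, point$increments$delta_qalys)
  }
})

test_that("Monte Carlo sampled transition rows stay on the simplex", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 61)
  est <- suppressWarnings(estimate_transition_matrix(trial, 3, "db_sativex"))
  set.seed(2)
  for (i in 1:50) {
    m <- markovboot:::sample_transition_matrix(est)
    expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(m >= 0))
    # structural zeros of the point estimate are preserved by the Dirichlet
    expect_true(all(m[est$matrix == 0] == 0))
  }
})

test_that("Monte Carlo runs are seed-reproducible and summarised identically", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 71)
  dp <- generate_delphi_panel(cfg, 72)
  point <- evaluate_cua(trial, dp$panel, dp$tariffs)
  m1 <- run_monte_carlo_psa(point, n_replicates = 15, seed = 4)
  m2 <- run_monte_carlo_psa(point, n_replicates = 15, seed = 4)
  expect_identical(m1$replicates, m2$replicates)
  expect_s3_class(m1$summary, "psa_summary")
  expect_equal(nrow(m1$summary$table), 5)
  expect_true(all(m1$summary$table$dominance_probability >= 0 &
                    m1$summary$table$dominance_probability <= 1))
})

test_that("bootstrap 95% interval for the 5-year QALY gain covers the truth", {
  # scaled-down coverage check: 40 regenerated trials, 150 replicates each;
  # the generator truth is computed from the configured chains and utilities
  cfg <- generator_config(coupling = 0)
  truth <- generator_truth(cfg)
  mcfg <- model_config()
  sched <- build_schedule(truth$sat_matrices, default_soc_matrix(), mcfg)
  sat <- run_cohort(mcfg, sched, truth$utilities, NULL, "sativex")
  soc <- run_cohort(mcfg, sched, truth$utilities, NULL, "soc")
  true_dq5 <- sat$discounted_qalys_by_horizon[["5"]] -
    soc$discounted_qalys_by_horizon[["5"]]
  dp <- generate_delphi_panel(cfg, 1000)

  covered <- vapply(1:40, function(i) {
    trial <- generate_trial(cfg, 2000 + i)
    psa <- run_bootstrap_psa(trial, dp$panel, dp$tariffs, mcfg,
                             bootstrap_config(150, seed = 3000 + i))
    ci <- summarize_psa(psa$replicates, 5)$ci_delta_qalys
    ci[[1]] <= true_dq5 && true_dq5 <= ci[[2]]
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("replicate and CE-plane CSV exports round-trip", {
  cfg <- generator_config()
  trial <- generate_trial(cfg, 81)
  dp <- generate_delphi_panel(cfg, 82)
  psa <- run_bootstrap_psa(trial, dp$panel, dp$tariffs,
                           psa_config = bootstrap_config(5, seed = 1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_replicates_csv(psa, f1)
  back <- utils::read.csv(f1)
  expect_equal(nrow(back), nrow(psa$replicates))
  write_ce_plane_csv(psa, f2, horizon = 5)
  plane <- utils::read.csv(f2)
  expect_equal(nrow(plane), 5)
  expect_named(plane, c("delta_qalys", "delta_costs"))
})

test_that("bootstrap preserves parameter-level correlations that independent MC discards", {
  # with strong positive coupling, replicates that resample better-improving
  # patients get both higher utilities and more favourable matrices; the
  # Monte Carlo comparator draws the two blocks independently
  cfg <- generator_config(coupling = 0.9)
  trial <- generate_trial(cfg, 200)
  dp <- generate_delphi_panel(cfg, 201)

  boot_pars <- function(trial, B, seed) {
    set.seed(seed)
    out <- matrix(NA_real_, B, 2)
    for (b in seq_len(B)) {
      r <- draw_bootstrap_replicate(trial, dp$panel)
      u <- estimate_utilities(r$trial)
      est <- suppressWarnings(
        estimate_transition_matrix(r$trial, 4, "db_sativex"))
      out[b, ] <- c(mean(u$u), est$matrix["moderate", "mild"])
    }
    out
  }
  bp <- boot_pars(trial, 600, 42)
  expect_gt(cor(bp[, 1], bp[, 2]), 0.1)

  # same statistic with the coupling switched off is near zero
  trial0 <- generate_trial(generator_config(coupling = 0), 200)
  bp0 <- boot_pars(trial0, 600, 44)
  expect_lt(abs(cor(bp0[, 1], bp0[, 2])), 0.1)

  # the Monte Carlo parameter draws are independent by construction
  point <- evaluate_cua(trial, dp$panel, dp$tariffs)
  set.seed(43)
  u_mc <- replicate(1000, mean(stats::rnorm(3, point$utilities$u,
                                            point$utilities$se)))
  p_mc <- replicate(1000, markovboot:::sample_transition_matrix(
    point$sat_estimates[[4]])["moderate", "mild"])
  expect_lt(abs(cor(u_mc, p_mc)), 0.1)
})
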