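test_that("compose_full_matrix layers discontinuation and death correctly", {
  # staying mild with certainty, 3.8% discontinuation, no deaths:
  # the on-treatment mild row keeps 0.962 and sends 0.038 to soc_mild
  sev <- identity_severity()
  p <- compose_full_matrix(sev, sev, 0.038, 0)
  expect_equal(p["sat_mild", "sat_mild"], 0.962)
  expect_equal(p["sat_mild", "soc_mild"], 0.038)
  expect_equal(sum(p["sat_mild", c("sat_mild", "soc_mild")]), 1)

  # no discontinuation and no death embeds the severity blocks unchanged
  m <- default_sativex_matrices()[[1]]
  p0 <- compose_full_matrix(m, m, 0, 0)
  expect_equal(unname(p0[1:3, 1:3]), unname(m))
  expect_equal(unname(p0[4:6, 4:6]), unname(m))
  expect_equal(unname(p0[, 7]), c(rep(0, 6), 1))

  # certain death turns every living row into the death unit vector
  p1 <- compose_full_matrix(m, m, 0.038, 1)
  expect_equal(unname(p1[1:6, 7]), rep(1, 6))
  expect_equal(unname(rowSums(p1)), rep(1, 7))

  # standard-care rows never re-initiate treatment
  expect_true(all(p0[4:6, 1:3] == 0))

  expect_error(compose_full_matrix(matrix(1, 3, 3), sev, 0, 0), "row 1")
})

test_that("load_published_matrix divides out discontinuation and renormalises", {
  # printed cycle-4 mild row (0.962, 0, 0) with d = 0.038 recovers (1, 0, 0)
  pub4 <- published_sativex_matrices()$matrices[[4]]
  m4 <- load_published_matrix(pub4, 0.038)
  expect_equal(unname(m4[1, ]), c(1, 0, 0))

  # with d = 0 a stochastic matrix is unchanged
  m1 <- published_sativex_matrices()$matrices[[1]]
  expect_equal(unname(load_published_matrix(m1, 0)), unname(m1))

  # printed cycle-2 severe row (0.048, 0.433, 0.481) with d = 0.038
  pub2 <- published_sativex_matrices()$matrices[[2]]
  m2 <- load_published_matrix(pub2, 0.038)
  expect_equal(unname(m2[3, ]), c(0.0499, 0.4501, 0.5000), tolerance = 1e-3)
  expect_equal(unname(rowSums(m2)), rep(1, 3), tolerance = 1e-12)

  # a row whose sum is not 1 - d within print rounding is rejected by name
  bad <- pub2; bad[2, 2] <- bad[2, 2] + 0.02
  expect_error(load_published_matrix(bad, 0.038), "row 2")
})

test_that("published matrices round-trip: load + compose reprints the table", {
  pub <- published_sativex_matrices()
  cond <- default_sativex_matrices()
  for (cy in seq_along(cond)) {
    p <- compose_full_matrix(cond[[cy]], identity_severity(),
                             pub$discontinuation[cy], 0)
    expect_lt(max(abs(p[1:3, 1:3] - pub$matrices[[cy]])), 0.002)
  }
})

test_that("discount factors follow the elapsed-time convention", {
  expect_equal(discount_factor(7, 0), 1)
  expect_equal(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(14, 0.03), 1.03^(-13 * 28 / 365.25))
  expect_equal(discount_factor(14, 0.03), 0.97098, tolerance = 1e-5)
  # annual-step alternative: constant within the first year
  expect_equal(discount_factor(13, 0.03, method = "annual"), 1)
  expect_equal(discount_factor(15, 0.03, method = "annual"), 1 / 1.03)
})

test_that("cohort run matches closed forms", {
  # an immortal cohort in a utility-1 state accrues 65 * 28 / 365.25 QALYs
  cfg <- plain_config(initial_distribution = c(1, 0, 0))
  sched <- build_schedule(identity_severity(), identity_severity(), cfg)
  out <- run_cohort(cfg, sched, utility_set(1, 1, 1), NULL, "sativex")
  expect_equal(out$total_qalys, 65 * 28 / 365.25, tolerance = 1e-12)
  expect_equal(out$total_qalys, 4.9829, tolerance = 1e-4)

  # certain death at the end of cycle 1: exactly one cycle of accrual
  cfg1 <- model_config(discount_rate_costs = 0, discount_rate_qalys = 0,
                       mortality_per_cycle = rep(1, 65),
                       discontinuation_per_cycle = rep(0, 65),
                       initial_distribution = c(0, 1, 0))
  sched1 <- build_schedule(identity_severity(), identity_severity(), cfg1)
  out1 <- run_cohort(cfg1, sched1, utility_set(0.9, 0.7, 0.5), NULL, "sativex")
  expect_equal(out1$total_qalys, 0.7 * 28 / 365.25, tolerance = 1e-12)

  # two-state toy: P = [[0.5, 0.5], [0, 1]], utilities (1, 0), two cycles
  toy <- matrix(c(0.5, 0.5, 0,
                  0,   1,   0,
                  0,   0,   1), 3, 3, byrow = TRUE)
  cfg2 <- plain_config(n_cycles = 2, initial_distribution = c(1, 0, 0))
  sched2 <- build_schedule(toy, toy, cfg2)
  out2 <- run_cohort(cfg2, sched2, utility_set(1, 0, 0), NULL, "sativex")
  expect_equal(out2$total_qalys, (1 + 0.5) * 28 / 365.25, tolerance = 1e-12)
  expect_equal(unname(out2$trace[2, 1:2]), c(0.5, 0.5))
  expect_equal(unname(out2$trace[3, 1:2]), c(0.25, 0.75))
})

test_that("trace conserves probability and death occupancy never decreases", {
  cfg <- model_config()
  sched <- build_schedule(default_sativex_matrices(), default_soc_matrix(), cfg)
  for (arm in c("sativex", "soc")) {
    out <- run_cohort(cfg, sched, utility_set(0.594, 0.509, 0.499), NULL, arm)
    expect_equal(rowSums(out$trace), rep(1, 66), tolerance = 1e-9)
    expect_true(all(diff(out$trace[, "death"]) >= -1e-15))
    expect_true(all(diff(out$discounted_qalys_by_horizon) > 0))
  }
})

test_that("QALYs increase with utilities and decrease with discounting", {
  cfg <- model_config()
  sched <- build_schedule(default_sativex_matrices(), default_soc_matrix(), cfg)
  base <- run_cohort(cfg, sched, utility_set(0.594, 0.509, 0.499), NULL,
                     "sativex")
  up <- run_cohort(cfg, sched, utility_set(0.694, 0.509, 0.499), NULL,
                   "sativex")
  expect_gt(up$total_qalys, base$total_qalys)

  cfg_hi <- model_config(discount_rate_qalys = 0.05)
  hi <- run_cohort(cfg_hi, sched, utility_set(0.594, 0.509, 0.499), NULL,
                   "sativex")
  expect_lt(hi$total_qalys, base$total_qalys)
  expect_true(all(hi$discounted_qalys_by_horizon <
                    base$discounted_qalys_by_horizon))
})

test_that("incremental outcomes compute ICER, dominance, and guards", {
  mk <- function(costs, qalys) {
    structure(list(discounted_costs_by_horizon = c(`5` = costs),
                   discounted_qalys_by_horizon = c(`5` = qalys)),
              class = "arm_outcome")
  }
  r1 <- incremental_outcomes(mk(1100, 3.01), mk(1000, 3.00), 5)
  expect_equal(r1$icer, 10000)
  expect_false(r1$dominant)

  r2 <- incremental_outcomes(mk(500, 3.1), mk(1000, 3.0), 5)
  expect_equal(r2$icer, -5000)
  expect_true(r2$dominant)

  r3 <- incremental_outcomes(mk(900, 3), mk(1000, 3), 5)
  expect_true(is.na(r3$icer))
  expect_false(r3$dominant)

  expect_error(incremental_outcomes(mk(1, 1), mk(1, 1), 3), "horizon")
})

test_that("schedule and config lengths must agree", {
  cfg <- plain_config(n_cycles = 10)
  sched <- build_schedule(identity_severity(), identity_severity(),
                          plain_config(n_cycles = 9))
  expect_error(run_cohort(cfg, sched, utility_set(1, 1, 1)), "schedule")
})
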