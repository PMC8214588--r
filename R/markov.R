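# The seven-state cohort Markov engine: model configuration, composition of
# the full 7x7 per-cycle matrices from 3x3 severity blocks, discounting, the
# cohort trace, and incremental outcomes.

#' Model configuration
#'
#' Collects the structural constants of the cohort model: 65 cycles of 28
#' days (13 cycles/year, 5-year horizon), annual discount rates of 3.0% for
#' costs and 1.5% for QALYs, background mortality ramping with cohort age
#' from 0.020% per cycle (age 51) to 0.035% (age 56), and treatment
#' discontinuation of 0 in cycle 1, 3.8% per cycle in cycles 2-4 and 3.5%
#' from cycle 5 onward.
#'
#' The initial severity distribution is a required modelling input; the
#' default 0 / 0.5 / 0.5 over mild / moderate / severe is a documented
#' placeholder matching the trial's moderate-to-severe entry criterion.
#'
#' @param n_cycles Number of model cycles (default 65).
#' @param cycle_days Cycle length in days (default 28).
#' @param cycles_per_year Cycles per model year for horizon bookkeeping
#'   (default 13; horizon h years = cycles 1..13h).
#' @param discount_rate_costs,discount_rate_qalys Annual discount rates.
#' @param starting_age Cohort age at model start, years (informational).
#' @param mortality_per_cycle Vector of length `n_cycles` of per-cycle death
#'   probabilities; default is a linear ramp 0.00020 to 0.00035.
#' @param discontinuation_per_cycle Vector of length `n_cycles` of per-cycle
#'   treatment discontinuation probabilities; default 0, then 0.038 for
#'   cycles 2-4, then 0.035.
#' @param initial_distribution Probability vector over (mild, moderate,
#'   severe) at model start; must sum to 1.
#' @param days_per_year Days per year used for time conversion (365.25).
#' @param discount_method `"continuous"` (exact elapsed-time exponent,
#'   default) or `"annual"` (per-completed-year steps); see
#'   [discount_factor()].
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_cycles = 65L,
                         cycle_days = 28,
                         cycles_per_year = 13L,
                         discount_rate_costs = 0.03,
                         discount_rate_qalys = 0.015,
                         starting_age = 51,
                         mortality_per_cycle = NULL,
                         discontinuation_per_cycle = NULL,
                         initial_distribution = c(mild = 0, moderate = 0.5,
                                                  severe = 0.5),
                         days_per_year = 365.25,
                         discount_method = c("continuous", "annual")) {
  n_cycles <- as.integer(n_cycles)
  discount_method <- match.arg(discount_method)
  if (is.null(mortality_per_cycle)) {
    mortality_per_cycle <- seq(0.00020, 0.00035, length.out = n_cycles)
  }
  if (is.null(discontinuation_per_cycle)) {
    discontinuation_per_cycle <-
      c(0, rep(0.038, min(3L, max(0L, n_cycles - 1L))),
        rep(0.035, max(0L, n_cycles - 4L)))[seq_len(n_cycles)]
  }
  stopifnot(length(mortality_per_cycle) == n_cycles,
            length(discontinuation_per_cycle) == n_cycles,
            all(mortality_per_cycle >= 0 & mortality_per_cycle <= 1),
            all(discontinuation_per_cycle >= 0 & discontinuation_per_cycle <= 1),
            length(initial_distribution) == 3L,
            all(initial_distribution >= 0))
  if (abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("initial_distribution must sum to 1", call. = FALSE)
  }
  structure(list(n_cycles = n_cycles, cycle_days = cycle_days,
                 cycles_per_year = as.integer(cycles_per_year),
                 discount_rate_costs = discount_rate_costs,
                 discount_rate_qalys = discount_rate_qalys,
                 starting_age = starting_age,
                 mortality_per_cycle = mortality_per_cycle,
                 discontinuation_per_cycle = discontinuation_per_cycle,
                 initial_distribution = stats::setNames(as.numeric(initial_distribution),
                                                        SEVERITY_LEVELS),
                 days_per_year = days_per_year,
                 discount_method = discount_method),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", x$n_cycles, "cycles x", x$cycle_days, "days;",
      "discounting", paste0(100 * x$discount_rate_costs, "%/",
                            100 * x$discount_rate_qalys, "%"),
      "(costs/QALYs,", x$discount_method, ")\n")
  cat("  initial distribution:",
      paste(names(x$initial_distribution), x$initial_distribution,
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Read a model configuration from YAML
#'
#' The YAML keys mirror the [model_config()] argument names; absent keys take
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [model_config()].
#' @export
read_model_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown model config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$initial_distribution)) {
    vals$initial_distribution <- unlist(vals$initial_distribution)
  }
  do.call(model_config, vals)
}

check_row_stochastic <- function(m, what, tol = 1e-8) {
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol | apply(m < -tol | m > 1 + tol, 1L, any))
  if (length(bad)) {
    stop(what, ": row ", bad[1L], " is not a probability row (sum = ",
         format(rs[bad[1L]], digits = 10), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Compose a full 7x7 per-cycle transition matrix
#'
#' Layers treatment discontinuation and background mortality onto the 3x3
#' severity transition matrices of the two arms. For an on-treatment row
#' `sat_i`: mass `death_p` goes to death; mass `(1 - death_p) *
#' discontinuation_p` goes to `soc_i` (the standard-care state of identical
#' severity -- a discontinuing patient keeps their current severity and
#' thereafter follows standard-care transitions with no drug cost); the rest
#' is spread over `sat_j` by the on-treatment severity matrix. Standard-care
#' rows split between death and `soc_j`; standard-care states place no mass
#' on treatment states (no re-initiation), and death is absorbing.
#'
#' @param sev_sat 3x3 row-stochastic severity matrix for on-treatment states
#'   (conditional on remaining on treatment and alive).
#' @param sev_soc 3x3 row-stochastic severity matrix for standard-care states.
#' @param discontinuation_p Per-cycle discontinuation probability.
#' @param death_p Per-cycle death probability.
#' @param validate Check inputs (disable only in inner loops that already
#'   validated them).
#' @return 7x7 matrix over [model_states()], every row summing to 1.
#' @export
compose_full_matrix <- function(sev_sat, sev_soc, discontinuation_p, death_p,
                                validate = TRUE) {
  if (validate) {
    check_row_stochastic(sev_sat, "on-treatment severity matrix")
    check_row_stochastic(sev_soc, "standard-care severity matrix")
    stopifnot(discontinuation_p >= 0, discontinuation_p <= 1,
              death_p >= 0, death_p <= 1)
  }
  p <- matrix(0, 7L, 7L, dimnames = list(MODEL_STATES, MODEL_STATES))
  live <- 1 - death_p
  stay <- live * (1 - discontinuation_p)
  p[1:3, 1:3] <- stay * sev_sat
  p[cbind(1:3, 4:6)] <- p[cbind(1:3, 4:6)] + live * discontinuation_p
  p[4:6, 4:6] <- live * sev_soc
  p[1:6, 7L] <- death_p
  p[7L, 7L] <- 1
  p
}

#' Recover a conditional severity matrix from published rows
#'
#' The published per-cycle matrices for the add-on arm are printed with
#' treatment discontinuation already removed, so each printed row sums to
#' `1 - discontinuation_p` up to print rounding (for example, the cycle-4
#' mild row sums to 0.962 = 1 - 0.038 exactly). This divides the printed
#' rows by `1 - discontinuation_p` and renormalises each row to sum exactly
#' to 1, yielding the severity matrix conditional on remaining on treatment.
#'
#' @param published 3x3 matrix as printed.
#' @param discontinuation_p Discontinuation probability embedded in the
#'   printed rows.
#' @param tol Allowed deviation of a printed row sum from
#'   `1 - discontinuation_p` (default 0.005, print rounding).
#' @return 3x3 row-stochastic matrix.
#' @export
load_published_matrix <- function(published, discontinuation_p, tol = 0.005) {
  stopifnot(is.matrix(published), all(dim(published) == c(3L, 3L)),
            discontinuation_p >= 0, discontinuation_p < 1)
  target <- 1 - discontinuation_p
  rs <- rowSums(published)
  bad <- which(abs(rs - target) > tol)
  if (length(bad)) {
    stop("published row ", bad[1L], " (", SEVERITY_LEVELS[bad[1L]],
         ") sums to ", format(rs[bad[1L]], digits = 6),
         ", expected ", format(target, digits = 6), " within ", tol,
         call. = FALSE)
  }
  m <- published / target
  m <- m / rowSums(m)
  dimnames(m) <- list(SEVERITY_LEVELS, SEVERITY_LEVELS)
  m
}

#' Discount factor for a model cycle
#'
#' The default convention discounts by exact elapsed time: factor
#' `(1 + annual_rate)^(-t)` with `t = (cycle - 1) * cycle_days /
#' days_per_year` years, so the first cycle is undiscounted. The `"annual"`
#' method instead steps the exponent down once per completed year
#' (`t = floor(elapsed years)`).
#'
#' @param cycle Positive integer cycle index (vectorised).
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_days Cycle length in days.
#' @param days_per_year Days per year (365.25).
#' @param method `"continuous"` (default) or `"annual"`.
#' @return Discount factor(s) in (0, 1\].
#' @export
discount_factor <- function(cycle, annual_rate, cycle_days = 28,
                            days_per_year = 365.25,
                            method = c("continuous", "annual")) {
  method <- match.arg(method)
  stopifnot(all(cycle >= 1), annual_rate >= 0)
  t <- (cycle - 1) * cycle_days / days_per_year
  if (method == "annual") t <- floor(t)
  (1 + annual_rate)^(-t)
}

#' Build a full per-cycle transition schedule
#'
#' Composes the 7x7 matrix for every model cycle from per-cycle 3x3 severity
#' matrices for the two arms plus the configuration's discontinuation and
#' mortality vectors. Severity matrices may be supplied as a list shorter
#' than `n_cycles`; the last matrix is carried forward (the base-case
#' extrapolation: cycles beyond the trial window reuse the last trial-based
#' matrix).
#'
#' @param sat_matrices List of 3x3 conditional severity matrices for the
#'   on-treatment states (cycle 1, 2, ...), or a single matrix.
#' @param soc_matrices Same for the standard-care states.
#' @param config A [model_config()].
#' @return Object of class `transition_schedule`: list of `n_cycles` 7x7
#'   matrices.
#' @export
build_schedule <- function(sat_matrices, soc_matrices, config) {
  stopifnot(inherits(config, "model_config"))
  sat <- extend_matrices(sat_matrices, config$n_cycles)
  soc <- extend_matrices(soc_matrices, config$n_cycles)
  for (i in seq_along(sat)) {
    check_row_stochastic(sat[[i]], paste0("on-treatment matrix, cycle ", i))
  }
  for (i in seq_along(soc)) {
    check_row_stochastic(soc[[i]], paste0("standard-care matrix, cycle ", i))
  }
  mats <- lapply(seq_len(config$n_cycles), function(cy) {
    compose_full_matrix(sat[[cy]], soc[[cy]],
                        config$discontinuation_per_cycle[cy],
                        config$mortality_per_cycle[cy],
                        validate = FALSE)
  })
  structure(mats, class = "transition_schedule")
}

# Recycle the last severity matrix out to n cycles (carry-forward
# extrapolation); accepts a bare matrix or a list.
extend_matrices <- function(mats, n) {
  if (is.matrix(mats)) mats <- list(mats)
  if (length(mats) == 0L) stop("no severity matrices supplied", call. = FALSE)
  if (length(mats) < n) {
    mats <- c(mats, rep(mats[length(mats)], n - length(mats)))
  }
  mats[seq_len(n)]
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule>", length(x), "cycles x 7 states\n")
  invisible(x)
}

#' Run the cohort model for one arm
#'
#' Propagates the cohort occupancy through the per-cycle 7x7 matrices and
#' accrues discounted costs and QALYs. Accrual uses start-of-cycle occupancy
#' (the transition happens at cycle end) and no half-cycle correction is
#' applied. QALYs accrued in cycle c are `sum(occupancy * utility) *
#' cycle_days / days_per_year * discount_factor(c)`; costs accrue analogously
#' from the per-state per-cycle cost matrix. Death accrues nothing.
#'
#' @param config A [model_config()].
#' @param schedule A [build_schedule()] result of length `config$n_cycles`.
#' @param utilities A [utility_set()].
#' @param cost_matrix 7 x `n_cycles` matrix of per-cycle EUR costs by model
#'   state (see [cycle_cost_matrix()]); `NULL` for a QALY-only run.
#' @param arm `"sativex"` starts the cohort in the on-treatment states,
#'   `"soc"` in the standard-care states.
#' @return Object of class `arm_outcome`: the occupancy `trace`
#'   (`n_cycles + 1` rows including the initial vector), per-cycle discounted
#'   cost and QALY accruals, and cumulative discounted totals by whole-year
#'   horizon (`discounted_costs_by_horizon`, `discounted_qalys_by_horizon`).
#' @export
run_cohort <- function(config, schedule, utilities, cost_matrix = NULL,
                       arm = c("sativex", "soc")) {
  stopifnot(inherits(config, "model_config"),
            inherits(utilities, "utility_set"))
  arm <- match.arg(arm)
  n <- config$n_cycles
  if (length(schedule) != n) {
    stop("schedule has ", length(schedule), " cycles but config expects ", n,
         call. = FALSE)
  }
  if (is.null(cost_matrix)) {
    cost_matrix <- matrix(0, 7L, n)
  }
  stopifnot(nrow(cost_matrix) == 7L, ncol(cost_matrix) == n)

  u7 <- c(utilities$u, utilities$u, 0)
  s <- numeric(7L)
  if (arm == "sativex") s[1:3] <- config$initial_distribution
  else s[4:6] <- config$initial_distribution

  year_frac <- config$cycle_days / config$days_per_year
  df_cost <- discount_factor(seq_len(n), config$discount_rate_costs,
                             config$cycle_days, config$days_per_year,
                             config$discount_method)
  df_qaly <- discount_factor(seq_len(n), config$discount_rate_qalys,
                             config$cycle_days, config$days_per_year,
                             config$discount_method)

  trace <- matrix(NA_real_, n + 1L, 7L,
                  dimnames = list(NULL, MODEL_STATES))
  trace[1L, ] <- s
  cost_cycle <- numeric(n)
  qaly_cycle <- numeric(n)
  for (cy in seq_len(n)) {
    cost_cycle[cy] <- sum(s * cost_matrix[, cy]) * df_cost[cy]
    qaly_cycle[cy] <- sum(s * u7) * year_frac * df_qaly[cy]
    s <- as.vector(s %*% schedule[[cy]])
    trace[cy + 1L, ] <- s
  }

  horizons <- seq_len(n %/% config$cycles_per_year)
  cum_cost <- cumsum(cost_cycle)
  cum_qaly <- cumsum(qaly_cycle)
  hz_cycles <- horizons * config$cycles_per_year
  structure(list(arm = arm,
                 trace = trace,
                 cost_per_cycle = cost_cycle,
                 qaly_per_cycle = qaly_cycle,
                 discounted_costs_by_horizon =
                   stats::setNames(cum_cost[hz_cycles], horizons),
                 discounted_qalys_by_horizon =
                   stats::setNames(cum_qaly[hz_cycles], horizons),
                 total_costs = cum_cost[n],
                 total_qalys = cum_qaly[n]),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat("<arm_outcome> arm =", x$arm, "\n")
  cat("  total discounted costs : ", format(round(x$total_costs, 2), big.mark = ","),
      " EUR\n", sep = "")
  cat("  total discounted QALYs : ", round(x$total_qalys, 4), "\n", sep = "")
  invisible(x)
}

#' Incremental outcomes at a horizon
#'
#' Differences (treatment minus control) in discounted costs and QALYs at a
#' whole-year horizon, the ICER when defined, and the dominance flag
#' (treatment dominates when it saves costs and gains QALYs).
#'
#' @param arm_treatment,arm_control [run_cohort()] results.
#' @param horizon Horizon in whole years, covered by both outcomes.
#' @return Object of class `incremental_result` with fields `horizon`,
#'   `delta_costs`, `delta_qalys`, `icer` (`NA` when `delta_qalys == 0`) and
#'   `dominant`.
#' @export
incremental_outcomes <- function(arm_treatment, arm_control, horizon) {
  stopifnot(inherits(arm_treatment, "arm_outcome"),
            inherits(arm_control, "arm_outcome"))
  h <- as.character(horizon)
  if (!h %in% names(arm_treatment$discounted_costs_by_horizon) ||
      !h %in% names(arm_control$discounted_costs_by_horizon)) {
    stop("horizon ", horizon, " not covered by both arm outcomes",
         call. = FALSE)
  }
  dc <- arm_treatment$discounted_costs_by_horizon[[h]] -
    arm_control$discounted_costs_by_horizon[[h]]
  dq <- arm_treatment$discounted_qalys_by_horizon[[h]] -
    arm_control$discounted_qalys_by_horizon[[h]]
  structure(list(horizon = as.numeric(horizon),
                 delta_costs = dc,
                 delta_qalys = dq,
                 icer = if (dq != 0) dc / dq else NA_real_,
                 dominant = dc < 0 && dq > 0),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> horizon", x$horizon, "y: ",
      "ΔC = ", format(round(x$delta_costs, 0), big.mark = ","), " EUR, ",
      "ΔQ = ", round(x$delta_qalys, 4),
      if (!is.na(x$icer)) paste0(", ICER = ",
                                 format(round(x$icer, 0), big.mark = ","),
                                 " EUR/QALY") else ", ICER undefined",
      if (x$dominant) " [dominant]" else "", "\n", sep = "")
  invisible(x)
}
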