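# Probabilistic sensitivity analysis engines.
#
# The primary engine resamples the source data themselves: a stratified
# bootstrap of the patient-level trial data (preserving the 53/53/remainder
# phase structure) and of the 8 Delphi panel experts, re-estimating every
# model parameter jointly within each replicate. Because transition
# probabilities and utilities are recomputed from the same resampled
# patients, the correlations between them present in the trial data carry
# into the uncertainty estimates. The comparator engine is a conventional
# Monte Carlo PSA that samples each parameter independently (Dirichlet rows,
# normal utilities, gamma costs) and therefore discards those correlations.

#' Bootstrap PSA configuration
#'
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Root seed; it spawns one independent substream per replicate,
#'   so results are reproducible and invariant to evaluation order.
#' @param scenario `"base"`, `"s1"` or `"s2"`; see [scenario_spec()].
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 1000L, seed = 1L,
                             scenario = c("base", "s1", "s2")) {
  scenario <- match.arg(scenario)
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L)
  structure(list(n_replicates = n_replicates, seed = as.integer(seed),
                 scenario = scenario),
            class = "bootstrap_config")
}

# Per-replicate substream seeds derived from one root seed (< 2^31).
seed_streams <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw one stratified bootstrap replicate of the source data
#'
#' Draws three independent with-replacement samples, each of the original
#' stratum size, from the `db_sativex`, `db_placebo` and `single_blind_only`
#' strata of the trial data, and a with-replacement sample of the panel
#' experts of the original panel size. Stratum sizes and the expert count
#' are preserved exactly on every replicate. Uses the current RNG state.
#'
#' @param trial A [trial_dataset()].
#' @param panel A [delphi_panel()].
#' @return List with elements `trial` and `panel`, the resampled data.
#' @export
draw_bootstrap_replicate <- function(trial, panel) {
  stopifnot(inherits(trial, "trial_dataset"), inherits(panel, "delphi_panel"))
  counts <- stratum_counts(trial)
  if (any(counts == 0L)) {
    stop("empty stratum: ", paste(names(counts)[counts == 0L], collapse = ", "),
         call. = FALSE)
  }
  idx <- unlist(lapply(STRATUM_LEVELS, function(s) {
    members <- which(trial$patients$stratum == s)
    members[sample.int(length(members), length(members), replace = TRUE)]
  }), use.names = FALSE)
  list(trial = resample_trial(trial, idx),
       panel = resample_panel(panel))
}

resample_trial <- function(trial, idx) {
  new_trial_dataset(trial$patients[idx, , drop = FALSE],
                    trial$nrs[idx, , drop = FALSE],
                    trial$utility[idx, , drop = FALSE])
}

resample_panel <- function(panel) {
  experts <- panel_experts(panel)
  chosen <- experts[sample.int(length(experts), length(experts),
                               replace = TRUE)]
  pieces <- lapply(seq_along(chosen), function(k) {
    rows <- panel[panel$expert_id == chosen[k], , drop = FALSE]
    rows$expert_id <- sprintf("B%d", k)
    rows
  })
  delphi_panel(do.call(rbind, pieces))
}

# Assemble the per-cycle severity matrices of both arms for a scenario.
# sat_trial: trial-based on-treatment matrices, cycles 1..k.
# soc_trial: placebo-stratum matrices for the double-blind cycles (s1 only);
#   carried back over the pre-randomisation cycles and forward past the
#   trial window, mirroring the base case's carry-forward.
# s2 keeps the trial matrices for the trial window but applies the external
# standard-care matrices to the on-treatment states from cycle k+1 on (drug
# costs continue regardless).
assemble_arm_matrices <- function(sat_trial, soc_trial, scenario,
                                  soc_external, n_cycles) {
  soc_ext <- extend_matrices(soc_external, n_cycles)
  soc <- if (scenario == "s1") {
    extend_matrices(c(soc_trial[1L], soc_trial[1L], soc_trial), n_cycles)
  } else {
    soc_ext
  }
  sat <- if (scenario == "s2") {
    k <- length(sat_trial)
    c(sat_trial, soc_ext[seq.int(k + 1L, n_cycles)])
  } else {
    extend_matrices(sat_trial, n_cycles)
  }
  list(sat = sat, soc = soc)
}

#' One full cost-utility evaluation from source data
#'
#' Runs the complete estimation-to-outcomes pipeline once: estimates
#' per-cycle transition matrices and state utilities from the trial data,
#' state care costs from the panel and tariffs, assembles both arms'
#' schedules for the requested scenario, runs the cohort model for both
#' arms, and returns incremental outcomes at every whole-year horizon. This
#' is the unit of work the PSA engines repeat per replicate; called on the
#' original data it is the deterministic point-estimate run.
#'
#' Trial-based on-treatment matrices use all strata for cycles 1-2 (every
#' patient is on add-on treatment in the single-blind phase) and the
#' `db_sativex` stratum for the double-blind cycles. Scenario `"s1"`
#' additionally estimates the standard-care arm's matrices from the
#' `db_placebo` stratum.
#'
#' @param trial A [trial_dataset()].
#' @param panel A [delphi_panel()].
#' @param tariffs A [unit_cost_table()].
#' @param config A [model_config()].
#' @param scenario `"base"`, `"s1"` or `"s2"`.
#' @param soc_matrices External standard-care severity matrices (3x3 matrix
#'   or per-cycle list); default is the packaged synthetic stand-in.
#' @param price A [drug_price()].
#' @param n_trial_cycles Number of trial-estimated transition cycles
#'   (default 5).
#' @param quiet Muffle the empty-row identity warnings emitted by the
#'   estimator inside bootstrap replicates (default `TRUE`).
#' @return Object of class `cua_evaluation`: list with `increments` (data
#'   frame over horizons with both arms' totals, deltas, ICER and dominance),
#'   the two [run_cohort()] outcomes, and the fitted components
#'   (`sat_estimates`, `placebo_estimates`, `utilities`, `state_costs`).
#' @export
evaluate_cua <- function(trial, panel, tariffs,
                         config = model_config(),
                         scenario = c("base", "s1", "s2"),
                         soc_matrices = default_soc_matrix(),
                         price = drug_price(),
                         n_trial_cycles = 5L,
                         quiet = TRUE) {
  scenario <- match.arg(scenario)
  run <- function(expr) {
    if (quiet) {
      withCallingHandlers(expr, markovboot_empty_row = function(w) {
        invokeRestart("muffleWarning")
      })
    } else expr
  }
  sat_est <- run(lapply(seq_len(n_trial_cycles), function(cy) {
    strata <- if (cy <= 2L) STRATUM_LEVELS else "db_sativex"
    estimate_transition_matrix(trial, cy, strata)
  }))
  plc_est <- NULL
  if (scenario == "s1") {
    plc_est <- run(lapply(seq.int(3L, n_trial_cycles), function(cy) {
      estimate_transition_matrix(trial, cy, "db_placebo")
    }))
  }
  utilities <- estimate_utilities(trial)
  state_costs <- state_cost_per_cycle(panel, tariffs)

  mats <- assemble_arm_matrices(lapply(sat_est, `[[`, "matrix"),
                                lapply(plc_est, `[[`, "matrix"),
                                scenario, soc_matrices, config$n_cycles)
  schedule <- build_schedule(mats$sat, mats$soc, config)
  cost_matrix <- cycle_cost_matrix(state_costs, config, price)
  arm_sat <- run_cohort(config, schedule, utilities, cost_matrix, "sativex")
  arm_soc <- run_cohort(config, schedule, utilities, cost_matrix, "soc")

  horizons <- as.integer(names(arm_sat$discounted_costs_by_horizon))
  inc <- lapply(horizons, function(h) incremental_outcomes(arm_sat, arm_soc, h))
  increments <- data.frame(
    horizon = horizons,
    cost_sativex = unname(arm_sat$discounted_costs_by_horizon),
    qaly_sativex = unname(arm_sat$discounted_qalys_by_horizon),
    cost_soc = unname(arm_soc$discounted_costs_by_horizon),
    qaly_soc = unname(arm_soc$discounted_qalys_by_horizon),
    delta_costs = vapply(inc, `[[`, numeric(1), "delta_costs"),
    delta_qalys = vapply(inc, `[[`, numeric(1), "delta_qalys"),
    icer = vapply(inc, `[[`, numeric(1), "icer"),
    dominant = vapply(inc, `[[`, logical(1), "dominant"))
  structure(list(increments = increments,
                 arm_sativex = arm_sat, arm_soc = arm_soc,
                 sat_estimates = sat_est, placebo_estimates = plc_est,
                 utilities = utilities, state_costs = state_costs,
                 scenario = scenario),
            class = "cua_evaluation")
}

#' @export
print.cua_evaluation <- function(x, ...) {
  cat("<cua_evaluation> scenario:", x$scenario, "\n")
  print(within(x$increments, {
    icer <- round(icer)
    delta_costs <- round(delta_costs)
    delta_qalys <- round(delta_qalys, 4)
  })[, c("horizon", "delta_costs", "delta_qalys", "icer", "dominant")],
  row.names = FALSE)
  invisible(x)
}

#' Run the stratified bootstrap PSA
#'
#' Repeats, `n_replicates` times: (1) draw a stratified with-replacement
#' sample of the trial patients and of the panel experts
#' ([draw_bootstrap_replicate()]); (2) re-estimate transition matrices and
#' utilities from the combined bootstrapped trial sample; (3) recompute
#' state costs from the bootstrapped panel; (4) run the cohort model for
#' both arms and record discounted totals at every horizon. Under scenario
#' `"s1"` the standard-care arm's matrices are re-estimated from the
#' bootstrapped placebo stratum inside each replicate; `"base"` and `"s2"`
#' keep the fixed external standard-care matrices unresampled.
#'
#' @inheritParams evaluate_cua
#' @param psa_config A [bootstrap_config()]; its `scenario` selects the
#'   analysis scenario.
#' @param identity_resample Deterministic test hook: when `TRUE`, every
#'   replicate uses the original data unchanged, so the PSA reduces to
#'   `n_replicates` copies of the point-estimate run.
#' @return Object of class `psa_result`: list with `replicates` (data frame:
#'   `replicate_id`, `horizon`, both arms' totals, `delta_costs`,
#'   `delta_qalys`, `icer`, `dominant`), `summary` (see [summarize_psa()]),
#'   `engine`, and the configuration used.
#' @export
run_bootstrap_psa <- function(trial, panel, tariffs,
                              config = model_config(),
                              psa_config = bootstrap_config(),
                              soc_matrices = default_soc_matrix(),
                              price = drug_price(),
                              n_trial_cycles = 5L,
                              identity_resample = FALSE) {
  stopifnot(inherits(psa_config, "bootstrap_config"))
  b_seeds <- seed_streams(psa_config$seed, psa_config$n_replicates)
  reps <- vector("list", psa_config$n_replicates)
  for (b in seq_len(psa_config$n_replicates)) {
    set.seed(b_seeds[b])
    dat <- if (identity_resample) list(trial = trial, panel = panel)
           else draw_bootstrap_replicate(trial, panel)
    ev <- evaluate_cua(dat$trial, dat$panel, tariffs, config,
                       psa_config$scenario, soc_matrices, price,
                       n_trial_cycles, quiet = TRUE)
    reps[[b]] <- cbind(replicate_id = b, ev$increments)
  }
  replicates <- do.call(rbind, reps)
  structure(list(replicates = replicates,
                 summary = summarize_psa_all(replicates),
                 engine = "bootstrap",
                 scenario = psa_config$scenario,
                 config = psa_config),
            class = "psa_result")
}

#' Monte Carlo dispersion specification from a point-estimate run
#'
#' Builds the parametric distributions the independent Monte Carlo
#' comparator samples from: one Dirichlet per transition-matrix row with
#' concentration equal to the row's at-risk count times its estimated
#' probabilities, a normal per state utility (estimated mean and standard
#' error), and a gamma per state care cost (moment-matched to the expert
#' mean and its standard error). Sampling of each block can be switched off,
#' in which case the point estimates are used (all off = fully degenerate).
#'
#' @param point A [evaluate_cua()] result on the original data.
#' @param sample_transitions,sample_utilities,sample_costs Logical switches.
#' @return Object of class `mc_dispersion`.
#' @export
mc_dispersion <- function(point, sample_transitions = TRUE,
                          sample_utilities = TRUE, sample_costs = TRUE) {
  stopifnot(inherits(point, "cua_evaluation"))
  structure(list(sat_estimates = point$sat_estimates,
                 placebo_estimates = point$placebo_estimates,
                 utilities = point$utilities,
                 state_costs = point$state_costs,
                 sample_transitions = sample_transitions,
                 sample_utilities = sample_utilities,
                 sample_costs = sample_costs),
            class = "mc_dispersion")
}

# One Dirichlet draw per row with concentration n_row * p; rows with no
# at-risk patients (or sampling switched off) keep the point row.
sample_transition_matrix <- function(est) {
  m <- est$matrix
  for (i in which(est$n_row > 0)) {
    alpha <- est$n_row[i] * est$matrix[i, ]
    g <- stats::rgamma(3L, shape = alpha)
    total <- sum(g)
    if (total > 0) m[i, ] <- g / total
  }
  m
}

#' Run the independent-parameter Monte Carlo PSA
#'
#' The conventional comparator: each replicate samples every model parameter
#' independently from its parametric distribution ([mc_dispersion()]) --
#' Dirichlet transition rows, normal state utilities, gamma state costs --
#' with no cross-parameter correlation, then runs the cohort model and
#' records outcomes exactly as the bootstrap engine does.
#'
#' @inheritParams evaluate_cua
#' @param point A [evaluate_cua()] result on the original data (the point
#'   estimates).
#' @param dispersion A [mc_dispersion()]; defaults to the spec derived from
#'   `point` with all blocks sampled.
#' @param n_replicates,seed Replication count and root seed.
#' @return A `psa_result` (see [run_bootstrap_psa()]) with
#'   `engine = "monte_carlo"`.
#' @export
run_monte_carlo_psa <- function(point, dispersion = NULL,
                                config = model_config(),
                                n_replicates = 1000L, seed = 1L,
                                soc_matrices = default_soc_matrix(),
                                price = drug_price()) {
  stopifnot(inherits(point, "cua_evaluation"))
  if (is.null(dispersion)) dispersion <- mc_dispersion(point)
  stopifnot(inherits(dispersion, "mc_dispersion"))
  scenario <- point$scenario
  n_cycles <- config$n_cycles
  u_pt <- dispersion$utilities$u
  u_se <- dispersion$utilities$se
  if (is.null(u_se)) u_se <- rep(0, 3L)
  c_pt <- dispersion$state_costs$costs
  c_se <- dispersion$state_costs$se
  if (is.null(c_se)) c_se <- rep(0, 3L)

  b_seeds <- seed_streams(seed, n_replicates)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    set.seed(b_seeds[b])
    sat <- if (dispersion$sample_transitions) {
      lapply(dispersion$sat_estimates, sample_transition_matrix)
    } else {
      lapply(dispersion$sat_estimates, `[[`, "matrix")
    }
    plc <- NULL
    if (!is.null(dispersion$placebo_estimates)) {
      plc <- if (dispersion$sample_transitions) {
        lapply(dispersion$placebo_estimates, sample_transition_matrix)
      } else {
        lapply(dispersion$placebo_estimates, `[[`, "matrix")
      }
    }
    u <- u_pt
    if (dispersion$sample_utilities) {
      u <- pmin(1, pmax(-1, stats::rnorm(3L, u_pt, u_se)))
    }
    costs <- c_pt
    if (dispersion$sample_costs) {
      pos <- c_pt > 0 & c_se > 0
      costs[pos] <- stats::rgamma(sum(pos), shape = (c_pt[pos] / c_se[pos])^2,
                                  rate = c_pt[pos] / c_se[pos]^2)
    }
    mats <- assemble_arm_matrices(sat, plc, scenario, soc_matrices, n_cycles)
    schedule <- build_schedule(mats$sat, mats$soc, config)
    cost_matrix <- cycle_cost_matrix(
      state_cost_set(costs[[1L]], costs[[2L]], costs[[3L]]), config, price)
    uset <- utility_set(u[[1L]], u[[2L]], u[[3L]])
    arm_sat <- run_cohort(config, schedule, uset, cost_matrix, "sativex")
    arm_soc <- run_cohort(config, schedule, uset, cost_matrix, "soc")
    horizons <- as.integer(names(arm_sat$discounted_costs_by_horizon))
    dc <- unname(arm_sat$discounted_costs_by_horizon -
                   arm_soc$discounted_costs_by_horizon)
    dq <- unname(arm_sat$discounted_qalys_by_horizon -
                   arm_soc$discounted_qalys_by_horizon)
    reps[[b]] <- data.frame(
      replicate_id = b, horizon = horizons,
      cost_sativex = unname(arm_sat$discounted_costs_by_horizon),
      qaly_sativex = unname(arm_sat$discounted_qalys_by_horizon),
      cost_soc = unname(arm_soc$discounted_costs_by_horizon),
      qaly_soc = unname(arm_soc$discounted_qalys_by_horizon),
      delta_costs = dc, delta_qalys = dq,
      icer = ifelse(dq != 0, dc / dq, NA_real_),
      dominant = dc < 0 & dq > 0)
  }
  replicates <- do.call(rbind, reps)
  structure(list(replicates = replicates,
                 summary = summarize_psa_all(replicates),
                 engine = "monte_carlo",
                 scenario = scenario,
                 config = list(n_replicates = n_replicates, seed = seed)),
            class = "psa_result")
}

#' Summarise PSA replicates at one horizon
#'
#' Dominance probability (fraction of replicates in the south-east quadrant
#' of the cost-effectiveness plane: cost-saving and QALY-gaining), quadrant
#' counts, the probability of any QALY gain, empirical 2.5th / 97.5th
#' percentile intervals (linear interpolation) for the incremental costs,
#' incremental QALYs and the per-replicate ICER, and the cost-effectiveness
#' plane point cloud. ICER percentiles are taken over the per-replicate
#' ratios; because ratio percentiles are ill-behaved when replicates span
#' plane quadrants, the quadrant counts are reported alongside.
#'
#' @param replicates Replicate data frame from a `psa_result` (columns
#'   `horizon`, `delta_costs`, `delta_qalys`, `icer`).
#' @param horizon Horizon in years to summarise.
#' @return List with `horizon`, `n`, `dominance_probability`,
#'   `prob_qaly_gain`, `quadrant_counts` (ne/se/sw/nw), `ci_delta_costs`,
#'   `ci_delta_qalys`, `ci_icer`, and `ce_plane` (data frame of
#'   (`delta_qalys`, `delta_costs`) pairs).
#' @export
summarize_psa <- function(replicates, horizon) {
  if (inherits(replicates, "psa_result")) replicates <- replicates$replicates
  r <- replicates[replicates$horizon == horizon, , drop = FALSE]
  if (nrow(r) == 0L) {
    stop("no replicates at horizon ", horizon, call. = FALSE)
  }
  dq <- r$delta_qalys
  dc <- r$delta_costs
  quadrants <- c(ne = sum(dq > 0 & dc >= 0),
                 se = sum(dq > 0 & dc < 0),
                 sw = sum(dq <= 0 & dc < 0),
                 nw = sum(dq <= 0 & dc >= 0))
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(`2.5%` = NA_real_, `97.5%` = NA_real_))
    stats::quantile(x, c(0.025, 0.975), type = 7, names = TRUE)
  }
  list(horizon = horizon,
       n = nrow(r),
       dominance_probability = unname(quadrants["se"]) / nrow(r),
       prob_qaly_gain = mean(dq > 0),
       quadrant_counts = quadrants,
       mean_delta_costs = mean(dc),
       mean_delta_qalys = mean(dq),
       ci_delta_costs = ci(dc),
       ci_delta_qalys = ci(dq),
       ci_icer = ci(r$icer),
       ce_plane = data.frame(delta_qalys = dq, delta_costs = dc))
}

# Summary table over all horizons plus the per-horizon detail lists.
summarize_psa_all <- function(replicates) {
  horizons <- sort(unique(replicates$horizon))
  detail <- lapply(horizons, function(h) summarize_psa(replicates, h))
  names(detail) <- horizons
  table <- do.call(rbind, lapply(detail, function(s) {
    data.frame(horizon = s$horizon,
               n = s$n,
               delta_costs = s$mean_delta_costs,
               delta_costs_lo = s$ci_delta_costs[[1L]],
               delta_costs_hi = s$ci_delta_costs[[2L]],
               delta_qalys = s$mean_delta_qalys,
               delta_qalys_lo = s$ci_delta_qalys[[1L]],
               delta_qalys_hi = s$ci_delta_qalys[[2L]],
               icer_lo = s$ci_icer[[1L]],
               icer_hi = s$ci_icer[[2L]],
               dominance_probability = s$dominance_probability,
               prob_qaly_gain = s$prob_qaly_gain)
  }))
  rownames(table) <- NULL
  structure(list(table = table, by_horizon = detail), class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat("<psa_summary>\n")
  tab <- x$table
  tab$delta_costs <- round(tab$delta_costs)
  tab$delta_costs_lo <- round(tab$delta_costs_lo)
  tab$delta_costs_hi <- round(tab$delta_costs_hi)
  tab$delta_qalys <- round(tab$delta_qalys, 3)
  tab$delta_qalys_lo <- round(tab$delta_qalys_lo, 3)
  tab$delta_qalys_hi <- round(tab$delta_qalys_hi, 3)
  tab$icer_lo <- round(tab$icer_lo)
  tab$icer_hi <- round(tab$icer_hi)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> engine:", x$engine, " scenario:", x$scenario,
      " replicates:", length(unique(x$replicates$replicate_id)), "\n")
  print(x$summary)
  invisible(x)
}

#' Write PSA replicates / cost-effectiveness plane to CSV
#'
#' @param psa A `psa_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_replicates_csv <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  utils::write.csv(psa$replicates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_replicates_csv
#' @param horizon Horizon in years for the plane cloud.
#' @export
write_ce_plane_csv <- function(psa, path, horizon) {
  stopifnot(inherits(psa, "psa_result"))
  s <- summarize_psa(psa$replicates, horizon)
  utils::write.csv(s$ce_plane, path, row.names = FALSE)
  invisible(path)
}
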