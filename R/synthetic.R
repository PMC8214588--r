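# Synthetic trial and Delphi-panel generators with known ground truth.
#
# The generator emulates the structure of the source trial: 190 patients with
# moderate-to-severe spasticity enter a 4-week single-blind add-on phase;
# early responders (NRS improvement >= 20% vs baseline) enter a wash-out
# cycle; patients re-qualifying after wash-out are randomised 53/53 into
# double-blind add-on vs placebo for three further cycles. Severity evolves
# under per-phase latent 3x3 chains; utilities are drawn around state means
# with patient-level random effects optionally coupled to each patient's
# transition propensity, which is the correlation structure the bootstrap
# PSA is designed to preserve.

#' Generator configuration
#'
#' Ground-truth parameters for [generate_trial()] and
#' [generate_delphi_panel()]. Defaults reproduce the source trial's design
#' counts (190 enrolled, 53 + 53 randomised, responder fraction 134/190,
#' wash-out pass fraction 106/134) and the published model inputs (per-cycle
#' on-treatment chains, state utility means 0.594 / 0.509 / 0.499).
#'
#' The phase gates use exact design counts: responders are the
#' `round(responder_fraction * n_enrolled)` patients with the largest
#' realised relative NRS improvement after the single-blind cycle, and a
#' random subset of `round(washout_pass_prob * n_responders)` of them passes
#' wash-out, so the default configuration always yields the 53/53/84 stratum
#' split.
#'
#' @param n_enrolled Patients entering the single-blind phase (default 190).
#' @param n_db_per_arm Patients randomised per double-blind arm; default
#'   scales the 53-of-190 design ratio with `n_enrolled`.
#' @param responder_fraction Target fraction of early responders
#'   (default 134/190).
#' @param washout_pass_prob Fraction of responders re-qualifying after
#'   wash-out (default 106/134).
#' @param n_cycles_observed Number of observed transition cycles (default 5:
#'   single-blind, wash-out, and three double-blind cycles); patients
#'   contribute `n_cycles_observed + 1` observation points at most.
#' @param sb_matrix,washout_matrix 3x3 chains for the single-blind and
#'   wash-out cycles (defaults: the base-case cycle-1 and cycle-2 matrices).
#' @param db_sativex_matrices List of 3x3 chains for the double-blind active
#'   arm, one per double-blind cycle (defaults: base-case cycles 3-5; the
#'   last is carried forward if the list is short).
#' @param db_placebo_matrix 3x3 chain (or list) for the double-blind placebo
#'   arm; the default is a distinctly less favourable chain than the active
#'   arm's.
#' @param baseline_distribution Severity distribution at entry; the default
#'   0 / 0.5 / 0.5 reflects the moderate-to-severe entry criterion.
#' @param utility_means State utility means (mild, moderate, severe).
#' @param sigma_patient Between-patient SD of the utility random effect.
#' @param sigma_obs Within-patient observation noise SD of utilities.
#' @param coupling Correlation knob `rho` in \[-1, 1\] linking a patient's
#'   latent propensity to improve with their utility level: the utility
#'   random effect is `sigma_patient * (rho * z + sqrt(1 - rho^2) * eps)`
#'   and the patient's transition rows are exponentially tilted toward
#'   improvement with strength `abs(rho) * tilt_scale * z`, so the sign of
#'   `rho` sets the sign of the utility-improvement correlation. At 0,
#'   utilities and transitions are independent and the latent chains are
#'   realised exactly.
#' @param tilt_scale Scale of the transition tilt per unit of `rho * z`.
#' @param missing_prob Probability that a post-baseline observation is lost
#'   (never imputed downstream).
#' @param delphi_items Data frame with columns `item`, `q_mild`,
#'   `q_moderate`, `q_severe`: true mean resource quantities per 28-day
#'   cycle, severity-monotone by default.
#' @param n_experts Number of Delphi experts (default 8).
#' @param expert_sdlog Log-normal dispersion of expert quantities around the
#'   item means (mean-preserving; 0 makes all experts identical).
#' @param tariffs A [unit_cost_table()] covering the items (default:
#'   packaged synthetic tariffs).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_enrolled = 190L,
                             n_db_per_arm = NULL,
                             responder_fraction = 134 / 190,
                             washout_pass_prob = 106 / 134,
                             n_cycles_observed = 5L,
                             sb_matrix = NULL,
                             washout_matrix = NULL,
                             db_sativex_matrices = NULL,
                             db_placebo_matrix = NULL,
                             baseline_distribution = c(0, 0.5, 0.5),
                             utility_means = c(0.594, 0.509, 0.499),
                             sigma_patient = 0.12,
                             sigma_obs = 0.05,
                             coupling = 0.3,
                             tilt_scale = 1,
                             missing_prob = 0.05,
                             delphi_items = default_delphi_items(),
                             n_experts = 8L,
                             expert_sdlog = 0.3,
                             tariffs = default_unit_costs()) {
  base <- default_sativex_matrices()
  if (is.null(sb_matrix)) sb_matrix <- base[[1L]]
  if (is.null(washout_matrix)) washout_matrix <- base[[2L]]
  if (is.null(db_sativex_matrices)) db_sativex_matrices <- base[3:5]
  if (is.null(db_placebo_matrix)) db_placebo_matrix <- default_placebo_matrix()
  if (is.matrix(db_sativex_matrices)) db_sativex_matrices <- list(db_sativex_matrices)
  if (is.matrix(db_placebo_matrix)) db_placebo_matrix <- list(db_placebo_matrix)
  n_enrolled <- as.integer(n_enrolled)
  if (is.null(n_db_per_arm)) n_db_per_arm <- as.integer(round(n_enrolled * 53 / 190))
  stopifnot(n_enrolled >= 2L, n_db_per_arm >= 1L,
            responder_fraction > 0, responder_fraction <= 1,
            washout_pass_prob > 0, washout_pass_prob <= 1,
            n_cycles_observed >= 2L,
            sigma_patient >= 0, sigma_obs >= 0,
            coupling >= -1, coupling <= 1,
            missing_prob >= 0, missing_prob < 1,
            n_experts >= 1L, expert_sdlog >= 0,
            length(baseline_distribution) == 3L,
            abs(sum(baseline_distribution) - 1) < 1e-12,
            all(c("item", "q_mild", "q_moderate", "q_severe") %in%
                  names(delphi_items)),
            inherits(tariffs, "unit_cost_table"))
  for (m in c(list(sb_matrix, washout_matrix), db_sativex_matrices,
              db_placebo_matrix)) {
    check_row_stochastic(m, "generator chain")
  }
  structure(list(n_enrolled = n_enrolled,
                 n_db_per_arm = as.integer(n_db_per_arm),
                 responder_fraction = responder_fraction,
                 washout_pass_prob = washout_pass_prob,
                 n_cycles_observed = as.integer(n_cycles_observed),
                 sb_matrix = sb_matrix, washout_matrix = washout_matrix,
                 db_sativex_matrices = db_sativex_matrices,
                 db_placebo_matrix = db_placebo_matrix,
                 baseline_distribution = baseline_distribution,
                 utility_means = stats::setNames(utility_means, SEVERITY_LEVELS),
                 sigma_patient = sigma_patient, sigma_obs = sigma_obs,
                 coupling = coupling, tilt_scale = tilt_scale,
                 missing_prob = missing_prob,
                 delphi_items = delphi_items,
                 n_experts = as.integer(n_experts),
                 expert_sdlog = expert_sdlog,
                 tariffs = tariffs),
            class = "generator_config")
}

#' Default placebo-arm chain for the generator
#'
#' A severity chain distinctly less favourable than the active arm's
#' double-blind chains: patients mostly hold their state, with net drift
#' toward worse severity.
#'
#' @return 3x3 row-stochastic matrix.
#' @export
default_placebo_matrix <- function() {
  matrix(c(0.75, 0.20, 0.05,
           0.10, 0.70, 0.20,
           0.02, 0.18, 0.80), 3L, 3L, byrow = TRUE,
         dimnames = list(SEVERITY_LEVELS, SEVERITY_LEVELS))
}

#' Default resource items for the Delphi generator
#'
#' True mean quantities per 28-day cycle per severity state, monotone in
#' severity, covering drug therapy, healthcare visits, tests and monitoring,
#' and (rare) surgical procedures.
#'
#' @return Data frame with columns `item`, `q_mild`, `q_moderate`,
#'   `q_severe`.
#' @export
default_delphi_items <- function() {
  data.frame(
    item = c("antispastic_drug_pack", "gp_visit", "neurologist_visit",
             "physiotherapy_session", "emergency_visit", "mri_scan",
             "blood_test", "surgical_procedure"),
    q_mild = c(1.0, 0.30, 0.15, 2.0, 0.01, 0.05, 0.20, 0.000),
    q_moderate = c(1.5, 0.60, 0.30, 4.0, 0.05, 0.08, 0.30, 0.002),
    q_severe = c(2.0, 1.00, 0.50, 8.0, 0.15, 0.10, 0.50, 0.010),
    stringsAsFactors = FALSE)
}

# One tilted chain step for all patients at once. `kz` is the per-patient
# tilt strength (rho * tilt_scale * z); destinations are scored +1 / 0 / -1
# for mild / moderate / severe so positive kz favours improvement.
tilt_step <- function(states, mat, kz) {
  p <- mat[states, , drop = FALSE]
  if (any(kz != 0)) {
    w <- p * exp(kz %o% c(1, 0, -1))
    p <- w / rowSums(w)
  }
  u <- stats::runif(length(states))
  1L + (u > p[, 1L]) + (u > p[, 1L] + p[, 2L])
}

nrs_for_state <- function(states) {
  lo <- c(0, 3.3, 6.6)[states]
  hi <- c(3.3, 6.6, 10)[states]
  stats::runif(length(states), lo, hi)
}

#' Generate a synthetic patient-level trial dataset
#'
#' Simulates the trial structure described under [generator_config()] and
#' returns a [trial_dataset()] with the three analysis strata. Observation
#' cycles: cycle 1 is the entry assessment; cycle 2 the end of the
#' single-blind phase; cycle 3 the end of wash-out (responders only); cycles
#' 4 onward the double-blind visits (randomised patients only). Utilities
#' are drawn at every observed cycle. Post-baseline observations are lost
#' with probability `missing_prob` (responder gating uses the clinic-known
#' pre-loss values).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A [trial_dataset()].
#' @export
generate_trial <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n_enrolled
  n_obs <- config$n_cycles_observed + 1L
  n_db_cycles <- config$n_cycles_observed - 2L

  z <- stats::rnorm(n)
  # |rho| scales how strongly the latent propensity tilts transitions; the
  # sign of rho lives only in the utility random effect, so corr(utility
  # effect, improvement) carries the sign of rho
  kz <- abs(config$coupling) * config$tilt_scale * z

  states <- matrix(NA_integer_, n, n_obs)
  states[, 1L] <- sample.int(3L, n, replace = TRUE,
                             prob = config$baseline_distribution)
  states[, 2L] <- tilt_step(states[, 1L], config$sb_matrix, kz)
  nrs <- matrix(NA_real_, n, n_obs)
  nrs[, 1L] <- nrs_for_state(states[, 1L])
  nrs[, 2L] <- nrs_for_state(states[, 2L])

  improvement <- (nrs[, 1L] - nrs[, 2L]) / nrs[, 1L]
  n_resp <- round(config$responder_fraction * n)
  responders <- order(improvement, decreasing = TRUE)[seq_len(n_resp)]
  n_pass <- round(config$washout_pass_prob * n_resp)
  passers <- sample(responders, n_pass)
  if (n_pass < 2L * config$n_db_per_arm) {
    stop("only ", n_pass, " patients re-qualify after wash-out but ",
         2L * config$n_db_per_arm, " are needed for randomisation; ",
         "increase n_enrolled, responder_fraction or washout_pass_prob, ",
         "or decrease n_db_per_arm", call. = FALSE)
  }
  db <- sample(passers, 2L * config$n_db_per_arm)
  sat_ids <- db[seq_len(config$n_db_per_arm)]
  plc_ids <- db[config$n_db_per_arm + seq_len(config$n_db_per_arm)]

  stratum <- rep("single_blind_only", n)
  stratum[sat_ids] <- "db_sativex"
  stratum[plc_ids] <- "db_placebo"

  # wash-out cycle for all responders
  states[responders, 3L] <- tilt_step(states[responders, 2L],
                                      config$washout_matrix, kz[responders])
  nrs[responders, 3L] <- nrs_for_state(states[responders, 3L])

  # double-blind cycles for randomised patients
  sat_chain <- extend_matrices(config$db_sativex_matrices, n_db_cycles)
  plc_chain <- extend_matrices(config$db_placebo_matrix, n_db_cycles)
  for (t in seq_len(n_db_cycles)) {
    cyc <- 3L + t
    states[sat_ids, cyc] <- tilt_step(states[sat_ids, cyc - 1L],
                                      sat_chain[[t]], kz[sat_ids])
    states[plc_ids, cyc] <- tilt_step(states[plc_ids, cyc - 1L],
                                      plc_chain[[t]], kz[plc_ids])
    obs_ids <- c(sat_ids, plc_ids)
    nrs[obs_ids, cyc] <- nrs_for_state(states[obs_ids, cyc])
  }

  # utilities at every observed cycle
  b <- config$sigma_patient *
    (config$coupling * z +
       sqrt(max(0, 1 - config$coupling^2)) * stats::rnorm(n))
  observed <- !is.na(states)
  util <- matrix(NA_real_, n, n_obs)
  u_draw <- config$utility_means[states[observed]] + b[row(states)[observed]] +
    stats::rnorm(sum(observed), sd = config$sigma_obs)
  util[observed] <- pmin(1, pmax(-1, u_draw))

  # observation loss (post-baseline only)
  if (config$missing_prob > 0) {
    post <- observed & col(states) > 1L
    lost <- post & matrix(stats::runif(length(states)) < config$missing_prob,
                          n, n_obs)
    nrs[lost] <- NA_real_
    util[lost] <- NA_real_
  }

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    stratum = stratum, stringsAsFactors = FALSE)
  new_trial_dataset(patients, nrs, util)
}

#' Generate a synthetic Delphi panel and its tariffs
#'
#' Draws per-expert resource quantities log-normally around the configured
#' item means (mean-preserving, dispersion `expert_sdlog`), on the complete
#' expert x severity x item grid with no missing values.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with elements `panel` (a [delphi_panel()]) and `tariffs`
#'   (the configured [unit_cost_table()]).
#' @export
generate_delphi_panel <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  items <- config$delphi_items
  grid <- expand.grid(expert_id = sprintf("E%d", seq_len(config$n_experts)),
                      severity = SEVERITY_LEVELS,
                      item = items$item,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qmat <- as.matrix(items[, c("q_mild", "q_moderate", "q_severe")])
  mean_q <- qmat[cbind(match(grid$item, items$item),
                       match(grid$severity, SEVERITY_LEVELS))]
  sdl <- config$expert_sdlog
  noise <- if (sdl > 0) {
    stats::rlnorm(nrow(grid), meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, nrow(grid))
  grid$quantity_per_cycle <- mean_q * noise
  list(panel = delphi_panel(grid), tariffs = config$tariffs)
}

#' Ground truth implied by a generator configuration
#'
#' The quantities the estimators target when `coupling = 0`: the per-cycle
#' on-treatment chains along the active-arm path (single-blind, wash-out,
#' double-blind active), the placebo chains, the state utility means, and
#' the state care costs implied by the item means and tariffs. With
#' `coupling != 0` the patient-level tilt perturbs realised population
#' transition rates slightly, so exact recovery holds only at 0.
#'
#' @param config A [generator_config()].
#' @return List with `sat_matrices`, `placebo_matrices`, `utilities`
#'   (a [utility_set()]) and `state_costs` (a [state_cost_set()]).
#' @export
generator_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_db_cycles <- config$n_cycles_observed - 2L
  sat <- c(list(config$sb_matrix, config$washout_matrix),
           extend_matrices(config$db_sativex_matrices, n_db_cycles))
  items <- config$delphi_items
  price <- config$tariffs$unit_cost_eur[match(items$item, config$tariffs$item)]
  if (anyNA(price)) {
    stop("tariffs do not cover all generator items", call. = FALSE)
  }
  costs <- c(sum(items$q_mild * price), sum(items$q_moderate * price),
             sum(items$q_severe * price))
  list(sat_matrices = sat,
       placebo_matrices = extend_matrices(config$db_placebo_matrix, n_db_cycles),
       utilities = utility_set(config$utility_means[[1L]],
                               config$utility_means[[2L]],
                               config$utility_means[[3L]]),
       state_costs = state_cost_set(costs[1L], costs[2L], costs[3L]))
}
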