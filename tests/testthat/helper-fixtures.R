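# Fixtures built in code: tiny hand-countable datasets and a plain
# Markov-chain simulator used as an independent oracle for the estimators.

# NRS values that classify to mild / moderate / severe.
NRS_OF <- c(mild = 2, moderate = 5, severe = 8)

# Build a trial_dataset from per-patient severity trajectories given as
# character vectors of state names ("mild"/"moderate"/"severe", NA for a
# missing cycle). Utilities default to the state code / 10 unless supplied.
make_trial <- function(trajectories, strata = NULL, utilities = NULL) {
  n <- length(trajectories)
  if (is.null(strata)) strata <- rep("db_sativex", n)
  rows <- lapply(seq_len(n), function(i) {
    st <- trajectories[[i]]
    cyc <- which(!is.na(st))
    u <- if (is.null(utilities)) {
      match(st[cyc], c("mild", "moderate", "severe")) / 10
    } else {
      utilities[[i]][cyc]
    }
    data.frame(patient_id = sprintf("P%03d", i), stratum = strata[i],
               cycle = cyc, nrs = unname(NRS_OF[st[cyc]]), utility = u,
               stringsAsFactors = FALSE)
  })
  trial_dataset(do.call(rbind, rows))
}

# Simulate n patients over n_steps transitions of a single severity chain
# (the independent oracle for estimator consistency checks).
simulate_chain_trial <- function(chain, n, n_steps, seed,
                                 start = c(1, 1, 1) / 3) {
  set.seed(seed)
  states <- matrix(NA_integer_, n, n_steps + 1L)
  states[, 1L] <- sample.int(3L, n, replace = TRUE, prob = start)
  for (t in seq_len(n_steps)) {
    p <- chain[states[, t], , drop = FALSE]
    u <- runif(n)
    states[, t + 1L] <- 1L + (u > p[, 1L]) + (u > p[, 1L] + p[, 2L])
  }
  nrs <- matrix(unname(NRS_OF[c("mild", "moderate", "severe")[states]]),
                n, n_steps + 1L)
  df <- data.frame(patient_id = rep(sprintf("P%05d", seq_len(n)), n_steps + 1L),
                   stratum = "db_sativex",
                   cycle = rep(seq_len(n_steps + 1L), each = n),
                   nrs = as.vector(nrs),
                   utility = NA_real_, stringsAsFactors = FALSE)
  df$utility <- runif(nrow(df), 0.3, 0.7)
  trial_dataset(df)
}

# A zero-mortality, zero-discontinuation, undiscounted config.
plain_config <- function(n_cycles = 65L, ...) {
  model_config(n_cycles = n_cycles,
               discount_rate_costs = 0, discount_rate_qalys = 0,
               mortality_per_cycle = rep(0, n_cycles),
               discontinuation_per_cycle = rep(0, n_cycles), ...)
}

identity_severity <- function() diag(3)

# Degenerate inputs: every patient has the same trajectory and utilities,
# every expert gives identical quantities -- the PSA must have zero variance.
degenerate_inputs <- function() {
  traj <- rep(list(c("severe", "moderate", "mild", "mild", "mild", "mild")),
              12L)
  strata <- rep(c("single_blind_only", "db_sativex", "db_placebo"), each = 4L)
  utilities <- rep(list(rep(0.5, 6L)), 12L)
  trial <- make_trial(traj, strata, utilities)
  cfg <- generator_config(expert_sdlog = 0)
  dp <- generate_delphi_panel(cfg, 1)
  list(trial = trial, panel = dp$panel, tariffs = dp$tariffs)
}
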