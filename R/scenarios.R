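# The three published analysis scenarios and results reporting.

#' Scenario specification
#'
#' The three scenarios differ only in the source of the severity transition
#' matrices:
#'
#' * `"base"`: on-treatment matrices from the trial estimates for the trial
#'   window (cycles 1-5), the last carried forward; standard-care matrices
#'   from the external long-term observational source for all cycles.
#' * `"s1"`: as base, but the standard-care matrices are estimated from the
#'   trial's placebo stratum (so all efficacy data come from the trial, and
#'   the PSA bootstraps the standard-care matrices too).
#' * `"s2"`: conservative; the treatment effect ends with the trial. From
#'   cycle 6 the on-treatment states follow the external standard-care
#'   matrices while drug costs continue to accrue.
#'
#' @param id `"base"`, `"s1"` or `"s2"`.
#' @return Object of class `scenario_spec` with the per-arm source map.
#' @export
scenario_spec <- function(id = c("base", "s1", "s2")) {
  id <- match.arg(id)
  sources <- switch(id,
    base = list(sativex = c(`cycles 1-5` = "trial estimate",
                            `cycles 6+` = "carry forward cycle 5"),
                soc = c(`all cycles` = "external matrices")),
    s1 = list(sativex = c(`cycles 1-5` = "trial estimate",
                          `cycles 6+` = "carry forward cycle 5"),
              soc = c(`all cycles` = "trial estimate (placebo stratum)")),
    s2 = list(sativex = c(`cycles 1-5` = "trial estimate",
                          `cycles 6+` = "external matrices (drug costs continue)"),
              soc = c(`all cycles` = "external matrices")))
  structure(list(id = id, sources = sources), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$id, "\n")
  for (arm in names(x$sources)) {
    for (rng in names(x$sources[[arm]])) {
      cat(sprintf("  %-8s %-12s %s\n", arm, rng, x$sources[[arm]][[rng]]))
    }
  }
  invisible(x)
}

#' Run an analysis scenario
#'
#' Wires the pipeline stages together for one scenario: a deterministic
#' point-estimate run (`mode = "point"`), the stratified bootstrap PSA
#' (`"bootstrap"`), or the independent Monte Carlo PSA (`"mc"`, which first
#' performs the point run to obtain the parametric dispersions). When
#' `out_dir` is given, the results table, per-horizon cost-effectiveness
#' plane CSVs and a reproducibility manifest (seed, scenario, package
#' version) are written there.
#'
#' @param scenario A [scenario_spec()] or a scenario id string.
#' @param inputs List with elements `trial` ([trial_dataset()]), `panel`
#'   ([delphi_panel()]), `tariffs` ([unit_cost_table()]), and optionally
#'   `soc_matrices` (default: packaged synthetic stand-in), `config`
#'   (default [model_config()]) and `price` (default [drug_price()]).
#' @param mode `"point"`, `"bootstrap"` or `"mc"`.
#' @param n_replicates Replicates for the PSA modes (default 1000).
#' @param seed Root seed for the PSA modes.
#' @param out_dir Optional output directory.
#' @return For `"point"` a [evaluate_cua()] result; for the PSA modes a
#'   `psa_result`.
#' @export
run_scenario <- function(scenario, inputs,
                         mode = c("point", "bootstrap", "mc"),
                         n_replicates = 1000L, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  required <- c("trial", "panel", "tariffs")
  missing_in <- setdiff(required, names(inputs))
  if (length(missing_in)) {
    stop("inputs bundle is missing: ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }
  soc <- inputs$soc_matrices
  if (is.null(soc)) soc <- default_soc_matrix()
  config <- inputs$config
  if (is.null(config)) config <- model_config()
  price <- inputs$price
  if (is.null(price)) price <- drug_price()

  result <- switch(mode,
    point = evaluate_cua(inputs$trial, inputs$panel, inputs$tariffs, config,
                         scenario$id, soc, price),
    bootstrap = run_bootstrap_psa(inputs$trial, inputs$panel, inputs$tariffs,
                                  config,
                                  bootstrap_config(n_replicates, seed,
                                                   scenario$id),
                                  soc, price),
    mc = {
      point <- evaluate_cua(inputs$trial, inputs$panel, inputs$tariffs,
                            config, scenario$id, soc, price)
      run_monte_carlo_psa(point, mc_dispersion(point), config,
                          n_replicates, seed, soc, price)
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(stats::setNames(list(result), scenario$id),
                        file.path(out_dir, "results.csv"))
    if (inherits(result, "psa_result")) {
      for (h in result$summary$table$horizon) {
        write_ce_plane_csv(result,
                           file.path(out_dir,
                                     sprintf("ce_plane_%dy.csv", h)), h)
      }
    }
    manifest <- list(scenario = scenario$id, mode = mode, seed = seed,
                     n_replicates = if (mode == "point") NULL else n_replicates,
                     package = "markovboot",
                     package_version = as.character(utils::packageVersion("markovboot")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  result
}

#' Write the scenario results table
#'
#' One row per (scenario, horizon) with the incremental costs and QALYs,
#' their 95% percentile intervals, the ICER interval and the dominance
#' probability in percent. Point-estimate runs fill the point columns and
#' leave the interval and probability columns `NA`.
#'
#' @param results Named list mapping scenario id to a [evaluate_cua()] or
#'   `psa_result` object, all covering the same horizons.
#' @param path Output CSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (inherits(results, "cua_evaluation") || inherits(results, "psa_result")) {
    results <- stats::setNames(list(results),
                               if (!is.null(results$scenario)) results$scenario
                               else "base")
  }
  rows <- lapply(names(results), function(id) {
    res <- results[[id]]
    if (inherits(res, "cua_evaluation")) {
      inc <- res$increments
      data.frame(scenario = id, horizon = inc$horizon,
                 delta_costs = inc$delta_costs,
                 delta_costs_lo = NA_real_, delta_costs_hi = NA_real_,
                 delta_qalys = inc$delta_qalys,
                 delta_qalys_lo = NA_real_, delta_qalys_hi = NA_real_,
                 icer = inc$icer,
                 icer_lo = NA_real_, icer_hi = NA_real_,
                 dominance_pct = NA_real_)
    } else if (inherits(res, "psa_result")) {
      tab <- res$summary$table
      data.frame(scenario = id, horizon = tab$horizon,
                 delta_costs = tab$delta_costs,
                 delta_costs_lo = tab$delta_costs_lo,
                 delta_costs_hi = tab$delta_costs_hi,
                 delta_qalys = tab$delta_qalys,
                 delta_qalys_lo = tab$delta_qalys_lo,
                 delta_qalys_hi = tab$delta_qalys_hi,
                 icer = tab$delta_costs / tab$delta_qalys,
                 icer_lo = tab$icer_lo, icer_hi = tab$icer_hi,
                 dominance_pct = 100 * tab$dominance_probability)
    } else {
      stop("unsupported result object for scenario '", id, "'", call. = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  horizons <- unique(out$horizon)
  want <- expand.grid(scenario = names(results), horizon = horizons,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(out$scenario, out$horizon)
  miss <- setdiff(paste(want$scenario, want$horizon), have)
  if (length(miss)) {
    stop("missing result cells: ", paste(miss, collapse = "; "), call. = FALSE)
  }
  # full-precision formatting so a read-back reproduces the doubles exactly
  out_txt <- out
  num <- vapply(out_txt, is.numeric, logical(1))
  out_txt[num] <- lapply(out_txt[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  utils::write.csv(out_txt, path, row.names = FALSE)
  invisible(out)
}
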