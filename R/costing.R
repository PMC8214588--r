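# Costing: drug acquisition costs from the dosing schedule and pack price,
# and severity-state care costs from Delphi-panel resource use priced at
# unit-cost tariffs.

#' Nabiximols dosing schedule
#'
#' Mean sprays per day by model cycle: 6.9 during the up-titration cycle
#' (cycle 1), 7.7 for cycles 2-5 (end of single-blind dose), then a linear
#' taper from 7.3 at cycle 6 to the long-term 6.2 at cycle 14, held constant
#' thereafter.
#'
#' @param n_cycles Schedule length (default 65).
#' @return Numeric vector of sprays/day, one entry per cycle.
#' @export
dose_schedule <- function(n_cycles = 65L) {
  full <- c(6.9, rep(7.7, 4L), 7.3 - 1.1 * (0:8) / 8, rep(6.2, 51L))
  if (n_cycles > length(full)) full <- c(full, rep(6.2, n_cycles - length(full)))
  full[seq_len(n_cycles)]
}

#' @rdname dose_schedule
#' @param cycle Cycle index in 1..65 (vectorised).
#' @export
sativex_dose_for_cycle <- function(cycle) {
  if (any(cycle < 1 | cycle > 65 | cycle != as.integer(cycle))) {
    stop("'cycle' must be an integer in 1..65", call. = FALSE)
  }
  dose_schedule(65L)[cycle]
}

#' Drug price
#'
#' Acquisition price of the oromucosal spray: list price per pack of 3 vials
#' of 90 sprays each (270 sprays), default EUR 466.40.
#'
#' @param pack_price Price per pack in EUR.
#' @param vials_per_pack,sprays_per_vial Pack composition.
#' @return Object of class `drug_price` with the derived `price_per_spray`.
#' @export
drug_price <- function(pack_price = 466.40, vials_per_pack = 3L,
                       sprays_per_vial = 90L) {
  stopifnot(pack_price >= 0, vials_per_pack >= 1, sprays_per_vial >= 1)
  structure(list(pack_price = pack_price,
                 vials_per_pack = vials_per_pack,
                 sprays_per_vial = sprays_per_vial,
                 price_per_spray = pack_price / (vials_per_pack * sprays_per_vial)),
            class = "drug_price")
}

#' Drug cost for one model cycle
#'
#' Cycle drug cost = sprays/day for the cycle x 28 days x price per spray.
#' The default prices fractional sprays continuously (no wastage rule);
#' `rounding = "pack"` instead charges whole packs per cycle, for wastage
#' sensitivity exploration. Drug costs apply only to the on-treatment
#' (`sat_*`) states.
#'
#' @param cycle Cycle index in 1..65 (vectorised).
#' @param price A [drug_price()].
#' @param cycle_days Days per cycle (default 28).
#' @param rounding `"continuous"` (default) or `"pack"`.
#' @return EUR cost(s) per patient-cycle on treatment.
#' @export
sativex_cost_per_cycle <- function(cycle, price = drug_price(),
                                   cycle_days = 28,
                                   rounding = c("continuous", "pack")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(price, "drug_price"))
  sprays <- sativex_dose_for_cycle(cycle) * cycle_days
  if (rounding == "continuous") {
    sprays * price$price_per_spray
  } else {
    sprays_per_pack <- price$vials_per_pack * price$sprays_per_vial
    ceiling(sprays / sprays_per_pack) * price$pack_price
  }
}

#' Construct a Delphi panel resource-use table
#'
#' Expert-elicited standard-of-care resource use: one row per (expert,
#' severity state, resource item) with the quantity used per 28-day cycle.
#' All experts must cover the identical (severity, item) grid with no
#' missing values. Resource use is assumed identical in both model arms.
#'
#' @param df Data frame with columns `expert_id`, `severity`, `item`,
#'   `quantity_per_cycle` (>= 0).
#' @return Object of class `delphi_panel` (the validated data frame).
#' @export
delphi_panel <- function(df) {
  required <- c("expert_id", "severity", "item", "quantity_per_cycle")
  if (!all(required %in% names(df))) {
    stop("panel data must have columns: ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("Delphi panel is empty", call. = FALSE)
  if (!all(df$severity %in% SEVERITY_LEVELS)) {
    stop("severity must be one of: ", paste(SEVERITY_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  q <- df$quantity_per_cycle
  if (any(is.na(q)) || any(q < 0)) {
    stop("quantities must be present and non-negative", call. = FALSE)
  }
  experts <- unique(df$expert_id)
  cells <- paste(df$severity, df$item, sep = "\r")
  grid <- unique(cells)
  per_expert <- split(cells, df$expert_id)
  complete <- vapply(per_expert, function(cc) {
    !anyDuplicated(cc) && length(cc) == length(grid) && all(grid %in% cc)
  }, logical(1))
  if (!all(complete)) {
    stop("expert(s) ", paste(experts[!complete[as.character(experts)]],
                             collapse = ", "),
         " do not cover the full severity x item grid exactly once",
         call. = FALSE)
  }
  structure(as.data.frame(df)[required], class = c("delphi_panel", "data.frame"))
}

#' Number and identity of panel experts
#' @param panel A [delphi_panel()].
#' @return Vector of unique expert identifiers.
#' @export
panel_experts <- function(panel) {
  stopifnot(inherits(panel, "delphi_panel"))
  unique(panel$expert_id)
}

#' Construct a unit-cost tariff table
#'
#' Maps every resource item to a EUR unit cost (point values; tariff
#' uncertainty is deliberately excluded from the PSA).
#'
#' @param df Data frame with columns `item`, `unit_cost_eur` (>= 0).
#' @return Object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(df) {
  required <- c("item", "unit_cost_eur")
  if (!all(required %in% names(df))) {
    stop("tariff table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$item)) stop("duplicate tariff items", call. = FALSE)
  if (any(is.na(df$unit_cost_eur)) || any(df$unit_cost_eur < 0)) {
    stop("unit costs must be present and non-negative", call. = FALSE)
  }
  structure(as.data.frame(df)[required],
            class = c("unit_cost_table", "data.frame"))
}

#' Read the panel / tariff CSV dialects
#'
#' @param path File path.
#' @return A [delphi_panel()] or [unit_cost_table()] respectively.
#' @export
read_panel_csv <- function(path) {
  delphi_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_panel_csv
#' @export
read_tariff_csv <- function(path) {
  unit_cost_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-cycle severity-state care cost
#'
#' For each severity state, resource quantities are first averaged over the
#' panel experts (the conventional Delphi point estimate, and the quantity
#' the bootstrap perturbs) and then priced at the unit-cost tariffs:
#' `cost(state) = sum over items of mean_expert(quantity) * tariff`. The same
#' care cost applies in both model arms.
#'
#' @param panel A [delphi_panel()].
#' @param tariffs A [unit_cost_table()].
#' @return Object of class `state_cost_set`: named EUR costs per cycle for
#'   mild / moderate / severe, with per-state standard errors of the
#'   expert-mean cost (`se`) carried along for the Monte Carlo engine.
#' @export
state_cost_per_cycle <- function(panel, tariffs) {
  stopifnot(inherits(panel, "delphi_panel"),
            inherits(tariffs, "unit_cost_table"))
  missing_items <- setdiff(unique(panel$item), tariffs$item)
  if (length(missing_items)) {
    stop("no tariff for item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  price <- tariffs$unit_cost_eur[match(panel$item, tariffs$item)]
  expert_cost <- rowsum(panel$quantity_per_cycle * price,
                        paste(panel$severity, panel$expert_id, sep = "\r"))
  sev <- sub("\r.*", "", rownames(expert_cost))
  costs <- tapply(expert_cost[, 1L], factor(sev, levels = SEVERITY_LEVELS), mean)
  ses <- tapply(expert_cost[, 1L], factor(sev, levels = SEVERITY_LEVELS),
                function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  if (anyNA(costs)) {
    stop("panel has no entries for state(s): ",
         paste(SEVERITY_LEVELS[is.na(costs)], collapse = ", "), call. = FALSE)
  }
  state_cost_set(costs[[1L]], costs[[2L]], costs[[3L]], se = as.numeric(ses))
}

#' Construct a severity-state cost set
#'
#' @param mild,moderate,severe Care cost per 28-day cycle, EUR (>= 0).
#' @param se Optional per-state standard errors.
#' @return Object of class `state_cost_set`.
#' @export
state_cost_set <- function(mild, moderate, severe, se = NULL) {
  costs <- c(mild = mild, moderate = moderate, severe = severe)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("state care costs must be non-negative", call. = FALSE)
  }
  structure(list(costs = costs, se = se), class = "state_cost_set")
}

#' @export
print.state_cost_set <- function(x, ...) {
  cat("<state_cost_set> EUR/cycle:",
      paste(names(x$costs), round(x$costs, 2), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-state per-cycle cost matrix for the cohort engine
#'
#' Total per-cycle cost of an on-treatment state is drug cost plus the care
#' cost of its severity; a standard-care state incurs the care cost only;
#' death incurs nothing.
#'
#' @param state_costs A [state_cost_set()].
#' @param config A [model_config()].
#' @param price A [drug_price()]; set `NULL` to omit drug costs entirely.
#' @param rounding Drug pricing mode, see [sativex_cost_per_cycle()].
#' @return 7 x `n_cycles` matrix of EUR costs, rows in [model_states()]
#'   order, suitable for [run_cohort()].
#' @export
cycle_cost_matrix <- function(state_costs, config, price = drug_price(),
                              rounding = "continuous") {
  stopifnot(inherits(state_costs, "state_cost_set"),
            inherits(config, "model_config"))
  n <- config$n_cycles
  drug <- if (is.null(price)) {
    numeric(n)
  } else {
    sprays <- dose_schedule(n) * config$cycle_days
    if (rounding == "continuous") {
      sprays * price$price_per_spray
    } else {
      ceiling(sprays / (price$vials_per_pack * price$sprays_per_vial)) *
        price$pack_price
    }
  }
  m <- matrix(0, 7L, n, dimnames = list(MODEL_STATES, NULL))
  m[1:3, ] <- state_costs$costs + rep(drug, each = 3L)
  m[4:6, ] <- state_costs$costs
  m
}
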