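# Patient-level trial data: container, estimators for per-cycle transition
# matrices, and state utilities.

#' Construct a patient-level trial dataset
#'
#' Builds the dataset object consumed by the transition-probability and
#' utility estimators and by the bootstrap engine. Input is one row per
#' patient-cycle observation. A row records the patient's cycle-level NRS
#' summary and, optionally, a concurrent utility observation; cycles with no
#' observation are simply absent (missing data are never imputed).
#'
#' Strata label the trial phase a patient reached: `db_sativex` and
#' `db_placebo` for the two double-blind randomisation arms, and
#' `single_blind_only` for patients who did not enter the double-blind phase.
#' The strata are the resampling units of the stratified bootstrap.
#'
#' @param df Data frame with columns `patient_id`, `stratum`, `cycle`
#'   (positive integer, 1-based observation index), `nrs` (in \[0, 10\]) and
#'   `utility` (in \[-1, 1\], may be `NA`).
#' @return An object of class `trial_dataset`.
#' @seealso [read_trial_csv()], [estimate_transition_matrix()],
#'   [estimate_utilities()]
#' @export
trial_dataset <- function(df) {
  required <- c("patient_id", "stratum", "cycle", "nrs", "utility")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trial data must have columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("trial dataset is empty", call. = FALSE)
  if (!all(df$stratum %in% STRATUM_LEVELS)) {
    stop("stratum must be one of: ", paste(STRATUM_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  cyc <- df$cycle
  if (any(is.na(cyc)) || any(cyc < 1L) || any(cyc != as.integer(cyc))) {
    stop("cycle indices must be positive integers", call. = FALSE)
  }
  if (any(is.na(df$nrs)) || any(df$nrs < 0) || any(df$nrs > 10)) {
    stop("every observation row needs an NRS value in [0, 10]", call. = FALSE)
  }
  u <- df$utility
  if (any(!is.na(u) & (u < -1 | u > 1))) {
    stop("utility values must lie in [-1, 1]", call. = FALSE)
  }
  key <- paste(df$patient_id, df$cycle, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate patient-cycle rows", call. = FALSE)
  }

  ids <- unique(df$patient_id)
  pid <- match(df$patient_id, ids)
  stratum <- character(length(ids))
  stratum[pid] <- as.character(df$stratum)
  # a patient must carry a single stratum label
  chk <- tapply(as.character(df$stratum), pid, function(s) length(unique(s)))
  if (any(chk > 1L)) {
    stop("a patient appears under more than one stratum", call. = FALSE)
  }

  n_cycles <- max(cyc)
  nrs_mat <- matrix(NA_real_, length(ids), n_cycles)
  util_mat <- matrix(NA_real_, length(ids), n_cycles)
  idx <- cbind(pid, cyc)
  nrs_mat[idx] <- df$nrs
  util_mat[idx] <- df$utility
  new_trial_dataset(data.frame(patient_id = ids, stratum = stratum,
                               stringsAsFactors = FALSE),
                    nrs_mat, util_mat)
}

# Internal constructor from the wide representation (used by the bootstrap
# resampler, where rebuilding the long data frame would dominate runtime).
new_trial_dataset <- function(patients, nrs_mat, util_mat) {
  structure(
    list(patients = patients,
         nrs = nrs_mat,
         utility = util_mat,
         state = matrix(classify_nrs_int(nrs_mat), nrow(nrs_mat))),
    class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cnt <- stratum_counts(x)
  cat("<trial_dataset>\n")
  cat("  patients:", nrow(x$patients), "  observation cycles:", ncol(x$nrs), "\n")
  cat("  strata:  ", paste(names(cnt), cnt, sep = " = ", collapse = ", "), "\n")
  cat("  NRS observations:", sum(!is.na(x$nrs)),
      "  utility observations:", sum(!is.na(x$utility)), "\n")
  invisible(x)
}

#' Patient counts per stratum
#'
#' @param dataset A [trial_dataset()].
#' @return Named integer vector over the three strata.
#' @export
stratum_counts <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  out <- table(factor(dataset$patients$stratum, levels = STRATUM_LEVELS))
  stats::setNames(as.integer(out), STRATUM_LEVELS)
}

#' Convert a trial dataset back to its long data-frame form
#'
#' @param x A [trial_dataset()].
#' @param ... Unused.
#' @return Data frame with columns `patient_id`, `stratum`, `cycle`, `nrs`,
#'   `utility`, one row per observed patient-cycle.
#' @export
as.data.frame.trial_dataset <- function(x, ...) {
  obs <- which(!is.na(x$nrs), arr.ind = TRUE)
  obs <- obs[order(obs[, 1L], obs[, 2L]), , drop = FALSE]
  data.frame(patient_id = x$patients$patient_id[obs[, 1L]],
             stratum = x$patients$stratum[obs[, 1L]],
             cycle = obs[, 2L],
             nrs = x$nrs[obs],
             utility = x$utility[obs],
             stringsAsFactors = FALSE)
}

#' Read / write the trial-data CSV dialect
#'
#' One row per patient-cycle with columns `patient_id`, `stratum`, `cycle`,
#' `nrs`, `utility` (utility may be empty). UTF-8, header required.
#'
#' @param path File path.
#' @return `read_trial_csv()` returns a [trial_dataset()];
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  trial_dataset(df)
}

#' @rdname read_trial_csv
#' @param dataset A [trial_dataset()].
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Estimate a per-cycle severity transition matrix
#'
#' Counts observed severity transitions from observation cycle `cycle` to
#' `cycle + 1` among patients in the requested strata and converts each row
#' to relative frequencies. Patients missing either endpoint observation are
#' excluded from that row's counts. The matrix is conditional on remaining on
#' treatment and alive; discontinuation and mortality are layered on
#' downstream by [compose_full_matrix()].
#'
#' A severity row with zero at-risk patients is returned as the identity row
#' and flagged (and signalled as a warning of class `markovboot_empty_row`),
#' so that small bootstrap replicates always yield a usable schedule.
#'
#' @param dataset A [trial_dataset()].
#' @param cycle Positive integer; transitions are counted from observation
#'   `cycle` to `cycle + 1`.
#' @param strata Character vector of strata to include (default: all three).
#' @return Object of class `transition_estimate`: list with `cycle`, `matrix`
#'   (3x3 row-stochastic, rows = origin, columns = destination), `n_at_risk`
#'   (total transitions observed), `n_row` (at-risk count per origin row) and
#'   `identity_rows` (logical flags for rows backfilled with identity).
#' @export
estimate_transition_matrix <- function(dataset, cycle,
                                       strata = STRATUM_LEVELS) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (length(strata) == 0L) stop("'strata' must be non-empty", call. = FALSE)
  cycle <- as.integer(cycle)
  if (is.na(cycle) || cycle < 1L) stop("'cycle' must be >= 1", call. = FALSE)
  if (cycle + 1L > ncol(dataset$state)) {
    stop("no observations beyond cycle ", cycle, " in this dataset",
         call. = FALSE)
  }
  sel <- dataset$patients$stratum %in% strata
  from <- dataset$state[sel, cycle]
  to <- dataset$state[sel, cycle + 1L]
  ok <- !is.na(from) & !is.na(to)
  if (!any(!is.na(from)) && !any(!is.na(to))) {
    stop("cycle ", cycle, " has no observations at either endpoint",
         call. = FALSE)
  }
  counts <- matrix(0, 3L, 3L, dimnames = list(SEVERITY_LEVELS, SEVERITY_LEVELS))
  if (any(ok)) {
    tab <- table(factor(from[ok], levels = 1:3), factor(to[ok], levels = 1:3))
    counts[] <- as.numeric(tab)
  }
  n_row <- rowSums(counts)
  mat <- counts
  identity_rows <- n_row == 0
  for (i in which(identity_rows)) {
    mat[i, ] <- 0
    mat[i, i] <- 1
  }
  nz <- which(!identity_rows)
  mat[nz, ] <- counts[nz, , drop = FALSE] / n_row[nz]
  if (any(identity_rows)) {
    warning(warningCondition(
      paste0("cycle ", cycle, ": no at-risk patients in row(s) ",
             paste(SEVERITY_LEVELS[identity_rows], collapse = ", "),
             "; identity row substituted"),
      class = "markovboot_empty_row"))
  }
  structure(list(cycle = cycle, matrix = mat,
                 n_at_risk = sum(n_row), n_row = n_row,
                 identity_rows = identity_rows),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat("<transition_estimate> cycle", x$cycle, "(n at risk =", x$n_at_risk, ")\n")
  print(round(x$matrix, 4))
  if (any(x$identity_rows)) {
    cat("identity rows (no at-risk patients):",
        paste(SEVERITY_LEVELS[x$identity_rows], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate state utilities from trial observations
#'
#' Each utility observation is attributed to the severity state of its
#' concurrent NRS value; the state utility is the arithmetic mean over all
#' such observations, pooled over patients, cycles, and strata. A single set
#' of three state utilities is shared by both model arms.
#'
#' @param dataset A [trial_dataset()].
#' @return Object of class `utility_set`: list with `u` (named utilities for
#'   mild/moderate/severe), `n` (observation counts) and `se` (standard
#'   errors of the means, used by the Monte Carlo comparator).
#' @export
estimate_utilities <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  st <- as.vector(dataset$state)
  u <- as.vector(dataset$utility)
  ok <- !is.na(st) & !is.na(u)
  st <- st[ok]; u <- u[ok]
  n <- tabulate(st, nbins = 3L)
  if (any(n == 0L)) {
    stop("no utility observations for state(s): ",
         paste(SEVERITY_LEVELS[n == 0L], collapse = ", "), call. = FALSE)
  }
  means <- as.numeric(rowsum(u, st)) / n
  sds <- vapply(1:3, function(i) stats::sd(u[st == i]), numeric(1))
  sds[is.na(sds)] <- 0
  utility_set(means[1L], means[2L], means[3L],
              n = n, se = sds / sqrt(n))
}

#' Construct a utility set
#'
#' Holds the QALY weight (per year of state occupancy) for each severity
#' state, either estimated from trial data ([estimate_utilities()]) or given
#' directly.
#'
#' @param u_mild,u_moderate,u_severe Utilities in \[-1, 1\].
#' @param n,se Optional observation counts and standard errors (carried along
#'   for the Monte Carlo engine's dispersion spec).
#' @return Object of class `utility_set`.
#' @export
utility_set <- function(u_mild, u_moderate, u_severe, n = NULL, se = NULL) {
  u <- c(mild = u_mild, moderate = u_moderate, severe = u_severe)
  if (any(!is.finite(u)) || any(u < -1) || any(u > 1)) {
    stop("utilities must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(u = u, n = n, se = se), class = "utility_set")
}

#' @export
print.utility_set <- function(x, ...) {
  cat("<utility_set>", paste(names(x$u), round(x$u, 4), sep = " = ",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Read / write severity transition matrices in long CSV form
#'
#' The dialect has columns `cycle`, `from_state`, `to_state`, `probability`,
#' one row per matrix entry.
#'
#' @param path File path.
#' @return `read_matrix_csv()` returns a named list of 3x3 matrices, one per
#'   cycle present in the file (names `"1"`, `"2"`, ...). A file with a
#'   single cycle still returns a one-element list.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cycle", "from_state", "to_state", "probability")
  if (!all(required %in% names(df))) {
    stop("matrix CSV needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  split_df <- split(df, df$cycle)
  out <- lapply(split_df, function(d) {
    m <- matrix(NA_real_, 3L, 3L,
                dimnames = list(SEVERITY_LEVELS, SEVERITY_LEVELS))
    m[cbind(match(d$from_state, SEVERITY_LEVELS),
            match(d$to_state, SEVERITY_LEVELS))] <- d$probability
    if (anyNA(m)) stop("incomplete matrix for cycle ", d$cycle[1L], call. = FALSE)
    m
  })
  out[order(as.integer(names(out)))]
}

#' @rdname read_matrix_csv
#' @param matrices Named list of 3x3 matrices (names = cycle labels), or a
#'   single 3x3 matrix (written as cycle 1).
#' @export
write_matrix_csv <- function(matrices, path) {
  if (is.matrix(matrices)) matrices <- list(`1` = matrices)
  rows <- lapply(names(matrices), function(cy) {
    m <- matrices[[cy]]
    data.frame(cycle = as.integer(cy),
               from_state = rep(SEVERITY_LEVELS, each = 3L),
               to_state = rep(SEVERITY_LEVELS, times = 3L),
               probability = as.vector(t(m)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
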