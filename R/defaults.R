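# Packaged default model inputs.

#' Base-case on-treatment transition matrices
#'
#' The published per-cycle severity transition matrices for the add-on arm
#' (trial-based base case), as printed: rows are conditional on surviving
#' the cycle but still include the removal of treatment discontinuers, so
#' each row sums to 1 minus the cycle's discontinuation probability (0 in
#' cycle 1, 0.038 in cycles 2-4, 0.035 from cycle 5). Use
#' [default_sativex_matrices()] for the conditional matrices ready for
#' [build_schedule()].
#'
#' @return Named list with `matrices` (list of 3x3 matrices, cycles 1-5;
#'   cycle 5 also applies to all later cycles) and `discontinuation` (the
#'   per-cycle probabilities embedded in the printed rows).
#' @export
published_sativex_matrices <- function() {
  m <- function(...) matrix(c(...), 3L, 3L, byrow = TRUE,
                            dimnames = list(SEVERITY_LEVELS, SEVERITY_LEVELS))
  list(matrices = list(
         m(0.219, 0.719, 0.062,
           0.094, 0.734, 0.172,
           0.100, 0.100, 0.800),
         m(0.769, 0.096, 0.096,
           0.100, 0.731, 0.130,
           0.048, 0.433, 0.481),
         m(0.962, 0.000, 0.000,
           0.329, 0.633, 0.000,
           0.000, 0.240, 0.721),
         m(0.962, 0.000, 0.000,
           0.111, 0.851, 0.000,
           0.000, 0.000, 0.962),
         m(0.844, 0.121, 0.000,
           0.241, 0.724, 0.000,
           0.000, 0.000, 0.965)),
       discontinuation = c(0, 0.038, 0.038, 0.038, 0.035))
}

#' @rdname published_sativex_matrices
#' @return `default_sativex_matrices()`: list of 3x3 conditional
#'   row-stochastic matrices for cycles 1-5 (each printed matrix divided by
#'   1 minus its discontinuation probability and renormalised).
#' @export
default_sativex_matrices <- function() {
  pub <- published_sativex_matrices()
  Map(load_published_matrix, pub$matrices, pub$discontinuation)
}

#' Synthetic stand-in standard-care transition matrix
#'
#' The base case uses an external long-term observational source for the
#' standard-care arm's severity transitions; that source is not redistributable,
#' so the package ships a synthetic stand-in: a single time-homogeneous 3x3
#' matrix with mildly progressive dynamics, applied to every cycle. It is
#' stored as a plain-text CSV under `inst/extdata/` and is clearly labelled
#' synthetic; replace it with real external matrices via [read_matrix_csv()]
#' for any substantive analysis.
#'
#' @return A 3x3 row-stochastic matrix.
#' @export
default_soc_matrix <- function() {
  path <- system.file("extdata", "soc_transitions_synthetic.csv",
                      package = "markovboot", mustWork = TRUE)
  read_matrix_csv(path)[[1L]]
}

#' Synthetic stand-in unit-cost tariffs
#'
#' The tariffs actually used in the published analysis (2019 national
#' reimbursement tariffs) are not redistributable; the package ships a
#' synthetic stand-in table of plausible EUR unit costs for the resource
#' items emitted by [generate_delphi_panel()].
#'
#' @return A [unit_cost_table()].
#' @export
default_unit_costs <- function() {
  read_tariff_csv(system.file("extdata", "unit_costs_synthetic.csv",
                              package = "markovboot", mustWork = TRUE))
}
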