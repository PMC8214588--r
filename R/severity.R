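# Severity-state vocabulary shared across the package.
#
# Spasticity severity is graded on the 0-10 numerical rating scale (NRS) and
# collapsed into three ordered states. The cut-offs follow the model lineage:
# mild < 3.3, moderate in [3.3, 6.6], severe > 6.6. The interval "between 3.3
# and 6.6" is read as closed, so the three states partition [0, 10] exactly.

SEVERITY_LEVELS <- c("mild", "moderate", "severe")

STRATUM_LEVELS <- c("single_blind_only", "db_sativex", "db_placebo")

MODEL_STATES <- c("sat_mild", "sat_moderate", "sat_severe",
                  "soc_mild", "soc_moderate", "soc_severe", "death")

#' Severity state labels
#'
#' The three spasticity severity states used throughout the model, in
#' increasing order of severity.
#'
#' @return Character vector `c("mild", "moderate", "severe")`.
#' @export
severity_levels <- function() SEVERITY_LEVELS

#' Model state labels
#'
#' The seven Markov states: three severity states on add-on treatment
#' (`sat_*`), three on standard care alone (`soc_*`), and absorbing `death`.
#'
#' @return Character vector of length 7.
#' @export
model_states <- function() MODEL_STATES

#' Classify an NRS score into a severity state
#'
#' Maps spasticity numerical rating scale (NRS) scores in \[0, 10\] onto the
#' three model severity states: mild for scores below 3.3, moderate for
#' scores in the closed interval \[3.3, 6.6\], severe for scores above 6.6.
#' Every score maps to exactly one state.
#'
#' @param score Numeric vector of NRS scores in \[0, 10\]. `NA` entries are
#'   propagated (missing observations are never imputed).
#' @return Ordered factor with levels `mild < moderate < severe`.
#' @examples
#' classify_nrs(c(2.5, 3.3, 6.6, 8.1))
#' @export
classify_nrs <- function(score) {
  if (!is.numeric(score)) {
    stop("'score' must be numeric", call. = FALSE)
  }
  bad <- !is.na(score) & (score < 0 | score > 10 | !is.finite(score))
  if (any(bad)) {
    stop("NRS scores must lie in [0, 10]; offending value(s): ",
         paste(utils::head(score[bad], 3L), collapse = ", "), call. = FALSE)
  }
  out <- ifelse(score < 3.3, "mild", ifelse(score <= 6.6, "moderate", "severe"))
  factor(out, levels = SEVERITY_LEVELS, ordered = TRUE)
}

# Integer severity codes (1 = mild, 2 = moderate, 3 = severe); NA passes
# through. Used internally where factors are too slow.
classify_nrs_int <- function(score) {
  ifelse(is.na(score), NA_integer_,
         ifelse(score < 3.3, 1L, ifelse(score <= 6.6, 2L, 3L)))
}
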