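#' COOP/WONCA total score to utility
#'
#' Linear transform of the 7-item COOP/WONCA functional health total
#' (7 = best possible, 35 = worst) onto a 0-1 utility scale:
#' `utility = (35 - score) / 28`. Strictly decreasing in the score; 7 maps
#' to 1 (perfect health) and 35 to 0.
#'
#' @param score numeric COOP/WONCA total(s) in [7, 35].
#' @return utility value(s) in [0, 1].
#' @export
#' @examples
#' wonca_to_utility(c(7, 18.48, 35)) # 1, 0.59, 0
wonca_to_utility <- function(score) {
  if (!is.numeric(score)) stop("`score` must be numeric", call. = FALSE)
  bad <- !is.na(score) & (score < 7 | score > 35)
  if (any(bad)) {
    stop(sprintf("COOP/WONCA score outside [7, 35]: %s",
                 paste(score[bad], collapse = ", ")), call. = FALSE)
  }
  (35 - score) / 28
}

check_utility_pair <- function(u_baseline, u_6m) {
  for (u in list(u_baseline, u_6m)) {
    if (!is.numeric(u)) stop("utilities must be numeric", call. = FALSE)
    bad <- !is.na(u) & (u < 0 | u > 1)
    if (any(bad)) stop("utility outside [0, 1]", call. = FALSE)
  }
  if (length(u_baseline) != length(u_6m)) {
    stop("utility vectors must have equal length", call. = FALSE)
  }
}

#' Absolute QALYs over the 6-month horizon
#'
#' Area under a linear utility trajectory between baseline and 6 months:
#' `((u_baseline + u_6m) / 2) * 0.5` years, hence in [0, 0.5].
#'
#' @param u_baseline,u_6m utilities in [0, 1].
#' @return QALYs accrued over the half-year.
#' @export
qaly_absolute <- function(u_baseline, u_6m) {
  check_utility_pair(u_baseline, u_6m)
  (u_baseline + u_6m) / 2 * 0.5
}

#' QALY gain over the 6-month horizon
#'
#' Incremental area between the linear trajectory and a flat-at-baseline
#' trajectory: `((u_6m - u_baseline) / 2) * 0.5`, in [-0.25, 0.25], zero when
#' the utilities are equal. This is the quantity whose group means are used
#' by the cost-utility stage: with a baseline utility near 0.59, only the
#' gain reading (not absolute half-year QALYs) can produce group values of
#' order 0.03-0.06.
#'
#' @param u_baseline,u_6m utilities in [0, 1].
#' @return QALY gain over the half-year.
#' @export
#' @examples
#' qaly_gain(0.59, 0.70)   # 0.0275
#' qaly_gain(0.50, 0.7444) # 0.0611
qaly_gain <- function(u_baseline, u_6m) {
  check_utility_pair(u_baseline, u_6m)
  (u_6m - u_baseline) / 2 * 0.5
}

#' Attach utility and QALY columns to a cohort
#'
#' Adds `u_baseline`, `u_6m`, `qaly_absolute` and `qaly_gain` computed from
#' the COOP/WONCA columns. Participants with a missing 6-month score keep
#' `NA` QALYs and are excluded from QALY analyses downstream (complete-case
#' convention); no imputation is performed.
#'
#' @param cohort a `bzd_cohort` with `wonca_baseline` and `wonca_6m`.
#' @return the cohort with four additional columns.
#' @export
add_utilities <- function(cohort) {
  for (col in c("wonca_baseline", "wonca_6m")) {
    if (!col %in% names(cohort)) {
      stop(sprintf("cohort lacks column '%s'", col), call. = FALSE)
    }
  }
  cohort$u_baseline <- wonca_to_utility(cohort$wonca_baseline)
  cohort$u_6m <- wonca_to_utility(cohort$wonca_6m)
  cohort$qaly_absolute <- qaly_absolute(cohort$u_baseline, cohort$u_6m)
  cohort$qaly_gain <- qaly_gain(cohort$u_baseline, cohort$u_6m)
  cohort
}
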