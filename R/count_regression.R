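#' Poisson regression of a utilization count, reported as IRRs
#'
#' Log-link Poisson maximum likelihood (no exposure offset: all participants
#' share the 6-month window). Each non-intercept coefficient is reported as
#' an incidence rate ratio `exp(coef)` with 95% Wald bounds
#' `exp(coef +/- 1.96 SE)` and a two-sided Wald p-value. Reference levels
#' are fixed by the factor codings of the cohort: group = continuation,
#' sex = women, income = `<=18000`, CCI = `0-2`; the discontinuation
#' coefficient therefore estimates the discontinuation-vs-continuation rate
#' ratio.
#'
#' @param cohort a `bzd_cohort`.
#' @param outcome one of the four utilization count columns.
#' @param covariates character vector of cohort column names.
#' @param robust if `TRUE`, replace model-based SEs by the sandwich
#'   (Huber-White) estimator; the plain Poisson variance does not absorb
#'   overdispersion, so robust SEs are the safer choice for overdispersed
#'   counts.
#' @return data.frame of class `irr_table` with columns `outcome`,
#'   `predictor`, `irr`, `ci_low`, `ci_high`, `p_value`, `flag`; the fitted
#'   `glm` is attached as attribute `fit` (NULL for degenerate outcomes).
#' @export
fit_poisson_irr <- function(cohort, outcome, covariates, robust = FALSE) {
  if (!outcome %in% names(cohort)) {
    stop(sprintf("missing outcome column '%s'", outcome), call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    stop(sprintf("missing covariate column(s): %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  y <- cohort[[outcome]]
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y))) {
    stop(sprintf("'%s' must contain nonnegative integer counts", outcome),
         call. = FALSE)
  }

  if (sum(y) == 0) {
    warning(sprintf("all '%s' counts are zero; model degenerate", outcome))
    return(structure(
      data.frame(outcome = outcome, predictor = covariates,
                 irr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, flag = "all_zero_outcome"),
      class = c("irr_table", "data.frame"), fit = NULL))
  }

  fml <- as.formula(paste(outcome, "~",
                          if (length(covariates)) {
                            paste(covariates, collapse = " + ")
                          } else "1"))
  X <- model.matrix(fml, data = cohort)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }

  # quasi-separation check: a factor level whose subgroup has all-zero counts
  flags <- character(0)
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.factor(v) || is.logical(v) || is.character(v)) {
      for (lv in unique(as.character(v))) {
        if (sum(y[as.character(v) == lv]) == 0) {
          flags <- c(flags, sprintf("%s=%s", cv, lv))
        }
      }
    }
  }
  if (length(flags)) {
    warning(sprintf(
      "level(s) with all-zero '%s' counts (possible separation): %s",
      outcome, paste(flags, collapse = ", ")))
  }

  fit <- glm(fml, data = cohort, family = poisson(link = "log"))
  est <- coef(fit)
  V <- if (robust) sandwich_vcov(fit) else vcov(fit)
  se <- sqrt(diag(V))
  keep <- names(est) != "(Intercept)"
  if (!any(keep)) {
    out <- data.frame(outcome = character(0), predictor = character(0),
                      irr = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_value = numeric(0),
                      flag = character(0))
    return(structure(out, class = c("irr_table", "data.frame"), fit = fit))
  }
  z <- est[keep] / se[keep]
  out <- data.frame(
    outcome = outcome,
    predictor = names(est)[keep],
    irr = exp(est[keep]),
    ci_low = exp(est[keep] - 1.96 * se[keep]),
    ci_high = exp(est[keep] + 1.96 * se[keep]),
    p_value = 2 * pnorm(-abs(z)),
    flag = if (length(flags)) paste(flags, collapse = ";") else "",
    row.names = NULL)
  structure(out, class = c("irr_table", "data.frame"), fit = fit)
}

# Huber-White sandwich variance for a fitted Poisson glm:
# bread = (X'WX)^-1 (model-based vcov), meat = X' diag((y - mu)^2) X.
sandwich_vcov <- function(fit) {
  X <- model.matrix(fit)
  r <- fit$y - fit$fitted.values
  bread <- vcov(fit)
  meat <- crossprod(X * r, X * r)
  bread %*% meat %*% bread
}

# Default per-outcome covariate sets for the published regression table:
# mental-disorder status enters the primary-care and emergency models, sex
# the specialist and emergency models.
DEFAULT_IRR_COVARIATES <- list(
  primary_care = c("group", "age", "cci_band", "income_band",
                   "minor_mental_disorder"),
  specialist = c("group", "age", "cci_band", "income_band", "sex"),
  pc_emergency = c("group", "age", "cci_band", "income_band",
                   "minor_mental_disorder", "sex"),
  hospital_emergency = c("group", "age", "cci_band", "income_band",
                         "minor_mental_disorder", "sex")
)

#' Fit the four per-category utilization regressions
#'
#' One covariate-adjusted Poisson model per resource category, using the
#' published per-model predictor lists by default.
#'
#' @param cohort a `bzd_cohort`.
#' @param covariates named list (category -> character vector) overriding
#'   the default predictor sets.
#' @param robust passed to [fit_poisson_irr()].
#' @return named list of four `irr_table` data.frames.
#' @export
irr_table <- function(cohort, covariates = DEFAULT_IRR_COVARIATES,
                      robust = FALSE) {
  out <- lapply(UTILIZATION_CATEGORIES, function(cat) {
    fit_poisson_irr(cohort, cat, covariates[[cat]], robust = robust)
  })
  names(out) <- UTILIZATION_CATEGORIES
  out
}
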