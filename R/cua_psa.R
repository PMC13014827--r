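#' Arm-level moments for cost-utility analysis
#'
#' Mean and standard error of per-person total cost and of the per-person
#' QALY measure for one arm. The PSA parameterizes its gamma/beta draws with
#' these standard errors of the MEAN (parameter uncertainty, second-order
#' PSA), not the person-level SDs.
#'
#' @param cost_mean,cost_se euros; `cost_se` must be > 0 for PSA use.
#' @param qaly_mean,qaly_se QALYs over the half-year horizon.
#' @param n number of participants the moments were estimated from.
#' @return object of class `arm_moments`.
#' @export
arm_moments <- function(cost_mean, cost_se, qaly_mean, qaly_se, n = NA_integer_) {
  for (v in c(cost_mean, cost_se, qaly_mean, qaly_se)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("arm moments must be single non-missing numbers", call. = FALSE)
    }
  }
  structure(list(cost_mean = cost_mean, cost_se = cost_se,
                 qaly_mean = qaly_mean, qaly_se = qaly_se, n = n),
            class = "arm_moments")
}

#' Estimate arm moments from a cohort
#'
#' @param cohort a `bzd_cohort` carrying `total_cost` and the chosen QALY
#'   column (see [add_costs()], [add_utilities()]).
#' @param group `"continuation"` or `"discontinuation"`.
#' @param effect QALY column to use; the gain measure by default, since only
#'   it reproduces published group values of order 0.03-0.06 given baseline
#'   utility around 0.59.
#' @return an `arm_moments`.
#' @export
arm_moments_from_cohort <- function(cohort, group,
                                    effect = c("qaly_gain",
                                               "qaly_absolute")) {
  effect <- match.arg(effect)
  for (col in c("total_cost", effect)) {
    if (!col %in% names(cohort)) {
      stop(sprintf("cohort lacks column '%s'", col), call. = FALSE)
    }
  }
  sub <- cohort[cohort$group == group & !is.na(cohort[[effect]]), ]
  if (nrow(sub) < 2L) {
    stop(sprintf("group '%s' has fewer than 2 complete cases", group),
         call. = FALSE)
  }
  n <- nrow(sub)
  arm_moments(mean(sub$total_cost), sd(sub$total_cost) / sqrt(n),
              mean(sub[[effect]]), sd(sub[[effect]]) / sqrt(n), n)
}

#' Deterministic incremental cost-utility result
#'
#' Differences are oriented discontinuation minus continuation. The ICER is
#' the ratio of incremental cost to incremental QALYs, undefined (flagged)
#' when the QALY difference is zero. Dominance: `dominant` = cheaper and
#' more effective, `dominated` = costlier and less effective, `tradeoff_ne`
#' = costlier and more effective (northeast), `tradeoff_sw` = cheaper and
#' less effective (southwest). Boundary (exactly zero) differences are
#' assigned to the more-effective / less-costly side by convention.
#'
#' @param arm_cont,arm_disc `arm_moments` for continuation/discontinuation.
#' @return object of class `icer_result`: `delta_cost`, `delta_qaly`,
#'   `icer`, `icer_defined`, `dominance`.
#' @export
#' @examples
#' cont <- arm_moments(826.60, 45.79, 0.0275, 0.0087, 223)
#' disc <- arm_moments(753.20, 58.43, 0.0611, 0.0092, 107)
#' compute_icer(cont, disc) # dominant, ICER about -2185 euros per QALY
compute_icer <- function(arm_cont, arm_disc) {
  stopifnot(inherits(arm_cont, "arm_moments"),
            inherits(arm_disc, "arm_moments"))
  dc <- arm_disc$cost_mean - arm_cont$cost_mean
  dq <- arm_disc$qaly_mean - arm_cont$qaly_mean
  defined <- dq != 0
  icer <- if (defined) dc / dq else NA_real_
  effective <- dq >= 0  # boundary assigned to the effective side
  cheaper <- dc <= 0    # boundary assigned to the cheaper side
  dominance <- if (cheaper && effective) "dominant"
  else if (!cheaper && !effective) "dominated"
  else if (!cheaper && effective) "tradeoff_ne"
  else "tradeoff_sw"
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 icer_defined = defined, dominance = dominance),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result> (discontinuation - continuation)\n")
  cat(sprintf("  incremental cost: %.2f EUR\n", x$delta_cost))
  cat(sprintf("  incremental QALY: %+.4f\n", x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("  ICER: %.2f EUR/QALY\n", x$icer))
  } else {
    cat("  ICER: undefined (zero QALY difference)\n")
  }
  cat(sprintf("  dominance: %s\n", x$dominance))
  invisible(x)
}

#' Gamma parameters from mean and SE (method of moments)
#'
#' `shape = mu^2 / sigma^2`, `scale = sigma^2 / mu`; the implied
#' distribution has mean `mu` and SD `sigma` exactly.
#'
#' @param mu positive mean (euros).
#' @param sigma positive SE (euros).
#' @return list with `shape` and `scale`.
#' @export
gamma_from_moments <- function(mu, sigma) {
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  list(shape = mu^2 / sigma^2, scale = sigma^2 / mu)
}

#' Beta parameters from mean and SE (method of moments)
#'
#' `nu = mu(1-mu)/sigma^2 - 1`, `a = mu nu`, `b = (1-mu) nu`; requires the
#' feasibility bound `sigma^2 < mu(1-mu)`.
#'
#' @param mu mean in (0, 1).
#' @param sigma positive SE with `sigma^2 < mu * (1 - mu)`.
#' @return list with `a` and `b`.
#' @export
beta_from_moments <- function(mu, sigma) {
  if (!is.numeric(mu) || mu <= 0 || mu >= 1) {
    stop("`mu` must lie strictly in (0, 1); negative or boundary QALY means",
         " cannot be beta-modeled", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  if (sigma^2 >= mu * (1 - mu)) {
    stop(sprintf(
      "infeasible variance: sigma^2 = %.6g must be < mu(1-mu) = %.6g",
      sigma^2, mu * (1 - mu)), call. = FALSE)
  }
  nu <- mu * (1 - mu) / sigma^2 - 1
  list(a = mu * nu, b = (1 - mu) * nu)
}

classify_quadrant <- function(delta_qaly, delta_cost) {
  eff <- delta_qaly >= 0
  cheap <- delta_cost <= 0
  ifelse(eff & cheap, "se",
         ifelse(eff & !cheap, "ne",
                ifelse(!eff & cheap, "sw", "nw")))
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte-Carlo: per iteration, each arm's mean cost is drawn
#' from a gamma distribution and each arm's mean QALY from a beta
#' distribution, both moment-matched to the arm's (mean, SE). Arms and
#' outcomes are sampled independently (no correlation structure is
#' available). Draw pairs are oriented discontinuation minus continuation
#' and classified on the cost-effectiveness plane (x = incremental QALY,
#' y = incremental cost; southeast = more effective, cheaper). Zero
#' differences - probability-zero events for these continuous draws - go to
#' the more-effective / less-costly side.
#'
#' @param arm_cont,arm_disc `arm_moments`.
#' @param n_iter number of Monte-Carlo iterations.
#' @param seed integer seed; the draw order (continuation cost,
#'   discontinuation cost, continuation QALY, discontinuation QALY) is fixed.
#' @return object of class `psa_result`: `draws` (data.frame with
#'   `delta_qaly`, `delta_cost`, `quadrant`, `icer`),
#'   `quadrant_proportions` (named, sums to 1 exactly), `icer_summary`,
#'   `n_iter`, `seed`.
#' @export
run_psa <- function(arm_cont, arm_disc, n_iter = 1000L, seed = 1L) {
  stopifnot(inherits(arm_cont, "arm_moments"),
            inherits(arm_disc, "arm_moments"))
  if (!is.numeric(n_iter) || n_iter < 1) {
    stop("`n_iter` must be >= 1", call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  # fail on infeasible moments before any sampling
  g_c <- gamma_from_moments(arm_cont$cost_mean, arm_cont$cost_se)
  g_d <- gamma_from_moments(arm_disc$cost_mean, arm_disc$cost_se)
  b_c <- beta_from_moments(arm_cont$qaly_mean, arm_cont$qaly_se)
  b_d <- beta_from_moments(arm_disc$qaly_mean, arm_disc$qaly_se)

  draws <- with_seed(seed, {
    cost_c <- rgamma(n_iter, shape = g_c$shape, scale = g_c$scale)
    cost_d <- rgamma(n_iter, shape = g_d$shape, scale = g_d$scale)
    q_c <- rbeta(n_iter, b_c$a, b_c$b)
    q_d <- rbeta(n_iter, b_d$a, b_d$b)
    data.frame(delta_qaly = q_d - q_c, delta_cost = cost_d - cost_c)
  })
  draws$quadrant <- classify_quadrant(draws$delta_qaly, draws$delta_cost)
  draws$icer <- ifelse(draws$delta_qaly == 0, NA_real_,
                       draws$delta_cost / draws$delta_qaly)

  quad <- vapply(c("se", "ne", "sw", "nw"),
                 function(q) sum(draws$quadrant == q), numeric(1)) / n_iter
  ic <- draws$icer[is.finite(draws$icer)]
  structure(list(
    draws = draws,
    quadrant_proportions = quad,
    icer_summary = c(mean = mean(ic), median = median(ic), sd = sd(ic),
                     q2.5 = unname(quantile(ic, 0.025)),
                     q97.5 = unname(quantile(ic, 0.975))),
    n_iter = n_iter, seed = as.integer(seed)
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n_iter, x$seed))
  cat("  quadrant proportions (x = dQALY, y = dCost):\n")
  print(round(x$quadrant_proportions, 3))
  cat(sprintf("  mean dCost %.2f EUR, mean dQALY %+.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  cat(sprintf("  ICER distribution median %.1f EUR/QALY\n",
              x$icer_summary[["median"]]))
  invisible(x)
}

#' ICER distribution as histogram bins
#'
#' Binned counts of the per-draw ICERs (the tabular equivalent of the
#' histogram-with-density figure). Extreme ratios arising from near-zero
#' QALY differences are truncated to the given quantile range first.
#'
#' @param psa a `psa_result`.
#' @param bins number of bins.
#' @param trim two quantiles delimiting the plotted range.
#' @return data.frame with `bin_low`, `bin_high`, `count`, `density`.
#' @export
icer_histogram <- function(psa, bins = 30L, trim = c(0.01, 0.99)) {
  stopifnot(inherits(psa, "psa_result"))
  ic <- psa$draws$icer[is.finite(psa$draws$icer)]
  lim <- quantile(ic, trim)
  ic <- ic[ic >= lim[1] & ic <= lim[2]]
  br <- seq(lim[1], lim[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(ic, br, rightmost.closed = TRUE), bins)
  width <- diff(br)
  data.frame(bin_low = br[-length(br)], bin_high = br[-1], count = cnt,
             density = cnt / (sum(cnt) * width))
}

#' Subgroup probabilistic sensitivity analysis
#'
#' Estimates arm moments within each level of a stratification variable and
#' runs [run_psa()] per stratum. Strata in which either group has fewer
#' than two complete cases, or whose moments are infeasible for the
#' gamma/beta models (e.g. a negative mean QALY gain), are reported as
#' skipped entries rather than aborting the analysis.
#'
#' @param cohort a `bzd_cohort` with cost and utility columns.
#' @param strata name of a factor column (`"cci_band"` or `"sex"` in the
#'   default cohort).
#' @param n_iter,seed passed to [run_psa()]; each stratum uses a sub-seed
#'   derived from `seed` and the stratum label.
#' @param effect QALY column, as in [arm_moments_from_cohort()].
#' @return named list (one element per stratum level): either a
#'   `psa_result` or a list with `skipped = TRUE` and a `reason`.
#' @export
subgroup_psa <- function(cohort, strata, n_iter = 1000L, seed = 1L,
                         effect = "qaly_gain") {
  if (!strata %in% names(cohort)) {
    stop(sprintf("stratification column '%s' not in cohort", strata),
         call. = FALSE)
  }
  x <- cohort[[strata]]
  lv <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  out <- lapply(lv, function(l) {
    sub <- cohort[!is.na(cohort[[strata]]) & cohort[[strata]] == l, ]
    res <- tryCatch({
      cont <- arm_moments_from_cohort(sub, "continuation", effect)
      disc <- arm_moments_from_cohort(sub, "discontinuation", effect)
      run_psa(cont, disc, n_iter = n_iter,
              seed = derive_seed(seed, paste0("stratum_", l)))
    }, error = function(e) {
      warning(sprintf("stratum '%s' skipped: %s", l, conditionMessage(e)),
              call. = FALSE)
      list(skipped = TRUE, reason = conditionMessage(e))
    })
    res
  })
  names(out) <- lv
  out
}
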