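#' Cohort simulation configuration
#'
#' Builds and validates the configuration of the synthetic deprescribing
#' cohort generator. The default values (see [default_cohort_config()])
#' reproduce the published marginal structure of a 6-month primary-care
#' benzodiazepine deprescribing cohort: two groups (continuation /
#' discontinuation), four Poisson-distributed utilization counts with
#' group-specific means, independent categorical covariates, and COOP/WONCA
#' functional-health scores at baseline and 6 months whose group mean
#' utility changes hit configured targets.
#'
#' @param n_total total number of participants (>= 2).
#' @param p_discontinue probability that a participant is in the
#'   discontinuation group (Bernoulli assignment, independent of covariates
#'   unless `assignment` is given).
#' @param group_mean_counts list with elements `continuation` and
#'   `discontinuation`, each a named numeric vector of nonnegative 6-month
#'   visit rates for the categories `primary_care`, `specialist`,
#'   `pc_emergency`, `hospital_emergency`.
#' @param covariate_marginals list of named probability vectors for `sex`
#'   (women/men), `income_band`, `cci_band`, `minor_mental_disorder`
#'   (no/yes) and `indication`; each must sum to 1 within 1e-9.
#' @param age_mean_sd numeric length-2, mean and SD of age in years
#'   (normal, clipped to [18, 105]).
#' @param bzd_duration_mean_sd numeric length-2, mean and SD of prior
#'   benzodiazepine use in years (gamma, moment matched, floored at 0.1).
#' @param wonca_baseline_mean_sd numeric length-2, mean and SD of the
#'   baseline COOP/WONCA total score on the 7-35 scale (normal, rounded,
#'   clipped).
#' @param utility_change_mean_sd_by_group list with `continuation` and
#'   `discontinuation` elements, each numeric length-2: mean and SD of the
#'   6-month utility change on the 0-1 utility scale. The mean is a
#'   post-truncation target: the generator solves for the latent location so
#'   that the realized group mean change equals it despite score clipping.
#' @param seed integer root seed; all randomness derives from it.
#' @param frailty_sdlog optional lognormal (mean-1) common frailty SD on the
#'   log scale shared by all four counts of a participant; 0 disables it.
#'   Positive values induce cross-category correlation and overdispersion.
#' @param assignment optional list of logistic coefficients
#'   (`intercept`, `age_per10`, `men`) making group assignment depend on
#'   covariates for confounding experiments; `NULL` keeps Bernoulli
#'   assignment.
#' @return object of class `cohort_config`.
#' @seealso [generate_cohort()], [calibration_report()]
#' @export
cohort_config <- function(n_total,
                          p_discontinue,
                          group_mean_counts,
                          covariate_marginals,
                          age_mean_sd,
                          bzd_duration_mean_sd,
                          wonca_baseline_mean_sd,
                          utility_change_mean_sd_by_group,
                          seed = 1L,
                          frailty_sdlog = 0,
                          assignment = NULL) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 2) {
    stop_field("n_total", "must be a single number >= 2")
  }
  n_total <- as.integer(n_total)
  if (!is_prob(p_discontinue) || length(p_discontinue) != 1L) {
    stop_field("p_discontinue", "must be a probability in [0, 1]")
  }
  for (g in GROUP_LEVELS) {
    r <- group_mean_counts[[g]]
    if (is.null(r) || !is.numeric(r) ||
        !all(UTILIZATION_CATEGORIES %in% names(r))) {
      stop_field("group_mean_counts",
                 sprintf("element '%s' must name all of: %s", g,
                         paste(UTILIZATION_CATEGORIES, collapse = ", ")))
    }
    if (any(r < 0)) stop_field("group_mean_counts", "rates must be >= 0")
  }
  needed <- c("sex", "income_band", "cci_band",
              "minor_mental_disorder", "indication")
  for (m in needed) {
    p <- covariate_marginals[[m]]
    if (is.null(p) || !is_prob(p) || is.null(names(p))) {
      stop_field("covariate_marginals",
                 sprintf("'%s' must be a named probability vector", m))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop_field("covariate_marginals",
                 sprintf("'%s' proportions sum to %.12f, not 1", m, sum(p)))
    }
  }
  chk2 <- function(x, nm, pos_sd = TRUE) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x)) {
      stop_field(nm, "must be numeric c(mean, sd)")
    }
    if (pos_sd && x[2] < 0) stop_field(nm, "sd must be >= 0")
  }
  chk2(age_mean_sd, "age_mean_sd")
  chk2(bzd_duration_mean_sd, "bzd_duration_mean_sd")
  chk2(wonca_baseline_mean_sd, "wonca_baseline_mean_sd")
  if (wonca_baseline_mean_sd[1] < 7 || wonca_baseline_mean_sd[1] > 35) {
    stop_field("wonca_baseline_mean_sd", "mean must lie in [7, 35]")
  }
  for (g in GROUP_LEVELS) {
    chk2(utility_change_mean_sd_by_group[[g]],
         sprintf("utility_change_mean_sd_by_group$%s", g))
  }
  if (!is.numeric(frailty_sdlog) || frailty_sdlog < 0) {
    stop_field("frailty_sdlog", "must be >= 0")
  }
  structure(list(
    n_total = n_total,
    p_discontinue = p_discontinue,
    group_mean_counts = lapply(group_mean_counts[GROUP_LEVELS],
                               function(r) r[UTILIZATION_CATEGORIES]),
    covariate_marginals = covariate_marginals[needed],
    age_mean_sd = age_mean_sd,
    bzd_duration_mean_sd = bzd_duration_mean_sd,
    wonca_baseline_mean_sd = wonca_baseline_mean_sd,
    utility_change_mean_sd_by_group =
      utility_change_mean_sd_by_group[GROUP_LEVELS],
    seed = as.integer(seed),
    frailty_sdlog = as.numeric(frailty_sdlog),
    assignment = assignment
  ), class = "cohort_config")
}

#' Default (study-calibrated) cohort configuration
#'
#' Returns a [cohort_config()] whose parameters reproduce the published
#' cohort structure: 330 complete-case participants split 223/107
#' (continuation/discontinuation), group mean 6-month visit counts of
#' 9.03/8.20 (primary care), 1.67/1.63 (hospital specialist), 0.58/0.31
#' (primary-care emergency) and 0.32/0.34 (hospital emergency), covariate
#' marginals taken from the baseline-characteristics table as exact count
#' fractions, baseline utility 0.59 (COOP/WONCA score 18.48), and 6-month
#' utility-change targets 0.11/0.2444 whose QALY-gain equivalents are
#' 0.0275 and 0.0611. Person-level change SDs are back-calculated from the
#' reported standard errors of the group QALY-gain means
#' (SD = 4 x SE x sqrt(n)).
#'
#' @param seed integer root seed.
#' @param n_total cohort size; the study's complete-case size by default.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, n_total = 330L) {
  cohort_config(
    n_total = n_total,
    p_discontinue = 107 / 330,
    group_mean_counts = list(
      continuation = c(primary_care = 9.03, specialist = 1.67,
                       pc_emergency = 0.58, hospital_emergency = 0.32),
      discontinuation = c(primary_care = 8.20, specialist = 1.63,
                          pc_emergency = 0.31, hospital_emergency = 0.34)
    ),
    covariate_marginals = list(
      sex = c(women = 233 / 333, men = 100 / 333),
      income_band = c("<=18000" = 235 / 333, ">18000" = 98 / 333),
      cci_band = c("0-2" = 137 / 330, "3-4" = 128 / 330, ">=5" = 65 / 330),
      minor_mental_disorder = c(no = 321 / 333, yes = 12 / 333),
      indication = c(anxiety = 79 / 311, insomnia = 189 / 311,
                     both = 29 / 311, other = 14 / 311)
    ),
    age_mean_sd = c(66.72, 0.68 * sqrt(333)),
    bzd_duration_mean_sd = c(4.04, 0.28 * sqrt(333)),
    wonca_baseline_mean_sd = c(35 - 28 * 0.59, 28 * 0.01 * sqrt(333)),
    utility_change_mean_sd_by_group = list(
      continuation = c(4 * 0.0275, 4 * 0.0087 * sqrt(223)),
      discontinuation = c(4 * 0.0611, 4 * 0.0092 * sqrt(107))
    ),
    seed = seed
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  n_total: %d   p_discontinue: %.4f   seed: %d\n",
              x$n_total, x$p_discontinue, x$seed))
  mc <- do.call(rbind, x$group_mean_counts)
  cat("  group mean counts (visits / 6 months):\n")
  print(round(mc, 3))
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_categorical <- function(n, p) {
  factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
}

# Latent utility-change location calibrated so the realized (post-clipping)
# mean change equals the configured target. Operates on this cohort's own
# baseline scores and standard-normal draws, hence deterministic given seed.
calibrate_change_location <- function(base_score, z, sd_change, target_mean) {
  stopifnot(length(base_score) == length(z))
  f <- function(delta) {
    s6 <- clip(base_score - 28 * (delta + sd_change * z), 7, 35)
    mean((base_score - s6) / 28) - target_mean
  }
  # realized mean change is monotone increasing in delta and saturates at the
  # score bounds; +/- 5 utility units comfortably brackets any feasible target
  if (f(-5) > 0 || f(5) < 0) {
    stop("utility change target not attainable within score bounds [7, 35]",
         call. = FALSE)
  }
  uniroot(f, c(-5, 5), tol = 1e-10)$root
}

#' Generate a synthetic deprescribing cohort
#'
#' Simulates one participant table from a [cohort_config()]. Group labels are
#' Bernoulli draws (optionally covariate-dependent), covariates are drawn
#' independently from the configured marginals, utilization counts are
#' independent Poisson draws with group-specific means (optionally sharing a
#' lognormal frailty), and the 6-month COOP/WONCA score equals the baseline
#' score minus 28 times a normal utility-scale change, clipped to [7, 35] and
#' rounded. The latent change location per group is calibrated so that the
#' realized mean utility change matches the configured target despite
#' clipping.
#'
#' @param config a `cohort_config`.
#' @return a `data.frame` of class `bzd_cohort`, one row per participant,
#'   with columns `id`, `group`, `age`, `sex`, `income_band`, `cci_band`,
#'   `minor_mental_disorder`, `bzd_duration`, `indication`, the four count
#'   columns, `wonca_baseline`, `wonca_6m`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config(seed = 1))
#' table(coh$group)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config", call. = FALSE)
  }
  n <- config$n_total
  cm <- config$covariate_marginals

  cov_df <- with_seed(derive_seed(config$seed, "covariates"), {
    data.frame(
      age = clip(rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2]),
                 18, 105),
      sex = draw_categorical(n, cm$sex),
      income_band = draw_categorical(n, cm$income_band),
      cci_band = draw_categorical(n, cm$cci_band),
      minor_mental_disorder =
        draw_categorical(n, cm$minor_mental_disorder) == "yes",
      bzd_duration = {
        m <- config$bzd_duration_mean_sd[1]
        s <- config$bzd_duration_mean_sd[2]
        if (s == 0) rep(m, n) else {
          pmax(rgamma(n, shape = m^2 / s^2, scale = s^2 / m), 0.1)
        }
      },
      indication = draw_categorical(n, cm$indication)
    )
  })

  group <- with_seed(derive_seed(config$seed, "assignment"), {
    if (is.null(config$assignment)) {
      rbinom(n, 1L, config$p_discontinue)
    } else {
      a <- config$assignment
      eta <- a$intercept +
        a$age_per10 * (cov_df$age - mean(cov_df$age)) / 10 +
        a$men * (cov_df$sex == "men")
      rbinom(n, 1L, 1 / (1 + exp(-eta)))
    }
  })
  group <- factor(ifelse(group == 1L, "discontinuation", "continuation"),
                  levels = GROUP_LEVELS)
  if (any(tabulate(group, 2L) == 0L)) {
    warning("a group is empty at this seed; downstream comparisons will fail")
  }

  counts <- with_seed(derive_seed(config$seed, "counts"), {
    frailty <- if (config$frailty_sdlog > 0) {
      rlnorm(n, meanlog = -config$frailty_sdlog^2 / 2,
             sdlog = config$frailty_sdlog)
    } else rep(1, n)
    out <- matrix(0L, n, length(UTILIZATION_CATEGORIES),
                  dimnames = list(NULL, UTILIZATION_CATEGORIES))
    for (cat in UTILIZATION_CATEGORIES) {
      lam <- ifelse(group == "continuation",
                    config$group_mean_counts$continuation[[cat]],
                    config$group_mean_counts$discontinuation[[cat]])
      out[, cat] <- rpois(n, lam * frailty)
    }
    out
  })

  wonca <- with_seed(derive_seed(config$seed, "wonca"), {
    wb <- config$wonca_baseline_mean_sd
    base <- round(clip(rnorm(n, wb[1], wb[2]), 7, 35))
    z <- rnorm(n)
    s6 <- numeric(n)
    for (g in GROUP_LEVELS) {
      idx <- which(group == g)
      if (!length(idx)) next
      pars <- config$utility_change_mean_sd_by_group[[g]]
      delta <- calibrate_change_location(base[idx], z[idx], pars[2], pars[1])
      s6[idx] <- clip(base[idx] - 28 * (delta + pars[2] * z[idx]), 7, 35)
    }
    data.frame(wonca_baseline = as.integer(base),
               wonca_6m = as.integer(round(s6)))
  })

  out <- cbind(
    data.frame(id = sprintf("P%05d", seq_len(n)), group = group),
    cov_df[c("age", "sex", "income_band", "cci_band",
             "minor_mental_disorder", "bzd_duration", "indication")],
    as.data.frame(counts),
    wonca
  )
  class(out) <- c("bzd_cohort", "data.frame")
  attr(out, "seed") <- config$seed
  out
}

#' Compare configured and realized cohort moments
#'
#' One row per calibrated quantity: group sizes, per-category mean counts per
#' group, mean baseline COOP/WONCA score, and mean utility change (with its
#' QALY-gain equivalent) per group, each with absolute and relative deviation
#' from the configured value.
#'
#' @param cohort a `bzd_cohort`.
#' @param config the `cohort_config` it was generated from.
#' @return data.frame with columns `quantity`, `group`, `configured`,
#'   `realized`, `abs_dev`, `rel_dev`.
#' @export
calibration_report <- function(cohort, config) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("`cohort` is empty; nothing to calibrate against", call. = FALSE)
  }
  sizes <- table(factor(cohort$group, levels = GROUP_LEVELS))
  if (any(sizes == 0L)) {
    stop(sprintf("group '%s' is empty; calibration undefined",
                 names(sizes)[sizes == 0L][1]), call. = FALSE)
  }
  rows <- list()
  add <- function(quantity, group, configured, realized) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, group = group,
      configured = configured, realized = realized,
      abs_dev = realized - configured,
      rel_dev = if (configured != 0) (realized - configured) / configured
                else NA_real_)
  }
  exp_n <- config$n_total * c(1 - config$p_discontinue, config$p_discontinue)
  for (i in 1:2) {
    add("group_size", GROUP_LEVELS[i], exp_n[i], as.numeric(sizes[i]))
  }
  for (g in GROUP_LEVELS) {
    sub <- cohort[cohort$group == g, ]
    for (cat in UTILIZATION_CATEGORIES) {
      add(paste0("mean_", cat), g, config$group_mean_counts[[g]][[cat]],
          mean(sub[[cat]]))
    }
  }
  add("mean_wonca_baseline", "all", config$wonca_baseline_mean_sd[1],
      mean(cohort$wonca_baseline))
  for (g in GROUP_LEVELS) {
    sub <- cohort[cohort$group == g, ]
    du <- (sub$wonca_baseline - sub$wonca_6m) / 28
    add("mean_utility_change", g,
        config$utility_change_mean_sd_by_group[[g]][1], mean(du))
    add("mean_qaly_gain", g,
        config$utility_change_mean_sd_by_group[[g]][1] / 4, mean(du) / 4)
  }
  do.call(rbind, rows)
}

#' Write / read a cohort CSV
#'
#' Fixed, documented column order; `group` stored as the literal strings
#' `"continuation"` / `"discontinuation"`.
#'
#' @param cohort a `bzd_cohort` data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `bzd_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("id", "group", "age", "sex", "income_band", "cci_band",
            "minor_mental_disorder", "bzd_duration", "indication",
            UTILIZATION_CATEGORIES, "wonca_baseline", "wonca_6m")
  extra <- setdiff(names(cohort), cols)
  write.csv(cohort[c(cols, extra)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df$sex <- factor(df$sex, levels = SEX_LEVELS)
  df$income_band <- factor(df$income_band, levels = INCOME_LEVELS)
  df$cci_band <- factor(df$cci_band, levels = CCI_LEVELS)
  df$indication <- factor(df$indication, levels = INDICATION_LEVELS)
  class(df) <- c("bzd_cohort", "data.frame")
  df
}

#' Read / write a cohort configuration as JSON
#'
#' @param path JSON file path.
#' @param config a `cohort_config`.
#' @return `read_cohort_config` returns a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (g in GROUP_LEVELS) {
    x$group_mean_counts[[g]] <- unlist(x$group_mean_counts[[g]])
    x$utility_change_mean_sd_by_group[[g]] <-
      unlist(x$utility_change_mean_sd_by_group[[g]])
  }
  x$covariate_marginals <- lapply(x$covariate_marginals, unlist)
  if (!length(x$assignment)) x$assignment <- NULL
  do.call(cohort_config, x)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors must serialize as JSON objects, not bare arrays
  x$group_mean_counts <- lapply(x$group_mean_counts, as.list)
  x$covariate_marginals <- lapply(x$covariate_marginals, as.list)
  # I(17) significant digits: exact double round-trip
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
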