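# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# U statistic by direct pairwise comparison (not via ranks).
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# values, with U computed by pairwise counting.
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  us <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  u_obs <- oracle_u(a, b)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Poisson log-link ML via iteratively reweighted least squares from first
# principles (no glm).
oracle_irls_poisson <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 1e-8)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  vcov <- solve(crossprod(X, X * exp(drop(X %*% beta))))
  list(coef = beta, vcov = vcov)
}

# Hand-built 4-participant cohort with known counts and scores.
tiny_cohort <- function() {
  df <- data.frame(
    id = sprintf("T%02d", 1:4),
    group = factor(c("continuation", "continuation",
                     "discontinuation", "discontinuation"),
                   levels = c("continuation", "discontinuation")),
    age = c(60, 70, 65, 75),
    sex = factor(c("women", "men", "women", "men"),
                 levels = c("women", "men")),
    income_band = factor(c("<=18000", ">18000", "<=18000", ">18000"),
                         levels = c("<=18000", ">18000")),
    cci_band = factor(c("0-2", "3-4", "0-2", "3-4"),
                      levels = c("0-2", "3-4", ">=5")),
    minor_mental_disorder = c(FALSE, TRUE, FALSE, FALSE),
    bzd_duration = c(2, 4, 3, 5),
    indication = factor(c("anxiety", "insomnia", "both", "other"),
                        levels = c("anxiety", "insomnia", "both", "other")),
    primary_care = c(10L, 8L, 6L, 4L),
    specialist = c(2L, 0L, 1L, 3L),
    pc_emergency = c(1L, 0L, 0L, 0L),
    hospital_emergency = c(0L, 1L, 0L, 1L),
    wonca_baseline = c(20L, 18L, 22L, 16L),
    wonca_6m = c(19L, 18L, 15L, 14L)
  )
  class(df) <- c("bzd_cohort", "data.frame")
  df
}

# Cohort whose group means exactly match the published use/person table:
# one accumulator participant per category carries the whole group total.
table2_cohort <- function(n_per_group = 100L) {
  means <- list(continuation = c(9.03, 1.67, 0.58, 0.32),
                discontinuation = c(8.20, 1.63, 0.31, 0.34))
  rows <- lapply(names(means), function(g) {
    m <- matrix(0L, n_per_group, 4)
    for (j in 1:4) m[j, j] <- as.integer(round(means[[g]][j] * n_per_group))
    df <- as.data.frame(m)
    names(df) <- c("primary_care", "specialist", "pc_emergency",
                   "hospital_emergency")
    df$group <- g
    df
  })
  df <- do.call(rbind, rows)
  df$group <- factor(df$group,
                     levels = c("continuation", "discontinuation"))
  df$id <- sprintf("A%03d", seq_len(nrow(df)))
  df$wonca_baseline <- 20L
  df$wonca_6m <- 18L
  class(df) <- c("bzd_cohort", "data.frame")
  df
}

default_tariff <- function() {
  unit_cost_table(c(primary_care = 64.07, specialist = 81.38,
                    pc_emergency = 73.30, hospital_emergency = 215.06),
                  2024)
}

# Published arm-level moments (costs in 2024 euros, QALY gains).
published_arms <- function() {
  list(cont = arm_moments(826.60, 45.79, 0.0275, 0.0087, 223),
       disc = arm_moments(753.20, 58.43, 0.0611, 0.0092, 107))
}
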