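test_that("deterministic CUA reproduces the published arm comparison", {
  arms <- published_arms()
  res <- compute_icer(arms$cont, arms$disc)
  expect_equal(res$delta_cost, -73.40)
  expect_equal(res$delta_qaly, 0.0336)
  expect_equal(res$dominance, "dominant")
  expect_true(res$icer_defined)
  expect_equal(res$icer, -73.40 / 0.0336)
  expect_equal(round_half_up(res$icer), -2185)
})

test_that("ICER is flagged undefined on zero QALY difference", {
  a <- arm_moments(100, 10, 0.05, 0.01, 50)
  res <- compute_icer(a, a)
  expect_false(res$icer_defined)
  expect_true(is.na(res$icer))
  cheaper <- arm_moments(90, 10, 0.05, 0.01, 50)
  expect_equal(compute_icer(a, cheaper)$dominance, "dominant")
})

test_that("compute_icer is antisymmetric under swapping arms", {
  arms <- published_arms()
  fwd <- compute_icer(arms$cont, arms$disc)
  rev <- compute_icer(arms$disc, arms$cont)
  expect_equal(rev$delta_cost, -fwd$delta_cost)
  expect_equal(rev$delta_qaly, -fwd$delta_qaly)
  expect_equal(fwd$dominance, "dominant")
  expect_equal(rev$dominance, "dominated")
})

test_that("gamma moment matching round-trips analytically", {
  expect_equal(gamma_from_moments(1, 1), list(shape = 1, scale = 1))
  g <- gamma_from_moments(826.60, 45.79)
  expect_equal(g$shape, 826.60^2 / 45.79^2) # about 325.9
  expect_equal(g$shape * g$scale, 826.60)
  expect_equal(sqrt(g$shape) * g$scale, 45.79)
  expect_error(gamma_from_moments(-1, 1), "mu")
  expect_error(gamma_from_moments(1, 0), "sigma")
})

test_that("beta moment matching round-trips and enforces feasibility", {
  b <- beta_from_moments(0.5, sqrt(0.125))
  expect_equal(b$a, 0.5)
  expect_equal(b$b, 0.5)
  b2 <- beta_from_moments(0.0611, 0.0092)
  expect_equal(b2$a / (b2$a + b2$b), 0.0611) # implied mean
  implied_var <- with(b2, a * b / ((a + b)^2 * (a + b + 1)))
  expect_equal(sqrt(implied_var), 0.0092)
  expect_equal(b2$a, 41.35, tolerance = 0.005)
  expect_equal(b2$b, 635.4, tolerance = 0.005)
  expect_error(beta_from_moments(0.5, 0.5), "mu\\(1-mu\\)")
  expect_error(beta_from_moments(-0.02, 0.01), "\\(0, 1\\)")
  expect_error(beta_from_moments(1, 0.01), "\\(0, 1\\)")
})

test_that("moment-matched sampling recovers inputs (Monte-Carlo oracle)", {
  n <- 2e5
  g <- gamma_from_moments(753.20, 58.43)
  set.seed(101)
  x <- rgamma(n, shape = g$shape, scale = g$scale)
  expect_lt(abs(mean(x) - 753.20) / 753.20, 0.005)
  b <- beta_from_moments(0.0275, 0.0087)
  y <- rbeta(n, b$a, b$b)
  expect_lt(abs(sd(y) - 0.0087) / 0.0087, 0.01)
})

test_that("run_psa is reproducible, exhaustive and consistent", {
  arms <- published_arms()
  p1 <- run_psa(arms$cont, arms$disc, n_iter = 2000, seed = 9)
  p2 <- run_psa(arms$cont, arms$disc, n_iter = 2000, seed = 9)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 2000L)
  expect_equal(sum(p1$quadrant_proportions), 1) # exact accounting
  expect_setequal(unique(p1$draws$quadrant),
                  names(which(p1$quadrant_proportions > 0)))
  # consistency: draw means near arm-moment differences within 3 MC SEs
  se_cost <- sqrt(45.79^2 + 58.43^2) / sqrt(2000)
  expect_lt(abs(mean(p1$draws$delta_cost) - (753.20 - 826.60)), 3 * se_cost)
  se_q <- sqrt(0.0087^2 + 0.0092^2) / sqrt(2000)
  expect_lt(abs(mean(p1$draws$delta_qaly) - 0.0336), 3 * se_q)
})

test_that("published moments put most simulations southeast", {
  arms <- published_arms()
  psa <- run_psa(arms$cont, arms$disc, n_iter = 1000, seed = 1)
  expect_gt(psa$quadrant_proportions[["se"]], 0.5)
  # expected share is about 0.83; sanity-check the neighborhood
  expect_lt(abs(psa$quadrant_proportions[["se"]] - 0.83), 0.08)
})

test_that("identical arms spread draws evenly over the quadrants", {
  a <- arm_moments(500, 40, 0.05, 0.01, 100)
  psa <- run_psa(a, a, n_iter = 4000, seed = 17)
  expect_true(all(abs(psa$quadrant_proportions - 0.25) < 0.03))
})

test_that("infeasible moments fail before sampling", {
  good <- arm_moments(500, 40, 0.05, 0.01, 100)
  neg_qaly <- arm_moments(500, 40, -0.02, 0.01, 100)
  expect_error(run_psa(good, neg_qaly), "\\(0, 1\\)")
  wide <- arm_moments(500, 40, 0.5, 0.6, 100)
  expect_error(run_psa(good, wide), "infeasible")
})

test_that("icer_histogram bins the draw distribution", {
  arms <- published_arms()
  psa <- run_psa(arms$cont, arms$disc, n_iter = 1000, seed = 3)
  h <- icer_histogram(psa, bins = 20)
  expect_equal(nrow(h), 20L)
  expect_true(all(h$bin_low < h$bin_high))
  expect_gt(sum(h$count), 900) # only extreme tails trimmed
})

test_that("subgroup PSA analyzes strata and skips degenerate ones", {
  cfg <- default_cohort_config(seed = 51, n_total = 4000)
  coh <- add_utilities(add_costs(generate_cohort(cfg), default_tariff()))
  by_sex <- subgroup_psa(coh, "sex", n_iter = 500, seed = 4)
  expect_named(by_sex, c("women", "men"))
  for (s in by_sex) {
    expect_s3_class(s, "psa_result")
    expect_gt(s$quadrant_proportions[["se"]], 0.5)
  }
  # drop one group within the men stratum -> skip record, not an error
  broken <- coh[!(coh$sex == "men" & coh$group == "discontinuation"), ]
  expect_warning(by_sex_b <- subgroup_psa(broken, "sex", n_iter = 200,
                                          seed = 4),
                 "skipped")
  expect_true(isTRUE(by_sex_b$men$skipped))
  expect_s3_class(by_sex_b$women, "psa_result")
  # a declared but empty CCI band yields a skip entry as well
  no_severe <- coh[coh$cci_band != ">=5", ]
  expect_warning(by_cci <- subgroup_psa(no_severe, "cci_band",
                                        n_iter = 200, seed = 4),
                 "skipped")
  expect_equal(length(by_cci), 3L)
  expect_true(isTRUE(by_cci[[">=5"]]$skipped))
})
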