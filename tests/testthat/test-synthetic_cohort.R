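test_that("config validation names the offending field", {
  base <- default_cohort_config()
  expect_error(cohort_config(n_total = 1, p_discontinue = 0.3,
                             base$group_mean_counts,
                             base$covariate_marginals, c(60, 10), c(4, 5),
                             c(18, 5), base$utility_change_mean_sd_by_group),
               "n_total")
  expect_error(cohort_config(100, 1.2, base$group_mean_counts,
                             base$covariate_marginals, c(60, 10), c(4, 5),
                             c(18, 5), base$utility_change_mean_sd_by_group),
               "p_discontinue")
  bad_rates <- base$group_mean_counts
  bad_rates$continuation["primary_care"] <- -1
  expect_error(cohort_config(100, 0.3, bad_rates, base$covariate_marginals,
                             c(60, 10), c(4, 5), c(18, 5),
                             base$utility_change_mean_sd_by_group),
               "group_mean_counts")
  bad_marg <- base$covariate_marginals
  bad_marg$sex <- c(women = 0.6, men = 0.3) # sums to 0.9
  expect_error(cohort_config(100, 0.3, base$group_mean_counts, bad_marg,
                             c(60, 10), c(4, 5), c(18, 5),
                             base$utility_change_mean_sd_by_group),
               "sex.*sum", ignore.case = TRUE)
  expect_error(cohort_config(100, 0.3, base$group_mean_counts,
                             base$covariate_marginals, c(60, 10), c(4, 5),
                             c(40, 5), # WONCA mean outside scale
                             base$utility_change_mean_sd_by_group),
               "wonca_baseline_mean_sd")
})

test_that("generation is deterministic given config + seed", {
  cfg <- default_cohort_config(seed = 7, n_total = 500)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed changes the realization
  expect_false(identical(
    generate_cohort(default_cohort_config(seed = 8, n_total = 500)), c1))
})

test_that("group split is binomial around the configured proportion", {
  cfg <- default_cohort_config(seed = 1, n_total = 330)
  coh <- generate_cohort(cfg)
  n_disc <- sum(coh$group == "discontinuation")
  # 107 expected; 4 binomial SDs = 34
  expect_lt(abs(n_disc - 107), 34)
  expect_setequal(levels(coh$group), c("continuation", "discontinuation"))
})

test_that("zero rates produce all-zero counts", {
  cfg <- default_cohort_config(seed = 3, n_total = 100)
  zero <- lapply(cfg$group_mean_counts, function(r) r * 0)
  cfg2 <- cohort_config(100, 0.3, zero, cfg$covariate_marginals,
                        cfg$age_mean_sd, cfg$bzd_duration_mean_sd,
                        cfg$wonca_baseline_mean_sd,
                        cfg$utility_change_mean_sd_by_group, seed = 3)
  coh <- generate_cohort(cfg2)
  for (cat in c("primary_care", "specialist", "pc_emergency",
                "hospital_emergency")) {
    expect_true(all(coh[[cat]] == 0L))
  }
})

test_that("covariate marginals are recovered within 3 SE at n = 10000", {
  cfg <- default_cohort_config(seed = 11, n_total = 10000)
  coh <- generate_cohort(cfg)
  checks <- list(
    c("sex", "men"), c("income_band", ">18000"), c("cci_band", "3-4"),
    c("indication", "insomnia"))
  for (ch in checks) {
    p_conf <- cfg$covariate_marginals[[ch[1]]][[ch[2]]]
    p_real <- mean(coh[[ch[1]]] == ch[2])
    se <- sqrt(p_conf * (1 - p_conf) / nrow(coh))
    expect_lt(abs(p_real - p_conf), 3 * se,
              label = sprintf("%s=%s deviation", ch[1], ch[2]))
  }
  p_mmd <- cfg$covariate_marginals$minor_mental_disorder[["yes"]]
  expect_lt(abs(mean(coh$minor_mental_disorder) - p_mmd),
            3 * sqrt(p_mmd * (1 - p_mmd) / nrow(coh)))
})

test_that("counts are Poisson without frailty, overdispersed with it", {
  cfg <- default_cohort_config(seed = 5, n_total = 20000)
  coh <- generate_cohort(cfg)
  cont <- coh[coh$group == "continuation", ]
  ratio <- var(cont$primary_care) / mean(cont$primary_care)
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)

  cfg_fr <- default_cohort_config(seed = 5, n_total = 20000)
  cfg_fr$frailty_sdlog <- 0.5
  coh_fr <- generate_cohort(cfg_fr)
  cont_fr <- coh_fr[coh_fr$group == "continuation", ]
  # lognormal frailty with sdlog 0.5: var/mean = 1 + mu*(e^{s^2}-1) >> 1
  expect_gt(var(cont_fr$primary_care) / mean(cont_fr$primary_care), 1.5)
})

test_that("realized mean QALY gains match configured targets", {
  cfg <- default_cohort_config(seed = 13, n_total = 20000)
  coh <- generate_cohort(cfg)
  rep <- calibration_report(coh, cfg)
  gains <- rep[rep$quantity == "mean_qaly_gain", ]
  expect_equal(nrow(gains), 2L)
  expect_lt(max(abs(gains$rel_dev)), 0.05)
  # scores stay on the instrument scale
  expect_true(all(coh$wonca_6m >= 7 & coh$wonca_6m <= 35))
  expect_true(all(coh$wonca_baseline >= 7 & coh$wonca_baseline <= 35))
})

test_that("calibration_report has the documented shape and fails loudly", {
  cfg <- default_cohort_config(seed = 1, n_total = 330)
  coh <- generate_cohort(cfg)
  rep <- calibration_report(coh, cfg)
  count_rows <- rep$quantity %in% sprintf("mean_%s",
    c("primary_care", "specialist", "pc_emergency", "hospital_emergency"))
  expect_equal(sum(count_rows), 8L) # 2 groups x 4 categories
  expect_named(rep, c("quantity", "group", "configured", "realized",
                      "abs_dev", "rel_dev"))
  expect_error(calibration_report(coh[0, ], cfg), "empty")
  one_group <- coh[coh$group == "continuation", ]
  expect_error(calibration_report(one_group, cfg), "empty")
})

test_that("covariate-dependent assignment induces confounding on request", {
  cfg <- default_cohort_config(seed = 9, n_total = 8000)
  cfg$assignment <- list(intercept = -0.7, age_per10 = 0.8, men = 0)
  coh <- generate_cohort(cfg)
  disc <- coh$group == "discontinuation"
  expect_gt(mean(coh$age[disc]), mean(coh$age[!disc]) + 1)
})

test_that("cohort CSV and config JSON round-trip", {
  cfg <- default_cohort_config(seed = 2, n_total = 120)
  coh <- generate_cohort(cfg)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back)[names(coh)], as.data.frame(coh),
               tolerance = 1e-12, ignore_attr = TRUE)
  cf <- tempfile(fileext = ".json")
  write_cohort_config(cfg, cf)
  expect_identical(generate_cohort(read_cohort_config(cf)), coh)
  # packaged default config reproduces the calibrated cohort
  pkg_cfg <- read_cohort_config(system.file(
    "extdata", "default_cohort_config.json", package = "bzdcua"))
  expect_identical(generate_cohort(pkg_cfg),
                   generate_cohort(default_cohort_config(seed = 1)))
})
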