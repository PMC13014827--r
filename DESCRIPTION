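Package: bzdcua
Title: Cost-Utility Analysis of Benzodiazepine Deprescribing Cohorts
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for short-horizon economic evaluation of benzodiazepine
    deprescribing programmes in primary care. Generates synthetic two-group
    (continuation vs discontinuation) cohorts calibrated to published
    marginals, monetizes healthcare utilization counts with tariff unit costs
    and CPI price-year updating, derives utilities and quality-adjusted life
    years (QALYs) from COOP/WONCA functional health scores, performs
    cost-consequence comparisons with Mann-Whitney rank tests, fits Poisson
    regressions of utilization counts reporting incidence rate ratios, and
    runs deterministic cost-utility analysis (incremental cost-effectiveness
    ratio, dominance) plus probabilistic sensitivity analysis via
    moment-matched gamma and beta Monte-Carlo draws with
    cost-effectiveness-plane quadrant summaries and subgroup stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
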