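#' Pipeline run configuration
#'
#' Exactly one cohort source must be given: an in-memory/synthetic
#' [cohort_config()] or a cohort CSV path.
#'
#' @param cohort_config a `cohort_config` for synthetic generation, or NULL.
#' @param cohort_file path to a cohort CSV, or NULL.
#' @param tariff_file tariff CSV; the packaged 2024 tariffs by default.
#' @param cpi_file CPI CSV (year, index); packaged synthetic series default.
#' @param analyses subset of `c("cohort", "cca", "regression", "cua",
#'   "psa")` to run.
#' @param out_dir output directory (created if needed).
#' @param seed root seed for every stochastic stage.
#' @param n_iter PSA iterations (>= 1).
#' @param psa_strata optional stratification variable for subgroup PSA
#'   quadrant tables (`"cci_band"` or `"sex"`), or NULL.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort_config = NULL, cohort_file = NULL,
                       tariff_file = NULL, cpi_file = NULL,
                       analyses = c("cohort", "cca", "regression",
                                    "cua", "psa"),
                       out_dir = tempfile("bzdcua_run_"),
                       seed = 1L, n_iter = 1000L, psa_strata = NULL) {
  if (is.null(cohort_config) == is.null(cohort_file)) {
    stop("specify exactly one cohort source: `cohort_config` or ",
         "`cohort_file`", call. = FALSE)
  }
  if (!is.null(cohort_file) && !file.exists(cohort_file)) {
    stop(sprintf("cohort file not readable: %s", cohort_file), call. = FALSE)
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!is.numeric(n_iter) || n_iter < 1) {
    stop("`n_iter` must be >= 1", call. = FALSE)
  }
  if (is.null(tariff_file)) {
    tariff_file <- system.file("extdata", "tariffs_2024.csv",
                               package = "bzdcua", mustWork = TRUE)
  }
  if (!file.exists(tariff_file)) {
    stop(sprintf("tariff file not readable: %s", tariff_file), call. = FALSE)
  }
  structure(list(cohort_config = cohort_config, cohort_file = cohort_file,
                 tariff_file = tariff_file, cpi_file = cpi_file,
                 analyses = analyses, out_dir = out_dir,
                 seed = as.integer(seed), n_iter = as.integer(n_iter),
                 psa_strata = psa_strata),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate/load -> cost -> utility/QALY -> cost-consequence tables ->
#' utilization regressions -> deterministic CUA -> PSA, writing one file per
#' artifact. Deterministic stages are byte-identical across reruns with the
#' same configuration; all randomness flows from the single configured seed.
#'
#' @param config a [run_config()].
#' @return named character vector: manifest of written files (invisible
#'   elements: `log` always present).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c()
  log_lines <- c(
    sprintf("bzdcua %s | R %s.%s", as.character(packageVersion("bzdcua")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", config$seed),
    sprintf("tariff: %s (md5 %s)", config$tariff_file,
            unname(md5sum(config$tariff_file))))

  if (!is.null(config$cohort_file)) {
    cohort <- read_cohort(config$cohort_file)
    log_lines <- c(log_lines, sprintf("cohort: %s (%d participants)",
                                      config$cohort_file, nrow(cohort)))
  } else {
    cc <- config$cohort_config
    cc$seed <- config$seed
    cohort <- generate_cohort(cc)
    log_lines <- c(log_lines,
                   sprintf("cohort: synthetic (%d participants, seed %d)",
                           nrow(cohort), config$seed))
  }

  tariff <- read_unit_costs(config$tariff_file, config$cpi_file)
  cohort <- add_costs(cohort, tariff)
  cohort <- add_utilities(cohort)
  n_complete <- sum(!is.na(cohort$qaly_gain))
  log_lines <- c(log_lines,
                 sprintf("complete cases for QALY analyses: %d of %d",
                         n_complete, nrow(cohort)))

  out <- function(f) file.path(config$out_dir, f)
  if ("cohort" %in% config$analyses) {
    write_cohort(cohort, out("cohort.csv"))
    manifest["cohort"] <- out("cohort.csv")
  }
  if ("cca" %in% config$analyses) {
    summ <- group_cost_summary(cohort, tariff)
    write.csv(as.data.frame(summ), out("table2.csv"), row.names = FALSE)
    manifest["table2"] <- out("table2.csv")
    write.csv(compare_groups(cohort, strata = "sex"), out("table3.csv"),
              row.names = FALSE)
    manifest["table3"] <- out("table3.csv")
  }
  if ("regression" %in% config$analyses) {
    irr <- do.call(rbind, irr_table(cohort))
    write.csv(irr, out("table4_irr.csv"), row.names = FALSE)
    manifest["table4_irr"] <- out("table4_irr.csv")
  }

  cont <- disc <- NULL
  if (any(c("cua", "psa") %in% config$analyses)) {
    cont <- arm_moments_from_cohort(cohort, "continuation")
    disc <- arm_moments_from_cohort(cohort, "discontinuation")
  }
  if ("cua" %in% config$analyses) {
    icer <- compute_icer(cont, disc)
    jsonlite::write_json(unclass(icer), out("icer.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest["icer"] <- out("icer.json")
  }
  if ("psa" %in% config$analyses) {
    psa <- run_psa(cont, disc, n_iter = config$n_iter,
                   seed = derive_seed(config$seed, "psa"))
    write.csv(psa$draws, out("psa_draws.csv"), row.names = FALSE)
    manifest["psa_draws"] <- out("psa_draws.csv")
    quad <- data.frame(stratum = "all",
                       quadrant = names(psa$quadrant_proportions),
                       proportion = unname(psa$quadrant_proportions))
    if (!is.null(config$psa_strata)) {
      sg <- subgroup_psa(cohort, config$psa_strata, n_iter = config$n_iter,
                         seed = derive_seed(config$seed, "psa_subgroup"))
      for (l in names(sg)) {
        if (isTRUE(sg[[l]]$skipped)) {
          quad <- rbind(quad, data.frame(stratum = l, quadrant = "skipped",
                                         proportion = NA_real_))
        } else {
          quad <- rbind(quad, data.frame(
            stratum = l, quadrant = names(sg[[l]]$quadrant_proportions),
            proportion = unname(sg[[l]]$quadrant_proportions)))
        }
      }
    }
    write.csv(quad, out("quadrants.csv"), row.names = FALSE)
    manifest["quadrants"] <- out("quadrants.csv")
    write.csv(icer_histogram(psa), out("icer_hist.csv"), row.names = FALSE)
    manifest["icer_hist"] <- out("icer_hist.csv")
  }

  writeLines(c(log_lines, sprintf("artifacts: %s",
                                  paste(names(manifest), collapse = ", "))),
             out("run_log.txt"))
  manifest["log"] <- out("run_log.txt")
  manifest
}

#' Validate a cohort CSV
#'
#' Checks column presence, group-label vocabulary, nonnegative integral
#' counts, and COOP/WONCA score ranges; every violation is reported with its
#' row number.
#'
#' @param path cohort CSV path.
#' @return data.frame of class `validation_report` with columns `row`,
#'   `column`, `message` (zero rows = valid), and attribute `ok`.
#' @export
validate_cohort_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  v <- list()
  bad <- function(rows, column, message) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- data.frame(row = rows, column = column,
                                         message = message)
    }
  }
  required <- c("id", "group", UTILIZATION_CATEGORIES,
                "wonca_baseline", "wonca_6m")
  for (col in setdiff(required, names(df))) {
    bad(NA_integer_, col, "required column missing")
  }
  if ("group" %in% names(df)) {
    rows <- which(!df$group %in% GROUP_LEVELS)
    bad(rows, "group", sprintf("label must be one of: %s",
                               paste(GROUP_LEVELS, collapse = ", ")))
  }
  for (cat in intersect(UTILIZATION_CATEGORIES, names(df))) {
    x <- df[[cat]]
    rows <- which(is.na(x) | x < 0 | x != floor(x))
    bad(rows, cat, "count must be a nonnegative integer")
  }
  for (col in intersect(c("wonca_baseline", "wonca_6m"), names(df))) {
    x <- df[[col]]
    rows <- which(!is.na(x) & (x < 7 | x > 35))
    bad(rows, col, "COOP/WONCA total must lie in [7, 35]")
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(0), column = character(0),
               message = character(0))
  structure(out, ok = nrow(out) == 0L,
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (attr(x, "ok")) {
    cat("cohort file valid: no violations\n")
  } else {
    cat(sprintf("cohort file INVALID: %d violation(s)\n", nrow(x)))
    print(as.data.frame(x))
  }
  invisible(x)
}
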