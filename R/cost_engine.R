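#' Unit-cost tariff table
#'
#' A tariff maps each utilization category to a euro unit cost at a stated
#' price year, with an optional CPI index series for price-year updating.
#'
#' @param entries named numeric vector, category -> unit cost in euros; must
#'   cover every utilization category exactly once with positive costs.
#' @param price_year calendar year the costs are expressed in.
#' @param cpi_index_by_year optional named numeric vector, year -> CPI index.
#' @return object of class `unit_cost_table`.
#' @export
#' @examples
#' unit_cost_table(c(primary_care = 64.07, specialist = 81.38,
#'                   pc_emergency = 73.30, hospital_emergency = 215.06), 2024)
unit_cost_table <- function(entries, price_year, cpi_index_by_year = NULL) {
  if (!is.numeric(entries) || is.null(names(entries))) {
    stop("`entries` must be a named numeric vector", call. = FALSE)
  }
  missing_cat <- setdiff(UTILIZATION_CATEGORIES, names(entries))
  if (length(missing_cat)) {
    stop(sprintf("tariff missing categories: %s",
                 paste(missing_cat, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicated tariff categories", call. = FALSE)
  }
  if (any(entries <= 0)) stop("unit costs must be > 0", call. = FALSE)
  structure(list(entries = entries[UTILIZATION_CATEGORIES],
                 price_year = as.integer(price_year),
                 cpi_index_by_year = cpi_index_by_year),
            class = "unit_cost_table")
}

#' Packaged 2024 tariffs
#'
#' Official public reimbursement rates in 2024 euros: 64.07 (primary care
#' visit), 81.38 (hospital specialist consultation), 73.30 (primary-care
#' emergency visit) and 215.06 (hospital emergency visit). The published
#' results table prints 73.34 for the primary-care emergency tariff while the
#' text states 73.30; `variant = "table2"` loads the 73.34 alternative so
#' either convention can be audited.
#'
#' @param variant `"default"` (prose value 73.30) or `"table2"` (73.34).
#' @return a `unit_cost_table` with the packaged CPI series attached.
#' @export
default_unit_costs <- function(variant = c("default", "table2")) {
  variant <- match.arg(variant)
  file <- if (variant == "table2") "tariffs_2024_table2.csv" else
    "tariffs_2024.csv"
  read_unit_costs(
    system.file("extdata", file, package = "bzdcua", mustWork = TRUE),
    cpi_path = system.file("extdata", "cpi_synthetic.csv", package = "bzdcua",
                           mustWork = TRUE))
}

#' Read a tariff CSV (columns category, unit_cost, price_year) and an
#' optional CPI CSV (columns year, index).
#'
#' @param path tariff CSV path.
#' @param cpi_path optional CPI CSV path.
#' @return a `unit_cost_table`.
#' @export
read_unit_costs <- function(path, cpi_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "unit_cost", "price_year")
  if (!all(need %in% names(df))) {
    stop(sprintf("tariff file must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(df$price_year)) != 1L) {
    stop("tariff file mixes price years", call. = FALSE)
  }
  cpi <- NULL
  if (!is.null(cpi_path)) {
    cdf <- read.csv(cpi_path, stringsAsFactors = FALSE)
    cpi <- setNames(cdf$index, cdf$year)
  }
  unit_cost_table(setNames(df$unit_cost, df$category), df$price_year[1], cpi)
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat(sprintf("<unit_cost_table> price year %d\n", x$price_year))
  print(x$entries)
  invisible(x)
}

#' Restate a cost in a different price year via CPI
#'
#' Multiplies by the ratio of CPI index values: `base_cost *
#' index(to_year) / index(from_year)`.
#'
#' @param base_cost positive cost in `from_year` euros.
#' @param from_year,to_year calendar years present in the index.
#' @param cpi_index_by_year named numeric vector, year -> index.
#' @return cost expressed in `to_year` euros.
#' @export
#' @examples
#' inflate_cost(50, 2020, 2024, c("2020" = 100, "2024" = 110)) # 55
inflate_cost <- function(base_cost, from_year, to_year, cpi_index_by_year) {
  if (!is.numeric(base_cost) || base_cost <= 0) {
    stop("`base_cost` must be > 0", call. = FALSE)
  }
  if (from_year == to_year) return(base_cost)
  for (y in c(from_year, to_year)) {
    if (!as.character(y) %in% names(cpi_index_by_year)) {
      stop(sprintf("year %s missing from CPI index", y), call. = FALSE)
    }
  }
  base_cost * cpi_index_by_year[[as.character(to_year)]] /
    cpi_index_by_year[[as.character(from_year)]]
}

#' Per-person cost breakdown
#'
#' Multiplies each utilization count by its tariff unit cost and sums across
#' categories. No rounding is applied: totals equal the exact sum of the
#' per-category costs.
#'
#' @param counts named numeric vector (or single-row slice) of nonnegative
#'   counts for the four utilization categories.
#' @param tariff a `unit_cost_table`.
#' @return list with `per_category_cost` (named euros) and `total_cost`.
#' @export
#' @examples
#' tar <- unit_cost_table(c(primary_care = 64.07, specialist = 81.38,
#'                          pc_emergency = 73.30,
#'                          hospital_emergency = 215.06), 2024)
#' cost_per_person(c(primary_care = 9, specialist = 0, pc_emergency = 0,
#'                   hospital_emergency = 0), tar)$total_cost # 576.63
cost_per_person <- function(counts, tariff) {
  stopifnot(inherits(tariff, "unit_cost_table"))
  counts <- unlist(counts)
  unknown <- setdiff(names(counts), names(tariff$entries))
  if (length(unknown)) {
    stop(sprintf("no tariff entry for category: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_cat <- setdiff(UTILIZATION_CATEGORIES, names(counts))
  if (length(missing_cat)) {
    stop(sprintf("counts missing category: %s",
                 paste(missing_cat, collapse = ", ")), call. = FALSE)
  }
  per <- counts[UTILIZATION_CATEGORIES] * tariff$entries
  list(per_category_cost = per, total_cost = sum(per))
}

#' Attach per-category and total cost columns to a cohort
#'
#' Adds `cost_<category>` columns and `total_cost`, computed row-wise as
#' count times unit cost with no intermediate rounding.
#'
#' @param cohort a `bzd_cohort`.
#' @param tariff a `unit_cost_table`.
#' @return the cohort with five additional euro columns.
#' @export
add_costs <- function(cohort, tariff) {
  stopifnot(inherits(tariff, "unit_cost_table"))
  for (cat in UTILIZATION_CATEGORIES) {
    if (!cat %in% names(cohort)) {
      stop(sprintf("cohort lacks count column '%s'", cat), call. = FALSE)
    }
    cohort[[paste0("cost_", cat)]] <- cohort[[cat]] * tariff$entries[[cat]]
  }
  cohort$total_cost <- Reduce(`+`, lapply(
    UTILIZATION_CATEGORIES, function(cat) cohort[[paste0("cost_", cat)]]))
  cohort
}

#' Group-level resource use and cost summary
#'
#' The published results-table shape: one row per utilization category plus a
#' total row, with per-group mean use, unit cost, mean cost per person
#' (unrounded and rounded to integer euros, half away from zero), the
#' between-group difference (discontinuation minus continuation) and the
#' standard error of the group mean total cost (sample SD / sqrt(n), n-1
#' denominator).
#'
#' @param cohort a `bzd_cohort` (costs are computed internally).
#' @param tariff a `unit_cost_table`.
#' @return object of class `group_cost_summary`: a data.frame plus `n` and
#'   `total_se` attributes.
#' @export
group_cost_summary <- function(cohort, tariff) {
  sizes <- table(factor(cohort$group, levels = GROUP_LEVELS))
  if (any(sizes == 0L)) {
    stop(sprintf("group '%s' empty: between-group summary undefined",
                 names(sizes)[sizes == 0L][1]), call. = FALSE)
  }
  cohort <- add_costs(cohort, tariff)
  cont <- cohort[cohort$group == "continuation", ]
  disc <- cohort[cohort$group == "discontinuation", ]
  row_for <- function(cat) {
    uc <- if (cat == "total") NA_real_ else tariff$entries[[cat]]
    col <- if (cat == "total") "total_cost" else paste0("cost_", cat)
    use_c <- if (cat == "total") NA_real_ else mean(cont[[cat]])
    use_d <- if (cat == "total") NA_real_ else mean(disc[[cat]])
    mc <- mean(cont[[col]]); md <- mean(disc[[col]])
    data.frame(
      quantity = cat, mean_use_continuation = use_c,
      mean_use_discontinuation = use_d, unit_cost = uc,
      cost_continuation = mc, cost_discontinuation = md,
      cost_continuation_rounded = round_half_up(mc),
      cost_discontinuation_rounded = round_half_up(md),
      difference = md - mc,
      difference_rounded = round_half_up(md) - round_half_up(mc))
  }
  out <- do.call(rbind, lapply(c(UTILIZATION_CATEGORIES, "total"), row_for))
  attr(out, "n") <- setNames(as.integer(sizes), GROUP_LEVELS)
  attr(out, "total_se") <- c(
    continuation = sd(cont$total_cost) / sqrt(nrow(cont)),
    discontinuation = sd(disc$total_cost) / sqrt(nrow(disc)))
  class(out) <- c("group_cost_summary", "data.frame")
  out
}
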