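# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding used when rendering integer-euro report cells;
#' base `round()` rounds half to even, which does not reproduce printed
#' tariff-table cells such as 578.55 -> 579.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(578.55, 0) # 579
#' round_half_up(132.65, 0) # 133
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation: one root seed, independent stage streams.
# Keeps results reproducible when stages are re-ordered or skipped.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

# canonical utilization categories, in documented column order
UTILIZATION_CATEGORIES <- c("primary_care", "specialist",
                            "pc_emergency", "hospital_emergency")

GROUP_LEVELS <- c("continuation", "discontinuation")
SEX_LEVELS <- c("women", "men")
INCOME_LEVELS <- c("<=18000", ">18000")
CCI_LEVELS <- c("0-2", "3-4", ">=5")
INDICATION_LEVELS <- c("anxiety", "insomnia", "both", "other")
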