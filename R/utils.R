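# Internal helpers shared across modules.

# One day in fractional calendar years.
DAY <- 1 / 365.25

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert a calendar date string to a fractional year
#'
#' Dates throughout the package are fractional calendar years at day
#' resolution (one day = 1/365.25 years). The end of December 31 of year
#' `y` is `y + 1` under the half-open interval convention, so
#' `as_year("2003-12-31")` is (almost) `2004`.
#'
#' @param x Character vector of dates in `"YYYY-MM-DD"` form, or a `Date`.
#' @return Numeric vector of fractional years.
#' @examples
#' as_year("1950-01-01")
#' as_year("1950-07-02")
#' @export
as_year <- function(x) {
  d <- as.Date(x)
  y <- as.integer(format(d, "%Y"))
  doy <- as.numeric(d - as.Date(paste0(y, "-01-01")))
  y + doy * DAY
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  assert_that(x >= min, sprintf("`%s` must be >= %g", name, min))
}

assert_prob <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1,
              sprintf("`%s` must be a probability in [0, 1]", name))
}

# Draw a vector of independent per-worker seeds from a master seed, so
# cohorts are reproducible even if workers are simulated in any order.
split_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

PLANT_LEVELS <- c("auxiliary", "reactor", "radiochemical",
                  "plutonium_auxiliary", "plutonium_main2", "plutonium_main1")

SEX_LEVELS <- c("male", "female")
SMOKING_LEVELS <- c("ever", "never", "unknown")
MONITORING_LEVELS <- c("unmonitored", "monitored_0_1y", "monitored_2plus")
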