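# Exposure covariates: lagged cumulative doses, exposure windows,
# plutonium surrogate categories, monitoring status, dose categories.

#' Default dose-category boundaries (mGy)
#'
#' Non-zero dose categories use boundaries at 10, 25, 40, 100, 150, 250,
#' 500, 1000, 1500, 2000 and 3000 mGy; internal (liver) dose adds 5000 mGy.
#' Zero dose is its own category.
#'
#' @param internal If `TRUE`, append the 5000 mGy boundary used for
#'   internal dose.
#' @return Numeric vector of strictly increasing boundaries.
#' @export
dose_boundaries <- function(internal = FALSE) {
  b <- c(10, 25, 40, 100, 150, 250, 500, 1000, 1500, 2000, 3000)
  if (internal) c(b, 5000) else b
}

# Cumulative dose D(t) from an annual series under uniform within-year
# accrual: dose for calendar year y accrues linearly over [y, y + 1).
# `years` integer years, `doses` mGy, `t` vectorized.
cumulative_dose_at <- function(years, doses, t) {
  if (length(years) == 0L) return(rep(0, length(t)))
  ord <- order(years)
  years <- as.numeric(years[ord])
  doses <- as.numeric(doses[ord])
  cum <- cumsum(doses)
  full <- findInterval(t - 1, years)       # years with year + 1 <= t
  k <- findInterval(t, years)              # years with year <= t
  out <- ifelse(full > 0, cum[pmax(full, 1)], 0)
  part <- k > full & k > 0
  out[part] <- out[part] + (t[part] - years[k[part]]) * doses[k[part]]
  out
}

#' Lagged cumulative dose
#'
#' Cumulative dose received up to `lag` years before time `t`, i.e.
#' \eqn{D(t - lag)} of the cumulative dose step function, with annual doses
#' accruing uniformly within each calendar year. Doses more recent than the
#' lag are excluded from the covariate on the presumption that they cannot
#' yet have caused the outcome.
#'
#' @param history Data frame with columns `year` (integer calendar year)
#'   and `dose_mgy` (annual dose, mGy); rows for one worker and organ.
#' @param lag Lag in years (>= 0). Default 5.
#' @param t Time(s) at risk, fractional years; vectorized.
#' @return Numeric vector of cumulative lagged doses in mGy.
#' @examples
#' h <- tibble::tibble(year = 1950:1959, dose_mgy = 100)
#' cumulative_lagged_dose(h, lag = 5, t = 1960)   # 500
#' cumulative_lagged_dose(h, lag = 5, t = 1957.5) # 250
#' @export
cumulative_lagged_dose <- function(history, lag = 5, t) {
  assert_scalar_number(lag, "lag", min = 0)
  assert_that(all(history$dose_mgy >= 0), "annual doses must be >= 0")
  cumulative_dose_at(history$year, history$dose_mgy, t - lag)
}

#' Define an exposure-window partition
#'
#' Windows partition a worker's past exposure either by time since exposure
#' (years before the time at risk) or by age at exposure. For
#' `time_since_exposure` the windows are the half-open intervals between
#' consecutive cutpoints plus an unbounded final window; dose received more
#' recently than the first cutpoint (the minimum lag) is excluded. For
#' `age_at_exposure` a first window from age 0 to the first cutpoint is
#' prepended so the windows are exhaustive.
#'
#' @param mode `"time_since_exposure"` or `"age_at_exposure"`.
#' @param cutpoints Strictly increasing numeric cutpoints, e.g.
#'   `c(5, 10, 15, 20)` for windows 5-9, 10-14, 15-19, 20+ years before
#'   the time at risk.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(mode = c("time_since_exposure", "age_at_exposure"),
                        cutpoints) {
  mode <- match.arg(mode)
  assert_that(is.numeric(cutpoints) && length(cutpoints) >= 1L &&
                all(diff(cutpoints) > 0),
              "`cutpoints` must be strictly increasing")
  lo <- if (mode == "age_at_exposure") c(0, cutpoints) else cutpoints
  hi <- c(lo[-1L], Inf)
  if (any(lo < 0)) stop("cutpoints must be non-negative", call. = FALSE)
  labels <- ifelse(is.finite(hi),
                   sprintf("%g-%g", lo, hi),
                   sprintf("%g+", lo))
  structure(list(mode = mode, lo = lo, hi = hi, labels = labels),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("<window_spec> mode:", x$mode, "\n windows:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Partition cumulative dose into exposure windows
#'
#' Splits the dose accumulated before time `t` into the components received
#' in each window of `spec`. Components are computed exactly as differences
#' of the continuous cumulative dose function, so they sum to the total
#' (lagged) cumulative dose.
#'
#' @inheritParams cumulative_lagged_dose
#' @param spec A [window_spec()].
#' @param t Single time at risk (fractional years).
#' @param birth_date Worker's birth date (fractional years); required for
#'   `age_at_exposure` mode.
#' @param lag Additional lag applied in `age_at_exposure` mode (dose within
#'   `lag` years of `t` is excluded); ignored for `time_since_exposure`,
#'   where the first cutpoint is the minimum lag.
#' @return Named numeric vector of window doses (mGy), one per window.
#' @export
dose_in_windows <- function(history, spec, t, birth_date = NULL, lag = 0) {
  stopifnot(inherits(spec, "window_spec"))
  assert_that(length(t) == 1L && is.finite(t), "`t` must be a single time")
  D <- function(u) cumulative_dose_at(history$year, history$dose_mgy, u)
  if (spec$mode == "time_since_exposure") {
    # s = t - u in [lo, hi)  <=>  u in (t - hi, t - lo]; D is continuous so
    # the component is D(t - lo) - D(t - hi).
    out <- D(t - spec$lo) - D(pmax(t - spec$hi, -Inf))
  } else {
    assert_that(!is.null(birth_date), "`birth_date` required for age windows")
    assert_scalar_number(lag, "lag", min = 0)
    cap <- t - lag
    out <- D(pmin(cap, birth_date + spec$hi)) - D(pmin(cap, birth_date + spec$lo))
  }
  out <- pmax(out, 0)
  names(out) <- spec$labels
  out
}

#' Plutonium exposure surrogate-category map
#'
#' Ordinal categories 0-5 proxying the potential for plutonium exposure,
#' assigned from workplace and the period of first entry into that
#' workplace. Reactor-complex and auxiliary-plant work carries no Pu
#' potential (category 0); the highest category (5) is early-era work in
#' the low-transportability plutonium production departments ("Main 1").
#' The map is exposed as data so it can be inspected or amended.
#'
#' @return A tibble with columns `plant`, `entry_from`, `entry_to`
#'   (inclusive years of first entry) and `category`.
#' @export
surrogate_category_map <- function() {
  tibble::tribble(
    ~plant,                 ~entry_from, ~entry_to, ~category,
    "auxiliary",            1948, Inf,  0L,
    "reactor",              1948, Inf,  0L,
    "radiochemical",        1964, Inf,  1L,
    "plutonium_auxiliary",  1964, Inf,  1L,
    "plutonium_main2",      1964, Inf,  1L,
    "plutonium_main1",      1964, Inf,  1L,
    "radiochemical",        1954, 1963, 2L,
    "plutonium_auxiliary",  1954, 1963, 2L,
    "plutonium_main2",      1959, 1963, 2L,
    "radiochemical",        1948, 1953, 3L,
    "plutonium_auxiliary",  1948, 1953, 3L,
    "plutonium_main2",      1950, 1958, 3L,
    "plutonium_main1",      1959, 1963, 3L,
    "plutonium_main2",      1948, 1949, 4L,
    "plutonium_main1",      1954, 1958, 4L,
    "plutonium_main1",      1948, 1953, 5L
  )
}

# Category for one (plant, first-entry-year) pair.
surrogate_pair_category <- function(plant, entry_year, map) {
  hit <- map$plant == plant & entry_year >= map$entry_from &
    entry_year <= map$entry_to
  if (!any(hit)) {
    # entries before the first mapped era fall back to the earliest row
    hit <- map$plant == plant
    if (!any(hit)) stop("unknown plant label: ", plant, call. = FALSE)
    return(max(map$category[hit]))
  }
  max(map$category[hit])
}

#' Assign a worker's plutonium surrogate category
#'
#' Each (workplace, period-of-first-entry) pair maps to a category via
#' [surrogate_category_map()]; the worker's category is the maximum over
#' all pairs in the career (the workplace with the highest potential for
#' plutonium exposure dominates). Reactor/auxiliary-only careers map to 0.
#'
#' @param segments Data frame of employment segments with columns `plant`
#'   and `start` (fractional years); one worker.
#' @param at Optional time: if given, only workplaces entered at or before
#'   `at` count (time-dependent category).
#' @param map Category map, defaulting to [surrogate_category_map()].
#' @return Integer category in 0-5.
#' @examples
#' seg <- tibble::tibble(plant = "radiochemical", start = 1950, end = 1960)
#' assign_surrogate_category(seg)  # 3
#' @export
assign_surrogate_category <- function(segments, at = NULL,
                                      map = surrogate_category_map()) {
  assert_that(nrow(segments) >= 1L, "worker must have at least one segment")
  bad <- setdiff(unique(as.character(segments$plant)), PLANT_LEVELS)
  if (length(bad)) stop("unknown plant label: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  first_entry <- segments |>
    dplyr::group_by(plant = as.character(.data$plant)) |>
    dplyr::summarise(entry = min(.data$start), .groups = "drop")
  if (!is.null(at)) first_entry <- dplyr::filter(first_entry, .data$entry <= at)
  if (nrow(first_entry) == 0L) return(0L)
  cats <- mapply(surrogate_pair_category, first_entry$plant,
                 floor(first_entry$entry),
                 MoreArgs = list(map = map))
  as.integer(max(cats))
}

#' Time-dependent plutonium monitoring status
#'
#' Workers are classified as unmonitored until two years after their first
#' plutonium (urine bioassay) monitoring date, because monitoring could be
#' triggered by suspected disease; thereafter they are classified by time
#' since the most recent monitoring (0-1 years vs 2 or more).
#'
#' @param first_monitoring_date First monitoring date (fractional years),
#'   or `NA` if never monitored.
#' @param t Time(s) at risk; vectorized.
#' @param last_monitoring_date Most recent monitoring date at or before
#'   `t`; defaults to the first date.
#' @return Factor with levels `unmonitored`, `monitored_0_1y`,
#'   `monitored_2plus`.
#' @examples
#' monitoring_status(1970, t = c(1971, 1973.5))
#' @export
monitoring_status <- function(first_monitoring_date, t,
                              last_monitoring_date = first_monitoring_date) {
  status <- rep("unmonitored", length(t))
  if (length(last_monitoring_date) == 0L || is.na(last_monitoring_date)) {
    last_monitoring_date <- first_monitoring_date
  }
  if (!is.na(first_monitoring_date)) {
    on <- t >= first_monitoring_date + 2
    since <- t - pmin(last_monitoring_date, t)
    status[on & since < 2] <- "monitored_0_1y"
    status[on & since >= 2] <- "monitored_2plus"
  }
  factor(status, levels = MONITORING_LEVELS)
}

#' Categorize a dose into the stratification categories
#'
#' Dose exactly 0 maps to category 0 when `zero_category = TRUE`;
#' otherwise doses fall in left-closed right-open bins
#' `[b_k, b_{k+1})` between the boundaries, with `(0, b_1)` the first
#' non-zero bin and the top bin unbounded.
#'
#' @param dose Dose(s) in mGy; must be >= 0.
#' @param boundaries Strictly increasing boundaries (mGy);
#'   default [dose_boundaries()].
#' @param zero_category Give exact zero its own category 0.
#' @return Integer category (0 = zero dose, 1 = first bin, ...).
#' @examples
#' categorize_dose(c(0, 5, 30, 10))  # 0 1 3 2
#' @export
categorize_dose <- function(dose, boundaries = dose_boundaries(),
                            zero_category = TRUE) {
  assert_that(all(diff(boundaries) > 0), "`boundaries` must be strictly increasing")
  if (any(dose < 0)) stop("negative dose", call. = FALSE)
  idx <- findInterval(dose, boundaries) + 1L   # 1 = below first boundary
  if (zero_category) idx[dose == 0] <- 0L
  idx
}

#' Labels for dose categories
#'
#' @inheritParams categorize_dose
#' @return Character vector of labels, index 1 corresponding to category 0.
#' @export
dose_category_labels <- function(boundaries = dose_boundaries(),
                                 zero_category = TRUE) {
  lab <- c(sprintf("(0,%g)", boundaries[1]),
           sprintf("[%g,%g)", boundaries[-length(boundaries)], boundaries[-1]),
           sprintf("%g+", boundaries[length(boundaries)]))
  if (zero_category) lab <- c("0", lab)
  lab
}
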