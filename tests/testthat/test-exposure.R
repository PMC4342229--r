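# Lagged doses, exposure windows, surrogate categories, monitoring
# status and dose categorization.

test_that("cumulative lagged dose matches hand sums under uniform accrual", {
  h <- make_history(1950:1959, rep(100, 10))
  expect_equal(cumulative_lagged_dose(h, lag = 5, t = 1960), 500)
  expect_equal(cumulative_lagged_dose(h, lag = 20, t = 1960), 0)
  expect_equal(cumulative_lagged_dose(h, lag = 5, t = 1957.5), 250)
  expect_equal(cumulative_lagged_dose(h, lag = 0, t = 1970), 1000)
  expect_equal(cumulative_lagged_dose(h, lag = 0, t = 1950.25), 25)
  expect_error(cumulative_lagged_dose(h, lag = -1, t = 1960), ">=")
})

test_that("lagged dose is non-decreasing in t and non-increasing in lag", {
  set.seed(11)
  for (rep in 1:20) {
    yrs <- sort(sample(1950:1980, sample(3:15, 1)))
    h <- make_history(yrs, stats::runif(length(yrs), 0, 200))
    ts <- sort(stats::runif(8, 1950, 1995))
    d <- cumulative_lagged_dose(h, lag = 5, t = ts)
    expect_true(all(diff(d) >= -1e-12))
    lags <- sort(stats::runif(5, 0, 30))
    dl <- vapply(lags, function(L) cumulative_lagged_dose(h, L, 1990),
                 numeric(1))
    expect_true(all(diff(dl) <= 1e-12))
  }
})

# Independent day-level oracle: assign each day's dose increment to the
# window containing its time-since-exposure (or age at exposure).
brute_force_windows <- function(history, spec, t, birth_date = NULL,
                                lag = 0) {
  out <- numeric(length(spec$lo))
  day <- 1 / 365.25
  for (i in seq_len(nrow(history))) {
    y <- history$year[i]
    inc <- history$dose_mgy[i] * day
    u <- seq(y + day / 2, y + 1 - day / 2, by = day)
    for (uk in u) {
      if (uk >= t) next
      x <- if (spec$mode == "time_since_exposure") t - uk else {
        if (t - uk < lag) next
        uk - birth_date
      }
      j <- which(x >= spec$lo & x < spec$hi)
      if (length(j) == 1L) out[j] <- out[j] + inc
    }
  }
  out
}

test_that("time-since-exposure window doses match the day-level oracle", {
  h <- make_history(1950:1959, rep(100, 10))
  spec <- window_spec("time_since_exposure", c(5, 10, 15, 20))
  got <- dose_in_windows(h, spec, t = 1970)
  # frozen from brute_force_windows(h, spec, 1970): one year of exposure
  # (1950) sits at 19-20 years before t, so the 20+ window stays empty
  expect_equal(unname(got), c(0, 500, 500, 0), tolerance = 1e-9)
  oracle <- brute_force_windows(h, spec, 1970)
  expect_equal(unname(got), oracle, tolerance = 0.5)

  set.seed(21)
  for (rep in 1:5) {
    yrs <- sort(sample(1950:1975, sample(3:10, 1)))
    h2 <- make_history(yrs, stats::runif(length(yrs), 0, 300))
    cuts <- sort(sample(2:25, 3))
    sp <- window_spec("time_since_exposure", cuts)
    tt <- 1980 + stats::runif(1, 0, 10)
    got2 <- dose_in_windows(h2, sp, t = tt)
    expect_equal(unname(got2), brute_force_windows(h2, sp, tt),
                 tolerance = 1)
    # conservation: windows partition everything at least cuts[1] old
    expect_equal(sum(got2),
                 cumulative_lagged_dose(h2, lag = cuts[1], t = tt),
                 tolerance = 1e-9)
  }
})

test_that("a single all-covering window equals the lagged cumulative dose", {
  h <- make_history(1950:1959, rep(100, 10))
  sp <- window_spec("time_since_exposure", 5)
  expect_equal(unname(dose_in_windows(h, sp, t = 1970)),
               cumulative_lagged_dose(h, lag = 5, t = 1970))
})

test_that("age-at-exposure windows respect containment and the oracle", {
  # exposed only at ages 26-28 -> all dose in the 25-29 component
  birth <- 1930
  h <- make_history(1956:1958, rep(50, 3))
  sp <- window_spec("age_at_exposure", c(25, 30, 40, 50))
  got <- dose_in_windows(h, sp, t = 1990, birth_date = birth)
  expect_equal(unname(got), c(0, 150, 0, 0, 0))
  expect_equal(unname(got),
               brute_force_windows(h, sp, 1990, birth_date = birth),
               tolerance = 0.5)
  # a 5-year lag excludes recent doses from every window
  h2 <- make_history(1986:1988, rep(10, 3))
  got2 <- dose_in_windows(h2, sp, t = 1990, birth_date = birth, lag = 5)
  expect_equal(sum(got2), 0)
})

test_that("window specs reject invalid cutpoints", {
  expect_error(window_spec("time_since_exposure", c(5, 5, 10)),
               "increasing")
  expect_error(window_spec("time_since_exposure", c(10, 5)), "increasing")
})

test_that("surrogate categories follow the workplace/period map", {
  expect_equal(assign_surrogate_category(
    make_segments(plant = "radiochemical", start = 1950, end = 1960)), 3L)
  expect_equal(assign_surrogate_category(
    make_segments(plant = "plutonium_main1", start = 1948, end = 1955)), 5L)
  # reactor first, then radiochemical entered 1956: radiochemical's
  # 1954-1963 row (category 2) dominates the reactor 0
  segs <- make_segments(plant = c("reactor", "radiochemical"),
                        start = c(1950, 1956), end = c(1955, 1965))
  expect_equal(assign_surrogate_category(segs), 2L)
  # reactor/auxiliary-only careers map to 0
  expect_equal(assign_surrogate_category(
    make_segments(plant = "reactor", start = 1950, end = 1980)), 0L)
  expect_equal(assign_surrogate_category(
    make_segments(plant = "plutonium_main2", start = 1948.5, end = 1955)),
    4L)
  expect_equal(assign_surrogate_category(
    make_segments(plant = "radiochemical", start = 1970, end = 1980)), 1L)
  expect_error(assign_surrogate_category(
    tibble::tibble(plant = "shipyard", start = 1950, end = 1960)),
    "unknown plant")
})

test_that("surrogate assignment is order-invariant and idempotent", {
  set.seed(31)
  plants <- levels(make_worker()$primary_plant)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    segs <- tibble::tibble(
      plant = sample(plants, k, replace = TRUE),
      start = stats::runif(k, 1948, 1982))
    segs$end <- segs$start + stats::runif(k, 1, 10)
    c1 <- assign_surrogate_category(segs)
    c2 <- assign_surrogate_category(segs[sample.int(k), ])
    expect_identical(c1, c2)
    expect_identical(assign_surrogate_category(segs), c1)
    expect_true(c1 %in% 0:5)
  }
})

test_that("monitoring status applies the two-year rule and 0-1/2+ split", {
  expect_equal(as.character(monitoring_status(NA, t = 1980)), "unmonitored")
  expect_equal(as.character(monitoring_status(1970, t = 1971)),
               "unmonitored")
  expect_equal(as.character(monitoring_status(1970, t = 1973.5)),
               "monitored_2plus")
  # a recent monitoring date within 2 years puts time-since at 0-1
  expect_equal(as.character(
    monitoring_status(1970, t = 1981, last_monitoring_date = 1980)),
    "monitored_0_1y")
  expect_equal(as.character(
    monitoring_status(1970, t = 1983, last_monitoring_date = 1980)),
    "monitored_2plus")
})

test_that("dose categorization uses a zero category and left-closed bins", {
  expect_equal(categorize_dose(0), 0L)
  expect_equal(categorize_dose(30), 3L)
  expect_equal(dose_category_labels()[categorize_dose(30) + 1L], "[25,40)")
  expect_equal(dose_category_labels()[categorize_dose(10) + 1L], "[10,25)")
  expect_equal(categorize_dose(5000), 12L)
  expect_equal(categorize_dose(5000, dose_boundaries(internal = TRUE)), 13L)
  expect_error(categorize_dose(-1), "negative")
  # bin-midpoint reconstruction never crosses a boundary
  b <- dose_boundaries()
  doses <- c(0.5, b - 1e-9, b, b + 1e-9, 4000)
  cats <- categorize_dose(doses)
  mids <- (c(0, b) + c(b, 8000)) / 2   # midpoint of non-zero bin k
  recon <- mids[cats]
  expect_equal(categorize_dose(recon[cats > 0]), cats[cats > 0])
})
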