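# Person-year tabulation: splitting follow-up over fixed and
# time-dependent stratification axes and accumulating cells.

#' Define a stratification scheme
#'
#' Fixed axes: sex, period of hire (1948-52/1953-57/1958-62/1963-72/
#' 1973-82), birth cohort (pre-1938, 1939-42, 1943-52, 1953-65; birth year
#' 1938 is assigned to the first bin), smoking, plant. Time-dependent
#' axes: attained age (5-year bins 10-84, 85+), calendar year (1948-49,
#' 5-year bins 1950-2003, 2004-07, 2008), duration of follow-up (cutpoints
#' 2/5/10/15, clock starting at hire), migration status, monitoring
#' status, lagged external and internal dose categories, and plutonium
#' surrogate category. Any subset of axes may be requested; dropping axes
#' never changes total person-years or events.
#'
#' @param axes Character vector of axis names to stratify on; any of
#'   `"sex"`, `"hire_period"`, `"birth_cohort"`, `"smoking"`, `"plant"`,
#'   `"age"`, `"calendar"`, `"duration"`, `"migration"`, `"monitoring"`,
#'   `"ext_dose"`, `"int_dose"`, `"surrogate"`. The attained-age axis is
#'   always present.
#' @param lag Dose lag in years (default 5).
#' @param age_breaks,cal_breaks,dur_breaks Axis cutpoints (half-open bins).
#' @param ext_boundaries,int_boundaries Dose category boundaries (mGy).
#' @param windows Optional [window_spec()]; adds person-year-weighted
#'   window dose columns `wdose_1 .. wdose_k` to each cell.
#' @return An object of class `strat_scheme`.
#' @export
stratification_scheme <- function(axes = c("sex", "hire_period",
                                           "birth_cohort", "smoking",
                                           "plant", "age", "calendar",
                                           "duration", "migration",
                                           "monitoring", "ext_dose",
                                           "int_dose", "surrogate"),
                                  lag = 5,
                                  age_breaks = c(seq(10, 85, 5), Inf),
                                  cal_breaks = c(1948, 1950,
                                                 seq(1955, 2000, 5),
                                                 2004, 2008, 2009),
                                  dur_breaks = c(0, 2, 5, 10, 15, Inf),
                                  ext_boundaries = dose_boundaries(),
                                  int_boundaries = dose_boundaries(internal = TRUE),
                                  windows = NULL) {
  all_axes <- c("sex", "hire_period", "birth_cohort", "smoking", "plant",
                "age", "calendar", "duration", "migration", "monitoring",
                "ext_dose", "int_dose", "surrogate")
  bad <- setdiff(axes, all_axes)
  if (length(bad)) stop("unknown axes: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  axes <- union(axes, "age")
  assert_scalar_number(lag, "lag", min = 0)
  for (b in list(age_breaks, cal_breaks, dur_breaks, ext_boundaries,
                 int_boundaries)) {
    assert_that(all(diff(b) > 0), "axis breaks must be strictly increasing")
  }
  if (!is.null(windows)) stopifnot(inherits(windows, "window_spec"))
  sch <- list(axes = axes, lag = lag, age_breaks = age_breaks,
              cal_breaks = cal_breaks, dur_breaks = dur_breaks,
              hire_breaks = c(1948, 1953, 1958, 1963, 1973, 1983),
              birth_breaks = c(-Inf, 1939, 1943, 1953, Inf),
              ext_boundaries = ext_boundaries,
              int_boundaries = int_boundaries,
              windows = windows)
  for (nm in c("age", "cal", "dur", "hire", "birth")) {
    sch[[paste0(nm, "_labels")]] <- make_bin_labels(sch[[paste0(nm, "_breaks")]])
  }
  sch$ext_labels <- dose_category_labels(ext_boundaries)
  sch$int_labels <- dose_category_labels(int_boundaries)
  structure(sch, class = "strat_scheme")
}

#' @export
print.strat_scheme <- function(x, ...) {
  cat("<strat_scheme> axes:", paste(x$axes, collapse = ", "),
      "\n lag:", x$lag, "years\n")
  invisible(x)
}

make_bin_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  ifelse(is.finite(hi), sprintf("[%g,%g)", lo, hi), sprintf("%g+", lo))
}

# Label a value into half-open bins [b_k, b_{k+1}).
bin_label <- function(x, breaks, labels = make_bin_labels(breaks)) {
  idx <- findInterval(x, breaks)
  idx[idx < 1L] <- 1L
  idx[idx >= length(breaks)] <- length(breaks) - 1L
  labels[idx]
}

# Times in (entry, exit) where the lagged cumulative dose kinks or crosses
# a category boundary. Returned so that D(t - lag) is linear between
# consecutive break times and the dose category is constant there.
dose_break_times <- function(years, dosevec, lag, boundaries, entry, exit) {
  if (length(years) == 0L) return(numeric(0))
  knots <- sort(unique(c(years, years + 1))) + lag
  knots <- knots[knots > entry & knots < exit]
  grid <- sort(unique(c(entry, knots, exit)))
  dg <- cumulative_dose_at(years, dosevec, grid - lag)
  cross <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    d0 <- dg[i]; d1 <- dg[i + 1L]
    if (d1 > d0) {
      b <- boundaries[boundaries > d0 & b_lt(boundaries, d1)]
      if (length(b)) {
        cross <- c(cross, grid[i] + (b - d0) / (d1 - d0) *
                     (grid[i + 1L] - grid[i]))
      }
    }
  }
  sort(unique(c(knots, cross[cross > entry & cross < exit])))
}

b_lt <- function(b, d) b < d | abs(b - d) < 1e-12

# Evaluate every covariate of a scheme at times t (vectorized) for one
# worker; returns a plain list of columns. Used at sub-interval midpoints
# by the splitter and at day midpoints by the brute-force oracle.
covariates_at <- function(t, w, segs, doses, internal, scheme, entry) {
  n <- length(t)
  out <- list()
  ax <- scheme$axes
  if ("sex" %in% ax) out$sex <- rep(as.character(w$sex), n)
  if ("hire_period" %in% ax) {
    out$hire_period <- rep(bin_label(floor(w$hire_date), scheme$hire_breaks,
                                     scheme$hire_labels), n)
  }
  if ("birth_cohort" %in% ax) {
    out$birth_cohort <- rep(bin_label(floor(w$birth_date),
                                      scheme$birth_breaks,
                                      scheme$birth_labels), n)
  }
  if ("smoking" %in% ax) out$smoking <- rep(as.character(w$smoking), n)
  if ("plant" %in% ax) out$plant <- rep(as.character(w$primary_plant), n)
  out$age <- bin_label(t - w$birth_date, scheme$age_breaks, scheme$age_labels)
  if ("calendar" %in% ax) {
    out$calendar <- bin_label(t, scheme$cal_breaks, scheme$cal_labels)
  }
  if ("duration" %in% ax) {
    out$duration <- bin_label(t - entry, scheme$dur_breaks, scheme$dur_labels)
  }
  if ("migration" %in% ax) {
    out$migration <- ifelse(!is.na(w$migration_date) & t >= w$migration_date,
                            "migrant", "resident")
  }
  if ("monitoring" %in% ax) {
    out$monitoring <- as.character(
      monitoring_status(w$first_monitoring_date, t,
                        w$last_monitoring_date %||% w$first_monitoring_date))
  }
  dext <- cumulative_dose_at(doses$year, doses$dose_mgy, t - scheme$lag)
  dint <- cumulative_dose_at(internal$year, internal$dose_mgy, t - scheme$lag)
  if ("ext_dose" %in% ax) {
    out$ext_dose <- scheme$ext_labels[
      categorize_dose(round(dext, 9), scheme$ext_boundaries) + 1L]
  }
  if ("int_dose" %in% ax) {
    out$int_dose <- scheme$int_labels[
      categorize_dose(round(dint, 9), scheme$int_boundaries) + 1L]
  }
  if ("surrogate" %in% ax) {
    # step function: career-max category over workplaces entered by t
    fe <- vapply(split(segs$start, as.character(segs$plant)), min, numeric(1))
    cats <- vapply(seq_along(fe), function(k) {
      surrogate_pair_category(names(fe)[k], floor(fe[k]),
                              surrogate_category_map())
    }, numeric(1))
    ord <- order(fe)
    steps <- cummax(cats[ord])
    idx <- findInterval(t, fe[ord])
    out$surrogate <- as.integer(ifelse(idx > 0, steps[pmax(idx, 1)], 0))
  }
  out$.age_mid <- t - w$birth_date
  out$.year_mid <- t
  out$.dose_ext <- dext
  out$.dose_int <- dint
  if (!is.null(scheme$windows)) {
    wd <- t(vapply(t, function(ti) {
      dose_in_windows(doses, scheme$windows, ti, birth_date = w$birth_date,
                      lag = if (scheme$windows$mode == "age_at_exposure")
                        scheme$lag else 0)
    }, numeric(length(scheme$windows$labels))))
    for (k in seq_along(scheme$windows$labels)) {
      out[[paste0("wdose_", k)]] <- wd[, k]
    }
  }
  out
}

#' Split one worker's follow-up into constant-covariate sub-intervals
#'
#' Partitions `[entry, exit)` at every boundary of every time-dependent
#' axis: birthdays at age-bin edges, calendar-bin edges, duration
#' cutpoints, migration date, monitoring switch dates, plant entries
#' (surrogate category) and the exact times at which the lagged cumulative
#' dose step function crosses a category boundary (dose accrues uniformly
#' within calendar years, so crossings can fall mid-year). Within each
#' sub-interval every axis level is constant; person-years of the parts
#' sum to `exit - entry`.
#'
#' @param w One-row worker tibble with follow-up columns `entry`, `exit`,
#'   `event` (see [apply_followup_rules()]).
#' @param segs,doses,internal The worker's long-format rows.
#' @param scheme A [stratification_scheme()].
#' @return Tibble of sub-intervals with stratum labels, `py`, sub-interval
#'   bounds, the event indicator on the final sub-interval, and
#'   person-year-weighted covariate values (midpoint age/calendar time,
#'   time-averaged lagged doses).
#' @export
split_followup <- function(w, segs, doses, internal, scheme) {
  entry <- w$entry
  exit <- w$exit
  if (!is.finite(entry) || !is.finite(exit) || exit <= entry) {
    return(tibble::tibble())
  }
  br <- numeric(0)
  ax <- scheme$axes
  br <- c(br, w$birth_date + scheme$age_breaks)
  if ("calendar" %in% ax) br <- c(br, scheme$cal_breaks)
  if ("duration" %in% ax) br <- c(br, entry + scheme$dur_breaks)
  if ("migration" %in% ax && !is.na(w$migration_date)) {
    br <- c(br, w$migration_date)
  }
  if ("monitoring" %in% ax && !is.na(w$first_monitoring_date)) {
    lastm <- w$last_monitoring_date %||% w$first_monitoring_date
    br <- c(br, w$first_monitoring_date + 2, lastm + 2)
  }
  if ("surrogate" %in% ax) br <- c(br, segs$start)
  br <- c(br, dose_break_times(doses$year, doses$dose_mgy, scheme$lag,
                               scheme$ext_boundaries, entry, exit))
  if (nrow(internal) > 0L) {
    br <- c(br, dose_break_times(internal$year, internal$dose_mgy, scheme$lag,
                                 scheme$int_boundaries, entry, exit))
  }
  br <- br[is.finite(br) & br > entry & br < exit]
  grid <- sort(unique(c(entry, br, exit)))
  lo <- grid[-length(grid)]
  hi <- grid[-1L]
  mid <- (lo + hi) / 2
  cov <- covariates_at(mid, w, segs, doses, internal, scheme, entry)
  # exact PY-weighted time averages of the lagged doses: D(t - lag) is
  # linear between consecutive break times, so the average is the mean of
  # the endpoint values
  dext_ends <- cumulative_dose_at(doses$year, doses$dose_mgy, grid - scheme$lag)
  cov$.dose_ext <- (dext_ends[-length(grid)] + dext_ends[-1L]) / 2
  if (nrow(internal) > 0L) {
    dint_ends <- cumulative_dose_at(internal$year, internal$dose_mgy,
                                    grid - scheme$lag)
    cov$.dose_int <- (dint_ends[-length(grid)] + dint_ends[-1L]) / 2
  }
  cov$py <- hi - lo
  cov$sub_start <- lo
  cov$sub_end <- hi
  ev <- integer(length(mid))
  if (isTRUE(w$event == 1L)) ev[length(ev)] <- 1L
  cov$event <- ev
  cov$worker_id <- rep(w$worker_id, length(mid))
  tibble::new_tibble(cov, nrow = length(mid))
}

# Aggregate split rows into cells.
aggregate_cells <- function(rows, scheme) {
  key <- intersect(c("sex", "hire_period", "birth_cohort", "smoking",
                     "plant", "age", "calendar", "duration", "migration",
                     "monitoring", "ext_dose", "int_dose", "surrogate"),
                   names(rows))
  wcols <- grep("^wdose_", names(rows), value = TRUE)
  out <- rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      mean_age = stats::weighted.mean(.data$.age_mid, .data$py),
      mean_year = stats::weighted.mean(.data$.year_mid, .data$py),
      mean_dose_ext = stats::weighted.mean(.data$.dose_ext, .data$py),
      mean_dose_int = stats::weighted.mean(.data$.dose_int, .data$py),
      dplyr::across(dplyr::all_of(wcols),
                    ~ stats::weighted.mean(.x, .data$py)),
      events = sum(.data$event),
      py = sum(.data$py),
      .groups = "drop")
  class(out) <- c("pytable", class(out))
  attr(out, "axes") <- key
  out
}

#' Tabulate person-years and events over a cohort
#'
#' Runs [split_followup()] for every worker and accumulates cells: total
#' person-years, event counts for the outcome of interest, and
#' person-year-weighted means of attained age, calendar time, lagged
#' external and internal dose (and window doses when the scheme carries a
#' window specification). The sum of cell person-years equals total
#' follow-up; each death falls in exactly one cell (the cell active at
#' the death time).
#'
#' @param cohort An `err_cohort` with follow-up columns (see
#'   [generate_cohort()]).
#' @param scheme A [stratification_scheme()].
#' @param outcome Which deaths count as events: a cause group
#'   (`"solid_other"`, the default, or `"other"`), a site name (matched
#'   against `death_site`), or a predicate `function(workers) -> logical`.
#' @return A `pytable` tibble: one row per cell with axis levels, `py`,
#'   `events` and weighted covariate means.
#' @export
tabulate_person_years <- function(cohort, scheme = stratification_scheme(),
                                  outcome = "solid_other") {
  w <- cohort$workers
  assert_that(all(c("entry", "exit", "event") %in% names(w)),
              "cohort lacks follow-up columns; run apply_followup_rules()")
  bad <- !is.na(w$death_date) & w$event == 1L &
    (w$death_date < w$entry | w$death_date > w$exit)
  assert_that(!any(bad), "death outside follow-up interval")
  is_case <- outcome_indicator(w, outcome)
  dsplit <- split(cohort$doses, cohort$doses$worker_id)
  isplit <- split(cohort$internal_doses, cohort$internal_doses$worker_id)
  ssplit <- split(cohort$segments, cohort$segments$worker_id)
  empty <- tibble::tibble(year = integer(), dose_mgy = numeric())
  skipped <- 0L
  wcols <- as.list(w)
  rows <- purrr::map(seq_len(nrow(w)), function(i) {
    wi <- lapply(wcols, `[[`, i)
    wi$event <- ifelse(wi$event == 1L & is_case[i], 1L, 0L)
    if (wi$exit <= wi$entry) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    split_followup(wi, ssplit[[wi$worker_id]] %||% empty,
                   dsplit[[wi$worker_id]] %||% empty,
                   isplit[[wi$worker_id]] %||% empty, scheme)
  })
  if (skipped > 0L) {
    message(skipped, " worker(s) with exit <= entry contributed no person-time")
  }
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0L) {
    return(aggregate_cells(
      tibble::tibble(age = character(), py = numeric(), event = integer(),
                     .age_mid = numeric(), .year_mid = numeric(),
                     .dose_ext = numeric(), .dose_int = numeric()),
      scheme))
  }
  aggregate_cells(rows, scheme)
}

outcome_indicator <- function(workers, outcome) {
  if (is.function(outcome)) return(isTRUE_vec(outcome(workers)))
  if (outcome %in% c("solid_other", "other")) {
    !is.na(workers$death_cause) & workers$death_cause == outcome
  } else {
    !is.na(workers$death_site) & workers$death_site == outcome
  }
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Brute-force person-year tabulation (test oracle)
#'
#' Steps through each worker's follow-up in fixed day-sized steps,
#' assigning each step to the stratum active at its midpoint. A slow,
#' simple reference implementation against which [tabulate_person_years()]
#' is verified; not for production use.
#'
#' @inheritParams tabulate_person_years
#' @param step Step size in days (>= 1).
#' @return A `pytable` tibble.
#' @export
brute_force_tabulate <- function(cohort, scheme = stratification_scheme(),
                                 outcome = "solid_other", step = 1) {
  assert_scalar_number(step, "step", min = 1)
  w <- cohort$workers
  is_case <- outcome_indicator(w, outcome)
  dsplit <- split(cohort$doses, cohort$doses$worker_id)
  isplit <- split(cohort$internal_doses, cohort$internal_doses$worker_id)
  ssplit <- split(cohort$segments, cohort$segments$worker_id)
  empty <- tibble::tibble(year = integer(), dose_mgy = numeric())
  h <- step * DAY
  wcols <- as.list(w)
  rows <- purrr::map(seq_len(nrow(w)), function(i) {
    wi <- lapply(wcols, `[[`, i)
    if (wi$exit <= wi$entry) return(NULL)
    lo <- seq(wi$entry, wi$exit, by = h)
    if (lo[length(lo)] >= wi$exit) lo <- lo[-length(lo)]
    hi <- pmin(lo + h, wi$exit)
    mid <- (lo + hi) / 2
    cov <- covariates_at(mid, wi, ssplit[[wi$worker_id]] %||% empty,
                         dsplit[[wi$worker_id]] %||% empty,
                         isplit[[wi$worker_id]] %||% empty, scheme, wi$entry)
    cov$py <- hi - lo
    ev <- integer(length(mid))
    if (wi$event == 1L && is_case[i]) ev[length(ev)] <- 1L
    cov$event <- ev
    tibble::new_tibble(cov, nrow = length(mid))
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0L) {
    return(aggregate_cells(
      tibble::tibble(age = character(), py = numeric(), event = integer(),
                     .age_mid = numeric(), .year_mid = numeric(),
                     .dose_ext = numeric(), .dose_int = numeric()),
      scheme))
  }
  aggregate_cells(rows, scheme)
}

#' Write / read a person-year table as delimited text
#'
#' One row per cell: axis levels as labelled columns, then person-years,
#' event counts and weighted means. The reader re-validates the cell
#' invariants (non-negative person-years, integer event counts).
#'
#' @param table A `pytable`.
#' @param path File path (TSV).
#' @return `read_pytable()` returns a `pytable`.
#' @export
write_pytable <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_pytable
#' @export
read_pytable <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("py", "events") %in% names(x)),
              "not a person-year table: missing py/events")
  assert_that(all(x$py >= 0), "negative person-years")
  assert_that(all(x$events >= 0 & x$events == round(x$events)),
              "event counts must be non-negative integers")
  key <- intersect(c("sex", "hire_period", "birth_cohort", "smoking",
                     "plant", "age", "calendar", "duration", "migration",
                     "monitoring", "ext_dose", "int_dose", "surrogate"),
                   names(x))
  class(x) <- c("pytable", class(x))
  attr(x, "axes") <- key
  x
}
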