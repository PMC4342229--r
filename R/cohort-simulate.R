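# Mortality simulation under a known ERR model, and follow-up rules.

# Baseline cause-of-interest hazard at times t (vectorized) for one worker.
baseline_hazard_at <- function(t, w, truth) {
  age <- t - w$birth_date
  lam <- truth$baseline_rate_60 * (pmax(age, 1) / 60)^truth$age_power
  if (w$sex == "female") lam <- lam * truth$sex_ratio_female
  if (w$smoking == "ever") lam <- lam * truth$smoking_rr
  if (w$smoking == "unknown") lam <- lam * truth$unknown_smoking_rr
  lam <- lam * exp(truth$birth_cohort_trend * (w$birth_date - 1915) / 10)
  if (!is.na(w$migration_date)) {
    lam <- lam * ifelse(t >= w$migration_date, truth$migration_rr, 1)
  }
  if (truth$monitored_rr != 1 && !is.na(w$first_monitoring_date)) {
    mon <- monitoring_status(w$first_monitoring_date, t,
                             w$last_monitoring_date) != "unmonitored"
    lam <- lam * ifelse(mon, truth$monitored_rr, 1)
  }
  lam
}

# Competing (other-cause) hazard at times t.
other_hazard_at <- function(t, w, truth) {
  age <- t - w$birth_date
  truth$other_rate_60 * exp(truth$other_log_slope * (age - 60))
}

#' Simulate death and cause for one worker
#'
#' Draws a death time from a piecewise-constant two-cause hazard process
#' on yearly sub-intervals of `[hire, admin_end)`: the cause-of-interest
#' hazard is `baseline(sex, age, smoking, birth cohort, migration,
#' monitoring) * (1 + ERR(t))` with a linear ERR in 5-year-lagged
#' cumulative external dose (Gy) and, for monitored person-time, lagged
#' internal liver dose (mGy); the competing other-cause death is drawn
#' from an independent cause-specific hazard; the earliest event wins.
#' When the death is from the cause of interest a site is assigned from
#' [site_composition()] with site shares re-weighted by any site-specific
#' true ERRs.
#'
#' @param w One-row worker tibble (as in `err_cohort$workers`).
#' @param doses Worker's external dose rows (`year`, `dose_mgy`).
#' @param internal_doses Worker's internal dose rows, possibly empty.
#' @param truth A [simulation_truth()].
#' @param seed Seed for this worker's stream.
#' @param admin_end Administrative end of follow-up.
#' @param lag Dose lag in years (default 5).
#' @return A list with `death_date` (or `NA`), `death_cause`
#'   (`"solid_other"`, `"other"`, or `NA`) and `death_site`.
#' @export
simulate_event_times <- function(w, doses, internal_doses, truth, seed,
                                 admin_end = 2009, lag = 5) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(seed, {
    breaks <- sort(unique(c(w$hire_date, seq(ceiling(w$hire_date), admin_end),
                            admin_end)))
    breaks <- breaks[breaks >= w$hire_date & breaks <= admin_end]
    lo <- breaks[-length(breaks)]
    hi <- breaks[-1L]
    mid <- (lo + hi) / 2
    lam0 <- baseline_hazard_at(mid, w, truth)
    dext <- cumulative_dose_at(doses$year, doses$dose_mgy, mid - lag) / 1000
    err <- truth$err_per_gy_external * dext
    if (!is.na(w$first_monitoring_date) && truth$err_per_mgy_internal != 0 &&
        nrow(internal_doses) > 0L) {
      mon <- monitoring_status(w$first_monitoring_date, mid,
                               w$last_monitoring_date) != "unmonitored"
      dint <- cumulative_dose_at(internal_doses$year,
                                 internal_doses$dose_mgy, mid - lag)
      err <- err + truth$err_per_mgy_internal * dint * mon
    }
    if (any(1 + err <= 0)) {
      stop("truth yields 1 + ERR <= 0 during follow-up", call. = FALSE)
    }
    lam1 <- lam0 * (1 + err)
    lam2 <- other_hazard_at(mid, w, truth)
    htot <- lam1 + lam2
    E <- stats::rexp(1)
    H <- cumsum(htot * (hi - lo))
    k <- which(H >= E)[1]
    if (is.na(k)) {
      return(list(death_date = NA_real_, death_cause = NA_character_,
                  death_site = NA_character_))
    }
    Hprev <- if (k == 1L) 0 else H[k - 1L]
    tdeath <- lo[k] + (E - Hprev) / htot[k]
    cause <- if (stats::runif(1) < lam1[k] / htot[k]) "solid_other" else "other"
    site <- NA_character_
    if (cause == "solid_other") {
      site <- draw_site(w, dext[k], truth)
    }
    list(death_date = tdeath, death_cause = cause, death_site = site)
  })
}

# Site assignment: shares by sex, re-weighted by site-specific dose response
# relative to the common ERR so that equal site ERRs reduce to fixed shares.
draw_site <- function(w, dose_gy, truth) {
  comp <- site_composition()
  share <- if (w$sex == "female") comp$female else comp$male
  beta <- rep(truth$err_per_gy_external, nrow(comp))
  if (!is.null(truth$site_err)) {
    j <- match(names(truth$site_err), comp$site)
    beta[j[!is.na(j)]] <- truth$site_err[!is.na(j)]
  }
  wgt <- share * (1 + beta * dose_gy)
  if (all(wgt <= 0)) wgt <- share
  sample(comp$site, 1L, prob = wgt)
}

#' Simulate mortality for a whole cohort
#'
#' Applies [simulate_event_times()] to every worker using per-worker seeds
#' split from the master seed.
#'
#' @param cohort An `err_cohort`.
#' @param truth A [simulation_truth()]; defaults to the cohort's.
#' @param seed Master seed; used when `seeds` is not supplied.
#' @param seeds Optional integer vector of per-worker seeds.
#' @param lag Dose lag in years.
#' @return The cohort with `death_date`, `death_cause`, `death_site`
#'   filled in on `workers`.
#' @export
simulate_mortality <- function(cohort, truth = cohort$truth, seed = 1L,
                               seeds = NULL, lag = 5) {
  w <- cohort$workers
  n <- nrow(w)
  if (is.null(seeds)) seeds <- split_seeds(seed, n)
  admin_end <- cohort$config$admin_end %||% 2009
  dsplit <- split(cohort$doses, cohort$doses$worker_id)
  isplit <- split(cohort$internal_doses, cohort$internal_doses$worker_id)
  empty <- tibble::tibble(year = integer(), dose_mgy = numeric())
  wcols <- as.list(w)
  res <- purrr::map(seq_len(n), function(i) {
    simulate_event_times(
      lapply(wcols, `[[`, i),
      dsplit[[w$worker_id[i]]] %||% empty,
      isplit[[w$worker_id[i]]] %||% empty,
      truth, seed = seeds[i] + 2L, admin_end = admin_end, lag = lag)
  })
  w$death_date <- vapply(res, `[[`, numeric(1), "death_date")
  w$death_cause <- vapply(res, `[[`, character(1), "death_cause")
  w$death_site <- vapply(res, `[[`, character(1), "death_site")
  # a death wipes later migration / loss dates drawn independently
  w$migration_date[!is.na(w$death_date) & !is.na(w$migration_date) &
                     w$migration_date >= w$death_date] <- NA_real_
  cohort$workers <- w
  cohort$truth <- truth
  cohort
}

#' Follow-up interval under the censoring rules
#'
#' Entry is the hire date. Exit is the earliest of: death; the
#' administrative end of follow-up; for workers who migrated before the
#' migration cutoff, the cutoff (vital status of such migrants could not
#' be ascertained after it); for later migrants, the migration date; for
#' never-migrants, the date of last known vital status. The event
#' indicator is 1 only when exit equals the death date.
#'
#' @param workers Worker tibble (or one row) with `hire_date`,
#'   `migration_date`, `death_date`, `last_known_date`.
#' @param admin_end Administrative end of follow-up (default 2009,
#'   i.e. the end of 2008).
#' @param migration_cutoff Censoring date for pre-cutoff migrants
#'   (default 2004, i.e. the end of 2003).
#' @return Tibble with `worker_id`, `entry`, `exit`, `event` (0/1 death
#'   observed within follow-up).
#' @export
apply_followup_rules <- function(workers, admin_end = 2009,
                                 migration_cutoff = 2004) {
  assert_that(migration_cutoff <= admin_end,
              "`migration_cutoff` must be <= `admin_end`")
  assert_that(all(admin_end >= workers$hire_date),
              "`admin_end` precedes a hire date")
  death <- workers$death_date
  mig <- workers$migration_date
  lost <- workers$last_known_date
  cens <- ifelse(!is.na(mig),
                 ifelse(mig <= migration_cutoff,
                        migration_cutoff,        # followed until the cutoff
                        pmin(mig, admin_end)),   # lost at migration
                 pmin(ifelse(is.na(lost), admin_end, lost), admin_end))
  cens <- pmin(cens, admin_end)
  exit <- pmin(ifelse(is.na(death), Inf, death), cens)
  event <- as.integer(!is.na(death) & exit == death)
  out <- tibble::tibble(worker_id = workers$worker_id,
                        entry = workers$hire_date, exit = exit,
                        event = event)
  if (any(out$exit < out$entry)) {
    stop("corrupt record: exit precedes entry for worker(s) ",
         paste(utils::head(out$worker_id[out$exit < out$entry], 3),
               collapse = ", "), call. = FALSE)
  }
  out
}
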