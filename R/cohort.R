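# Synthetic cohort generation and mortality simulation.

new_cohort <- function(workers, segments, doses, internal_doses,
                       config = NULL, truth = NULL) {
  structure(list(workers = workers, segments = segments, doses = doses,
                 internal_doses = internal_doses, config = config,
                 truth = truth),
            class = "err_cohort")
}

#' @export
print.err_cohort <- function(x, ...) {
  w <- x$workers
  cat("<err_cohort> ", nrow(w), " workers (",
      sprintf("%.1f%%", 100 * mean(w$sex == "female")), " female), hired ",
      floor(min(w$hire_date)), "-", floor(max(w$hire_date)), "\n", sep = "")
  if ("death_date" %in% names(w)) {
    cat("  deaths simulated: ", sum(!is.na(w$death_date)),
        " (outcome of interest: ",
        sum(!is.na(w$death_cause) & w$death_cause == "solid_other"), ")\n",
        sep = "")
  }
  invisible(x)
}

# Truncated-normal age at hire.
draw_hire_age <- function(n, mean, sd, lo = 16, hi = 60) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic occupational cohort
#'
#' Draws worker demographics, employment segments, annual external (colon)
#' dose series with era-declining means, plutonium monitoring histories and
#' internal liver-dose series with the statistical structure set by
#' `config`, then (by default) simulates mortality under `config$truth`
#' via [simulate_event_times()] and applies the follow-up/censoring rules
#' via [apply_followup_rules()]. Per-worker random streams are split from
#' the master seed, so the result is reproducible independent of
#' generation order.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed (integer); defaults to `config$seed`.
#' @param n Number of workers; defaults to `config$n`.
#' @param simulate Also simulate death/censoring and attach follow-up
#'   columns (`entry`, `exit`, `event`). Default `TRUE`.
#' @return An `err_cohort`: a list of tibbles `workers` (one row per
#'   worker), `segments`, `doses` and `internal_doses` (long format),
#'   carrying `config` and its `truth`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 50), seed = 1)
#' coh$workers
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            n = config$n, simulate = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  assert_that(is.numeric(n) && length(n) == 1L && n >= 1, "`n` must be >= 1")
  assert_that(length(seed) == 1L && is.finite(seed), "`seed` must be given")
  n <- as.integer(n)
  seeds <- split_seeds(seed, n + 1L)

  frame <- with_seed(seeds[n + 1L], {
    workers <- draw_worker_frame(config, n)
    list(workers = workers, segments = draw_segments(workers, config))
  })
  workers <- frame$workers
  segments <- frame$segments
  doses <- draw_doses(workers, segments, config, seeds)
  internal <- draw_internal_doses(workers, segments, config, seeds)
  workers <- attr(internal, "workers")
  attr(internal, "workers") <- NULL

  coh <- new_cohort(workers, segments, doses, internal,
                    config = config, truth = config$truth)
  if (simulate) {
    coh <- simulate_mortality(coh, truth = config$truth, seeds = seeds)
    fu <- apply_followup_rules(coh$workers, admin_end = config$admin_end,
                               migration_cutoff = config$migration_cutoff)
    coh$workers <- dplyr::left_join(coh$workers, fu, by = "worker_id")
  }
  coh
}

draw_worker_frame <- function(config, n) {
  sex <- factor(ifelse(stats::runif(n) < config$female_fraction,
                       "female", "male"), levels = SEX_LEVELS)
  hp <- config$hire_periods
  per <- sample.int(nrow(hp), n, replace = TRUE, prob = hp$weight)
  hire <- hp$from[per] + stats::runif(n) * (hp$to[per] + 1 - hp$from[per])
  age_hire <- draw_hire_age(n, config$hire_age_mean, config$hire_age_sd)
  birth <- hire - age_hire
  plant <- sample(names(config$plant_weights), n, replace = TRUE,
                  prob = config$plant_weights)
  dur <- pmin(pmax(stats::rgamma(n, shape = 2,
                                 scale = config$employment_mean_years / 2),
                   0.5),
              config$admin_end - hire)
  ever_p <- config$smoking_ever_prob[as.character(sex)]
  u <- stats::runif(n)
  smoking <- factor(
    ifelse(stats::runif(n) < config$smoking_unknown_prob, "unknown",
           ifelse(u < ever_p, "ever", "never")),
    levels = SMOKING_LEVELS)
  migration <- rep(NA_real_, n)
  mig <- stats::runif(n) < config$migration_prob
  migration[mig] <- hire[mig] + 2 +
    stats::runif(sum(mig)) * (config$admin_end - hire[mig] - 2)
  lost <- rep(NA_real_, n)
  is_lost <- !mig & stats::runif(n) < config$lost_prob
  lost[is_lost] <- hire[is_lost] + 1 +
    stats::runif(sum(is_lost)) * (config$admin_end - hire[is_lost] - 1)
  tibble::tibble(
    worker_id = sprintf("W%06d", seq_len(n)),
    sex = sex,
    birth_date = birth,
    hire_date = hire,
    employment_end = hire + dur,
    primary_plant = factor(plant, levels = PLANT_LEVELS),
    smoking = smoking,
    migration_date = migration,
    last_known_date = ifelse(is_lost, lost, config$admin_end)
  )
}

draw_segments <- function(workers, config) {
  n <- nrow(workers)
  two <- stats::runif(n) < config$second_plant_prob
  frac <- stats::runif(n, 0.2, 0.8)
  other <- vapply(as.character(workers$primary_plant), function(p) {
    sample(setdiff(PLANT_LEVELS, p), 1L)
  }, character(1))
  # the primary (highest-exposure-potential) plant comes first; careers
  # with a second segment move to another plant at a uniform fraction
  mid <- workers$hire_date + frac * (workers$employment_end -
                                       workers$hire_date)
  k <- ifelse(two, 2L, 1L)
  idx <- rep(seq_len(n), k)
  first <- !duplicated(idx)
  tibble::tibble(
    worker_id = workers$worker_id[idx],
    plant = factor(ifelse(first, as.character(workers$primary_plant)[idx],
                          other[idx]), levels = PLANT_LEVELS),
    start = ifelse(first, workers$hire_date[idx], mid[idx]),
    end = ifelse(first & two[idx], mid[idx], workers$employment_end[idx]))
}

# Annual external colon doses, era-declining lognormal means.
draw_doses <- function(workers, segments, config, seeds) {
  seg_by_worker <- split(seq_len(nrow(segments)), segments$worker_id)
  ids <- character(0); yrs_all <- list(); dose_all <- list()
  for (i in seq_len(nrow(workers))) {
    id <- workers$worker_id[i]
    ki <- seg_by_worker[[id]]
    wd <- with_seed(seeds[i], {
      draw_worker_doses(segments$start[ki], segments$end[ki],
                        as.character(segments$plant[ki]), config)
    })
    if (!is.null(wd)) {
      ids <- c(ids, id)
      yrs_all[[length(yrs_all) + 1L]] <- wd$year
      dose_all[[length(dose_all) + 1L]] <- wd$dose
    }
  }
  nrows <- lengths(yrs_all)
  tibble::tibble(
    worker_id = rep(ids, nrows),
    organ = "colon",
    year = as.integer(unlist(yrs_all) %||% integer(0)),
    dose_mgy = as.numeric(unlist(dose_all) %||% numeric(0)))
}

draw_worker_doses <- function(starts, ends, plants, config) {
  yr_list <- list(); d_list <- list()
  for (k in seq_along(starts)) {
    if (ends[k] - 1e-9 < starts[k]) next
    yrs <- seq(floor(starts[k]), floor(ends[k] - 1e-9))
    # fraction of each calendar year actually worked in this segment
    frac <- pmax(pmin(pmin(yrs + 1, ends[k]) - pmax(yrs, starts[k]), 1), 0)
    m <- config$dose_scale * config$plant_dose_factors[[plants[k]]] *
      exp(-config$dose_decline * (yrs - 1948))
    meanlog <- log(pmax(m, 1e-12)) - config$dose_sdlog^2 / 2
    yr_list[[length(yr_list) + 1L]] <- yrs
    d_list[[length(d_list) + 1L]] <-
      stats::rlnorm(length(yrs), meanlog, config$dose_sdlog) * frac
  }
  if (length(yr_list) == 0L) return(NULL)
  yrs <- unlist(yr_list)
  d <- unlist(d_list)
  if (anyDuplicated(yrs)) {
    agg <- rowsum(d, yrs)
    list(year = as.numeric(rownames(agg)), dose = agg[, 1])
  } else {
    ord <- order(yrs)
    list(year = yrs[ord], dose = d[ord])
  }
}

draw_internal_doses <- function(workers, segments, config, seeds) {
  n <- nrow(workers)
  pu_plants <- c("radiochemical", "plutonium_auxiliary",
                 "plutonium_main2", "plutonium_main1")
  seg_by_worker <- split(seq_len(nrow(segments)), segments$worker_id)
  firsts <- rep(NA_real_, n); lasts <- rep(NA_real_, n)
  ids <- character(0); yrs_all <- list(); dose_all <- list()
  # internal doses re-use the external dose machinery with the internal
  # scale/factors; only Pu-plant segments contribute
  icfg <- config
  icfg$dose_scale <- config$internal_dose_scale
  icfg$plant_dose_factors <- config$internal_plant_factors
  icfg$dose_sdlog <- 1
  for (i in seq_len(n)) {
    id <- workers$worker_id[i]
    ki <- seg_by_worker[[id]]
    plants <- as.character(segments$plant[ki])
    pu <- plants %in% pu_plants
    if (!any(pu)) next
    res <- with_seed(seeds[i] + 1L, {
      if (stats::runif(1) >= config$monitoring_prob) {
        NULL
      } else {
        first <- max(workers$hire_date[i] +
                       stats::runif(1, 0.5, config$monitoring_delay_max),
                     config$monitoring_earliest)
        if (first >= config$admin_end) {
          NULL
        } else {
          last <- max(first, min(workers$employment_end[i],
                                 config$admin_end - 1))
          wd <- draw_worker_doses(segments$start[ki][pu],
                                  segments$end[ki][pu], plants[pu], icfg)
          list(first = first, last = last, wd = wd)
        }
      }
    })
    if (is.null(res)) next
    firsts[i] <- res$first
    lasts[i] <- res$last
    if (!is.null(res$wd)) {
      ids <- c(ids, id)
      yrs_all[[length(yrs_all) + 1L]] <- res$wd$year
      dose_all[[length(dose_all) + 1L]] <- res$wd$dose
    }
  }
  workers$first_monitoring_date <- firsts
  workers$last_monitoring_date <- lasts
  doses <- tibble::tibble(
    worker_id = rep(ids, lengths(yrs_all)),
    year = as.integer(unlist(yrs_all) %||% integer(0)),
    dose_mgy = as.numeric(unlist(dose_all) %||% numeric(0)))
  attr(doses, "workers") <- workers
  doses
}
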