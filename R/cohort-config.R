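# Generator configuration and simulation truth.

#' True generator parameters for mortality simulation
#'
#' The "truth" against which parameter recovery is tested. Baseline rates
#' follow a log-linear model in attained age (a power law), sex, smoking,
#' birth-cohort trend, residence (migration) and, optionally, monitoring
#' status; the radiation excess is multiplicative:
#' rate = baseline * (1 + ERR), with a linear ERR in 5-year-lagged
#' cumulative external dose and (optionally) internal liver dose.
#'
#' Defaults are the point estimates that the analysis this package
#' implements is expected to recover in a cohort of this structure:
#' baseline cancer mortality rising as attained age to the fifth power, a
#' female:male baseline ratio of 0.8, an ever/never-smoker rate ratio of
#' 1.5, post-migration mortality 15% lower, and an external ERR of
#' 0.16 per Gy.
#'
#' @param baseline_rate_60 Cause-of-interest baseline rate per person-year
#'   at attained age 60 for a male never-smoker resident (default 2e-3).
#' @param age_power Exponent of attained age in the baseline (default 5).
#' @param sex_ratio_female Female:male baseline rate ratio (default 0.8).
#' @param smoking_rr Ever/never-smoker rate ratio (default 1.5).
#' @param unknown_smoking_rr Rate ratio for unknown smoking status
#'   (default 1.2, between never and ever).
#' @param birth_cohort_trend Log-rate slope per decade of birth year
#'   (default 0).
#' @param migration_rr Post-migration rate ratio (default 0.85).
#' @param monitored_rr Baseline rate ratio for monitored vs unmonitored
#'   workers (default 1: no monitoring selection effect; set to e.g. 1.16
#'   to emulate health-based selection into monitoring).
#' @param err_per_gy_external True linear external ERR per Gy (default 0.16).
#' @param err_per_mgy_internal True linear internal ERR per mGy liver dose
#'   (default 0: no printed point estimate exists for this slope).
#' @param site_err Optional named vector of site-specific external ERR/Gy,
#'   overriding `err_per_gy_external` for those sites.
#' @param other_rate_60 Competing (other-cause) mortality rate at age 60
#'   (default 0.015).
#' @param other_log_slope Log-linear slope of the competing hazard per year
#'   of age (default log(2)/8: doubling every 8 years).
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(baseline_rate_60 = 2e-3,
                             age_power = 5,
                             sex_ratio_female = 0.8,
                             smoking_rr = 1.5,
                             unknown_smoking_rr = 1.2,
                             birth_cohort_trend = 0,
                             migration_rr = 0.85,
                             monitored_rr = 1,
                             err_per_gy_external = 0.16,
                             err_per_mgy_internal = 0,
                             site_err = NULL,
                             other_rate_60 = 0.015,
                             other_log_slope = log(2) / 8) {
  for (nm in c("baseline_rate_60", "sex_ratio_female", "smoking_rr",
               "unknown_smoking_rr", "migration_rr", "monitored_rr",
               "other_rate_60")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  rm(nm)
  assert_that(is.finite(age_power), "`age_power` must be finite")
  structure(as.list(environment()), class = "simulation_truth")
}

#' Cohort generator configuration
#'
#' Settings controlling the structure of a synthetic occupational cohort:
#' size, sex mix, hire-year distribution, plant assignment, era-declining
#' annual external doses, plutonium monitoring, smoking, migration and
#' loss to follow-up. Defaults emulate a plutonium-production worker
#' cohort of ~25% women hired 1948-1982 across six plant groups, with
#' annual external doses declining steeply over calendar time so that the
#' cohort mean 5-year-lagged cumulative external (colon) dose at end of
#' follow-up is about 354 mGy.
#'
#' @param n Number of workers (>= 1).
#' @param seed Default master seed used by [generate_cohort()].
#' @param female_fraction Proportion of women (default 0.25).
#' @param hire_periods Tibble of hire-period weights (`from`, `to`,
#'   `weight`); hire year is drawn by period then uniformly within it.
#' @param plant_weights Named weights for primary plant assignment.
#' @param hire_age_mean,hire_age_sd Age-at-hire distribution (normal,
#'   truncated to `[16, 60]`).
#' @param employment_mean_years Mean employment duration (gamma, shape 2),
#'   capped at the administrative end of follow-up.
#' @param second_plant_prob Probability a career includes a move to a
#'   second plant (segment split at a uniform fraction of employment).
#' @param dose_scale Mean annual external dose (mGy/yr) in 1948 for a
#'   plant factor of 1.
#' @param dose_decline Exponential decline rate of mean annual dose per
#'   calendar year since 1948.
#' @param dose_sdlog Log-sd of the annual dose lognormal.
#' @param plant_dose_factors Named multipliers of the era mean dose.
#' @param monitoring_prob Probability that a radiochemical/plutonium-plant
#'   worker is monitored for plutonium.
#' @param monitoring_delay_max Latest first-monitoring delay after hire
#'   (years, uniform); first monitoring never precedes
#'   `monitoring_earliest`.
#' @param monitoring_earliest Calendar year monitoring begins.
#' @param internal_dose_scale Mean annual liver dose (mGy/yr) for a
#'   monitored plutonium_main1 worker in 1948 (scaled by plant factor and
#'   the same era decline).
#' @param internal_plant_factors Named multipliers for internal dose.
#' @param smoking_ever_prob Named (male/female) ever-smoker probabilities.
#' @param smoking_unknown_prob Probability smoking status is unknown.
#' @param migration_prob Probability of migrating during follow-up.
#' @param lost_prob Probability a never-migrant is lost to follow-up
#'   before the administrative end.
#' @param admin_end Administrative end of follow-up (fractional years;
#'   default 2009 = end of 2008).
#' @param migration_cutoff Date after which migrants can no longer be
#'   followed (default 2004 = end of 2003).
#' @param organ_dose_factors Named multipliers converting the external
#'   colon-dose series to other organ doses (personal dose equivalent
#'   `hp10` is noticeably higher than colon dose; other organs are close
#'   to colon).
#' @param truth A [simulation_truth()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 1000,
                          seed = 1L,
                          female_fraction = 0.25,
                          hire_periods = default_hire_periods(),
                          plant_weights = default_plant_weights(),
                          hire_age_mean = 25,
                          hire_age_sd = 6,
                          employment_mean_years = 18,
                          second_plant_prob = 0.2,
                          dose_scale = 125,
                          dose_decline = 0.105,
                          dose_sdlog = 1,
                          plant_dose_factors = default_plant_dose_factors(),
                          monitoring_prob = 0.4,
                          monitoring_delay_max = 15,
                          monitoring_earliest = 1960,
                          internal_dose_scale = 330,
                          internal_plant_factors = default_internal_plant_factors(),
                          smoking_ever_prob = c(male = 0.6, female = 0.1),
                          smoking_unknown_prob = 0.1,
                          migration_prob = 0.25,
                          lost_prob = 0.05,
                          admin_end = 2009,
                          migration_cutoff = 2004,
                          organ_dose_factors = default_organ_dose_factors(),
                          truth = simulation_truth()) {
  assert_that(is.numeric(n) && length(n) == 1L && n >= 1, "`n` must be >= 1")
  n <- as.integer(n)
  assert_prob(female_fraction, "female_fraction")
  assert_prob(monitoring_prob, "monitoring_prob")
  assert_prob(migration_prob, "migration_prob")
  assert_prob(second_plant_prob, "second_plant_prob")
  assert_prob(lost_prob, "lost_prob")
  assert_prob(smoking_unknown_prob, "smoking_unknown_prob")
  assert_that(migration_cutoff <= admin_end,
              "`migration_cutoff` must be <= `admin_end`")
  assert_that(inherits(truth, "simulation_truth"),
              "`truth` must be a simulation_truth()")
  structure(as.list(environment()), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_hire_periods <- function() {
  tibble::tibble(
    from = c(1948, 1954, 1959, 1964, 1973),
    to = c(1953, 1958, 1963, 1972, 1982),
    weight = c(9213, 4221, 4378, 3675, 4270)
  )
}

#' @rdname cohort_config
#' @export
default_plant_weights <- function() {
  c(auxiliary = 3384, reactor = 5416, radiochemical = 9194,
    plutonium_auxiliary = 3505, plutonium_main2 = 1994,
    plutonium_main1 = 2264)
}

#' @rdname cohort_config
#' @export
default_plant_dose_factors <- function() {
  c(auxiliary = 0.21, reactor = 0.94, radiochemical = 1.70,
    plutonium_auxiliary = 0.32, plutonium_main2 = 0.44,
    plutonium_main1 = 1.01)
}

#' @rdname cohort_config
#' @export
default_internal_plant_factors <- function() {
  c(auxiliary = 0, reactor = 0, radiochemical = 0.45,
    plutonium_auxiliary = 0.35, plutonium_main2 = 0.55,
    plutonium_main1 = 1)
}

#' @rdname cohort_config
#' @export
default_organ_dose_factors <- function() {
  c(colon = 1, esophagus = 1, stomach = 1, rectum = 1, pancreas = 1,
    bladder = 1, kidney = 1, brain = 0.95, larynx = 1, prostate = 1,
    breast = 1.05, ovary = 1, uterus = 1, hp10 = 1.44, other = 1)
}

#' Site composition of the simulated cancer outcome
#'
#' Sex-specific relative shares used to assign a site to each simulated
#' death from the outcome group (solid cancers outside the main plutonium
#' deposition organs), together with the organ whose dose drives each
#' site's risk.
#'
#' @return Tibble with columns `site`, `organ`, `male`, `female` (shares).
#' @export
site_composition <- function() {
  tibble::tribble(
    ~site,       ~organ,      ~male, ~female,
    "stomach",   "stomach",   374,   78,
    "colon",     "colon",     110,   46,
    "rectum",    "rectum",    103,   43,
    "pancreas",  "pancreas",  103,   25,
    "breast",    "breast",    0,     107,
    "prostate",  "prostate",  80,    0,
    "kidney",    "kidney",    61,    17,
    "melanoma",  "hp10",      23,    15,
    "larynx",    "larynx",    66,    2,
    "esophagus", "esophagus", 58,    8,
    "brain",     "brain",     58,    8,
    "bladder",   "bladder",   62,    1,
    "ovary",     "ovary",     0,     43,
    "uterus",    "uterus",    0,     36,
    "other",     "colon",     236,   65
  )
}

#' Write or read a generator configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_config()` returns a `cohort_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$truth <- unclass(x$truth)
  x$hire_periods <- as.list(x$hire_periods)
  # yaml serializes named atomic vectors as plain sequences; convert the
  # named-vector fields to lists so their names survive as map keys
  for (nm in c("plant_weights", "plant_dose_factors",
               "internal_plant_factors", "smoking_ever_prob",
               "organ_dose_factors")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  if (!is.null(x$truth$site_err)) x$truth$site_err <- as.list(x$truth$site_err)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$hire_periods <- tibble::as_tibble(x$hire_periods)
  for (nm in c("plant_weights", "plant_dose_factors", "internal_plant_factors",
               "smoking_ever_prob", "organ_dose_factors")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  site_err <- x$truth$site_err
  x$truth$site_err <- NULL
  truth_args <- x$truth
  truth_args$site_err <- if (!is.null(site_err)) unlist(site_err)
  x$truth <- do.call(simulation_truth, truth_args)
  do.call(cohort_config, x)
}
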