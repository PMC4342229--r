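# Shared fixtures: hand-built workers, histories and tables.

make_history <- function(years, dose_mgy) {
  tibble::tibble(year = years, dose_mgy = dose_mgy)
}

# One-row worker tibble with sensible defaults; override any field.
make_worker <- function(worker_id = "W1", sex = "male", birth_date = 1925,
                        hire_date = 1950, employment_end = 1970,
                        primary_plant = "reactor", smoking = "never",
                        migration_date = NA_real_,
                        first_monitoring_date = NA_real_,
                        last_monitoring_date = NA_real_,
                        death_date = NA_real_,
                        death_cause = NA_character_,
                        death_site = NA_character_,
                        last_known_date = 2009,
                        entry = hire_date, exit = 2009, event = 0L) {
  tibble::tibble(
    worker_id = worker_id,
    sex = factor(sex, levels = c("male", "female")),
    birth_date = birth_date, hire_date = hire_date,
    employment_end = employment_end,
    primary_plant = factor(primary_plant,
                           levels = c("auxiliary", "reactor",
                                      "radiochemical",
                                      "plutonium_auxiliary",
                                      "plutonium_main2",
                                      "plutonium_main1")),
    smoking = factor(smoking, levels = c("ever", "never", "unknown")),
    migration_date = migration_date,
    last_known_date = last_known_date,
    first_monitoring_date = first_monitoring_date,
    last_monitoring_date = last_monitoring_date,
    death_date = death_date, death_cause = death_cause,
    death_site = death_site,
    entry = entry, exit = exit, event = event)
}

make_segments <- function(worker_id = "W1", plant = "reactor",
                          start = 1950, end = 1970) {
  tibble::tibble(worker_id = worker_id,
                 plant = factor(plant,
                                levels = levels(make_worker()$primary_plant)),
                 start = start, end = end)
}

# Minimal hand-built cohort from worker/segment/dose pieces.
make_cohort <- function(workers, segments = NULL, doses = NULL,
                        internal_doses = NULL) {
  if (is.null(segments)) {
    segments <- make_segments(workers$worker_id,
                              as.character(workers$primary_plant),
                              workers$hire_date, workers$employment_end)
  }
  if (is.null(doses)) {
    doses <- tibble::tibble(worker_id = character(), organ = character(),
                            year = integer(), dose_mgy = numeric())
  }
  if (is.null(internal_doses)) {
    internal_doses <- tibble::tibble(worker_id = character(),
                                     year = integer(), dose_mgy = numeric())
  }
  structure(list(workers = workers, segments = segments, doses = doses,
                 internal_doses = internal_doses,
                 config = NULL, truth = NULL),
            class = "err_cohort")
}

two_cell_table <- function() {
  tibble::tibble(mean_dose_ext = c(0, 1000), py = c(1000, 1000),
                 events = c(50L, 60L), mean_age = 60, mean_year = 1980)
}

coarse_axes <- c("sex", "age", "calendar", "ext_dose")
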