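# Cohort file round-trip and record validation.

#' Write / read a cohort as delimited text
#'
#' A cohort is stored as a directory of tab-separated files: `workers.tsv`
#' (one row per worker, scalar fields), `segments.tsv`, `doses.tsv` and
#' `internal_doses.tsv` (long format), plus `config.yml` when the cohort
#' carries its generator configuration. The round trip is lossless.
#'
#' @param cohort An `err_cohort`.
#' @param dir Directory (created if needed).
#' @return `read_cohort()` returns an `err_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "err_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$workers, file.path(dir, "workers.tsv"))
  readr::write_tsv(cohort$segments, file.path(dir, "segments.tsv"))
  readr::write_tsv(cohort$doses, file.path(dir, "doses.tsv"))
  readr::write_tsv(cohort$internal_doses, file.path(dir, "internal_doses.tsv"))
  if (!is.null(cohort$config)) {
    write_config(cohort$config, file.path(dir, "config.yml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  # numeric fields are read as text and converted with as.numeric: the
  # shortest decimal representation then reproduces the original double
  # bit-for-bit, making the round trip lossless
  read_exact <- function(path, int_cols = character(0)) {
    x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = "NA")
    char_cols <- c("worker_id", "sex", "smoking", "primary_plant",
                   "death_cause", "death_site", "plant", "organ")
    for (cn in setdiff(names(x), char_cols)) {
      x[[cn]] <- if (cn %in% int_cols) as.integer(x[[cn]]) else
        as.numeric(x[[cn]])
    }
    x
  }
  workers <- read_exact(file.path(dir, "workers.tsv"), int_cols = "event")
  workers$sex <- factor(workers$sex, levels = SEX_LEVELS)
  workers$smoking <- factor(workers$smoking, levels = SMOKING_LEVELS)
  workers$primary_plant <- factor(workers$primary_plant,
                                  levels = PLANT_LEVELS)
  segments <- read_exact(file.path(dir, "segments.tsv"))
  segments$plant <- factor(segments$plant, levels = PLANT_LEVELS)
  doses <- read_exact(file.path(dir, "doses.tsv"), int_cols = "year")
  internal <- read_exact(file.path(dir, "internal_doses.tsv"),
                         int_cols = "year")
  cfg_path <- file.path(dir, "config.yml")
  config <- if (file.exists(cfg_path)) read_config(cfg_path)
  coh <- new_cohort(workers, segments, doses, internal, config = config,
                    truth = if (!is.null(config)) config$truth)
  validate_cohort(coh)
  coh
}

#' Validate cohort record invariants
#'
#' Checks that hire follows birth by at least 10 years, employment
#' segments are ordered and non-overlapping within worker, annual doses
#' are non-negative, any death is not before hire, and hire years lie in
#' the configured window.
#'
#' @param cohort An `err_cohort`.
#' @param hire_window Allowed hire-year range (default 1948-1982).
#' @return The cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort, hire_window = c(1948, 1982)) {
  w <- cohort$workers
  assert_that(all(w$hire_date >= w$birth_date + 10),
              "hire_date must be >= birth_date + 10 years")
  assert_that(all(floor(w$hire_date) >= hire_window[1] &
                    floor(w$hire_date) <= hire_window[2]),
              "hire year outside configured window")
  if ("death_date" %in% names(w)) {
    ok <- is.na(w$death_date) | w$death_date >= w$hire_date
    assert_that(all(ok), "death date precedes hire date")
  }
  assert_that(all(cohort$doses$dose_mgy >= 0), "negative annual dose")
  assert_that(all(cohort$internal_doses$dose_mgy >= 0),
              "negative annual internal dose")
  seg_ok <- cohort$segments |>
    dplyr::arrange(.data$worker_id, .data$start) |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(
      ok = all(.data$end >= .data$start) &&
        (dplyr::n() == 1L ||
           all(utils::head(.data$end, -1) <= utils::tail(.data$start, -1) + 1e-9)),
      .groups = "drop")
  assert_that(all(seg_ok$ok), "employment segments overlap or are unordered")
  invisible(cohort)
}
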