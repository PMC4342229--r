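# Synthetic cohort generation, mortality simulation, follow-up rules.

test_that("generation is deterministic and respects record invariants", {
  c1 <- generate_cohort(cohort_config(n = 120), seed = 5)
  c2 <- generate_cohort(cohort_config(n = 120), seed = 5)
  expect_identical(c1$workers, c2$workers)
  expect_identical(c1$doses, c2$doses)
  expect_identical(c1$internal_doses, c2$internal_doses)
  c3 <- generate_cohort(cohort_config(n = 120), seed = 6)
  expect_false(identical(c1$workers, c3$workers))
  expect_silent(validate_cohort(c1))
  w <- c1$workers
  expect_true(all(w$hire_date >= w$birth_date + 10))
  expect_true(all(floor(w$hire_date) >= 1948 & floor(w$hire_date) <= 1982))
  # monitoring only among radiochemical/plutonium workers
  mon_ids <- w$worker_id[!is.na(w$first_monitoring_date)]
  pu <- c("radiochemical", "plutonium_auxiliary", "plutonium_main2",
          "plutonium_main1")
  seg_pu <- c1$segments |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(any_pu = any(as.character(.data$plant) %in% pu))
  expect_true(all(seg_pu$any_pu[match(mon_ids, seg_pu$worker_id)]))
})

test_that("degenerate and invalid generator inputs are handled", {
  c1 <- generate_cohort(cohort_config(n = 1), seed = 3)
  expect_equal(nrow(c1$workers), 1L)
  expect_silent(validate_cohort(c1))
  expect_error(cohort_config(n = 0), ">= 1")
  expect_error(cohort_config(female_fraction = 1.2), "probability")
  expect_error(generate_cohort(cohort_config(n = 10), seed = NULL), "seed")
})

test_that("female fraction matches the configured proportion", {
  coh <- generate_cohort(cohort_config(n = 1000), seed = 1,
                         simulate = FALSE)
  nf <- sum(coh$workers$sex == "female")
  expect_gt(nf, 200)   # binomial 99.9% band around 250
  expect_lt(nf, 300)
})

test_that("era-declining doses hit the cohort mean lagged-dose target", {
  coh <- generate_cohort(cohort_config(n = 5000), seed = 2)
  w <- coh$workers
  ds <- split(coh$doses, coh$doses$worker_id)
  cum <- vapply(seq_len(nrow(w)), function(i) {
    d <- ds[[w$worker_id[i]]]
    if (is.null(d)) 0 else
      cumulative_lagged_dose(d, lag = 5, t = w$exit[i])
  }, numeric(1))
  expect_gt(mean(cum), 354 * 0.8)
  expect_lt(mean(cum), 354 * 1.2)
  # doses decline across hire eras
  by_era <- tapply(cum, findInterval(floor(w$hire_date),
                                     c(1948, 1959, 1973)), mean)
  expect_true(all(diff(by_era) < 0))
})

test_that("null hazards produce no deaths and full follow-up", {
  truth0 <- simulation_truth(baseline_rate_60 = 0, other_rate_60 = 0)
  coh <- generate_cohort(cohort_config(n = 40, truth = truth0,
                                       migration_prob = 0, lost_prob = 0),
                         seed = 9)
  expect_true(all(is.na(coh$workers$death_date)))
  expect_true(all(coh$workers$exit == 2009))
  expect_true(all(coh$workers$event == 0L))
})

test_that("a constant total hazard yields exponential death times", {
  # age_power 0 and a flat competing hazard make the all-cause hazard
  # constant; simulated times must follow Exponential(h)
  h <- 0.05
  truth <- simulation_truth(baseline_rate_60 = h / 2, age_power = 0,
                            sex_ratio_female = 1, smoking_rr = 1,
                            unknown_smoking_rr = 1, migration_rr = 1,
                            err_per_gy_external = 0,
                            other_rate_60 = h / 2, other_log_slope = 0)
  w <- make_worker(hire_date = 1950, employment_end = 1960,
                   birth_date = 1925)
  empty <- tibble::tibble(year = integer(), dose_mgy = numeric())
  times <- vapply(1:5000, function(s) {
    r <- simulate_event_times(w, empty, empty, truth, seed = s,
                              admin_end = 2400)   # P(T > 450) ~ 0
    r$death_date - 1950
  }, numeric(1))
  ks <- stats::ks.test(times, stats::pexp, rate = h)
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(times), 1 / h, tolerance = 0.05)
})

test_that("with zero dose effect, death rates are flat across dose tertiles", {
  truth <- simulation_truth(err_per_gy_external = 0)
  coh <- generate_cohort(cohort_config(n = 10000, truth = truth), seed = 4)
  w <- coh$workers
  ds <- split(coh$doses, coh$doses$worker_id)
  cum <- vapply(seq_len(nrow(w)), function(i) {
    d <- ds[[w$worker_id[i]]]
    if (is.null(d)) 0 else cumulative_lagged_dose(d, 5, w$exit[i])
  }, numeric(1))
  case <- !is.na(w$death_cause) & w$death_cause == "solid_other" &
    w$event == 1L
  py <- w$exit - w$entry
  ter <- cut(cum, stats::quantile(cum, c(0, 1 / 3, 2 / 3, 1)),
             include.lowest = TRUE, labels = FALSE)
  rates <- tapply(case, ter, sum) / tapply(py, ter, sum)
  # crude rate ratios near 1 (age confounding aside, no dose gradient)
  rr <- rates / rates[1]
  expect_true(all(rr > 0.5 & rr < 2))
})

test_that("follow-up censoring rules match the migration cutoff design", {
  # migrated 1990, alive in 2004 -> censored at the end of 2003
  w1 <- make_worker(migration_date = 1990.5)
  fu1 <- apply_followup_rules(w1)
  expect_equal(fu1$exit, 2004)
  expect_equal(fu1$event, 0L)
  # migrating after the cutoff -> lost at the migration date
  w2 <- make_worker(migration_date = 2005.4)
  fu2 <- apply_followup_rules(w2)
  expect_equal(fu2$exit, 2005.4)
  expect_equal(fu2$event, 0L)
  # death in residence before any censoring -> event at the death date
  w3 <- make_worker(death_date = 1980.2, death_cause = "solid_other")
  fu3 <- apply_followup_rules(w3)
  expect_equal(fu3$exit, 1980.2)
  expect_equal(fu3$event, 1L)
  # migrant who died before the cutoff keeps the death
  w4 <- make_worker(migration_date = 1990, death_date = 1995.1,
                    death_cause = "other")
  fu4 <- apply_followup_rules(w4)
  expect_equal(fu4$exit, 1995.1)
  expect_equal(fu4$event, 1L)
  # never-migrant lost to follow-up censors at last known date
  w5 <- make_worker(last_known_date = 1999.9)
  fu5 <- apply_followup_rules(w5)
  expect_equal(fu5$exit, 1999.9)
  expect_equal(fu5$event, 0L)
  # corrupt record signals
  w6 <- make_worker(hire_date = 1950, last_known_date = 1940)
  expect_error(apply_followup_rules(w6), "corrupt")
})

test_that("follow-up intervals never pass admin_end; events mean death", {
  coh <- generate_cohort(cohort_config(n = 400), seed = 12)
  fu <- coh$workers
  expect_true(all(fu$exit <= 2009))
  expect_true(all(fu$exit >= fu$entry))
  ev <- fu$event == 1L
  expect_true(all(fu$exit[ev] == fu$death_date[ev]))
  expect_true(all(is.na(fu$death_date[!ev]) |
                    fu$death_date[!ev] > fu$exit[!ev] |
                    fu$death_date[!ev] < fu$entry[!ev]))
})

test_that("never-smoker age-specific rates recover the age power", {
  truth <- simulation_truth(err_per_gy_external = 0)
  coh <- generate_cohort(cohort_config(n = 12000, truth = truth,
                                       smoking_ever_prob = c(male = 0,
                                                             female = 0),
                                       smoking_unknown_prob = 0,
                                       migration_prob = 0),
                         seed = 8)
  tab <- tabulate_person_years(coh,
                               stratification_scheme(axes = c("age")))
  tab <- tab[tab$events > 0 & tab$py > 0, ]
  fitl <- stats::lm(log(events / py) ~ log(mean_age / 60), data = tab,
                    weights = events)
  expect_lt(abs(unname(stats::coef(fitl)[2]) - 5), 0.2)
})
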