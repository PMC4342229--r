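# ERR model evaluation, likelihood, fitting, LRT, profile CIs,
# attribution.

test_that("composite ERR evaluation matches hand arithmetic", {
  cells <- tibble::tibble(mean_dose_ext = c(500, 0), py = 1, events = 0L,
                          mean_age = 60, mean_year = 1990)
  m <- err_model(~1, err_linear("mean_dose_ext"))
  expect_equal(evaluate_err(m, c(0, 0.16), cells), c(0.08, 0))
  mck <- err_model(~1, err_cell_killing("mean_dose_ext"))
  cells2 <- tibble::tibble(mean_dose_ext = 1000, py = 1, events = 0L,
                           mean_age = 60, mean_year = 1990)
  expect_equal(evaluate_err(mck, c(0, 0.11, 0.02), cells2),
               0.11 * exp(-0.02))
  # unmonitored zero-dose cell with surrogate category 0 has ERR 0
  cells3 <- tibble::tibble(mean_dose_ext = 0, mean_dose_int = 0,
                           surrogate = c(0L, 1L), monitoring = "unmonitored",
                           py = 1, events = 0L, mean_age = 60,
                           mean_year = 1990)
  ms <- err_model(~1, list(err_linear("mean_dose_ext"), err_surrogate()))
  e <- evaluate_err(ms, c(0, 0.16, 0.4), cells3)
  expect_equal(e, c(0, 0.4))
  # inadmissible points signal
  expect_error(evaluate_err(m, c(0, -3), cells), "inadmissible")
})

test_that("expected counts are PY x baseline x (1 + ERR)", {
  cells <- tibble::tibble(mean_dose_ext = c(1000, 1000, 0),
                          py = c(1000, 0, 500), events = 0L,
                          mean_age = 60, mean_year = 1990)
  m <- err_model(~1, err_linear("mean_dose_ext"))
  mu <- expected_count(m, c(log(0.05), 0.2), cells)
  expect_equal(mu, c(0.05 * 1000 * 1.2, 0, 0.05 * 500))
})

test_that("loglik matches the saturated Poisson model at the MLE", {
  tab <- two_cell_table()
  m <- err_model(~1, err_linear("mean_dose_ext"))
  f <- fit_err(m, tab)
  ll_sat <- sum(tab$events * log(tab$events) - tab$events)
  expect_equal(f$loglik, ll_sat, tolerance = 1e-10)
  # shifting the log-baseline intercept changes loglik by a closed-form
  # amount: ll(g0 + c) = ll(g0) + c * sum(e) - (exp(c) - 1) * sum(mu)
  p <- unname(f$params)
  cshift <- 0.3
  ll1 <- loglik(m, p, tab)
  ll2 <- loglik(m, p + c(cshift, 0), tab)
  mu <- sum(expected_count(m, p, tab))
  expect_equal(ll2 - ll1,
               cshift * sum(tab$events) - (exp(cshift) - 1) * mu,
               tolerance = 1e-10)
  # all-zero events: loglik tends to 0 from below as mu -> 0
  tab0 <- dplyr::mutate(two_cell_table(), events = 0L)
  lls <- vapply(c(-5, -10, -20), function(g0) loglik(m, c(g0, 0), tab0),
                numeric(1))
  expect_true(all(lls < 0) && all(diff(lls) > 0))
  expect_gt(lls[3], -1e-5)
})

test_that("the two-cell saturated example has its closed-form MLE", {
  f <- fit_err(err_model(~1, err_linear("mean_dose_ext")),
               two_cell_table())
  expect_equal(unname(exp(f$params[1])), 0.05, tolerance = 1e-8)
  expect_equal(unname(f$params[2]), 0.2, tolerance = 1e-8)
  expect_true(f$converged)
  # baseline-only model pools events over person-time
  f0 <- fit_err(err_model(~1), two_cell_table())
  expect_equal(unname(exp(f0$params[1])), 110 / 2000, tolerance = 1e-8)
})

test_that("likelihood-ratio tests behave at the null and under nesting", {
  tab <- two_cell_table()
  f1 <- fit_err(err_model(~1, err_linear("mean_dose_ext")), tab)
  expect_equal(lrt(f1, f1)$statistic, 0)
  expect_equal(lrt(f1, f1)$p_value, 1)
  # linear vs linear-quadratic on two cells: the quadratic is absorbed,
  # statistic 0 with df 1 and the rank deficiency flagged
  f2 <- fit_err(err_model(~1, err_linear_quadratic("mean_dose_ext")), tab,
                start = c(unname(f1$params), 0))
  out <- lrt(f1, f2)
  expect_lt(out$statistic, 1e-6)
  expect_equal(out$df, 1L)
  expect_equal(out$p_value, 1, tolerance = 1e-6)
  expect_match(out$flag, "rank_deficient")
})

test_that("nested response shapes reproduce the linear loglik", {
  coh <- generate_cohort(cohort_config(n = 250), seed = 41)
  tab <- tabulate_person_years(coh,
                               stratification_scheme(axes = coarse_axes))
  base <- ~ log(pmax(mean_age, 1) / 60) + sex
  flin <- fit_err(err_model(base, err_linear("mean_dose_ext")), tab)
  p <- unname(flin$params)
  # evaluation identities at the nested point
  expect_equal(loglik(err_model(base, err_cell_killing("mean_dose_ext")),
                      c(p, 0), tab), flin$loglik, tolerance = 1e-12)
  expect_equal(loglik(err_model(base, err_linear_quadratic("mean_dose_ext")),
                      c(p, 0), tab), flin$loglik, tolerance = 1e-12)
  expect_equal(loglik(err_model(base, err_threshold("mean_dose_ext",
                                                    threshold = 0)),
                      p, tab), flin$loglik, tolerance = 1e-12)
  # fitted nestings can only improve on the linear fit
  flq <- fit_err(err_model(base, err_linear_quadratic("mean_dose_ext")),
                 tab, start = c(p, 0))
  fck <- fit_err(err_model(base, err_cell_killing("mean_dose_ext")),
                 tab, start = c(p, 0))
  expect_gte(flq$loglik, flin$loglik - 1e-8)
  expect_gte(fck$loglik, flin$loglik - 1e-8)
})

test_that("rescaling dose units rescales the slope and not the loglik", {
  coh <- generate_cohort(cohort_config(n = 250), seed = 43)
  tab <- tabulate_person_years(coh,
                               stratification_scheme(axes = coarse_axes))
  base <- ~ log(pmax(mean_age, 1) / 60)
  f_gy <- fit_err(err_model(base, err_linear("mean_dose_ext",
                                             scale = 1e-3)), tab)
  f_mgy <- fit_err(err_model(base, err_linear("mean_dose_ext",
                                              scale = 1)), tab)
  expect_equal(f_gy$loglik, f_mgy$loglik, tolerance = 1e-5)
  expect_equal(unname(f_gy$params["ext:beta"]),
               1000 * unname(f_mgy$params["ext:beta"]), tolerance = 1e-6)
})

test_that("a free intercept forces fitted totals to match observed", {
  coh <- generate_cohort(cohort_config(n = 400), seed = 47)
  tab <- tabulate_person_years(coh,
                               stratification_scheme(axes = coarse_axes))
  f <- fit_err(err_model(~ log(pmax(mean_age, 1) / 60) + sex,
                         err_linear("mean_dose_ext")), tab)
  expect_equal(sum(f$fitted$total), sum(tab$events), tolerance = 1e-6)
  att <- attribute_cases(f, grouping = "ext_dose")
  tot <- att[att$group == "Total", ]
  expect_equal(tot$background + tot$excess_ext, tot$observed,
               tolerance = 1e-6)
  expect_equal(tot$total, tot$observed, tolerance = 1e-6)
  # an ERR-free model has no excess column to decompose
  f0 <- fit_err(err_model(~ log(pmax(mean_age, 1) / 60)), tab)
  att0 <- attribute_cases(f0, grouping = "ext_dose")
  expect_equal(att0$background, att0$total, tolerance = 1e-10)
})

test_that("profile CIs match a dense grid-search oracle on two cells", {
  tab <- two_cell_table()
  f <- fit_err(err_model(~1, err_linear("mean_dose_ext")), tab)
  ci <- profile_ci(f, "ext:beta", level = 0.95)
  # oracle: grid over beta, re-maximizing lambda0 in closed form
  prof <- function(b) {
    lam <- 110 / (1000 + 1000 * (1 + b))
    sum(c(50, 60) * log(lam * 1000 * c(1, 1 + b)) -
          lam * 1000 * c(1, 1 + b))
  }
  g <- seq(-0.4, 1.2, by = 1e-5)
  pv <- vapply(g, prof, numeric(1))
  target <- max(pv) - stats::qchisq(0.95, 1) / 2
  lo <- g[min(which(pv >= target))]
  hi <- g[max(which(pv >= target))]
  expect_equal(ci$lower, lo, tolerance = 1e-4)
  expect_equal(ci$upper, hi, tolerance = 1e-4)
  expect_false(ci$lower_open || ci$upper_open)
  # the profile drop at each endpoint equals 1.921 within 1e-3
  expect_equal(f$loglik - prof(ci$lower), 1.921, tolerance = 1e-3)
  expect_equal(f$loglik - prof(ci$upper), 1.921, tolerance = 1e-3)
  expect_true(ci$lower < ci$estimate && ci$estimate < ci$upper)
})

test_that("profile CIs approach Wald CIs when the profile is quadratic", {
  # large counts make the log-likelihood effectively quadratic
  tab <- tibble::tibble(mean_dose_ext = c(0, 1000),
                        py = c(4e6, 4e6), events = c(200000L, 220000L),
                        mean_age = 60, mean_year = 1980)
  f <- fit_err(err_model(~1, err_linear("mean_dose_ext")), tab)
  ci <- profile_ci(f, "ext:beta")
  se <- sqrt(f$vcov["ext:beta", "ext:beta"])
  wald <- unname(f$params["ext:beta"]) + c(-1, 1) * 1.959964 * se
  expect_equal(c(ci$lower, ci$upper), wald, tolerance = 2e-3)
})

test_that("an admissibility edge is reported as an open bound", {
  # the event-free 2 Gy cell caps beta from below at -1/d while leaving
  # the likelihood finite there, so the 1.921 drop is never reached
  tab <- tibble::tibble(mean_dose_ext = c(0, 500, 2000),
                        py = c(10000, 1000, 20),
                        events = c(100L, 12L, 0L), mean_age = 60,
                        mean_year = 1980)
  f <- fit_err(err_model(~1, err_linear("mean_dose_ext")), tab)
  ci <- profile_ci(f, "ext:beta")
  expect_true(ci$lower_open)
  expect_gte(ci$lower, -0.5 - 1e-6)
  expect_false(ci$upper_open)
})

test_that("inadmissible start values are rejected with guidance", {
  tab <- two_cell_table()
  m <- err_model(~1, err_linear("mean_dose_ext"))
  expect_error(fit_err(m, tab, start = c(log(0.05), -1.5)),
               "inadmissible start")
})

test_that("ERR modifiers scale the linear slope as specified", {
  cells <- tibble::tibble(
    mean_dose_ext = c(1000, 1000, 1000),
    sex = c("male", "female", "male"),
    mean_age = c(60, 60, 75),
    py = 1, events = 0L, mean_year = 1990)
  # female:male ratio on the identity scale
  ms <- err_model(~1, err_linear("mean_dose_ext", sex_ratio = TRUE))
  e <- evaluate_err(ms, c(0, 0.2, 0.5), cells)
  expect_equal(e, c(0.2, 0.1, 0.2))
  # attained-age power (a/60)^alpha
  ma <- err_model(~1, err_linear("mean_dose_ext", age_power = TRUE))
  e2 <- evaluate_err(ma, c(0, 0.2, 2), cells)
  expect_equal(e2, 0.2 * (cells$mean_age / 60)^2)
  # both modifiers fit and recover the unmodified model at the null
  coh <- generate_cohort(cohort_config(n = 300), seed = 83)
  tab <- tabulate_person_years(
    coh, stratification_scheme(axes = c("sex", "age", "ext_dose")))
  base <- ~ log(pmax(mean_age, 1) / 60) + sex
  flin <- fit_err(err_model(base, err_linear("mean_dose_ext")), tab)
  p <- unname(flin$params)
  expect_equal(loglik(err_model(base, err_linear("mean_dose_ext",
                                                 sex_ratio = TRUE)),
                      c(p, 1), tab), flin$loglik, tolerance = 1e-12)
  expect_equal(loglik(err_model(base, err_linear("mean_dose_ext",
                                                 age_power = TRUE)),
                      c(p, 0), tab), flin$loglik, tolerance = 1e-12)
  fs <- fit_err(err_model(base, err_linear("mean_dose_ext",
                                           sex_ratio = TRUE)), tab,
                start = c(p, 1))
  expect_gte(fs$loglik, flin$loglik - 1e-8)
  expect_equal(lrt(flin, fs)$df, 1L)
})
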