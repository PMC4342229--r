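# End-to-end analysis recipes: primary ERR estimates, dose-response model
# suite, site-specific risks, sex-weighted averaging.

default_baseline <- function(table, monitoring = FALSE) {
  terms <- c("log(pmax(mean_age, 1) / 60)")
  add <- function(cond, term) if (cond) term else NULL
  nm <- names(table)
  terms <- c(terms,
             add("sex" %in% nm && length(unique(table$sex)) > 1, "sex"),
             add("smoking" %in% nm && length(unique(table$smoking)) > 1,
                 "smoking"),
             add(all(c("mean_year", "mean_age") %in% nm), "birth_year_c"),
             add("migration" %in% nm &&
                   length(unique(table$migration)) > 1, "migrant"),
             add(monitoring && "monitoring" %in% nm &&
                   length(unique(table$monitoring)) > 1, ".I_mon"))
  stats::as.formula(paste("~", paste(terms, collapse = " + ")))
}

#' Primary ERR analysis of a cohort
#'
#' Runs the exposure -> person-years -> ERR-fit chain for the primary
#' outcome: a linear external-dose ERR model fitted (a) without any
#' internal-exposure adjustment and (b) adjusted for internal plutonium
#' dose (monitored person-time), plutonium surrogate categories
#' (unmonitored person-time) and a monitoring-status baseline term.
#' Reports estimates with profile-likelihood CIs, likelihood-ratio test
#' p-values against the no-dose-effect null, and background/excess case
#' attribution by external dose category.
#'
#' @param cohort An `err_cohort` with follow-up columns.
#' @param lag Dose lag in years (default 5).
#' @param outcome Outcome passed to [tabulate_person_years()].
#' @param axes Stratification axes (default: a full scheme).
#' @param conf_level Level for profile CIs.
#' @param scheme Optional pre-built [stratification_scheme()] overriding
#'   `lag`/`axes`.
#' @param table Optional pre-built person-year table (skips tabulation).
#' @return An `err_report` list: `estimates` (model, term, estimate,
#'   CI, p), `fits`, `attribution` (adjusted model, by dose category),
#'   `table`, `log`.
#' @export
run_primary_analysis <- function(cohort, lag = 5, outcome = "solid_other",
                                 axes = c("sex", "smoking", "age",
                                          "calendar", "migration",
                                          "monitoring", "ext_dose",
                                          "int_dose", "surrogate"),
                                 conf_level = 0.95, scheme = NULL,
                                 table = NULL) {
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  if (is.null(scheme)) scheme <- stratification_scheme(axes = axes, lag = lag)
  if (is.null(table)) {
    say("tabulating person-years: lag ", scheme$lag, ", axes ",
        paste(scheme$axes, collapse = ","))
    table <- tabulate_person_years(cohort, scheme, outcome = outcome)
  }
  say("table: ", nrow(table), " cells, ", round(sum(table$py)), " PY, ",
      sum(table$events), " events")

  base_un <- default_baseline(table, monitoring = FALSE)
  base_ad <- default_baseline(table, monitoring = TRUE)
  has_int <- "monitoring" %in% names(table) &&
    any(table$mean_dose_int > 0)

  m_null_un <- err_model(base_un)
  m_un <- err_model(base_un, err_linear("mean_dose_ext"))
  terms_ad <- list(err_linear("mean_dose_ext"))
  if (has_int) {
    terms_ad <- c(terms_ad,
                  list(err_linear("mean_dose_int", label = "int",
                                  indicator = ".I_mon")))
  }
  if ("surrogate" %in% names(table) && any(table$surrogate > 0)) {
    terms_ad <- c(terms_ad, list(err_surrogate()))
  }
  m_null_ad <- err_model(base_ad, terms_ad[-1])
  m_ad <- err_model(base_ad, terms_ad)

  fits <- list(
    unadjusted_null = fit_err(m_null_un, table),
    unadjusted = fit_err(m_un, table),
    adjusted_null = fit_err(m_null_ad, table),
    adjusted = fit_err(m_ad, table))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    say("fit ", nm, ": loglik ", format(f$loglik, digits = 10),
        ", ", f$iterations, " iterations, converged ", f$converged,
        ", grad ", format(f$gradient_norm, digits = 3))
  }

  est <- purrr::map_dfr(c("unadjusted", "adjusted"), function(nm) {
    f <- fits[[nm]]
    ci <- profile_ci(f, "ext:beta", level = conf_level)
    p <- lrt(fits[[paste0(nm, "_null")]], f)
    tibble::tibble(model = nm, term = "ext:beta",
                   estimate = ci$estimate, lower = ci$lower,
                   upper = ci$upper, lower_open = ci$lower_open,
                   upper_open = ci$upper_open,
                   lrt_statistic = p$statistic, p_value = p$p_value)
  })
  attribution <- list(
    adjusted = attribute_cases(fits$adjusted,
                               grouping = if ("ext_dose" %in% names(table))
                                 "ext_dose"),
    unadjusted = attribute_cases(fits$unadjusted,
                                 grouping = if ("ext_dose" %in% names(table))
                                   "ext_dose"))
  say("excess cases (unadjusted): ",
      round(sum(attribution$unadjusted$excess_ext[
        attribution$unadjusted$group == "Total"]), 1))
  structure(list(estimates = est, fits = fits, attribution = attribution,
                 table = table, scheme = scheme, log = log_lines),
            class = "err_report")
}

#' @export
print.err_report <- function(x, ...) {
  cat("<err_report>\n")
  print(dplyr::mutate(x$estimates,
                      ci = format_ci(.data$lower, .data$upper,
                                     .data$lower_open, .data$upper_open)),
        n = Inf)
  invisible(x)
}

format_ci <- function(lower, upper, lower_open = FALSE, upper_open = FALSE,
                      digits = 2) {
  lo <- ifelse(lower_open, paste0("<", signif(lower, digits)),
               signif(round(lower, 6), digits))
  hi <- ifelse(upper_open, paste0(">", signif(upper, digits)),
               signif(round(upper, 6), digits))
  paste0("(", lo, " to ", hi, ")")
}

#' Dose-response model comparison suite
#'
#' Fits the family of external dose-response shapes to one person-year
#' table: linear, linear-quadratic, pure-quadratic, linear with
#' cell-killing, linear-threshold (threshold profiled over a grid), and
#' time-since-exposure / age-at-exposure window models (fitted on window
#' tables built from the cohort). Reports estimates, profile CIs,
#' likelihood-ratio p-values against the linear model, and window
#' heterogeneity tests.
#'
#' @inheritParams run_primary_analysis
#' @param tse_cutpoints,aae_cutpoints Window cutpoints for the
#'   time-since-exposure and age-at-exposure models.
#' @param thresholds Grid for the threshold profile (Gy).
#' @return A list: `comparison` (one row per parameter), `lrt` (one row
#'   per model vs linear), `threshold_profile`, `fits`.
#' @export
run_dose_response_suite <- function(cohort, lag = 5,
                                    outcome = "solid_other",
                                    axes = c("sex", "smoking", "age",
                                             "calendar", "ext_dose"),
                                    tse_cutpoints = c(5, 10, 15, 20),
                                    aae_cutpoints = c(25, 30, 40, 50),
                                    thresholds = seq(0, 1, by = 0.1),
                                    conf_level = 0.95) {
  scheme <- stratification_scheme(axes = axes, lag = lag)
  table <- tabulate_person_years(cohort, scheme, outcome = outcome)
  base <- default_baseline(table)
  models <- list(
    linear = err_model(base, err_linear("mean_dose_ext")),
    linear_quadratic = err_model(base, err_linear_quadratic("mean_dose_ext")),
    pure_quadratic = err_model(base, err_quadratic("mean_dose_ext")),
    cell_killing = err_model(base, err_cell_killing("mean_dose_ext")))
  fits <- list()
  comparison <- list()
  lrt_rows <- list()
  # non-linear shapes start from the fitted linear model (their nested
  # point), so their maximized loglik can never fall below the linear one
  warm_start <- function(nm, f_lin) {
    if (is.null(f_lin)) return(NULL)
    g <- unname(f_lin$params)
    nb <- f_lin$n_base
    switch(nm,
           linear_quadratic = c(g, 0),
           cell_killing = c(g, 0),
           pure_quadratic = c(g[seq_len(nb)], 0),
           NULL)
  }
  for (nm in names(models)) {
    f <- tryCatch(fit_err(models[[nm]], table,
                          start = warm_start(nm, fits$linear)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      lrt_rows[[nm]] <- tibble::tibble(model = nm, statistic = NA_real_,
                                       df = NA_integer_, p_value = NA_real_,
                                       note = conditionMessage(f))
      next
    }
    fits[[nm]] <- f
    comparison[[nm]] <- tryCatch(
      dplyr::mutate(tidy(f, conf_int = TRUE, conf_level = conf_level),
                    model = nm, .before = 1) |>
        dplyr::filter(!startsWith(.data$term, "b:")),
      error = function(e) tibble::tibble(model = nm,
                                         note = conditionMessage(e)))
    if (nm %in% c("linear_quadratic", "cell_killing")) {
      # only shapes that nest the linear model admit an LRT against it
      lr <- lrt(fits$linear, f)
      lrt_rows[[nm]] <- tibble::tibble(model = nm, statistic = lr$statistic,
                                       df = lr$df, p_value = lr$p_value,
                                       note = lr$flag)
    }
  }
  thr <- tryCatch(profile_threshold(base, table, thresholds = thresholds),
                  error = function(e) NULL)

  # window models on specially constructed tables
  win <- list(
    tse = window_spec("time_since_exposure", tse_cutpoints),
    aae = window_spec("age_at_exposure", aae_cutpoints))
  for (wn in names(win)) {
    ws <- stratification_scheme(axes = axes, lag = lag, windows = win[[wn]])
    wt <- tabulate_person_years(cohort, ws, outcome = outcome)
    vars <- grep("^wdose_", names(wt), value = TRUE)
    ident <- vapply(vars, function(v) stats::sd(wt[[v]]) > 1e-9, logical(1))
    # common-slope null on the summed window dose, so the window model
    # nests it exactly (all window slopes equal)
    wt$wdose_sum <- rowSums(wt[, vars, drop = FALSE])
    flin <- fit_err(err_model(default_baseline(wt),
                              err_linear("wdose_sum")), wt)
    f <- tryCatch(
      fit_err(err_model(default_baseline(wt),
                        err_windows(vars, label = wn)), wt,
              start = c(unname(flin$params)[-length(flin$params)],
                        rep(unname(flin$params)[length(flin$params)],
                            length(vars)))),
      error = function(e) e)
    if (inherits(f, "error")) {
      lrt_rows[[wn]] <- tibble::tibble(model = wn, statistic = NA_real_,
                                       df = NA_integer_, p_value = NA_real_,
                                       note = conditionMessage(f))
      next
    }
    fits[[wn]] <- f
    cmp <- tidy(f) |>
      dplyr::filter(!startsWith(.data$term, "b:")) |>
      dplyr::mutate(model = wn, .before = 1,
                    window = win[[wn]]$labels[match(.data$term,
                                                    paste0(wn, ":", vars))],
                    identifiable = ident[match(.data$term,
                                               paste0(wn, ":", vars))])
    comparison[[wn]] <- cmp
    # heterogeneity: common slope vs separate window slopes
    lr <- lrt(flin, f)
    lrt_rows[[wn]] <- tibble::tibble(model = paste0(wn, "_heterogeneity"),
                                     statistic = lr$statistic, df = lr$df,
                                     p_value = lr$p_value, note = lr$flag)
  }
  # effect modification of the linear slope: female:male ERR ratio and
  # attained-age power, each tested against the unmodified linear model
  modification <- NULL
  if (!is.null(fits$linear)) {
    g <- unname(fits$linear$params)
    mods <- list(
      sex_ratio = list(term = err_linear("mean_dose_ext",
                                         sex_ratio = TRUE),
                       null_value = 1),
      age_power = list(term = err_linear("mean_dose_ext",
                                         age_power = TRUE),
                       null_value = 0))
    modification <- purrr::map_dfr(names(mods), function(mn) {
      fm <- tryCatch(
        fit_err(err_model(base, mods[[mn]]$term), table,
                start = c(g, mods[[mn]]$null_value)),
        error = function(e) NULL)
      if (is.null(fm)) {
        return(tibble::tibble(modifier = mn, estimate = NA_real_,
                              statistic = NA_real_, p_value = NA_real_))
      }
      lr <- lrt(fits$linear, fm)
      tibble::tibble(modifier = mn,
                     estimate = unname(fm$params[length(fm$params)]),
                     statistic = lr$statistic, p_value = lr$p_value)
    })
  }
  list(comparison = dplyr::bind_rows(comparison),
       lrt = dplyr::bind_rows(lrt_rows),
       threshold_profile = thr,
       modification = modification,
       fits = fits, table = table)
}

#' Site-specific ERR estimates
#'
#' Fits a linear external-dose ERR model per cancer site, using the
#' site's own organ dose (melanoma uses the personal dose equivalent
#' Hp(10)); analyses of bladder and larynx cancer are restricted to men,
#' with female cases of those sites counted in the remainder group; no
#' plutonium adjustment is applied. Sites with no cases are skipped with
#' a notice.
#'
#' @inheritParams run_primary_analysis
#' @param organ_factors Named organ:colon dose ratios (defaults from the
#'   cohort's config, else [default_organ_dose_factors()]).
#' @param conf_level Level for profile CIs.
#' @return A tibble: site, organ, deaths, ERR/Gy estimate, profile CI,
#'   LRT p-value, excess cases; plus attributes `pooled_excess` and
#'   `total_excess` (sum over sites).
#' @export
run_site_specific <- function(cohort, lag = 5,
                              axes = c("sex", "age", "calendar",
                                       "ext_dose"),
                              organ_factors = NULL, conf_level = 0.95) {
  if (is.null(organ_factors)) {
    organ_factors <- cohort$config$organ_dose_factors %||%
      default_organ_dose_factors()
  }
  comp <- site_composition()
  male_only <- c("bladder", "larynx")
  scheme <- stratification_scheme(axes = union(axes, "sex"), lag = lag)

  w <- cohort$workers
  outcomes <- stats::setNames(lapply(comp$site, function(s) {
    if (s == "other") {
      function(workers) {
        !is.na(workers$death_site) &
          (workers$death_site == "other" |
             (workers$death_site %in% male_only & workers$sex == "female"))
      }
    } else if (s %in% male_only) {
      function(workers) {
        !is.na(workers$death_site) & workers$death_site == s &
          workers$sex == "male"
      }
    } else {
      function(workers) !is.na(workers$death_site) & workers$death_site == s
    }
  }), comp$site)

  tables <- tabulate_outcomes(cohort, scheme, outcomes)
  rows <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    s <- comp$site[i]
    organ <- comp$organ[i]
    tab <- tables[[s]]
    if (s %in% male_only) tab <- dplyr::filter(tab, .data$sex == "male")
    single_sex <- s %in% male_only || (comp$male[i] == 0) || (comp$female[i] == 0)
    if (single_sex && comp$male[i] == 0) {
      tab <- dplyr::filter(tab, .data$sex == "female")
    }
    deaths <- sum(tab$events)
    if (deaths == 0L) {
      message("site ", s, ": no cases, skipped")
      return(NULL)
    }
    tab$mean_dose_organ <- tab$mean_dose_ext *
      (organ_factors[[organ]] %||% 1)
    # site baselines adjust for attained age, sex and smoking only
    terms <- c("log(pmax(mean_age, 1) / 60)",
               if ("sex" %in% names(tab) &&
                     length(unique(tab$sex)) > 1) "sex",
               if ("smoking" %in% names(tab) &&
                     length(unique(tab$smoking)) > 1) "smoking")
    base <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    out <- tryCatch({
      f0 <- fit_err(err_model(base), tab)
      f1 <- fit_err(err_model(base, err_linear("mean_dose_organ",
                                               label = "ext")), tab)
      ci <- profile_ci(f1, "ext:beta", level = conf_level)
      lr <- lrt(f0, f1)
      att <- attribute_cases(f1)
      tibble::tibble(site = s, organ = organ, deaths = deaths,
                     err_per_gy = ci$estimate, lower = ci$lower,
                     upper = ci$upper, lower_open = ci$lower_open,
                     upper_open = ci$upper_open, p_value = lr$p_value,
                     excess_cases = att$excess_ext[att$group == "Total"],
                     note = NA_character_)
    }, error = function(e) {
      message("site ", s, ": ", conditionMessage(e))
      tibble::tibble(site = s, organ = organ, deaths = deaths,
                     err_per_gy = NA_real_, lower = NA_real_,
                     upper = NA_real_, lower_open = NA, upper_open = NA,
                     p_value = NA_real_, excess_cases = NA_real_,
                     note = conditionMessage(e))
    })
    out
  })
  attr(rows, "total_excess") <- sum(rows$excess_cases, na.rm = TRUE)
  rows
}

# Tabulate several outcomes re-using one follow-up split.
tabulate_outcomes <- function(cohort, scheme, outcomes) {
  w <- cohort$workers
  dsplit <- split(cohort$doses, cohort$doses$worker_id)
  isplit <- split(cohort$internal_doses, cohort$internal_doses$worker_id)
  ssplit <- split(cohort$segments, cohort$segments$worker_id)
  empty <- tibble::tibble(year = integer(), dose_mgy = numeric())
  wcols <- as.list(w)
  rows <- purrr::map(seq_len(nrow(w)), function(i) {
    wi <- lapply(wcols, `[[`, i)
    if (wi$exit <= wi$entry) return(NULL)
    split_followup(wi, ssplit[[wi$worker_id]] %||% empty,
                   dsplit[[wi$worker_id]] %||% empty,
                   isplit[[wi$worker_id]] %||% empty, scheme)
  })
  rows <- dplyr::bind_rows(rows)
  is_last <- rows$event == 1L  # death marker from the split (any cause)
  lapply(outcomes, function(pred) {
    keep <- outcome_indicator(w, pred)
    names(keep) <- w$worker_id
    r <- rows
    r$event <- as.integer(is_last & keep[r$worker_id] &
                            w$event[match(r$worker_id, w$worker_id)] == 1L)
    aggregate_cells(r, scheme)
  })
}

#' Sex-weighted average ERR
#'
#' Convex combination `weight_male * err_male + (1 - weight_male) *
#' err_female`, used to compare cohorts with different sex compositions.
#'
#' @param err_male,err_female Sex-specific ERR estimates.
#' @param weight_male Weight for the male estimate, in `[0, 1]`
#'   (default 0.75).
#' @return The combined ERR.
#' @examples
#' sex_weighted_average(0.30, 0.52, 0.75)  # 0.355
#' @export
sex_weighted_average <- function(err_male, err_female, weight_male = 0.75) {
  assert_prob(weight_male, "weight_male")
  weight_male * err_male + (1 - weight_male) * err_female
}

#' Descriptive cohort summary
#'
#' Table-1-style margins of a (synthetic) cohort: workers, per cent
#' female, mean 5-year-lagged cumulative external dose at end of
#' follow-up, numbers monitored for plutonium, deaths and losses to
#' follow-up, by sex, primary workplace and period of hire.
#'
#' @param cohort An `err_cohort` with follow-up columns.
#' @param lag Dose lag in years used for the cumulative dose column.
#' @return A tibble with one row per group plus a `Total` row.
#' @export
describe_cohort <- function(cohort, lag = 5) {
  w <- cohort$workers
  ds <- split(cohort$doses, cohort$doses$worker_id)
  cum <- vapply(seq_len(nrow(w)), function(i) {
    d <- ds[[w$worker_id[i]]]
    if (is.null(d)) 0 else
      cumulative_dose_at(d$year, d$dose_mgy, w$exit[i] - lag)
  }, numeric(1))
  hire_lab <- bin_label(floor(w$hire_date),
                        c(1948, 1954, 1959, 1964, 1973, 1983))
  grp <- function(label, level, idx) {
    tibble::tibble(
      group = label, level = level,
      workers = sum(idx),
      pct_female = 100 * mean(w$sex[idx] == "female"),
      mean_ext_dose_mgy = mean(cum[idx]),
      monitored_pu = sum(!is.na(w$first_monitoring_date[idx])),
      deaths = sum(w$event[idx] == 1L),
      outcome_deaths = sum(w$event[idx] == 1L &
                             w$death_cause[idx] == "solid_other",
                           na.rm = TRUE),
      person_years = sum(w$exit[idx] - w$entry[idx]))
  }
  rows <- list(grp("total", "Total", rep(TRUE, nrow(w))))
  for (s in levels(w$sex)) {
    rows <- c(rows, list(grp("sex", s, w$sex == s)))
  }
  for (p in levels(w$primary_plant)) {
    idx <- w$primary_plant == p
    if (any(idx)) rows <- c(rows, list(grp("plant", p, idx)))
  }
  for (h in sort(unique(hire_lab))) {
    rows <- c(rows, list(grp("hire_period", h, hire_lab == h)))
  }
  dplyr::bind_rows(rows)
}
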