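# Lexis splitting, person-year tabulation, oracle equivalence, table IO.

test_that("a hand-checked split lands in the right age and calendar bins", {
  w <- make_worker(birth_date = 1921, hire_date = 1950, entry = 1950,
                   exit = 1952)
  coh <- make_cohort(w)
  sch <- stratification_scheme(axes = c("age", "calendar"))
  tab <- tabulate_person_years(coh, sch)
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$py), 2)
  expect_equal(sum(tab$events), 0)
  expect_equal(tab$py[tab$age == "[25,30)"], 1)
  expect_equal(tab$py[tab$age == "[30,35)"], 1)
  expect_true(all(tab$calendar == "[1950,1955)"))
  # weighted mean age lies inside each bin
  expect_true(all(tab$mean_age >= c(25, 30)[order(tab$age)] - 5))
})

test_that("follow-up shorter than any bin stays in a single stratum", {
  w <- make_worker(birth_date = 1921, entry = 1951.2, exit = 1951.9)
  tab <- tabulate_person_years(make_cohort(w),
                               stratification_scheme(axes = c("age",
                                                              "calendar")))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$py, 0.7)
})

test_that("person-years are conserved exactly and refinement is monotone", {
  coh <- generate_cohort(cohort_config(n = 150), seed = 17)
  total <- sum(pmax(coh$workers$exit - coh$workers$entry, 0))
  sch1 <- stratification_scheme(axes = c("sex", "age"))
  sch2 <- stratification_scheme()
  t1 <- tabulate_person_years(coh, sch1)
  t2 <- tabulate_person_years(coh, sch2)
  expect_equal(sum(t1$py), total, tolerance = 1e-10)
  expect_equal(sum(t2$py), total, tolerance = 1e-10)
  expect_equal(sum(t1$events), sum(t2$events))
})

test_that("splitter agrees with the daily brute-force oracle per cell", {
  coh <- generate_cohort(cohort_config(n = 12), seed = 23)
  sch <- stratification_scheme(axes = c("sex", "age", "calendar",
                                        "ext_dose", "monitoring"))
  fast <- tabulate_person_years(coh, sch)
  slow <- brute_force_tabulate(coh, sch, step = 1)
  key <- attr(fast, "axes")
  j <- dplyr::full_join(fast, slow, by = key, suffix = c("_f", "_s"))
  j$py_f[is.na(j$py_f)] <- 0
  j$py_s[is.na(j$py_s)] <- 0
  expect_lt(max(abs(j$py_f - j$py_s)), 12 * 2 / 365.25)
  expect_equal(sum(j$events_f, na.rm = TRUE), sum(j$events_s, na.rm = TRUE))
  # events land in the same cells
  ev <- j[which(j$events_f > 0 | j$events_s > 0), ]
  expect_equal(ev$events_f, ev$events_s)
})

test_that("the hand split example matches the brute force within 2 days", {
  w <- make_worker(birth_date = 1921, entry = 1950, exit = 1952)
  coh <- make_cohort(w)
  sch <- stratification_scheme(axes = c("age", "calendar"))
  slow <- brute_force_tabulate(coh, sch)
  expect_equal(nrow(slow), 2L)
  expect_true(all(abs(slow$py - 1) < 2 / 365.25))
  # empty cohort gives an empty table
  coh0 <- make_cohort(make_worker(entry = 1950, exit = 1950))
  expect_equal(nrow(brute_force_tabulate(coh0, sch)), 0L)
})

test_that("lagged-dose category crossings split mid-year exactly", {
  # 60 mGy over 1950: lagged dose crosses the 25 mGy boundary at
  # 1950 + 25/60 + 5 years
  w <- make_worker(birth_date = 1900, entry = 1950, exit = 1960)
  doses <- tibble::tibble(worker_id = "W1", organ = "colon",
                          year = 1950L, dose_mgy = 60)
  coh <- make_cohort(w, doses = doses)
  sch <- stratification_scheme(axes = c("ext_dose"),
                               age_breaks = c(10, Inf))
  tab <- tabulate_person_years(coh, sch)
  py0 <- tab$py[tab$ext_dose == "0"]
  py1 <- tab$py[tab$ext_dose == "(0,10)"]
  py2 <- tab$py[tab$ext_dose == "[10,25)"]
  py3 <- tab$py[tab$ext_dose == "[25,40)"]
  py4 <- tab$py[tab$ext_dose == "[40,100)"]
  expect_equal(py0, 5)                 # before any lagged dose
  expect_equal(py1, 10 / 60)           # crossing 10 mGy at +10/60 y
  expect_equal(py2, 15 / 60)
  expect_equal(py3, 15 / 60)
  expect_equal(py4, 5 - 40 / 60)       # the rest, dose frozen at 60
  # weighted dose means stay inside their bins
  expect_true(tab$mean_dose_ext[tab$ext_dose == "[10,25)"] >= 10)
  expect_true(tab$mean_dose_ext[tab$ext_dose == "[10,25)"] < 25)
})

test_that("a death is placed in the cell active at the death time", {
  w <- make_worker(birth_date = 1920, entry = 1950, exit = 1962.5,
                   event = 1L, death_date = 1962.5,
                   death_cause = "solid_other")
  tab <- tabulate_person_years(make_cohort(w),
                               stratification_scheme(axes = "age"))
  cell <- tab[tab$events == 1, ]
  expect_equal(nrow(cell), 1L)
  expect_equal(cell$age, "[40,45)")   # age 42.5 at death
})

test_that("deaths on entry day + 1 give n events and n/365.25 person-years", {
  n <- 8
  w <- purrr::map_dfr(seq_len(n), function(i) {
    make_worker(worker_id = sprintf("W%d", i), entry = 1950,
                exit = 1950 + 1 / 365.25, event = 1L,
                death_date = 1950 + 1 / 365.25,
                death_cause = "solid_other")
  })
  segs <- make_segments(w$worker_id, "reactor", w$hire_date,
                        w$employment_end)
  tab <- tabulate_person_years(make_cohort(w, segments = segs),
                               stratification_scheme(axes = "age"))
  expect_equal(sum(tab$events), n)
  expect_equal(sum(tab$py), n / 365.25, tolerance = 1e-10)
})

test_that("workers with no person-time are skipped with a message", {
  w <- dplyr::bind_rows(
    make_worker(worker_id = "A", entry = 1950, exit = 1950),
    make_worker(worker_id = "B", entry = 1950, exit = 1951))
  segs <- make_segments(w$worker_id, "reactor", w$hire_date,
                        w$employment_end)
  expect_message(
    tab <- tabulate_person_years(make_cohort(w, segments = segs),
                                 stratification_scheme(axes = "age")),
    "no person-time")
  expect_equal(sum(tab$py), 1)
})

test_that("person-year tables round-trip through delimited text", {
  coh <- generate_cohort(cohort_config(n = 60), seed = 31)
  tab <- tabulate_person_years(coh, stratification_scheme(axes = coarse_axes))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pytable(tab, path)
  back <- read_pytable(path)
  expect_equal(as.data.frame(back)[names(tab)], as.data.frame(tab),
               tolerance = 1e-12, ignore_attr = TRUE)
  # reader validates invariants
  bad <- tab
  bad$py[1] <- -1
  write_pytable(bad, path)
  expect_error(read_pytable(path), "negative person-years")
})

test_that("window columns carry person-year-weighted window doses", {
  w <- make_worker(birth_date = 1920, entry = 1950, exit = 1980)
  doses <- tibble::tibble(worker_id = "W1", organ = "colon",
                          year = 1950:1959, dose_mgy = 100)
  coh <- make_cohort(w, doses = doses)
  ws <- window_spec("time_since_exposure", c(5, 10, 15, 20))
  sch <- stratification_scheme(axes = "age", windows = ws)
  tab <- tabulate_person_years(coh, sch)
  expect_true(all(paste0("wdose_", 1:4) %in% names(tab)))
  # late in follow-up all dose is old: the 20+ window dominates
  late <- tab[which.max(tab$mean_year), ]
  expect_gt(late$wdose_4, late$wdose_1)
})
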