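test_that("a well-formed study constructs and round-trips through CSV", {
  study <- mini_study()
  expect_s3_class(study, "amu_study")
  expect_equal(nrow(validate_study(study)), 0)

  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(
    dir, paste0(names(study_schema()), ".csv")))))
  reloaded <- read_study(dir)
  for (nm in names(study_schema())) {
    expect_equal(as.data.frame(reloaded[[nm]]),
                 as.data.frame(study[[nm]]),
                 info = nm)
  }
})

test_that("percentages are converted at the reader boundary", {
  dir <- withr::local_tempdir()
  write_study(mini_study(), dir)
  on_disk <- readr::read_csv(file.path(dir, "injection.csv"),
                             show_col_types = FALSE)
  expect_equal(on_disk$pct_exposed, 5) # questionnaire scale 0-100
  expect_equal(read_study(dir)$injection$pct_exposed, 0.05)
})

test_that("validation names the offending record and field", {
  study <- mini_study()
  study$injection$pct_exposed <- 1.2
  problems <- validate_study(study)
  expect_equal(problems$code, "E_RANGE")
  expect_equal(problems$field, "pct_exposed")
  expect_match(problems$message, "pct_exposed")
  expect_error(amu_study(cohorts = study$cohorts,
                         injection = study$injection),
               "validation")
})

test_that("validation catches orphans, missing fields and flow mismatches", {
  study <- mini_study()
  study$feed$cohort_id[1] <- "ZZ9"
  expect_equal(validate_study(study)$code, "E_ORPHAN")

  study <- mini_study()
  study$water$g_per_litre <- NA_real_
  expect_equal(validate_study(study)$code, "E_MISSING")

  study <- mini_study()
  study$cohorts$cycle_start_date[3] <- as.Date("2017-07-01") # continuous
  expect_true("E_FLOW" %in% validate_study(study)$code)

  study <- mini_study()
  study$cohorts$n_deaths[1] <- 31 # exceeds n_start_or_entered
  expect_true("E_RANGE" %in% validate_study(study)$code)

  study <- mini_study()
  study$cohorts$weaning_age_days[3] <- 21 # nursery cohort
  expect_true("E_STAGE" %in% validate_study(study)$code)
})

test_that("status classification maps 2/2/1 levels and rejects others", {
  expect_equal(classify_status("likely_positive"), "positive")
  expect_equal(classify_status("confirmed_positive"), "positive")
  expect_equal(classify_status("likely_negative"), "negative")
  expect_equal(classify_status("confirmed_negative"), "negative")
  expect_equal(classify_status("unknown"), "unknown")
  mapped <- classify_status(c("confirmed_positive", "likely_positive",
                              "confirmed_negative", "likely_negative",
                              "unknown"))
  expect_equal(as.vector(table(mapped)[c("positive", "negative", "unknown")]),
               c(2L, 2L, 1L))
  expect_error(classify_status("maybe"), "unrecognized")
})

test_that("treatment episodes merge, split on dose change and split on gaps", {
  one <- segment_treatments(
    data.frame(start_day = 1, duration = 5, dose = 2))
  expect_equal(nrow(one), 1)
  expect_equal(one$duration, 5)

  dose_change <- segment_treatments(data.frame(
    start_day = c(1, 6), duration = 5, dose = c(2, 4)))
  expect_equal(nrow(dose_change), 2)
  expect_equal(dose_change$duration, c(5, 5))

  paused <- segment_treatments(data.frame(
    start_day = c(1, 7), duration = 3, dose = 2))
  expect_equal(nrow(paused), 2)
  expect_equal(paused$start_day, c(1, 7))

  merged <- segment_treatments(data.frame(
    start_day = c(1, 4, 6), duration = c(3, 2, 4), dose = 2))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration, 9)

  expect_error(segment_treatments(
    data.frame(start_day = 1, duration = -1, dose = 1)), "non-negative")
})

test_that("gap-free episode durations sum to total administered days", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    durations <- sample(1:5, n, replace = TRUE)
    starts <- cumsum(c(1, utils::head(durations, -1))) # back-to-back
    doses <- sample(c(1, 2), n, replace = TRUE)
    eps <- segment_treatments(
      data.frame(start_day = starts, duration = durations, dose = doses))
    expect_equal(sum(eps$duration), sum(durations))
  }
})
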