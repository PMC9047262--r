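# A small hand-built study: one farrowing herd (sows + suckling rows),
# one nursery herd, one grower-finisher herd, with one record of every
# route whose masses are easy to recompute by hand in tests.

mini_cohorts <- function() {
  tibble::tibble(
    cohort_id = c("F01", "F01", "N01", "G01"),
    stage = c("farrowing_sows", "suckling", "nursery", "grower_finisher"),
    flow_type = c("all_in_all_out", "all_in_all_out", "continuous",
                  "all_in_all_out"),
    rwa_program = FALSE,
    questionnaire_date = as.Date(c("2017-06-24", "2017-06-24",
                                   "2017-08-15", "2017-10-21")),
    cycle_start_date = as.Date(c("2017-06-01", "2017-06-01", NA,
                                 "2017-07-01")),
    avg_cycle_length_days = c(NA, NA, 52, NA),
    n_start_or_entered = c(30, 400, 500, 1000),
    n_deaths = c(2, 40, 20, 40),
    weaning_age_days = c(21, 21, NA, NA),
    avg_start_weight = c(240, 1.5, 6.5, 25),
    avg_end_weight = c(240, 6.5, 25, 120),
    litters_observed = c(30, 30, NA, NA)
  )
}

mini_study <- function() {
  amu_study(
    cohorts = mini_cohorts(),
    feed = tibble::tibble(
      cohort_id = c("F01", "N01", "G01"),
      pig_type = c("sows", "nursery", "grower_finisher"),
      ration_name = c("sow_ration", "starter", "grower"),
      aai = c("chlortetracycline", "chlortetracycline", "lincomycin"),
      g_per_tonne = c(500, 550, 44),
      reason = "prevention",
      start_weight = c(240, 6.5, 25),
      end_weight = c(240, 16, 67),
      duration_fed = c(14, 28, 56),
      pct_fed = 1
    ),
    creep = tibble::tibble(
      cohort_id = "F01", aai = "chlortetracycline", g_per_tonne = 600,
      reason = "prevention", age_start = 7, age_end = 21,
      pct_piglets_fed = 1, pct_wasted = 0.2
    ),
    water = tibble::tibble(
      cohort_id = "N01", pig_type = "nursery", aai = "amoxicillin",
      product = "amoxicillin_soluble", g_per_litre = 0.4,
      reason = "prevention", duration = 5, weight_at_start = 6.5,
      age_at_start = NA, pct_exposed = 1
    ),
    injection = tibble::tibble(
      cohort_id = "F01", pig_type = "sows", aai = "procaine_penicillin_g",
      long_acting = FALSE, product = "pen_g_inj", concentration = 300,
      volume_per_pig_per_day = 2, duration = 3, reason = "treatment",
      weight_at_start = 240, age_at_start = NA, pct_exposed = 0.05
    ),
    health = tibble::tibble(
      cohort_id = c("F01", "F01", "N01", "G01"),
      pig_type = c("sows", "suckling", "nursery", "grower_finisher"),
      disease = "E_coli",
      raw_status = c("confirmed_positive", "likely_positive",
                     "likely_negative", "unknown"),
      vaccinated = c(TRUE, FALSE, FALSE, FALSE),
      amu_for_disease = c(TRUE, TRUE, FALSE, FALSE)
    ),
    biosecurity = tibble::tibble(
      cohort_id = c("F01", "N01", "G01"),
      practice = "barn_boots", used = c(TRUE, TRUE, FALSE),
      downtime_hours = NA, farms_within_2km = c(2, 0, 5)
    )
  )
}

# independent re-statement of the farrowing = sows + suckling convention
stage_to_herd_type_oracle <- function(stage) {
  ifelse(stage %in% c("farrowing_sows", "suckling"), "farrowing", stage)
}

stage_to_pig_type_oracle <- function(stage) {
  ifelse(stage == "farrowing_sows", "sows", stage)
}

# independent Horner-free polynomial evaluation, the oracle for the
# package's closed-form curve arithmetic
poly_eval_oracle <- function(coefficients, x) {
  out <- 0
  for (i in seq_along(coefficients)) {
    out <- out + coefficients[i] * x^(i - 1)
  }
  out
}

# small generator configuration for fast multi-seed property tests
small_config <- function(seed = 1, ...) {
  generator_config(
    seed = seed,
    n_cohorts = c(farrowing = 5, nursery = 5, grower_finisher = 5),
    n_continuous = c(farrowing = 1, nursery = 1, grower_finisher = 1),
    n_rwa = c(farrowing = 1, nursery = 1, grower_finisher = 1),
    ...
  )
}
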