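# Seeded synthetic questionnaire studies. The generator emulates the
# structure of a cross-sectional AMU study on farrowing, nursery and
# grower-finisher herds -- demographics, all four treatment routes,
# health and biosecurity records -- and keeps a ledger of every drawn
# quantity so that pipeline output can be checked against closed-form
# expectations.

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the marginal structure of an Ontario-style
#' cross-sectional study: 25 farrowing, 25 nursery and 23 grower-finisher
#' herds; four continuous-flow herds per stage; 4/2/1 herds per stage on a
#' raised-without-antimicrobials (RWA) program; production-cycle lengths
#' spanning 18--41 / 28--99 / 87--157 days with medians 23 / 52 / 112;
#' and batch sizes chosen so stage totals of pigs at risk land near
#' 780 sows, 10,000 suckling, 13,250 nursery and 21,600 grower-finisher
#' pigs.
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   seed.
#' @param n_cohorts Named counts of herds per herd type.
#' @param n_continuous Named counts of continuous-flow herds per type.
#' @param n_rwa Named counts of RWA herds per type.
#' @param cycle_days Per herd type, `c(min, median, max)` production-cycle
#'   days; generated cycles have exactly the configured median.
#' @param batch_size Per pig type, `c(min, max)` pigs in the sampled
#'   batch (sows: sows farrowing in the sampled room).
#' @param born_alive_per_litter `c(min, max)` piglets born alive per
#'   litter.
#' @param mortality Named per-pig-type mortality proportions; deaths are
#'   drawn binomially and feed the minus-half-the-mortality rule.
#' @param weaning_age `c(min, max)` weaning age in days.
#' @param weight_ranges Per pig type, list of `start` and `end` weight
#'   ranges (kg).
#' @param creep_offered_prob Probability a farrowing herd offers
#'   (medicated) creep feed.
#' @param treatment_menu Tibble describing candidate administrations; see
#'   [default_treatment_menu()].
#' @param disease_prevalence Named per-disease probability of a positive
#'   status.
#' @param unknown_prob,confirmed_frac Probability a status is reported
#'   unknown; fraction of non-unknown statuses that are
#'   laboratory-confirmed.
#' @param vaccination_prob,amu_for_disease_prob Per-record probabilities.
#' @param biosecurity_probs Named per-practice use probabilities.
#' @param curves Intake-curve configuration ([read_intake_curves()]);
#'   the generator draws intakes from the same curves the pipeline uses.
#' @param water_params,sow_params Intake parameters shared with the
#'   pipeline.
#' @return A list of class `amu_generator_config`.
#' @export
generator_config <- function(
    seed = 1,
    n_cohorts = c(farrowing = 25, nursery = 25, grower_finisher = 23),
    n_continuous = c(farrowing = 4, nursery = 4, grower_finisher = 4),
    n_rwa = c(farrowing = 4, nursery = 2, grower_finisher = 1),
    cycle_days = list(farrowing = c(18, 23, 41), nursery = c(28, 52, 99),
                      grower_finisher = c(87, 112, 157)),
    batch_size = list(sows = c(20, 45), nursery = c(300, 760),
                      grower_finisher = c(600, 1280)),
    born_alive_per_litter = c(11, 15),
    mortality = c(sows = 0.02, suckling = 0.10, nursery = 0.03,
                  grower_finisher = 0.025),
    weaning_age = c(18, 28),
    weight_ranges = list(
      sows = list(start = c(220, 250), end = c(220, 250)),
      suckling = list(start = c(1.2, 1.8), end = c(5.5, 7.5)),
      nursery = list(start = c(5.5, 7.5), end = c(20, 30)),
      grower_finisher = list(start = c(20, 30), end = c(105, 135))
    ),
    creep_offered_prob = 0.6,
    treatment_menu = default_treatment_menu(),
    disease_prevalence = c(
      APP = 0.05, E_coli = 0.8, erysipelas = 0.65, H_parasuis = 0.7,
      ileitis = 0.6, influenza = 0.6, mycoplasma = 0.55, PCVAD = 0.8,
      PED = 0.02, PRRS = 0.35, salmonella = 0.25, strep_suis = 0.85,
      TGE = 0.02
    ),
    unknown_prob = 0.08,
    confirmed_frac = 0.3,
    vaccination_prob = 0.3,
    amu_for_disease_prob = 0.2,
    biosecurity_probs = c(
      barn_boots = 1, coveralls = 0.96, boot_dip = 0.15,
      biosecurity_sign = 1, danish_entry = 0.9, barn_locked = 0.8,
      visitors_restricted = 0.98, shower_in = 0.7,
      quarantine_gilts = 0.4, downtime = 0.85
    ),
    curves = read_intake_curves(),
    water_params = water_intake_params(),
    sow_params = sow_feed_params()) {
  stopifnot(all(mortality >= 0 & mortality <= 1),
            creep_offered_prob >= 0, creep_offered_prob <= 1,
            all(biosecurity_probs >= 0 & biosecurity_probs <= 1),
            all(vapply(cycle_days, function(x) x[1] <= x[2] && x[2] <= x[3],
                       logical(1))))
  structure(as.list(environment()), class = "amu_generator_config")
}

#' Default candidate-treatment menu of the generator
#'
#' One row per (pig type, route, ingredient, reason): the probability a
#' herd uses it, and the ranges the dose, duration, exposed fraction and
#' (for injections) daily volume are drawn from. Doses are in the route's
#' native unit: g/tonne feed, g/L water, or mg/mL injectable
#' concentration. Frequencies echo a realistic mix: chlortetracycline
#' dominant in sow, creep and nursery feed; lincomycin in grower-finisher
#' feed; procaine penicillin G the commonest injectable; amoxicillin the
#' commonest nursery water medication.
#'
#' @return A tibble with columns `pig_type`, `route`, `aai`,
#'   `long_acting`, `reason`, `use_prob`, `dose_lo`, `dose_hi`, `dur_lo`,
#'   `dur_hi`, `pct_lo`, `pct_hi`, `vol_lo`, `vol_hi`.
#' @export
default_treatment_menu <- function() {
  menu <- function(pig_type, route, aai, reason, use_prob, dose_lo,
                   dose_hi, dur_lo, dur_hi, pct_lo, pct_hi,
                   long_acting = FALSE, vol_lo = NA, vol_hi = NA) {
    tibble::tibble(
      pig_type = pig_type, route = route, aai = aai,
      long_acting = long_acting, reason = reason, use_prob = use_prob,
      dose_lo = dose_lo, dose_hi = dose_hi, dur_lo = dur_lo,
      dur_hi = dur_hi, pct_lo = pct_lo, pct_hi = pct_hi,
      vol_lo = vol_lo, vol_hi = vol_hi
    )
  }
  dplyr::bind_rows(
    # sows
    menu("sows", "feed", "chlortetracycline", "prevention", 0.12,
         300, 600, 10, 21, 100, 100),
    menu("sows", "feed", "oxytetracycline", "prevention", 0.08,
         300, 600, 10, 21, 100, 100),
    menu("sows", "feed", "bacitracin", "prevention", 0.06,
         150, 330, 10, 21, 100, 100),
    menu("sows", "injection", "procaine_penicillin_g", "treatment", 0.50,
         300, 300, 1, 5, 2, 10, vol_lo = 1, vol_hi = 3),
    menu("sows", "injection", "oxytetracycline", "treatment", 0.28,
         200, 200, 1, 3, 2, 10, vol_lo = 1, vol_hi = 3),
    menu("sows", "injection", "sulfadoxine", "treatment", 0.36,
         200, 200, 1, 3, 2, 10, vol_lo = 1, vol_hi = 3),
    menu("sows", "injection", "trimethoprim", "treatment", 0.36,
         40, 40, 1, 3, 2, 10, vol_lo = 1, vol_hi = 3),
    # suckling pigs (creep feed + injections)
    menu("suckling", "creep", "chlortetracycline", "prevention", 0.56,
         400, 800, NA, NA, 80, 100),
    menu("suckling", "creep", "tiamulin", "prevention", 0.30,
         30, 40, NA, NA, 80, 100),
    menu("suckling", "creep", "salinomycin", "prevention", 0.04,
         15, 25, NA, NA, 80, 100),
    menu("suckling", "injection", "procaine_penicillin_g", "treatment",
         0.44, 300, 300, 1, 3, 2, 10, vol_lo = 0.3, vol_hi = 1),
    menu("suckling", "injection", "ceftiofur", "prevention", 0.16,
         50, 50, 1, 1, 100, 100, long_acting = TRUE,
         vol_lo = 0.1, vol_hi = 0.3),
    menu("suckling", "injection", "sulfadoxine", "treatment", 0.40,
         200, 200, 1, 3, 2, 10, vol_lo = 0.3, vol_hi = 1),
    menu("suckling", "injection", "trimethoprim", "treatment", 0.40,
         40, 40, 1, 3, 2, 10, vol_lo = 0.3, vol_hi = 1),
    menu("suckling", "injection", "tulathromycin", "prevention", 0.04,
         100, 100, 1, 1, 100, 100, vol_lo = 0.1, vol_hi = 0.2),
    # nursery pigs
    menu("nursery", "feed", "chlortetracycline", "prevention", 0.72,
         400, 700, 14, 35, 80, 100),
    menu("nursery", "feed", "tiamulin", "prevention", 0.44,
         30, 40, 14, 35, 80, 100),
    menu("nursery", "feed", "procaine_penicillin_g", "prevention", 0.32,
         100, 300, 14, 35, 80, 100),
    menu("nursery", "feed", "sulfamethazine", "prevention", 0.24,
         300, 500, 14, 35, 80, 100),
    menu("nursery", "feed", "tylosin", "prevention", 0.04,
         20, 110, 14, 35, 80, 100),
    menu("nursery", "water", "amoxicillin", "prevention", 0.20,
         0.2, 0.6, 3, 7, 80, 100),
    menu("nursery", "water", "penicillin_g_potassium", "prevention", 0.12,
         0.1, 0.4, 3, 5, 80, 100),
    menu("nursery", "water", "apramycin", "prevention", 0.08,
         0.1, 0.3, 5, 7, 80, 100),
    menu("nursery", "injection", "procaine_penicillin_g", "treatment",
         0.52, 300, 300, 1, 3, 2, 8, vol_lo = 0.5, vol_hi = 1.5),
    menu("nursery", "injection", "tulathromycin", "treatment", 0.12,
         100, 100, 1, 1, 2, 8, vol_lo = 0.2, vol_hi = 0.5),
    # grower-finisher pigs
    menu("grower_finisher", "feed", "lincomycin", "prevention", 0.43,
         40, 110, 21, 80, 90, 100),
    menu("grower_finisher", "feed", "chlortetracycline", "prevention",
         0.22, 300, 600, 21, 60, 90, 100),
    menu("grower_finisher", "feed", "tylosin", "prevention", 0.13,
         20, 110, 21, 80, 90, 100),
    menu("grower_finisher", "feed", "salinomycin", "growth_promotion",
         0.09, 25, 60, 40, 100, 100, 100),
    menu("grower_finisher", "feed", "virginiamycin", "growth_promotion",
         0.04, 11, 44, 40, 100, 100, 100),
    menu("grower_finisher", "water", "penicillin_g_potassium",
         "prevention", 0.09, 0.1, 0.4, 3, 5, 80, 100),
    menu("grower_finisher", "water", "amoxicillin", "treatment", 0.04,
         0.2, 0.6, 3, 5, 80, 100),
    menu("grower_finisher", "injection", "procaine_penicillin_g",
         "treatment", 0.26, 300, 300, 1, 3, 1, 5,
         vol_lo = 2, vol_hi = 5),
    menu("grower_finisher", "injection", "lincomycin", "treatment", 0.09,
         100, 100, 1, 3, 1, 5, vol_lo = 2, vol_hi = 5)
  )
}

# Cycle lengths whose sample median is exactly the configured median:
# equal numbers of draws strictly below and strictly above it, the rest
# pinned at the median.
draw_cycle_lengths <- function(n, range) {
  lo <- range[1]
  med <- range[2]
  hi <- range[3]
  k <- (n - (if (n %% 2 == 1) 1 else 2)) / 2
  below <- if (k > 0 && med > lo) {
    sample(seq(lo, med - 1), k, replace = TRUE)
  } else {
    rep(med, k)
  }
  above <- if (k > 0 && hi > med) {
    sample(seq(med + 1, hi), k, replace = TRUE)
  } else {
    rep(med, k)
  }
  sample(c(below, above, rep(med, n - 2 * k)))
}

# guarded against R's sample(scalar) surprise when lo == hi
draw_grid <- function(lo, hi, step = 1) {
  grid <- seq(lo, hi, by = step)
  grid[sample.int(length(grid), 1)]
}

#' Generate a seeded synthetic study with a ground-truth ledger
#'
#' Deterministic given `config$seed`. Emits a complete, validated
#' `amu_study` (cohorts, all four treatment routes, health and
#' biosecurity records) plus a ledger recording every drawn quantity:
#' true total mg per record (computed in closed form from the drawn doses
#' and intakes, independent of the exposure pipeline), per-cohort pigs at
#' risk and time at risk, and the drawn health/biosecurity outcomes.
#'
#' @param config A [generator_config()].
#' @return A list with elements `study` (an `amu_study`) and `ledger`
#'   (list of tibbles `exposure`, `cohorts`, `health`, `biosecurity`).
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "amu_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  dates <- seq(as.Date("2017-05-01"), as.Date("2018-04-30"), by = 1)
  cohorts <- list()
  herd_meta <- list()

  add_cohort <- function(...) {
    cohorts[[length(cohorts) + 1]] <<- list(...)
  }

  wr <- config$weight_ranges
  rwa_ids <- list()
  for (ht in names(config$n_cohorts)) {
    n <- config$n_cohorts[[ht]]
    prefix <- c(farrowing = "F", nursery = "N", grower_finisher = "G")[[ht]]
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    continuous <- ids %in% sample(ids, min(config$n_continuous[[ht]], n))
    rwa <- ids %in% sample(ids, min(config$n_rwa[[ht]], n))
    rwa_ids[[ht]] <- ids[rwa]
    cyc <- draw_cycle_lengths(n, config$cycle_days[[ht]])
    qdate <- sample(dates, n, replace = TRUE)

    for (i in seq_len(n)) {
      common <- list(
        cohort_id = ids[i],
        flow_type = if (continuous[i]) "continuous" else "all_in_all_out",
        rwa_program = rwa[i],
        questionnaire_date = qdate[i],
        cycle_start_date = if (continuous[i]) as.Date(NA) else
          qdate[i] - cyc[i],
        avg_cycle_length_days = if (continuous[i]) cyc[i] else NA_real_
      )
      if (ht == "farrowing") {
        n_sows <- draw_grid(config$batch_size$sows[1],
                            config$batch_size$sows[2])
        wean <- draw_grid(config$weaning_age[1], config$weaning_age[2])
        n_suck <- sum(sample(
          seq(config$born_alive_per_litter[1],
              config$born_alive_per_litter[2]),
          n_sows, replace = TRUE))
        sow_w <- round(runif(1, wr$sows$start[1], wr$sows$start[2]), 1)
        do.call(add_cohort, c(common, list(
          stage = "farrowing_sows",
          n_start_or_entered = n_sows,
          n_deaths = rbinom(1, n_sows, config$mortality[["sows"]]),
          weaning_age_days = wean,
          avg_start_weight = sow_w, avg_end_weight = sow_w,
          litters_observed = n_sows
        )))
        do.call(add_cohort, c(common, list(
          stage = "suckling",
          n_start_or_entered = n_suck,
          n_deaths = rbinom(1, n_suck, config$mortality[["suckling"]]),
          weaning_age_days = wean,
          avg_start_weight = round(runif(1, wr$suckling$start[1],
                                         wr$suckling$start[2]), 2),
          avg_end_weight = round(runif(1, wr$suckling$end[1],
                                       wr$suckling$end[2]), 2),
          litters_observed = n_sows
        )))
      } else {
        n_pigs <- draw_grid(config$batch_size[[ht]][1],
                            config$batch_size[[ht]][2])
        do.call(add_cohort, c(common, list(
          stage = ht,
          n_start_or_entered = n_pigs,
          n_deaths = rbinom(1, n_pigs, config$mortality[[ht]]),
          weaning_age_days = NA_real_,
          avg_start_weight = round(runif(1, wr[[ht]]$start[1],
                                         wr[[ht]]$start[2]), 1),
          avg_end_weight = round(runif(1, wr[[ht]]$end[1],
                                       wr[[ht]]$end[2]), 1),
          litters_observed = NA_real_
        )))
      }
    }
  }
  cohorts <- dplyr::bind_rows(cohorts)

  # derived per-cohort-row quantities the ledger tracks
  info <- cohorts |>
    dplyr::mutate(
      pig_type = stage_to_pig_type(.data$stage),
      pigs_at_risk = .data$n_start_or_entered - .data$n_deaths / 2,
      time_at_risk = ifelse(
        .data$flow_type == "continuous", .data$avg_cycle_length_days,
        as.numeric(.data$questionnaire_date - .data$cycle_start_date)),
      adg_val = ifelse(
        .data$stage %in% c("nursery", "grower_finisher"),
        (.data$avg_end_weight - .data$avg_start_weight) / .data$time_at_risk,
        NA_real_)
    ) |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(stratum = if (all(is.na(.data$adg_val))) {
      NA_character_
    } else {
      assign_stratum(.data$adg_val, .data$adg_val)
    }) |>
    dplyr::ungroup()

  curves <- config$curves
  wp <- config$water_params
  sow_feed_g <- config$sow_params$gross_daily_feed *
    (1 - config$sow_params$wastage)

  feed <- list()
  creep <- list()
  water <- list()
  injection <- list()
  ledger_rows <- list()

  log_mass <- function(cohort_id, pig_type, route, aai, long_acting,
                       reason, total_mg, pigs_exposed) {
    ledger_rows[[length(ledger_rows) + 1]] <<- list(
      cohort_id = cohort_id, pig_type = pig_type, route = route,
      aai = aai, long_acting = long_acting, reason = reason,
      total_mg = total_mg, pigs_exposed = pigs_exposed
    )
  }

  info_df <- as.data.frame(info)
  menu_df <- as.data.frame(config$treatment_menu)
  for (r in seq_len(nrow(info_df))) {
    row <- info_df[r, ]
    is_rwa <- row$rwa_program
    offers_creep <- row$pig_type == "suckling" && !is_rwa &&
      runif(1) < config$creep_offered_prob
    candidates <- menu_df[menu_df$pig_type == row$pig_type, ,
                          drop = FALSE]
    for (m in seq_len(nrow(candidates))) {
      cand <- candidates[m, ]
      # RWA herds only treat clinically ill individuals by injection
      if (is_rwa && !(cand$route == "injection" &&
                      cand$reason == "treatment")) next
      if (cand$route == "creep" && !offers_creep) next
      if (runif(1) >= cand$use_prob) next
      tt <- row$time_at_risk
      pct <- draw_grid(cand$pct_lo, cand$pct_hi) / 100

      if (cand$route == "feed") {
        dose <- draw_grid(round(cand$dose_lo), round(cand$dose_hi))
        dur <- draw_grid(min(cand$dur_lo, tt), min(cand$dur_hi, tt))
        if (row$pig_type == "sows") {
          fpp <- sow_feed_g * dur / 1000
          sw <- row$avg_start_weight
          ew <- row$avg_end_weight
        } else {
          t0 <- draw_grid(0, max(0, floor(tt - dur)))
          fpp <- poly_integral(
            curves$curves[[row$stage]][[row$stratum]]$coefficients,
            t0, t0 + dur)
          sw <- row$avg_start_weight + row$adg_val * t0
          ew <- sw + row$adg_val * dur
        }
        feed[[length(feed) + 1]] <- list(
          cohort_id = row$cohort_id, pig_type = row$pig_type,
          ration_name = paste0(cand$aai, "_ration"), aai = cand$aai,
          g_per_tonne = dose, reason = cand$reason, start_weight = sw,
          end_weight = ew, duration_fed = dur, pct_fed = pct
        )
        log_mass(row$cohort_id, row$pig_type, "feed", cand$aai, FALSE,
                 cand$reason,
                 dose * (fpp / 1000) * row$pigs_at_risk * pct * 1000,
                 round(row$pigs_at_risk * pct))
      } else if (cand$route == "creep") {
        dose <- draw_grid(round(cand$dose_lo), round(cand$dose_hi))
        age_start <- draw_grid(3, 10)
        wasted <- draw_grid(5, 30) / 100
        per_piglet <- poly_eval(curves$creep$coefficients,
                                row$weaning_age_days - age_start) /
          curves$creep$litter_size_standard
        creep[[length(creep) + 1]] <- list(
          cohort_id = row$cohort_id, aai = cand$aai, g_per_tonne = dose,
          reason = cand$reason, age_start = age_start,
          age_end = row$weaning_age_days, pct_piglets_fed = pct,
          pct_wasted = wasted
        )
        log_mass(row$cohort_id, "suckling", "creep", cand$aai, FALSE,
                 cand$reason,
                 dose * (per_piglet / 1e6) * row$pigs_at_risk * pct *
                   (1 - wasted) * 1000,
                 round(row$pigs_at_risk * pct))
      } else if (cand$route == "water") {
        dose <- draw_grid(cand$dose_lo, cand$dose_hi, step = 0.05)
        dur <- draw_grid(min(cand$dur_lo, tt), min(cand$dur_hi, tt))
        daily_water <- if (row$pig_type == "sows") {
          wp$sow_daily_water
        } else {
          mean_feed <- poly_integral(
            curves$curves[[row$stage]][[row$stratum]]$coefficients,
            0, tt) / tt
          wp$intercept + wp$slope * mean_feed
        }
        water[[length(water) + 1]] <- list(
          cohort_id = row$cohort_id, pig_type = row$pig_type,
          aai = cand$aai, product = paste0(cand$aai, "_soluble"),
          g_per_litre = dose, reason = cand$reason, duration = dur,
          weight_at_start = row$avg_start_weight,
          age_at_start = NA_real_, pct_exposed = pct
        )
        log_mass(row$cohort_id, row$pig_type, "water", cand$aai, FALSE,
                 cand$reason,
                 dose * daily_water * dur * row$pigs_at_risk * pct * 1000,
                 round(row$pigs_at_risk * pct))
      } else {
        conc <- cand$dose_lo
        vol <- draw_grid(cand$vol_lo, cand$vol_hi, step = 0.1)
        dur <- draw_grid(cand$dur_lo, cand$dur_hi)
        injection[[length(injection) + 1]] <- list(
          cohort_id = row$cohort_id, pig_type = row$pig_type,
          aai = cand$aai, long_acting = cand$long_acting,
          product = paste0(cand$aai, "_inj"), concentration = conc,
          volume_per_pig_per_day = vol, duration = dur,
          reason = cand$reason, weight_at_start = row$avg_start_weight,
          age_at_start = NA_real_, pct_exposed = pct
        )
        log_mass(row$cohort_id, row$pig_type, "injection", cand$aai,
                 cand$long_acting, cand$reason,
                 conc * vol * dur * row$pigs_at_risk * pct,
                 round(row$pigs_at_risk * pct))
      }
    }
  }

  # health and biosecurity records, with drawn outcomes kept in the ledger
  health <- tidyr::crossing(
    info[c("cohort_id", "pig_type")],
    disease = amu_diseases
  ) |>
    dplyr::filter(!(.data$disease == "TGE" &
                      .data$pig_type %in% c("sows", "suckling")))
  n_h <- nrow(health)
  u_unknown <- runif(n_h)
  u_pos <- runif(n_h)
  u_conf <- runif(n_h)
  prev <- config$disease_prevalence[health$disease]
  health$raw_status <- ifelse(
    u_unknown < config$unknown_prob, "unknown",
    ifelse(u_pos < prev,
           ifelse(u_conf < config$confirmed_frac,
                  "confirmed_positive", "likely_positive"),
           ifelse(u_conf < config$confirmed_frac,
                  "confirmed_negative", "likely_negative"))
  )
  health$vaccinated <- runif(n_h) < config$vaccination_prob
  health$amu_for_disease <- runif(n_h) < config$amu_for_disease_prob

  herds <- info |>
    dplyr::distinct(.data$cohort_id, .keep_all = TRUE) |>
    dplyr::mutate(herd_type = stage_to_herd_type(.data$stage),
                  farms_within_2km = sample(0:8, dplyr::n(),
                                            replace = TRUE))
  biosec <- tidyr::crossing(
    herds[c("cohort_id", "herd_type", "farms_within_2km")],
    practice = amu_biosecurity_practices
  ) |>
    dplyr::filter(!(.data$practice == "quarantine_gilts" &
                      .data$herd_type != "farrowing"))
  biosec$used <- runif(nrow(biosec)) <
    config$biosecurity_probs[biosec$practice]
  biosec$downtime_hours <- ifelse(
    biosec$practice == "downtime" & biosec$used,
    sample(12:72, nrow(biosec), replace = TRUE), NA_real_)
  biosec <- biosec[c("cohort_id", "practice", "used", "downtime_hours",
                     "farms_within_2km")]

  study <- amu_study(
    cohorts = cohorts,
    feed = if (length(feed)) dplyr::bind_rows(feed) else NULL,
    creep = if (length(creep)) dplyr::bind_rows(creep) else NULL,
    water = if (length(water)) dplyr::bind_rows(water) else NULL,
    injection = if (length(injection)) dplyr::bind_rows(injection) else
      NULL,
    health = health,
    biosecurity = biosec
  )

  exposure_ledger <- if (length(ledger_rows)) {
    dplyr::bind_rows(ledger_rows)
  } else {
    tibble::tibble(cohort_id = character(), pig_type = character(),
                   route = character(), aai = character(),
                   long_acting = logical(), reason = character(),
                   total_mg = numeric(), pigs_exposed = numeric())
  }
  ledger <- list(
    exposure = exposure_ledger,
    cohorts = info[c("cohort_id", "stage", "pig_type", "pigs_at_risk",
                     "time_at_risk", "stratum")],
    health = health |>
      dplyr::mutate(status = classify_status(.data$raw_status)) |>
      dplyr::count(.data$pig_type, .data$disease, .data$status),
    biosecurity = biosec |>
      dplyr::left_join(herds[c("cohort_id", "herd_type")],
                       by = "cohort_id") |>
      dplyr::group_by(.data$herd_type, .data$practice) |>
      dplyr::summarise(n_used = sum(.data$used), n_total = dplyr::n(),
                       .groups = "drop")
  )
  list(study = study, ledger = ledger)
}

#' Closed-form expected pooled metrics from a generator ledger
#'
#' Computes, from the ledger alone (the drawn masses and denominators,
#' bypassing the intake and exposure pipeline), the pooled per pig type x
#' route (plus all-routes) metrics the pipeline must reproduce: total
#' mass, mg/kg biomass, doses per pig and doses per 1000 pig-days, with
#' creep reported under the feed route. All arithmetic is written out
#' directly so the result is an independent check of the pipeline's
#' aggregation.
#'
#' @param ledger Ledger from [generate_study()].
#' @param registry DDD registry (see [read_ddd_registry()]).
#' @param weights See [standard_weights()].
#' @return A tibble keyed by `pig_type`, `route` with columns `total_g`,
#'   `mg_per_kg_biomass`, `ddd_per_pig`, `ddd_rate`, `pigs_at_risk`.
#' @export
expected_metrics <- function(ledger, registry = read_ddd_registry(),
                             weights = standard_weights()) {
  par_total <- ledger$cohorts |>
    dplyr::group_by(.data$pig_type) |>
    dplyr::summarise(pigs_at_risk = sum(.data$pigs_at_risk),
                     median_time = stats::median(.data$time_at_risk),
                     .groups = "drop")

  ex <- ledger$exposure |>
    dplyr::mutate(route = ifelse(.data$route == "creep", "feed",
                                 .data$route)) |>
    dplyr::left_join(registry[c("aai", "long_acting",
                                "ddd_mg_per_kg_day")],
                     by = c("aai", "long_acting"))
  if (any(is.na(ex$ddd_mg_per_kg_day))) {
    stop("ledger contains ingredient(s) absent from the registry",
         call. = FALSE)
  }

  per_route <- ex |>
    dplyr::mutate(row_doses = .data$total_mg /
                    (.data$ddd_mg_per_kg_day *
                       unname(weights[.data$pig_type]))) |>
    dplyr::group_by(.data$pig_type, .data$route) |>
    dplyr::summarise(
      total_mg = sum(.data$total_mg),
      doses = sum(.data$row_doses),
      .groups = "drop"
    )
  all_routes <- per_route |>
    dplyr::group_by(.data$pig_type) |>
    dplyr::summarise(route = "all_routes",
                     total_mg = sum(.data$total_mg),
                     doses = sum(.data$doses), .groups = "drop")
  dplyr::bind_rows(per_route, all_routes) |>
    dplyr::left_join(par_total, by = "pig_type") |>
    dplyr::mutate(
      total_g = .data$total_mg / 1000,
      mg_per_kg_biomass = .data$total_mg /
        (.data$pigs_at_risk * unname(weights[.data$pig_type])),
      ddd_per_pig = .data$doses / .data$pigs_at_risk,
      ddd_rate = .data$ddd_per_pig / .data$median_time * 1000
    ) |>
    dplyr::select("pig_type", "route", "pigs_at_risk", "total_g",
                  "mg_per_kg_biomass", "ddd_per_pig", "ddd_rate") |>
    dplyr::arrange(.data$pig_type, .data$route)
}
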