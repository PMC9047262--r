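# Exposure quantification: who was at risk, for how long, and how many
# milligrams of each active ingredient were consumed by which route.

#' Number of pigs at risk of antimicrobial exposure
#'
#' Pigs entering the production cycle minus half the deaths during the
#' cycle; deaths are assumed to occur, on average, halfway through, so
#' half of each dead pig's cycle counts toward exposure opportunity. The
#' result may be fractional and is kept unrounded internally to avoid
#' biasing biomass denominators.
#'
#' @param n_start_or_entered Pigs at the start of the cycle (all-in-all-out)
#'   or pigs that entered during the data-collection period (continuous).
#' @param n_deaths Deaths during the cycle, `<= n_start_or_entered`.
#' @return Pigs at risk (possibly fractional).
#' @export
pigs_at_risk <- function(n_start_or_entered, n_deaths) {
  if (any(n_start_or_entered < 0) || any(n_deaths < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(n_deaths > n_start_or_entered)) {
    stop("n_deaths cannot exceed n_start_or_entered", call. = FALSE)
  }
  n_start_or_entered - n_deaths / 2
}

#' Time at risk of a cohort (days)
#'
#' For all-in-all-out cohorts, the anticipated end of the production cycle
#' (the questionnaire date) minus the day the first pigs entered,
#' inclusive of the start day and exclusive of the end day. For
#' continuous-flow cohorts, the producer-reported average cycle length.
#'
#' @param cohorts A cohort data frame (rows of the `cohorts` table).
#' @return Numeric vector of days, one per row.
#' @export
time_at_risk <- function(cohorts) {
  cohorts <- tibble::as_tibble(cohorts)
  aiao <- cohorts$flow_type == "all_in_all_out"
  if (any(aiao & is.na(cohorts$cycle_start_date))) {
    stop("all-in-all-out cohort lacks cycle_start_date", call. = FALSE)
  }
  if (any(!aiao & is.na(cohorts$avg_cycle_length_days))) {
    stop("continuous-flow cohort lacks avg_cycle_length_days", call. = FALSE)
  }
  out <- ifelse(
    aiao,
    as.numeric(cohorts$questionnaire_date - cohorts$cycle_start_date),
    cohorts$avg_cycle_length_days
  )
  if (any(out <= 0)) {
    stop("time at risk must be positive", call. = FALSE)
  }
  out
}

exposure_result <- function(cohort_id, pig_type, route, aai,
                            long_acting = FALSE, reason, total_mg,
                            pigs_exposed) {
  tibble::tibble(
    cohort_id = as.character(cohort_id),
    pig_type = as.character(pig_type),
    route = route,
    aai = as.character(aai),
    long_acting = as.logical(long_acting),
    reason = as.character(reason),
    total_mg = as.numeric(total_mg),
    pigs_exposed = as.numeric(pigs_exposed)
  )
}

#' Antimicrobial mass consumed through a medicated feed ration
#'
#' `total_mg = g_per_tonne x (feed_per_pig / 1000) x pigs_at_risk x
#' pct_fed x 1000`: grams of ingredient per tonne of feed, times tonnes of
#' feed consumed by the exposed fraction of the pigs at risk, converted to
#' milligrams. The exposed fraction multiplies the mass, not just the
#' head count.
#'
#' @param record One or more `feed` rows (needs `cohort_id`, `pig_type`,
#'   `aai`, `reason`, `g_per_tonne`, `pct_fed`).
#' @param feed_per_pig kg feed consumed per pig over the ration window.
#' @param pigs_at_risk Pigs at risk in the cohort.
#' @return An exposure tibble: `cohort_id`, `pig_type`, `route`, `aai`,
#'   `long_acting`, `reason`, `total_mg`, `pigs_exposed`.
#' @export
feed_mass <- function(record, feed_per_pig, pigs_at_risk) {
  record <- tibble::as_tibble(record)
  stopifnot(feed_per_pig >= 0)
  exposure_result(
    cohort_id = record$cohort_id, pig_type = record$pig_type,
    route = "feed", aai = record$aai, reason = record$reason,
    total_mg = record$g_per_tonne * (feed_per_pig / 1000) *
      pigs_at_risk * record$pct_fed * 1000,
    pigs_exposed = round(pigs_at_risk * record$pct_fed)
  )
}

#' Antimicrobial mass consumed through medicated water
#'
#' `total_mg = g_per_litre x daily_water x duration x pigs_at_risk x
#' pct_exposed x 1000`.
#'
#' @param record One or more `water` rows.
#' @param daily_water L water consumed per pig per day.
#' @param pigs_at_risk Pigs at risk in the cohort.
#' @return An exposure tibble (see [feed_mass()]).
#' @export
water_mass <- function(record, daily_water, pigs_at_risk) {
  record <- tibble::as_tibble(record)
  stopifnot(daily_water >= 0)
  exposure_result(
    cohort_id = record$cohort_id, pig_type = record$pig_type,
    route = "water", aai = record$aai, reason = record$reason,
    total_mg = record$g_per_litre * daily_water * record$duration *
      pigs_at_risk * record$pct_exposed * 1000,
    pigs_exposed = round(pigs_at_risk * record$pct_exposed)
  )
}

#' Antimicrobial mass administered by injection
#'
#' `total_mg = concentration (mg/mL) x volume_per_pig_per_day (mL) x
#' duration (days) x pigs_at_risk x pct_exposed`.
#'
#' @param record One or more `injection` rows.
#' @param pigs_at_risk Pigs at risk in the cohort.
#' @return An exposure tibble (see [feed_mass()]).
#' @export
injection_mass <- function(record, pigs_at_risk) {
  record <- tibble::as_tibble(record)
  long_acting <- if ("long_acting" %in% names(record)) {
    record$long_acting
  } else {
    FALSE
  }
  long_acting[is.na(long_acting)] <- FALSE
  exposure_result(
    cohort_id = record$cohort_id, pig_type = record$pig_type,
    route = "injection", aai = record$aai, long_acting = long_acting,
    reason = record$reason,
    total_mg = record$concentration * record$volume_per_pig_per_day *
      record$duration * pigs_at_risk * record$pct_exposed,
    pigs_exposed = round(pigs_at_risk * record$pct_exposed)
  )
}

#' Antimicrobial mass consumed through creep feed
#'
#' `total_mg = g_per_tonne x (creep_per_piglet / 1e6) x piglets_at_risk x
#' pct_piglets_fed x (1 - pct_wasted) x 1000`. Producer-estimated creep
#' wastage is applied against the consumed antimicrobial mass.
#'
#' @param record One or more `creep` rows.
#' @param creep_per_piglet g creep feed consumed per piglet (pre-wastage).
#' @param piglets_at_risk Suckling piglets at risk in the cohort.
#' @return An exposure tibble (see [feed_mass()]); `route` is `"creep"`.
#' @export
creep_mass <- function(record, creep_per_piglet, piglets_at_risk) {
  record <- tibble::as_tibble(record)
  stopifnot(creep_per_piglet >= 0)
  exposure_result(
    cohort_id = record$cohort_id, pig_type = "suckling",
    route = "creep", aai = record$aai, reason = record$reason,
    total_mg = record$g_per_tonne * (creep_per_piglet / 1e6) *
      piglets_at_risk * record$pct_piglets_fed *
      (1 - record$pct_wasted) * 1000,
    pigs_exposed = round(piglets_at_risk * record$pct_piglets_fed)
  )
}

# Per-cohort denominators plus ADG-based performance strata, the shared
# scaffolding for all route-level mass computations.
cohort_exposure_frame <- function(study) {
  co <- study$cohorts
  info <- dplyr::mutate(
    co,
    pig_type = stage_to_pig_type(.data$stage),
    pigs_at_risk = pigs_at_risk(.data$n_start_or_entered, .data$n_deaths),
    time_at_risk = time_at_risk(co)
  )
  info <- dplyr::mutate(
    info,
    adg = dplyr::if_else(
      .data$stage %in% c("nursery", "grower_finisher"),
      adg(.data$avg_start_weight, .data$avg_end_weight, .data$time_at_risk),
      NA_real_
    )
  )
  dplyr::mutate(
    dplyr::group_by(info, .data$stage),
    stratum = if (all(is.na(.data$adg))) {
      NA_character_
    } else {
      assign_stratum(.data$adg, .data$adg)
    }
  ) |>
    dplyr::ungroup()
}

#' Compute the full exposure table of a study
#'
#' Runs the intake models and the per-route mass formulas over every
#' treatment record: sow feed and water use fixed daily estimates; creep
#' feed uses the litter intake model over the creep-start-to-weaning
#' window; nursery and grower-finisher rations integrate the cohort's
#' performance-stratum daily-intake curve over the ration window (offset
#' into the curve by `(ration start weight - cohort start weight) / ADG`);
#' water for growing pigs uses the affine water model driven by the mean
#' daily feed intake over the full production period.
#'
#' @param study A validated `amu_study`.
#' @param curves Curve configuration from [read_intake_curves()].
#' @param water_params See [water_intake_params()].
#' @param sow_params See [sow_feed_params()].
#' @return A tidy exposure tibble, one row per treatment record:
#'   `cohort_id`, `pig_type`, `route`, `aai`, `long_acting`, `reason`,
#'   `total_mg`, `pigs_exposed`.
#' @export
compute_exposure <- function(study, curves = read_intake_curves(),
                             water_params = water_intake_params(),
                             sow_params = sow_feed_params()) {
  stopifnot(inherits(study, "amu_study"))
  info <- cohort_exposure_frame(study)
  results <- list()

  ration_feed_per_pig <- function(rec, inf) {
    # offset the ration window into the intake curve using the weight at
    # which the ration started; ADG converts weight offset to days
    curve <- curves$curves[[inf$stage]][[inf$stratum]]
    t0 <- 0
    if (!is.na(rec$start_weight) && !is.na(inf$adg) && inf$adg > 0) {
      t0 <- max(0, (rec$start_weight - inf$avg_start_weight) / inf$adg)
    }
    cumulative_feed_per_pig(curve, rec$duration_fed, from = t0)
  }

  if (nrow(study$feed) > 0) {
    for (i in seq_len(nrow(study$feed))) {
      rec <- study$feed[i, ]
      inf <- info[info$cohort_id == rec$cohort_id &
                    info$pig_type == rec$pig_type, ]
      if (rec$pig_type == "sows") {
        fpp <- sow_daily_feed(sow_params) * rec$duration_fed / 1000
      } else if (rec$pig_type %in% c("nursery", "grower_finisher")) {
        fpp <- ration_feed_per_pig(rec, inf)
      } else {
        stop("in-feed antimicrobial use for suckling pigs must be recorded ",
             "as creep feed (cohort ", rec$cohort_id, ")", call. = FALSE)
      }
      results[[length(results) + 1]] <-
        feed_mass(rec, fpp, inf$pigs_at_risk)
    }
  }

  if (nrow(study$creep) > 0) {
    for (i in seq_len(nrow(study$creep))) {
      rec <- study$creep[i, ]
      inf <- info[info$cohort_id == rec$cohort_id &
                    info$pig_type == "suckling", ]
      per_piglet <- creep_feed_per_piglet(rec$age_start,
                                          inf$weaning_age_days,
                                          model = curves$creep)
      results[[length(results) + 1]] <-
        creep_mass(rec, per_piglet, inf$pigs_at_risk)
    }
  }

  if (nrow(study$water) > 0) {
    for (i in seq_len(nrow(study$water))) {
      rec <- study$water[i, ]
      inf <- info[info$cohort_id == rec$cohort_id &
                    info$pig_type == rec$pig_type, ]
      if (rec$pig_type == "sows") {
        daily_water <- water_params$sow_daily_water
      } else if (rec$pig_type %in% c("nursery", "grower_finisher")) {
        curve <- curves$curves[[inf$stage]][[inf$stratum]]
        mean_feed <- cumulative_feed_per_pig(curve, inf$time_at_risk) /
          inf$time_at_risk
        daily_water <- water_intake_per_day(mean_feed, water_params)
      } else {
        stop("in-water antimicrobial use is not modelled for suckling pigs",
             " (cohort ", rec$cohort_id, ")", call. = FALSE)
      }
      results[[length(results) + 1]] <-
        water_mass(rec, daily_water, inf$pigs_at_risk)
    }
  }

  if (nrow(study$injection) > 0) {
    for (i in seq_len(nrow(study$injection))) {
      rec <- study$injection[i, ]
      inf <- info[info$cohort_id == rec$cohort_id &
                    info$pig_type == rec$pig_type, ]
      results[[length(results) + 1]] <-
        injection_mass(rec, inf$pigs_at_risk)
    }
  }

  if (length(results) == 0) {
    return(exposure_result(character(), character(), character(),
                           character(), logical(), character(),
                           numeric(), numeric()))
  }
  out <- dplyr::bind_rows(results)
  dplyr::arrange(out, .data$cohort_id, .data$pig_type, .data$route,
                 .data$aai)
}
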