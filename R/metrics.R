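# Frequency, weight-based and dose-based AMU metrics, and assembly of the
# stage x route and stage x route x ingredient report tables.

#' Standard weights at treatment
#'
#' Average weight at treatment per pig type, the biomass factor of the
#' weight-based metric and the per-animal factor of the defined daily
#' dose. Defaults: sows 240 kg and suckling pigs 4 kg and grower-finishers
#' 65 kg (European Medicines Agency standard weights), nursery pigs
#' 11.5 kg (no EMA value exists; a study-derived average is used).
#'
#' @param sows,suckling,nursery,grower_finisher kg, all positive.
#' @return Named numeric vector keyed by pig type.
#' @export
standard_weights <- function(sows = 240, suckling = 4, nursery = 11.5,
                             grower_finisher = 65) {
  w <- c(sows = sows, suckling = suckling, nursery = nursery,
         grower_finisher = grower_finisher)
  stopifnot(all(w > 0))
  w
}

#' Read a defined-daily-dose registry
#'
#' One row per (active ingredient, long-acting flag): the standard daily
#' dose in mg per kg animal weight per day, the antimicrobial class, and
#' the Health Canada importance category (I--IV or uncategorized;
#' ionophores count as antimicrobials, in category IV). Long-acting
#' formulations (e.g. long-acting procaine penicillin G or ceftiofur) are
#' distinct registry keys. The packaged default registry carries
#' illustrative standard doses intended to be replaced by a
#' jurisdiction-specific table.
#'
#' @param path CSV path, or `NULL` for the packaged default registry.
#' @return A tibble with columns `aai`, `long_acting`,
#'   `ddd_mg_per_kg_day`, `antimicrobial_class`, `hc_category`.
#' @export
read_ddd_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ddd_registry_default.csv",
                                package = "swineamu", mustWork = TRUE)
  reg <- readr::read_csv(path, col_types = "cldcc", progress = FALSE)
  needed <- c("aai", "long_acting", "ddd_mg_per_kg_day",
              "antimicrobial_class", "hc_category")
  missing_col <- setdiff(needed, names(reg))
  if (length(missing_col) > 0) {
    stop("DDD registry is missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  if (any(reg$ddd_mg_per_kg_day <= 0)) {
    stop("ddd_mg_per_kg_day must be positive", call. = FALSE)
  }
  if (anyDuplicated(reg[c("aai", "long_acting")]) > 0) {
    stop("DDD registry keys (aai, long_acting) must be unique",
         call. = FALSE)
  }
  reg
}

#' Milligrams of antimicrobial per kilogram of biomass
#'
#' Biomass is the number of animals at risk of treatment multiplied by
#' the standard weight at treatment.
#'
#' @param total_mg mg of active ingredient consumed.
#' @param pigs_at_risk Animals at risk (positive).
#' @param standard_weight kg, the average weight at treatment.
#' @return mg per kg biomass.
#' @export
mg_per_kg_biomass <- function(total_mg, pigs_at_risk, standard_weight) {
  if (any(pigs_at_risk <= 0)) {
    stop("pigs_at_risk must be positive", call. = FALSE)
  }
  total_mg / (pigs_at_risk * standard_weight)
}

#' Number of defined daily doses
#'
#' `total_mg / (ddd_mg_per_kg_day x standard_weight)`: how many standard
#' animal-days of treatment the consumed mass represents.
#'
#' @param total_mg mg of active ingredient consumed.
#' @param ddd_mg_per_kg_day The ingredient's standard dose (mg/kg/day), or
#'   a registry row carrying a `ddd_mg_per_kg_day` column.
#' @param standard_weight kg, the average weight at treatment.
#' @return Number of defined daily doses.
#' @export
n_ddd <- function(total_mg, ddd_mg_per_kg_day, standard_weight) {
  if (is.list(ddd_mg_per_kg_day)) {
    ddd_mg_per_kg_day <- ddd_mg_per_kg_day$ddd_mg_per_kg_day
  }
  stopifnot(all(ddd_mg_per_kg_day > 0), all(standard_weight > 0))
  total_mg / (ddd_mg_per_kg_day * standard_weight)
}

#' Defined daily doses per pig
#'
#' @param n_ddd Number of defined daily doses.
#' @param pigs_at_risk Animals at risk (positive).
#' @return Doses per pig.
#' @export
ddd_per_pig <- function(n_ddd, pigs_at_risk) {
  if (any(pigs_at_risk <= 0)) {
    stop("pigs_at_risk must be positive", call. = FALSE)
  }
  n_ddd / pigs_at_risk
}

#' Defined daily doses per 1000 pig-days
#'
#' Treatment intensity per animal-time: doses per pig divided by the time
#' at risk, per 1000 pig-days.
#'
#' @param ddd_per_pig Doses per pig.
#' @param time_at_risk Days at risk (positive); stage-level report rows
#'   use the stage's median production-cycle length.
#' @return Doses per 1000 pig-days.
#' @export
ddd_rate <- function(ddd_per_pig, time_at_risk) {
  if (any(time_at_risk <= 0)) {
    stop("time_at_risk must be positive", call. = FALSE)
  }
  ddd_per_pig / time_at_risk * 1000
}

# Resolve ddd values for exposure rows; errors name every unresolvable
# ingredient rather than silently defaulting.
registry_join <- function(exposures, registry) {
  out <- dplyr::left_join(exposures, registry,
                          by = c("aai", "long_acting"))
  missing_rows <- is.na(out$ddd_mg_per_kg_day)
  if (any(missing_rows)) {
    bad <- unique(paste0(
      out$aai[missing_rows],
      ifelse(out$long_acting[missing_rows], " (long-acting)", "")
    ))
    stop("no DDD registry entry for ingredient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Percentage of herds using antimicrobials
#'
#' Numerator: herds of the pig type with at least one positive-mass
#' exposure matching the route/ingredient filter. Denominator: all herds
#' of that pig type in the study.
#'
#' @param exposures Exposure table from [compute_exposure()].
#' @param study The `amu_study` the exposures came from.
#' @param pig_type One of the pig types.
#' @param route A route of administration, or `"all"`.
#' @param aai An active ingredient, or `"all"`.
#' @return A one-row tibble: `pig_type`, `route`, `aai`, `n_herds`,
#'   `n_total`, `percent`.
#' @export
percent_herds_using <- function(exposures, study, pig_type, route = "all",
                                aai = "all") {
  stage <- pig_type_to_stage(pig_type)
  denom_ids <- unique(study$cohorts$cohort_id[study$cohorts$stage == stage])
  if (length(denom_ids) == 0) {
    stop("no cohorts of pig type '", pig_type, "' in the study",
         call. = FALSE)
  }
  sel <- exposures$pig_type == pig_type & exposures$total_mg > 0
  if (route != "all") sel <- sel & exposures$route == route
  if (aai != "all") sel <- sel & exposures$aai == aai
  users <- unique(exposures$cohort_id[sel])
  tibble::tibble(
    pig_type = pig_type, route = route, aai = aai,
    n_herds = length(intersect(users, denom_ids)),
    n_total = length(denom_ids),
    percent = 100 * length(intersect(users, denom_ids)) / length(denom_ids)
  )
}

#' Median time at risk per pig type
#'
#' Stage-wide median production-cycle length, the animal-time denominator
#' of the dose rate in stage-level report rows. Sows and suckling pigs
#' share the farrowing cycle.
#'
#' @param study An `amu_study`.
#' @return Named numeric vector of days, keyed by pig type.
#' @export
median_times_at_risk <- function(study) {
  co <- study$cohorts
  tau <- time_at_risk(co)
  vapply(setNames(amu_pig_types, amu_pig_types), function(pt) {
    stats::median(tau[co$stage == pig_type_to_stage(pt)])
  }, numeric(1))
}

#' Assemble the stage-level AMU report tables
#'
#' Converts the exposure table into the three report shapes: per pig type
#' and route (plus an all-routes row), per pig type, route and active
#' ingredient, and a reasons-for-use mass breakdown. Creep feed is
#' reported under the feed route for suckling pigs.
#'
#' The default `"pooled"` mode sums masses over all cohorts of a stage and
#' divides once by the pooled denominator (total pigs at risk x standard
#' weight; stage median time at risk for the dose rate), so every stage
#' row is the exact mass-weighted study-level value. The `"per_herd"` mode
#' additionally returns per-cohort metric rows (each cohort's own
#' denominators and time at risk) with a median summary, for benchmarking
#' individual herds.
#'
#' @param study A validated `amu_study`.
#' @param exposures Exposure table from [compute_exposure()].
#' @param registry DDD registry from [read_ddd_registry()].
#' @param weights See [standard_weights()].
#' @param times Named vector of stage median times at risk (days) per pig
#'   type; computed from the study when `NULL`.
#' @param mode `"pooled"` (default) or `"per_herd"`.
#' @return A list of tibbles: `by_route`, `by_ingredient`, `reasons`, and
#'   (in per-herd mode) `per_herd` and `per_herd_summary`. Values are
#'   unrounded; see [round_half_even()] for report rounding.
#' @export
build_metrics_tables <- function(study, exposures,
                                 registry = read_ddd_registry(),
                                 weights = standard_weights(),
                                 times = NULL, mode = c("pooled", "per_herd")) {
  mode <- match.arg(mode)
  times <- times %||% median_times_at_risk(study)

  co <- study$cohorts
  denom <- tibble::tibble(
    pig_type = stage_to_pig_type(co$stage),
    cohort_id = co$cohort_id,
    pigs_at_risk = pigs_at_risk(co$n_start_or_entered, co$n_deaths),
    cohort_time = time_at_risk(co)
  )
  pooled_par <- denom |>
    dplyr::group_by(.data$pig_type) |>
    dplyr::summarise(pigs_at_risk = sum(.data$pigs_at_risk),
                     .groups = "drop")

  # creep is the suckling pigs' feed route in all report tables
  ex <- exposures |>
    dplyr::mutate(route = dplyr::if_else(.data$route == "creep", "feed",
                                         .data$route)) |>
    registry_join(registry) |>
    dplyr::mutate(
      weight = unname(unname(weights[.data$pig_type])),
      time = unname(unname(times[.data$pig_type])),
      n_doses = n_ddd(.data$total_mg, .data$ddd_mg_per_kg_day,
                      .data$weight)
    )

  by_ingredient <- ex |>
    dplyr::group_by(.data$pig_type, .data$route, .data$aai,
                    .data$long_acting, .data$antimicrobial_class,
                    .data$hc_category) |>
    dplyr::summarise(
      n_herds = dplyr::n_distinct(.data$cohort_id[.data$total_mg > 0]),
      total_mg = sum(.data$total_mg),
      n_doses = sum(.data$n_doses),
      .groups = "drop"
    ) |>
    dplyr::left_join(pooled_par, by = "pig_type") |>
    dplyr::mutate(
      total_g = .data$total_mg / 1000,
      mg_per_kg_biomass = mg_per_kg_biomass(
        .data$total_mg, .data$pigs_at_risk, unname(weights[.data$pig_type])),
      ddd_per_pig = ddd_per_pig(.data$n_doses, .data$pigs_at_risk),
      ddd_rate = ddd_rate(.data$ddd_per_pig, unname(times[.data$pig_type]))
    ) |>
    dplyr::arrange(.data$pig_type, .data$route, .data$aai) |>
    dplyr::select("pig_type", "route", "aai", "long_acting",
                  "antimicrobial_class", "hc_category", "n_herds",
                  "pigs_at_risk", "total_g", "mg_per_kg_biomass",
                  "ddd_per_pig", "ddd_rate")

  route_totals <- ex |>
    dplyr::group_by(.data$pig_type, .data$route) |>
    dplyr::summarise(total_mg = sum(.data$total_mg),
                     n_doses = sum(.data$n_doses), .groups = "drop")
  all_totals <- route_totals |>
    dplyr::group_by(.data$pig_type) |>
    dplyr::summarise(route = "all_routes", total_mg = sum(.data$total_mg),
                     n_doses = sum(.data$n_doses), .groups = "drop")
  by_route <- dplyr::bind_rows(route_totals, all_totals) |>
    dplyr::left_join(pooled_par, by = "pig_type") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      pct_herds = percent_herds_using(
        exposures |> dplyr::mutate(route = dplyr::if_else(
          .data$route == "creep", "feed", .data$route)),
        study, .data$pig_type,
        route = dplyr::if_else(.data$route == "all_routes", "all",
                               .data$route)
      )$percent
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      total_g = .data$total_mg / 1000,
      mg_per_kg_biomass = mg_per_kg_biomass(
        .data$total_mg, .data$pigs_at_risk, unname(weights[.data$pig_type])),
      ddd_per_pig = ddd_per_pig(.data$n_doses, .data$pigs_at_risk),
      ddd_rate = ddd_rate(.data$ddd_per_pig, unname(times[.data$pig_type])),
      pig_type = factor(.data$pig_type, levels = amu_pig_types),
      route = factor(.data$route,
                     levels = c("feed", "water", "injection", "all_routes"))
    ) |>
    dplyr::arrange(.data$pig_type, .data$route) |>
    dplyr::mutate(pig_type = as.character(.data$pig_type),
                  route = as.character(.data$route)) |>
    dplyr::select("pig_type", "route", "pct_herds", "pigs_at_risk",
                  "total_g", "mg_per_kg_biomass", "ddd_per_pig",
                  "ddd_rate")

  reasons <- ex |>
    dplyr::group_by(.data$pig_type, .data$route, .data$reason) |>
    dplyr::summarise(total_mg = sum(.data$total_mg), .groups = "drop") |>
    dplyr::group_by(.data$pig_type, .data$route) |>
    dplyr::mutate(pct_of_route_mass =
                    100 * .data$total_mg / sum(.data$total_mg)) |>
    dplyr::ungroup()

  out <- list(by_route = by_route, by_ingredient = by_ingredient,
              reasons = reasons)

  if (mode == "per_herd") {
    per_herd <- ex |>
      dplyr::group_by(.data$cohort_id, .data$pig_type, .data$route) |>
      dplyr::summarise(total_mg = sum(.data$total_mg),
                       n_doses = sum(.data$n_doses), .groups = "drop") |>
      dplyr::left_join(denom, by = c("cohort_id", "pig_type")) |>
      dplyr::mutate(
        mg_per_kg_biomass = mg_per_kg_biomass(
          .data$total_mg, .data$pigs_at_risk, unname(weights[.data$pig_type])),
        ddd_per_pig = ddd_per_pig(.data$n_doses, .data$pigs_at_risk),
        ddd_rate = ddd_rate(.data$ddd_per_pig, .data$cohort_time)
      )
    out$per_herd <- per_herd
    out$per_herd_summary <- per_herd |>
      dplyr::group_by(.data$pig_type, .data$route) |>
      dplyr::summarise(
        n_herds = dplyr::n(),
        median_mg_per_kg_biomass = stats::median(.data$mg_per_kg_biomass),
        median_ddd_per_pig = stats::median(.data$ddd_per_pig),
        median_ddd_rate = stats::median(.data$ddd_rate),
        .groups = "drop"
      )
  }
  out
}
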