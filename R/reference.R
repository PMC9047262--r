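#' Published route-level AMU summary used for reconciliation checks
#'
#' A route-of-administration summary published for a 2017--2018
#' cross-sectional AMU study of Ontario swine herds (25 farrowing, 25
#' nursery, 23 grower-finisher): per pig type and route, the percentage
#' of herds using antimicrobials, pigs at risk, total mass of active
#' ingredient, and the printed weight- and dose-based metrics. The mass
#' column is in grams: that is the unit under which the printed mg/kg
#' biomass values and the route-additivity of totals reconcile exactly.
#'
#' The printed pigs-at-risk and mass columns serve as *inputs* to the
#' package's reconciliation checks (recomputing mg/kg biomass and dose
#' rates from them); the `printed_*` columns are the published values
#' those recomputations are compared against. Note the published nursery
#' all-routes mg/kg (274.2) is slightly below the sum of its route rows
#' (276.6); the package follows additivity and does not reproduce that
#' figure.
#'
#' @return A tibble with columns `pig_type`, `route`, `pct_herds`,
#'   `pigs_at_risk`, `total_g`, `printed_mg_per_kg`,
#'   `printed_ddd_per_pig`, `printed_ddd_rate`.
#' @export
reference_route_summary <- function() {
  readr::read_csv(
    system.file("extdata", "reference_route_summary.csv",
                package = "swineamu", mustWork = TRUE),
    col_types = "ccdddddd", progress = FALSE
  )
}

#' Published stage median production-cycle lengths (days)
#'
#' Median time at risk per herd type from the same published study as
#' [reference_route_summary()]: farrowing 23 days (shared by lactating
#' sows and suckling pigs), nursery 52, grower-finisher 112. These are
#' the animal-time denominators of the published dose rates.
#'
#' @return Named numeric vector of days, keyed by pig type.
#' @export
reference_times <- function() {
  c(sows = 23, suckling = 23, nursery = 52, grower_finisher = 112)
}
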