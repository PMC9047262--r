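# Feed and water intake estimation: the inputs to in-feed and in-water
# antimicrobial mass. Sows use fixed NRC-style daily estimates; growing
# pigs use performance-stratified daily-intake curves that are fit by
# least squares and integrated in closed form.

#' Water intake model parameters
#'
#' Affine model of daily water intake (L/day) as a function of mean daily
#' feed intake (kg/day) for growing pigs, plus a fixed daily estimate for
#' lactating sows.
#'
#' @param intercept L/day at zero feed intake (default 0.149).
#' @param slope L of water per kg of daily feed (default 3.053).
#' @param sow_daily_water L/day for lactating sows (default 18).
#' @return A named list of parameters.
#' @export
water_intake_params <- function(intercept = 0.149, slope = 3.053,
                                sow_daily_water = 18) {
  stopifnot(slope > 0, sow_daily_water > 0)
  list(intercept = intercept, slope = slope,
       sow_daily_water = sow_daily_water)
}

#' Lactating-sow feed parameters
#'
#' @param gross_daily_feed g feed offered per sow per day (default 6280).
#' @param wastage Proportion of offered feed wasted (default 0.05).
#' @return A named list of parameters.
#' @export
sow_feed_params <- function(gross_daily_feed = 6280, wastage = 0.05) {
  stopifnot(gross_daily_feed > 0, wastage >= 0, wastage < 1)
  list(gross_daily_feed = gross_daily_feed, wastage = wastage)
}

#' Daily feed consumed by a lactating sow
#'
#' Gross daily allowance minus wastage; the default parameters give
#' 6280 g/day less 5 percent, i.e. 5966 g consumed per sow per day.
#'
#' @param params See [sow_feed_params()].
#' @return g feed consumed per sow per day.
#' @export
sow_daily_feed <- function(params = sow_feed_params()) {
  params$gross_daily_feed * (1 - params$wastage)
}

#' Daily water intake of growing pigs
#'
#' `intercept + slope * mean_daily_feed`, an affine function of mean daily
#' feed intake.
#'
#' @param mean_daily_feed kg feed per day (non-negative).
#' @param params See [water_intake_params()].
#' @return L water per day.
#' @export
water_intake_per_day <- function(mean_daily_feed,
                                 params = water_intake_params()) {
  if (any(mean_daily_feed < 0)) {
    stop("mean_daily_feed must be non-negative", call. = FALSE)
  }
  params$intercept + params$slope * mean_daily_feed
}

#' Average daily gain
#'
#' @param start_weight,end_weight kg at start and end of the period.
#' @param days Length of the period in days (positive).
#' @return kg gained per day.
#' @export
adg <- function(start_weight, end_weight, days) {
  if (any(days <= 0)) stop("days must be positive", call. = FALSE)
  (end_weight - start_weight) / days
}

#' Assign herds to performance strata by average daily gain
#'
#' Herds below the 25th percentile of the stage's ADG distribution are
#' "low" performers, herds above the 75th percentile "high", and the rest
#' "average". Percentiles use linear interpolation between order
#' statistics at `(n + 1) p` positions (quantile type 6, the common
#' epidemiological convention); a herd exactly at a threshold falls to
#' the non-extreme (average) stratum.
#'
#' @param cohort_adg ADG value(s) to classify (kg/day).
#' @param all_adg ADG values of every cohort in the stage (non-empty).
#' @return Character vector over `{"low", "average", "high"}`.
#' @export
assign_stratum <- function(cohort_adg, all_adg) {
  all_adg <- all_adg[!is.na(all_adg)]
  if (length(all_adg) == 0) {
    stop("all_adg must contain at least one cohort", call. = FALSE)
  }
  qs <- stats::quantile(all_adg, c(0.25, 0.75), names = FALSE, type = 6)
  # values within rounding error of a threshold count as ties (-> average)
  tol <- 1e-9 * pmax(1, abs(qs))
  dplyr::case_when(
    cohort_adg < qs[1] - tol[1] ~ "low",
    cohort_adg > qs[2] + tol[2] ~ "high",
    .default = "average"
  )
}

#' Fit a daily-intake curve to sampled points
#'
#' Fits a least-squares polynomial of the given degree to sampled
#' (day, kg/day) points; cumulative feed is then obtained by integrating
#' the fit in closed form.
#'
#' @param days Days on feed at which intake was sampled.
#' @param intake_kg Daily intake (kg/day) at those days.
#' @param degree Polynomial degree (default 2).
#' @return An object of class `intake_curve` with elements `coefficients`
#'   (ascending) and `domain`.
#' @export
fit_intake_curve <- function(days, intake_kg, degree = 2) {
  stopifnot(length(days) == length(intake_kg), length(days) > degree)
  fit <- stats::lm(intake_kg ~ stats::poly(days, degree, raw = TRUE))
  structure(
    list(coefficients = unname(stats::coef(fit)),
         domain = c(0, max(days))),
    class = "intake_curve"
  )
}

#' Construct an intake curve directly from polynomial coefficients
#'
#' @param coefficients Ascending polynomial coefficients of daily intake
#'   (kg/day) in days on feed.
#' @param domain Two-element numeric: the day range the curve is valid on.
#' @return An `intake_curve`.
#' @export
intake_curve <- function(coefficients, domain = c(0, 365)) {
  structure(list(coefficients = as.numeric(coefficients),
                 domain = as.numeric(domain)),
            class = "intake_curve")
}

#' @export
print.intake_curve <- function(x, ...) {
  cat("<intake_curve> degree", length(x$coefficients) - 1,
      "on days [", x$domain[1], ",", x$domain[2], "]\n")
  invisible(x)
}

#' Cumulative feed consumed per pig
#'
#' Definite integral of the stratum's daily-intake curve from `from` to
#' `from + days_on_feed`, evaluated in closed form from the polynomial
#' coefficients. Errors if the curve is negative anywhere on the interval.
#'
#' @param curve An [intake_curve()].
#' @param days_on_feed Days the ration was fed (non-negative).
#' @param from First day on feed of the ration window (default 0).
#' @return kg feed consumed per pig over the window.
#' @export
cumulative_feed_per_pig <- function(curve, days_on_feed, from = 0) {
  stopifnot(inherits(curve, "intake_curve"))
  if (any(days_on_feed < 0)) {
    stop("days_on_feed must be non-negative", call. = FALSE)
  }
  upper <- from + days_on_feed
  grid <- seq(min(from), max(upper), length.out = 513)
  if (min(poly_eval(curve$coefficients, grid)) < -1e-9) {
    stop("daily-intake curve is negative on the integration interval",
         call. = FALSE)
  }
  poly_integral(curve$coefficients, from, upper)
}

#' Creep-feed intake model
#'
#' Total litter creep intake (g) as a polynomial in creep-feeding duration
#' (days), normalized to a standard litter. The default model must predict
#' non-negative, non-decreasing litter intake over its domain.
#'
#' @param litter_size_standard Pigs per standard litter (default 11).
#' @param coefficients Ascending polynomial coefficients (g per litter).
#' @param domain Duration range (days) the model is checked on.
#' @return An object of class `creep_intake_model`.
#' @export
creep_intake_model <- function(litter_size_standard = 11,
                               coefficients = c(0, 20, 6),
                               domain = c(0, 42)) {
  grid <- seq(domain[1], domain[2], length.out = 257)
  pred <- poly_eval(coefficients, grid)
  if (any(pred < -1e-9) || any(diff(pred) < -1e-9)) {
    stop("creep model must be non-negative and non-decreasing in duration",
         call. = FALSE)
  }
  structure(list(litter_size_standard = litter_size_standard,
                 coefficients = as.numeric(coefficients),
                 domain = as.numeric(domain)),
            class = "creep_intake_model")
}

#' Creep feed consumed per piglet (pre-wastage)
#'
#' Evaluates the litter-total intake model at
#' `duration = weaning_age - creep_start_age` and divides by the standard
#' litter size. Producer-estimated wastage is applied downstream, against
#' the consumed antimicrobial mass.
#'
#' @param creep_start_age Age (days) when creep feed was first offered.
#' @param weaning_age Weaning age (days), `>= creep_start_age`.
#' @param model A [creep_intake_model()].
#' @return g creep feed consumed per piglet.
#' @export
creep_feed_per_piglet <- function(creep_start_age, weaning_age,
                                  model = creep_intake_model()) {
  duration <- weaning_age - creep_start_age
  if (any(duration < 0)) {
    stop("weaning_age must be >= creep_start_age", call. = FALSE)
  }
  poly_eval(model$coefficients, duration) / model$litter_size_standard
}

#' Read an intake-curve configuration
#'
#' Loads a YAML curve configuration: a creep model plus, per stage
#' (`nursery`, `grower_finisher`) and performance stratum (`low`,
#' `average`, `high`), sampled daily-intake points that are fit with
#' [fit_intake_curve()]. The packaged default configuration is used when
#' `path` is `NULL`.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @return A list with elements `creep` (a `creep_intake_model`) and
#'   `curves` (nested list `stage -> stratum -> intake_curve`).
#' @export
read_intake_curves <- function(path = NULL) {
  path <- path %||% system.file("extdata", "intake_curves.yaml",
                                package = "swineamu", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  degree <- cfg$degree %||% 2
  stages <- intersect(c("nursery", "grower_finisher"), names(cfg))
  curves <- lapply(setNames(stages, stages), function(stage) {
    lapply(setNames(names(cfg[[stage]]), names(cfg[[stage]])), function(st) {
      pts <- cfg[[stage]][[st]]
      fit_intake_curve(as.numeric(pts$days), as.numeric(pts$intake_kg),
                       degree = degree)
    })
  })
  creep_cfg <- cfg$creep %||% list()
  creep <- creep_intake_model(
    litter_size_standard = creep_cfg$litter_size_standard %||% 11,
    coefficients = as.numeric(creep_cfg$coefficients %||% c(0, 20, 6))
  )
  list(creep = creep, curves = curves)
}
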