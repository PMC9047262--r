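# Controlled vocabularies shared across the questionnaire model, the
# generator and the reporting layer.

#' Controlled vocabularies
#'
#' Enumerations used throughout the package: production stages, pig types,
#' routes of administration, reasons for use, raw health-status levels,
#' the disease panel and the biosecurity practice list.
#'
#' A "farrowing" herd contributes two pig types (lactating sows and
#' suckling pigs) that share one cohort identifier and one time at risk;
#' `stage` distinguishes the two rows (`farrowing_sows`, `suckling`) while
#' treatment and health records carry `pig_type` (`sows`, `suckling`, ...).
#'
#' @name vocabularies
#' @keywords internal
NULL

amu_stages <- c("farrowing_sows", "suckling", "nursery", "grower_finisher")
amu_pig_types <- c("sows", "suckling", "nursery", "grower_finisher")
amu_herd_types <- c("farrowing", "nursery", "grower_finisher")
amu_routes <- c("feed", "creep", "water", "injection")
amu_reasons <- c("treatment", "prevention", "growth_promotion", "unknown")
amu_flow_types <- c("all_in_all_out", "continuous")
amu_raw_statuses <- c(
  "confirmed_positive", "likely_positive",
  "confirmed_negative", "likely_negative", "unknown"
)
amu_diseases <- c(
  "APP", "E_coli", "erysipelas", "H_parasuis", "ileitis", "influenza",
  "mycoplasma", "PCVAD", "PED", "PRRS", "salmonella", "strep_suis", "TGE"
)
amu_biosecurity_practices <- c(
  "barn_boots", "coveralls", "boot_dip", "biosecurity_sign", "danish_entry",
  "barn_locked", "visitors_restricted", "shower_in", "quarantine_gilts",
  "downtime"
)

stage_to_pig_type <- function(stage) {
  ifelse(stage == "farrowing_sows", "sows", stage)
}

pig_type_to_stage <- function(pig_type) {
  ifelse(pig_type == "sows", "farrowing_sows", pig_type)
}

stage_to_herd_type <- function(stage) {
  ifelse(stage %in% c("farrowing_sows", "suckling"), "farrowing", stage)
}

# Polynomial helpers (coefficients in ascending order: c0 + c1*x + c2*x^2 ...)

poly_eval <- function(coefficients, x) {
  out <- rep(0, length(x))
  for (i in rev(seq_along(coefficients))) {
    out <- out * x + coefficients[[i]]
  }
  out
}

poly_antiderivative <- function(coefficients) {
  c(0, coefficients / seq_along(coefficients))
}

# Definite integral of the polynomial on [lower, upper]
poly_integral <- function(coefficients, lower, upper) {
  anti <- poly_antiderivative(coefficients)
  poly_eval(anti, upper) - poly_eval(anti, lower)
}

# round() in R is IEC 60559 round-half-even, the convention used for all
# report output; kept behind a name so report code reads unambiguously.
round_half_even <- function(x, digits = 1) round(x, digits)

abort_field <- function(message, code) {
  stop(structure(
    class = c("swineamu_error", "error", "condition"),
    list(message = message, call = NULL, code = code)
  ))
}
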