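# Descriptive herd-level tables: biosecurity frequencies with exact
# binomial confidence intervals, health status, vaccination, and
# antimicrobial-use-by-disease counts.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computes the exact binomial interval for a proportion from beta
#' quantiles: `lower = qbeta(alpha/2, k, n - k + 1)` and
#' `upper = qbeta(1 - alpha/2, k + 1, n - k)`, with `lower = 0` when
#' `k = 0` and `upper = 1` when `k = n`. The exact interval is used
#' because herd counts are small (about 25 per herd type), where
#' asymptotic intervals undercover.
#'
#' @param k Successes (herds using the practice), `0 <= k <= n`.
#' @param n Trials (herds), positive.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `numerator`, `denominator`, `point`,
#'   `lower`, `upper`, `level`; one row per element of `k`.
#' @export
#' @examples
#' proportion_ci(3, 25) # boot-dip use in 3 of 25 herds
proportion_ci <- function(k, n, level = 0.95) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  k <- as.numeric(k)
  n <- rep_len(as.numeric(n), length(k))
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(numerator = k, denominator = n, point = k / n,
                 lower = lower, upper = upper, level = level)
}

#' Build the descriptive report tables of a study
#'
#' Produces, per herd type: production-cycle-length summaries; biosecurity
#' practice frequencies with exact binomial confidence intervals; and, per
#' pig type and disease: health-status counts (positive / negative /
#' unknown after [classify_status()]), vaccination counts, and counts of
#' herds using antimicrobials against each disease.
#'
#' @param study A validated `amu_study`.
#' @param ci_level Confidence level for biosecurity intervals.
#' @return A list of tibbles: `cycle_length`, `biosecurity`,
#'   `health_status`, `vaccination`, `amu_by_disease`.
#' @export
build_descriptive_tables <- function(study, ci_level = 0.95) {
  stopifnot(inherits(study, "amu_study"))
  co <- study$cohorts

  herd <- tibble::tibble(
    cohort_id = co$cohort_id,
    herd_type = stage_to_herd_type(co$stage),
    time = time_at_risk(co)
  ) |> dplyr::distinct(.data$cohort_id, .data$herd_type,
                       .keep_all = TRUE)

  cycle_length <- herd |>
    dplyr::group_by(.data$herd_type) |>
    dplyr::summarise(
      n_herds = dplyr::n(),
      min_days = min(.data$time), max_days = max(.data$time),
      mean_days = mean(.data$time),
      median_days = stats::median(.data$time),
      .groups = "drop"
    )

  herd_n <- herd |> dplyr::count(.data$herd_type, name = "n_total")

  biosecurity <- study$biosecurity |>
    dplyr::left_join(herd[c("cohort_id", "herd_type")], by = "cohort_id") |>
    dplyr::group_by(.data$herd_type, .data$practice) |>
    dplyr::summarise(n_herds = sum(.data$used), .groups = "drop") |>
    dplyr::left_join(herd_n, by = "herd_type")
  if (nrow(biosecurity) > 0) {
    ci <- proportion_ci(biosecurity$n_herds, biosecurity$n_total,
                        level = ci_level)
    biosecurity <- biosecurity |>
      dplyr::mutate(percent = 100 * ci$point, ci_lower = ci$lower,
                    ci_upper = ci$upper)
  } else {
    biosecurity <- dplyr::mutate(biosecurity, percent = numeric(0),
                                 ci_lower = numeric(0),
                                 ci_upper = numeric(0))
  }

  pig_type_n <- tibble::tibble(
    pig_type = stage_to_pig_type(co$stage),
    cohort_id = co$cohort_id
  ) |> dplyr::count(.data$pig_type, name = "n_total")

  health <- study$health
  health_status <- health |>
    dplyr::mutate(status = classify_status(.data$raw_status)) |>
    dplyr::group_by(.data$pig_type, .data$disease) |>
    dplyr::summarise(
      n_positive = sum(.data$status == "positive"),
      n_negative = sum(.data$status == "negative"),
      n_unknown = sum(.data$status == "unknown"),
      .groups = "drop"
    ) |>
    dplyr::left_join(pig_type_n, by = "pig_type") |>
    dplyr::mutate(
      pct_positive = 100 * .data$n_positive / .data$n_total,
      pct_negative = 100 * .data$n_negative / .data$n_total,
      pct_unknown = 100 * .data$n_unknown / .data$n_total
    )

  vaccination <- health |>
    dplyr::group_by(.data$pig_type, .data$disease) |>
    dplyr::summarise(n_vaccinated = sum(.data$vaccinated, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::left_join(pig_type_n, by = "pig_type") |>
    dplyr::mutate(percent = 100 * .data$n_vaccinated / .data$n_total)

  amu_by_disease <- health |>
    dplyr::group_by(.data$pig_type, .data$disease) |>
    dplyr::summarise(n_using_amu = sum(.data$amu_for_disease,
                                       na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::left_join(pig_type_n, by = "pig_type") |>
    dplyr::mutate(percent = 100 * .data$n_using_amu / .data$n_total)

  list(cycle_length = cycle_length, biosecurity = biosecurity,
       health_status = health_status, vaccination = vaccination,
       amu_by_disease = amu_by_disease)
}
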