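# End-to-end pipeline: load -> validate -> intake -> exposure -> metrics
# -> descriptive tables, with deterministic CSV/JSON report output.

#' Run the full AMU quantification pipeline
#'
#' Loads (or accepts) a study, validates it, computes the exposure table,
#' the stage-level metric tables and the descriptive tables, and writes
#' the report set to `out_dir`: `cycle_length.csv`, `biosecurity.csv`,
#' `health_status.csv`, `vaccination.csv`, `amu_by_disease.csv`,
#' `exposure.csv`, `amu_by_route.csv`, `amu_by_ingredient.csv`,
#' `reasons.csv` and a machine-readable `summary.json`. Report CSVs are
#' written deterministically: re-running on identical inputs reproduces
#' byte-identical files.
#'
#' @param input A directory of study CSVs (see [read_study()]) or an
#'   `amu_study` object.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing and just return the computed tables.
#' @param curves Intake-curve configuration path or object; `NULL` for
#'   packaged defaults.
#' @param registry DDD registry path or tibble; `NULL` for the packaged
#'   default.
#' @param weights See [standard_weights()].
#' @param times Stage median times at risk per pig type, or `NULL` to
#'   derive them from the study.
#' @param mode `"pooled"` or `"per_herd"` (see [build_metrics_tables()]).
#' @param round_digits Decimal places for metric columns in report files
#'   (round-half-even); in-memory tables stay unrounded.
#' @param validate_only If `TRUE`, stop after validation and write
#'   `validation.json` (a machine-readable problem report) to `out_dir`.
#' @return Invisibly, a list: `study`, `problems`, `exposure`, `metrics`,
#'   `descriptive`, `files`.
#' @export
run_pipeline <- function(input, out_dir = NULL, curves = NULL,
                         registry = NULL, weights = standard_weights(),
                         times = NULL, mode = c("pooled", "per_herd"),
                         round_digits = 1, validate_only = FALSE) {
  mode <- match.arg(mode)
  if (inherits(input, "amu_study")) {
    study <- input
    problems <- validate_study(study)
  } else {
    loaded <- load_study(input)
    study <- loaded$study
    problems <- loaded$problems
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  if (validate_only || nrow(problems) > 0) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(n_problems = nrow(problems), problems = problems),
        file.path(out_dir, "validation.json"),
        dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
      )
    }
    if (nrow(problems) > 0) {
      stop("study failed validation (", nrow(problems), " problem(s)); ",
           "first: ", problems$message[1], call. = FALSE)
    }
    return(invisible(list(study = study, problems = problems)))
  }

  if (!inherits(curves, "list") || is.null(curves$curves)) {
    curves <- read_intake_curves(curves)
  }
  if (!is.data.frame(registry)) {
    registry <- read_ddd_registry(registry)
  }

  exposure <- compute_exposure(study, curves = curves)
  metrics <- build_metrics_tables(study, exposure, registry = registry,
                                  weights = weights, times = times,
                                  mode = mode)
  descriptive <- build_descriptive_tables(study)

  files <- character()
  if (!is.null(out_dir)) {
    round_cols <- function(df, cols) {
      for (cl in intersect(cols, names(df))) {
        df[[cl]] <- round_half_even(df[[cl]], round_digits)
      }
      df
    }
    metric_cols <- c("pct_herds", "total_g", "mg_per_kg_biomass",
                     "ddd_per_pig", "ddd_rate", "percent",
                     "pct_of_route_mass", "mean_days", "median_days",
                     "pct_positive", "pct_negative", "pct_unknown",
                     "median_mg_per_kg_biomass", "median_ddd_per_pig",
                     "median_ddd_rate")
    out_tables <- list(
      cycle_length = descriptive$cycle_length,
      biosecurity = dplyr::mutate(
        descriptive$biosecurity,
        ci_lower = round_half_even(.data$ci_lower, 2),
        ci_upper = round_half_even(.data$ci_upper, 2)
      ),
      health_status = descriptive$health_status,
      vaccination = descriptive$vaccination,
      amu_by_disease = descriptive$amu_by_disease,
      exposure = exposure,
      amu_by_route = metrics$by_route,
      amu_by_ingredient = metrics$by_ingredient,
      reasons = metrics$reasons
    )
    if (mode == "per_herd") {
      out_tables$amu_per_herd <- metrics$per_herd
      out_tables$amu_per_herd_summary <- metrics$per_herd_summary
    }
    for (nm in names(out_tables)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(round_cols(out_tables[[nm]], metric_cols), f,
                       na = "")
      files <- c(files, f)
    }
    summary <- list(
      package_version = as.character(utils::packageVersion("swineamu")),
      mode = mode,
      round_digits = round_digits,
      n_herds = length(unique(study$cohorts$cohort_id)),
      n_cohort_rows = nrow(study$cohorts),
      n_records = vapply(
        study[setdiff(names(study), "cohorts")], nrow, integer(1)),
      tables_written = basename(files)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, file.path(out_dir, "summary.json"))
  }

  invisible(list(study = study, problems = problems, exposure = exposure,
                 metrics = metrics, descriptive = descriptive,
                 files = files))
}
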