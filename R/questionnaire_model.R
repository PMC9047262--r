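#' Construct a study object from its component tables
#'
#' An `amu_study` bundles the seven questionnaire record families for one
#' cross-sectional study: cohorts (one row per production-stage batch and
#' pig type), in-feed rations, creep feed, water medications, injections,
#' herd health status and biosecurity practices. All proportions are stored
#' internally in `[0, 1]`; the CSV reader converts questionnaire
#' percentages (0--100) at the boundary.
#'
#' A farrowing herd contributes two cohort rows (stages `farrowing_sows`
#' and `suckling`) sharing one `cohort_id`, one flow type and one time at
#' risk, so that lactating sows and suckling pigs can be reported
#' separately from a single farrowing questionnaire.
#'
#' @param cohorts,feed,creep,water,injection,health,biosecurity Data frames
#'   with the columns documented in [study_schema()]. Missing record
#'   families default to empty tables.
#' @param validate If `TRUE` (default), run [validate_study()] and stop on
#'   any validation error.
#' @return An object of class `amu_study`: a named list of tibbles.
#' @export
amu_study <- function(cohorts, feed = NULL, creep = NULL, water = NULL,
                      injection = NULL, health = NULL, biosecurity = NULL,
                      validate = TRUE) {
  schema <- study_schema()
  study <- list(
    cohorts = coerce_table(cohorts, schema$cohorts),
    feed = coerce_table(feed, schema$feed),
    creep = coerce_table(creep, schema$creep),
    water = coerce_table(water, schema$water),
    injection = coerce_table(injection, schema$injection),
    health = coerce_table(health, schema$health),
    biosecurity = coerce_table(biosecurity, schema$biosecurity)
  )
  class(study) <- "amu_study"
  if (validate) {
    problems <- validate_study(study)
    if (nrow(problems) > 0) {
      stop(
        "study failed validation (", nrow(problems), " problem(s)):\n",
        paste(utils::head(problems$message, 10), collapse = "\n"),
        call. = FALSE
      )
    }
  }
  study
}

#' @export
print.amu_study <- function(x, ...) {
  n_herds <- table(factor(
    stage_to_herd_type(unique(x$cohorts[c("cohort_id", "stage")])$stage),
    levels = amu_herd_types
  ))
  cat("<amu_study>\n")
  cat("  herds:", paste(names(n_herds), n_herds, sep = " = ", collapse = ", "), "\n")
  for (nm in setdiff(names(x), "cohorts")) {
    cat(sprintf("  %-11s %d record(s)\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Column schema of the questionnaire tables
#'
#' Returns, for each record family, the expected column names and readr
#' column types, plus which columns are questionnaire percentages
#' (converted between 0--100 on disk and 0--1 in memory).
#'
#' @return A named list with elements `cols` (readr type string),
#'   `pct_cols` and `required`.
#' @export
study_schema <- function() {
  list(
    cohorts = list(
      cols = c(
        cohort_id = "c", stage = "c", flow_type = "c", rwa_program = "l",
        questionnaire_date = "D", cycle_start_date = "D",
        avg_cycle_length_days = "d", n_start_or_entered = "d",
        n_deaths = "d", weaning_age_days = "d", avg_start_weight = "d",
        avg_end_weight = "d", litters_observed = "d"
      ),
      pct_cols = character(),
      required = c(
        "cohort_id", "stage", "flow_type", "rwa_program",
        "questionnaire_date", "n_start_or_entered", "n_deaths",
        "avg_start_weight", "avg_end_weight"
      )
    ),
    feed = list(
      cols = c(
        cohort_id = "c", pig_type = "c", ration_name = "c", aai = "c",
        g_per_tonne = "d", reason = "c", start_weight = "d",
        end_weight = "d", duration_fed = "d", pct_fed = "d"
      ),
      pct_cols = "pct_fed",
      required = c("cohort_id", "pig_type", "aai", "g_per_tonne",
                   "duration_fed", "pct_fed")
    ),
    creep = list(
      cols = c(
        cohort_id = "c", aai = "c", g_per_tonne = "d", reason = "c",
        age_start = "d", age_end = "d", pct_piglets_fed = "d",
        pct_wasted = "d"
      ),
      pct_cols = c("pct_piglets_fed", "pct_wasted"),
      required = c("cohort_id", "aai", "g_per_tonne", "age_start",
                   "age_end", "pct_piglets_fed", "pct_wasted")
    ),
    water = list(
      cols = c(
        cohort_id = "c", pig_type = "c", aai = "c", product = "c",
        g_per_litre = "d", reason = "c", duration = "d",
        weight_at_start = "d", age_at_start = "d", pct_exposed = "d"
      ),
      pct_cols = "pct_exposed",
      required = c("cohort_id", "pig_type", "aai", "g_per_litre",
                   "duration", "pct_exposed")
    ),
    injection = list(
      cols = c(
        cohort_id = "c", pig_type = "c", aai = "c", long_acting = "l",
        product = "c", concentration = "d", volume_per_pig_per_day = "d",
        duration = "d", reason = "c", weight_at_start = "d",
        age_at_start = "d", pct_exposed = "d"
      ),
      pct_cols = "pct_exposed",
      required = c("cohort_id", "pig_type", "aai", "concentration",
                   "volume_per_pig_per_day", "duration", "pct_exposed")
    ),
    health = list(
      cols = c(
        cohort_id = "c", pig_type = "c", disease = "c", raw_status = "c",
        vaccinated = "l", amu_for_disease = "l"
      ),
      pct_cols = character(),
      required = c("cohort_id", "pig_type", "disease", "raw_status")
    ),
    biosecurity = list(
      cols = c(
        cohort_id = "c", practice = "c", used = "l", downtime_hours = "d",
        farms_within_2km = "d"
      ),
      pct_cols = character(),
      required = c("cohort_id", "practice", "used")
    )
  )
}

coerce_table <- function(df, table_schema) {
  template <- empty_table(table_schema)
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    return(template)
  }
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(names(table_schema$cols), names(df))
  for (nm in missing_cols) {
    df[[nm]] <- template[[nm]][NA_integer_]
  }
  for (nm in names(table_schema$cols)) {
    df[[nm]] <- switch(table_schema$cols[[nm]],
      c = as.character(df[[nm]]),
      d = as.numeric(df[[nm]]),
      l = as.logical(df[[nm]]),
      D = as.Date(df[[nm]])
    )
  }
  df[names(table_schema$cols)]
}

empty_table <- function(table_schema) {
  proto <- list(c = character(), d = double(), l = logical(),
                D = as.Date(character()))
  tibble::as_tibble(lapply(table_schema$cols, function(tp) proto[[tp]]))
}

#' Read a study from a directory of CSV files
#'
#' Expects one CSV per record family (`cohorts.csv`, `feed.csv`,
#' `creep.csv`, `water.csv`, `injection.csv`, `health.csv`,
#' `biosecurity.csv`); absent files are treated as empty tables.
#' Percentage columns (`pct_*`) are converted from the questionnaire scale
#' (0--100) to proportions in `[0, 1]`. Dates are ISO-8601.
#'
#' @param path Directory containing the CSV files.
#' @param validate Stop on validation problems (default `TRUE`); see
#'   [load_study()] for a non-throwing report.
#' @return An `amu_study`.
#' @export
read_study <- function(path, validate = TRUE) {
  schema <- study_schema()
  tables <- lapply(names(schema), function(nm) {
    file <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(file)) {
      return(NULL)
    }
    types <- paste(schema[[nm]]$cols, collapse = "")
    df <- readr::read_csv(file, col_types = types, progress = FALSE)
    missing_header <- setdiff(names(schema[[nm]]$cols), names(df))
    if (length(missing_header) > 0) {
      stop("file ", basename(file), " is missing required column(s): ",
           paste(missing_header, collapse = ", "), call. = FALSE)
    }
    for (pc in schema[[nm]]$pct_cols) {
      df[[pc]] <- df[[pc]] / 100
    }
    df
  })
  names(tables) <- names(schema)
  if (is.null(tables$cohorts)) {
    stop("cohorts.csv not found in ", path, call. = FALSE)
  }
  amu_study(
    cohorts = tables$cohorts, feed = tables$feed, creep = tables$creep,
    water = tables$water, injection = tables$injection,
    health = tables$health, biosecurity = tables$biosecurity,
    validate = validate
  )
}

#' Write a study to a directory of CSV files
#'
#' Inverse of [read_study()]: writes one CSV per record family in the
#' dialect the reader consumes (percentages on the 0--100 questionnaire
#' scale, ISO-8601 dates). Re-reading the output reproduces the study's
#' field values.
#'
#' @param study An `amu_study`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "amu_study"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  schema <- study_schema()
  for (nm in names(schema)) {
    df <- study[[nm]]
    for (pc in schema[[nm]]$pct_cols) {
      df[[pc]] <- df[[pc]] * 100
    }
    readr::write_csv(df, file.path(path, paste0(nm, ".csv")), na = "")
  }
  invisible(path)
}

#' Load and validate a study, returning a validation report
#'
#' Reads the CSV files under `path` and validates every record against the
#' type invariants (ranges, enumerations, flow-type field presence,
#' referential integrity of `cohort_id`). Unlike [read_study()], this
#' never throws on content problems: it returns the study (possibly
#' invalid) together with the problem table, for use by validation-only
#' front ends.
#'
#' @param path Directory of CSV files.
#' @return A list with elements `study` (an unvalidated `amu_study`) and
#'   `problems` (tibble with columns `code`, `table`, `row`, `cohort_id`,
#'   `field`, `message`).
#' @export
load_study <- function(path) {
  study <- read_study(path, validate = FALSE)
  list(study = study, problems = validate_study(study))
}

#' Validate a study against the questionnaire-model invariants
#'
#' Checks, per record family: required fields present, enumerations within
#' their controlled vocabulary, proportions in `[0, 1]`, non-negative
#' doses and durations, `n_deaths <= n_start_or_entered`, positive
#' weights, exactly one of `cycle_start_date` /
#' `avg_cycle_length_days` according to flow type, stage-specific fields
#' only for their stage, and that every record references an existing
#' `(cohort_id, pig_type)`.
#'
#' @param study An `amu_study`.
#' @return A tibble of problems (zero rows when the study is valid) with
#'   columns `code`, `table`, `row`, `cohort_id`, `field`, `message`.
#' @export
validate_study <- function(study) {
  problems <- list()
  add <- function(code, table, row, cohort_id, field, message) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      code = code, table = table, row = as.integer(row),
      cohort_id = as.character(cohort_id), field = field, message = message
    )
  }
  check_range <- function(table, df, field, ok, code, what) {
    bad <- which(!is.na(df[[field]]) & !ok)
    for (i in bad) {
      add(code, table, i, df$cohort_id[i], field,
          sprintf("%s row %d (cohort %s): field '%s' %s (value %s)",
                  table, i, df$cohort_id[i], field, what,
                  format(df[[field]][i])))
    }
  }
  check_required <- function(table, df, fields) {
    for (field in fields) {
      bad <- which(is.na(df[[field]]))
      for (i in bad) {
        add("E_MISSING", table, i, df$cohort_id[i], field,
            sprintf("%s row %d (cohort %s): required field '%s' is missing",
                    table, i, df$cohort_id[i], field))
      }
    }
  }
  check_enum <- function(table, df, field, levels) {
    bad <- which(!is.na(df[[field]]) & !(df[[field]] %in% levels))
    for (i in bad) {
      add("E_ENUM", table, i, df$cohort_id[i], field,
          sprintf("%s row %d (cohort %s): field '%s' has unrecognized level '%s'",
                  table, i, df$cohort_id[i], field, df[[field]][i]))
    }
  }
  schema <- study_schema()

  co <- study$cohorts
  check_required("cohorts", co, schema$cohorts$required)
  check_enum("cohorts", co, "stage", amu_stages)
  check_enum("cohorts", co, "flow_type", amu_flow_types)
  check_range("cohorts", co, "n_deaths",
              co$n_deaths >= 0 & co$n_deaths <= co$n_start_or_entered,
              "E_RANGE", "must satisfy 0 <= n_deaths <= n_start_or_entered")
  check_range("cohorts", co, "avg_start_weight", co$avg_start_weight > 0,
              "E_RANGE", "must be positive")
  check_range("cohorts", co, "avg_end_weight", co$avg_end_weight > 0,
              "E_RANGE", "must be positive")
  # flow-type-dependent fields: AIAO needs cycle_start_date, continuous
  # needs avg_cycle_length_days, and not the other way round
  aiao <- !is.na(co$flow_type) & co$flow_type == "all_in_all_out"
  cont <- !is.na(co$flow_type) & co$flow_type == "continuous"
  for (i in which(aiao & is.na(co$cycle_start_date))) {
    add("E_FLOW", "cohorts", i, co$cohort_id[i], "cycle_start_date",
        sprintf("cohorts row %d (cohort %s): all-in-all-out cohort lacks cycle_start_date",
                i, co$cohort_id[i]))
  }
  for (i in which(cont & is.na(co$avg_cycle_length_days))) {
    add("E_FLOW", "cohorts", i, co$cohort_id[i], "avg_cycle_length_days",
        sprintf("cohorts row %d (cohort %s): continuous-flow cohort lacks avg_cycle_length_days",
                i, co$cohort_id[i]))
  }
  for (i in which(aiao & !is.na(co$avg_cycle_length_days))) {
    add("E_FLOW", "cohorts", i, co$cohort_id[i], "avg_cycle_length_days",
        sprintf("cohorts row %d (cohort %s): all-in-all-out cohort must not set avg_cycle_length_days",
                i, co$cohort_id[i]))
  }
  for (i in which(cont & !is.na(co$cycle_start_date))) {
    add("E_FLOW", "cohorts", i, co$cohort_id[i], "cycle_start_date",
        sprintf("cohorts row %d (cohort %s): continuous-flow cohort must not set cycle_start_date",
                i, co$cohort_id[i]))
  }
  # stage-specific fields
  farrowing <- !is.na(co$stage) & co$stage %in% c("farrowing_sows", "suckling")
  for (i in which(!farrowing & !is.na(co$weaning_age_days))) {
    add("E_STAGE", "cohorts", i, co$cohort_id[i], "weaning_age_days",
        sprintf("cohorts row %d (cohort %s): weaning_age_days only applies to farrowing stages",
                i, co$cohort_id[i]))
  }
  for (i in which(!farrowing & !is.na(co$litters_observed))) {
    add("E_STAGE", "cohorts", i, co$cohort_id[i], "litters_observed",
        sprintf("cohorts row %d (cohort %s): litters_observed only applies to farrowing stages",
                i, co$cohort_id[i]))
  }
  dup <- duplicated(co[c("cohort_id", "stage")])
  for (i in which(dup)) {
    add("E_DUP", "cohorts", i, co$cohort_id[i], "cohort_id",
        sprintf("cohorts row %d: duplicate (cohort_id, stage) = (%s, %s)",
                i, co$cohort_id[i], co$stage[i]))
  }

  cohort_keys <- paste(co$cohort_id, stage_to_pig_type(co$stage))
  check_ref <- function(table, df, with_pig_type = TRUE,
                        fixed_pig_type = NULL) {
    if (nrow(df) == 0) return()
    key <- if (!is.null(fixed_pig_type)) {
      paste(df$cohort_id, fixed_pig_type)
    } else if (with_pig_type) {
      paste(df$cohort_id, df$pig_type)
    } else {
      df$cohort_id
    }
    universe <- if (with_pig_type || !is.null(fixed_pig_type)) {
      cohort_keys
    } else {
      co$cohort_id
    }
    for (i in which(!(key %in% universe))) {
      add("E_ORPHAN", table, i, df$cohort_id[i], "cohort_id",
          sprintf("%s row %d: no cohort matches (cohort_id, pig_type) = (%s)",
                  table, i, key[i]))
    }
  }

  fd <- study$feed
  check_required("feed", fd, schema$feed$required)
  check_enum("feed", fd, "pig_type", amu_pig_types)
  check_enum("feed", fd, "reason", amu_reasons)
  check_range("feed", fd, "g_per_tonne", fd$g_per_tonne >= 0, "E_RANGE",
              "must be >= 0")
  check_range("feed", fd, "duration_fed", fd$duration_fed >= 0, "E_RANGE",
              "must be >= 0")
  check_range("feed", fd, "pct_fed", fd$pct_fed >= 0 & fd$pct_fed <= 1,
              "E_RANGE", "must be a proportion in [0, 1]")
  check_ref("feed", fd)

  cr <- study$creep
  check_required("creep", cr, schema$creep$required)
  check_enum("creep", cr, "reason", amu_reasons)
  check_range("creep", cr, "g_per_tonne", cr$g_per_tonne >= 0, "E_RANGE",
              "must be >= 0")
  check_range("creep", cr, "age_end", cr$age_end >= cr$age_start, "E_RANGE",
              "must satisfy age_start <= age_end")
  check_range("creep", cr, "pct_piglets_fed",
              cr$pct_piglets_fed >= 0 & cr$pct_piglets_fed <= 1,
              "E_RANGE", "must be a proportion in [0, 1]")
  check_range("creep", cr, "pct_wasted",
              cr$pct_wasted >= 0 & cr$pct_wasted < 1,
              "E_RANGE", "must be a proportion in [0, 1)")
  check_ref("creep", cr, fixed_pig_type = "suckling")

  wa <- study$water
  check_required("water", wa, schema$water$required)
  check_enum("water", wa, "pig_type", amu_pig_types)
  check_enum("water", wa, "reason", amu_reasons)
  check_range("water", wa, "g_per_litre", wa$g_per_litre >= 0, "E_RANGE",
              "must be >= 0")
  check_range("water", wa, "duration", wa$duration >= 0, "E_RANGE",
              "must be >= 0")
  check_range("water", wa, "pct_exposed",
              wa$pct_exposed >= 0 & wa$pct_exposed <= 1,
              "E_RANGE", "must be a proportion in [0, 1]")
  check_ref("water", wa)

  inj <- study$injection
  check_required("injection", inj, schema$injection$required)
  check_enum("injection", inj, "pig_type", amu_pig_types)
  check_enum("injection", inj, "reason", amu_reasons)
  check_range("injection", inj, "concentration", inj$concentration > 0,
              "E_RANGE", "must be > 0 (mg active ingredient per mL)")
  check_range("injection", inj, "volume_per_pig_per_day",
              inj$volume_per_pig_per_day >= 0, "E_RANGE", "must be >= 0")
  check_range("injection", inj, "duration", inj$duration >= 0, "E_RANGE",
              "must be >= 0")
  check_range("injection", inj, "pct_exposed",
              inj$pct_exposed >= 0 & inj$pct_exposed <= 1,
              "E_RANGE", "must be a proportion in [0, 1]")
  check_ref("injection", inj)

  he <- study$health
  check_required("health", he, schema$health$required)
  check_enum("health", he, "pig_type", amu_pig_types)
  check_enum("health", he, "raw_status", amu_raw_statuses)
  check_ref("health", he)

  bi <- study$biosecurity
  check_required("biosecurity", bi, schema$biosecurity$required)
  check_enum("biosecurity", bi, "practice", amu_biosecurity_practices)
  check_range("biosecurity", bi, "downtime_hours", bi$downtime_hours >= 0,
              "E_RANGE", "must be >= 0")
  check_ref("biosecurity", bi, with_pig_type = FALSE)

  if (length(problems) == 0) {
    tibble::tibble(
      code = character(), table = character(), row = integer(),
      cohort_id = character(), field = character(), message = character()
    )
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Collapse a five-level reported health status to positive/negative/unknown
#'
#' Herds reporting "confirmed positive" or "likely positive" are classified
#' positive; "confirmed negative" or "likely negative" negative; "unknown"
#' stays unknown. Laboratory confirmation is deliberately not required for
#' a positive classification: a herd believed positive is managed (and
#' medicated) as positive.
#'
#' @param raw_status Character vector of raw status levels.
#' @return Character vector over `{"positive", "negative", "unknown"}`.
#' @export
#' @examples
#' classify_status(c("likely_positive", "confirmed_negative", "unknown"))
classify_status <- function(raw_status) {
  bad <- setdiff(unique(raw_status[!is.na(raw_status)]), amu_raw_statuses)
  if (length(bad) > 0) {
    stop("unrecognized health status level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(raw_status))
  out[raw_status %in% c("confirmed_positive", "likely_positive")] <- "positive"
  out[raw_status %in% c("confirmed_negative", "likely_negative")] <- "negative"
  out[raw_status == "unknown"] <- "unknown"
  out
}

#' Segment daily administrations into treatment episodes
#'
#' A treatment is a continuous daily administration of an antimicrobial at
#' a specific dose: consecutive, gap-free administrations at the same dose
#' merge into one episode, while a dose change or a pause of at least one
#' day starts a new episode.
#'
#' @param records Data frame with columns `start_day` (integer day index),
#'   `duration` (days, `>= 1`) and `dose` (daily dose in any consistent
#'   unit), all for one cohort, route and ingredient.
#' @return A tibble with one row per episode: `episode`, `start_day`,
#'   `duration`, `dose`.
#' @export
segment_treatments <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("start_day", "duration", "dose") %in% names(records)))
  if (any(records$duration < 0)) {
    stop("treatment duration must be non-negative", call. = FALSE)
  }
  records <- records[records$duration > 0, ]
  if (nrow(records) == 0) {
    return(tibble::tibble(episode = integer(), start_day = double(),
                          duration = double(), dose = double()))
  }
  records <- records[order(records$start_day), ]
  episodes <- list()
  cur <- list(start = records$start_day[1],
              end = records$start_day[1] + records$duration[1] - 1,
              dose = records$dose[1])
  for (i in seq_len(nrow(records))[-1]) {
    gap_free <- records$start_day[i] <= cur$end + 1
    same_dose <- isTRUE(all.equal(records$dose[i], cur$dose))
    if (gap_free && same_dose) {
      cur$end <- max(cur$end, records$start_day[i] + records$duration[i] - 1)
    } else {
      episodes[[length(episodes) + 1]] <- cur
      cur <- list(start = records$start_day[i],
                  end = records$start_day[i] + records$duration[i] - 1,
                  dose = records$dose[i])
    }
  }
  episodes[[length(episodes) + 1]] <- cur
  tibble::tibble(
    episode = seq_along(episodes),
    start_day = vapply(episodes, `[[`, numeric(1), "start"),
    duration = vapply(episodes, function(e) e$end - e$start + 1, numeric(1)),
    dose = vapply(episodes, `[[`, numeric(1), "dose")
  )
}
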