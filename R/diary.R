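#' Assemble and validate a survey diary
#'
#' A `survey_diary` bundles the participant table, the contact-record table,
#' the period calendar and the reference population counts per age bin (the
#' `G_j` used for reciprocity correction). Construction validates the schema:
#' category levels, referential integrity of contact records, diary dates
#' inside the survey windows, and the deterministic derived fields
#' (household-size class, major region, diary mode). Zero-contact days are
#' legal and represented by the absence of records.
#'
#' Derived participant columns (`household_size_class`, `region5`,
#' `diary_mode`) are recomputed from their sources if absent; if present they
#' are checked for consistency. Diary mode is `paper` exactly for ages 0-18
#' and 65+, `mobile` otherwise.
#'
#' @param participants Data frame with columns `participant_id`, `age_years`,
#'   `sex`, `household_size`, `region17`, `occupation`.
#' @param contacts Data frame with columns `participant_id`, `date`,
#'   `contact_age_years` (NA = unknown), `contact_sex`, `contact_region17`
#'   (may be `"unknown"`), `relation`, `location`, `duration_class`,
#'   `frequency_class`, `physical`.
#' @param population Data frame with columns `age_bin`, `count`: population
#'   size per analysis age bin.
#' @param calendar A [survey_calendar()].
#' @return An object of class `survey_diary`.
#' @export
survey_diary <- function(participants, contacts, population,
                         calendar = survey_calendar()) {
  participants <- tibble::as_tibble(participants)
  contacts <- tibble::as_tibble(contacts)
  population <- tibble::as_tibble(population)

  req_p <- c("participant_id", "age_years", "sex", "household_size",
             "region17", "occupation")
  req_c <- c("participant_id", "date", "contact_age_years", "contact_sex",
             "contact_region17", "relation", "location", "duration_class",
             "frequency_class", "physical")
  check_columns(participants, req_p, "participants")
  check_columns(contacts, req_c, "contacts")
  check_columns(population, c("age_bin", "count"), "population")

  participants$participant_id <- as.character(participants$participant_id)
  contacts$participant_id <- as.character(contacts$participant_id)
  contacts$date <- as.Date(contacts$date)
  contacts$physical <- as.logical(contacts$physical)

  problems <- character()
  problems <- c(problems,
    check_levels(participants$sex, sex_levels(), "participants$sex"),
    check_levels(participants$region17, region17_levels(), "participants$region17"))
  if (anyDuplicated(participants$participant_id)) {
    problems <- c(problems, "duplicated participant_id in participants")
  }
  if (any(participants$age_years < 0, na.rm = TRUE) ||
      anyNA(participants$age_years)) {
    problems <- c(problems, "participants$age_years must be a non-negative integer")
  }
  if (any(participants$household_size < 1, na.rm = TRUE)) {
    problems <- c(problems, "participants$household_size must be >= 1")
  }

  unk <- unknown_label()
  problems <- c(problems,
    check_levels(contacts$contact_sex, c(sex_levels(), unk), "contacts$contact_sex"),
    check_levels(contacts$contact_region17, c(region17_levels(), unk),
                 "contacts$contact_region17"),
    check_levels(contacts$relation, relation_levels(), "contacts$relation"),
    check_levels(contacts$location, location_levels(), "contacts$location"),
    check_levels(contacts$duration_class, duration_levels(), "contacts$duration_class"),
    check_levels(contacts$frequency_class, frequency_levels(), "contacts$frequency_class"))
  if (any(contacts$contact_age_years < 0, na.rm = TRUE)) {
    problems <- c(problems, "contacts$contact_age_years must be >= 0 or NA")
  }
  if (length(problems)) {
    rlang::abort(c("diary validation failed", problems),
                 class = "contactdiaries_validation_error")
  }

  orphan <- setdiff(contacts$participant_id, participants$participant_id)
  if (length(orphan)) {
    rlang::abort(
      c("contact records reference unknown participants",
        utils::head(paste0("participant_id: ", orphan), 5)),
      class = "contactdiaries_referential_error")
  }
  out_dates <- !(contacts$date %in% calendar$days$date)
  if (any(out_dates)) {
    bad <- which(out_dates)
    rlang::abort(
      c("contact dates outside the survey windows",
        utils::head(paste0("row ", bad, ": ", format(contacts$date[bad])), 5)),
      class = "contactdiaries_validation_error")
  }

  participants <- derive_participant_fields(participants, problems_ok = FALSE)

  structure(
    list(participants = participants,
         contacts = contacts,
         population = population,
         calendar = calendar),
    class = "survey_diary"
  )
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(paste0(what, " table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "contactdiaries_schema_error")
  }
  invisible(df)
}

check_levels <- function(x, levels, what) {
  bad <- unique(x[!is.na(x) & !(x %in% levels)])
  if (length(bad)) {
    paste0(what, ": unknown level(s) ", paste(utils::head(bad, 5), collapse = ", "))
  } else character()
}

derive_participant_fields <- function(participants, problems_ok = TRUE) {
  hh_class <- household_class(participants$household_size)
  reg5 <- region5_of(participants$region17)
  mode <- ifelse(participants$age_years <= 18 | participants$age_years >= 65,
                 "paper", "mobile")
  check_derived <- function(name, derived) {
    if (name %in% names(participants)) {
      mismatch <- as.character(participants[[name]]) != as.character(derived)
      if (any(mismatch, na.rm = TRUE)) {
        rlang::abort(
          paste0("participants$", name, " inconsistent with its source column (",
                 sum(mismatch, na.rm = TRUE), " row(s))"),
          class = "contactdiaries_validation_error")
      }
    }
  }
  check_derived("household_size_class", hh_class)
  check_derived("region5", reg5)
  check_derived("diary_mode", mode)
  participants$household_size_class <- hh_class
  participants$region5 <- reg5
  participants$diary_mode <- mode
  participants
}

#' @export
print.survey_diary <- function(x, ...) {
  cat("<survey_diary>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  contact records:", nrow(x$contacts), "\n")
  cat("  diary days:", nrow(x$calendar$days), "\n")
  cat("  mean contacts/participant/day:",
      format(round(overall_mean(x), 2), nsmall = 2), "\n")
  invisible(x)
}

#' Number of diary days
#'
#' @param diary A [survey_diary()].
#' @return Integer count of calendar days covered by the diary.
#' @export
n_diary_days <- function(diary) nrow(diary$calendar$days)

#' Read a survey diary from delimited files
#'
#' Reads the participant, contact and population CSV files written by
#' [write_diary()] (comma-separated, UTF-8, ISO-8601 dates) and validates
#' them into a [survey_diary()]. Rows violating the schema are rejected with
#' row-level messages.
#'
#' @param participants_path,contacts_path,population_path CSV file paths.
#' @param calendar A [survey_calendar()].
#' @return A validated `survey_diary`.
#' @export
read_diary <- function(participants_path, contacts_path, population_path,
                       calendar = survey_calendar()) {
  for (p in c(participants_path, contacts_path, population_path)) {
    if (!file.exists(p)) {
      rlang::abort(paste0("file not found: ", p),
                   class = "contactdiaries_schema_error")
    }
  }
  participants <- readr::read_csv(
    participants_path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age_years = readr::col_integer(),
      sex = readr::col_character(),
      household_size = readr::col_integer(),
      region17 = readr::col_character(),
      occupation = readr::col_character(),
      .default = readr::col_character()
    ))
  contacts <- readr::read_csv(
    contacts_path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      date = readr::col_date(),
      contact_age_years = readr::col_integer(),
      physical = readr::col_logical(),
      .default = readr::col_character()
    ))
  population <- readr::read_csv(
    population_path,
    col_types = readr::cols(
      age_bin = readr::col_character(),
      count = readr::col_double()
    ))
  survey_diary(participants, contacts, population, calendar)
}

#' Write a survey diary to delimited files
#'
#' Writes `participants.csv`, `contacts.csv` and `population.csv` with a
#' stable column order and stable row order (participants by id; contacts by
#' participant id, then date), so that `read_diary()` round-trips the diary
#' exactly.
#'
#' @param diary A [survey_diary()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_diary <- function(diary, out_dir) {
  stopifnot(inherits(diary, "survey_diary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  p_cols <- c("participant_id", "age_years", "sex", "household_size",
              "household_size_class", "region17", "region5", "occupation",
              "diary_mode")
  c_cols <- c("participant_id", "date", "contact_age_years", "contact_sex",
              "contact_region17", "relation", "location", "duration_class",
              "frequency_class", "physical")

  participants <- diary$participants |>
    dplyr::mutate(dplyr::across(dplyr::where(is.factor), as.character)) |>
    dplyr::select(dplyr::all_of(p_cols)) |>
    dplyr::arrange(.data$participant_id)
  contacts <- diary$contacts |>
    dplyr::mutate(dplyr::across(dplyr::where(is.factor), as.character)) |>
    dplyr::select(dplyr::all_of(c_cols)) |>
    dplyr::arrange(.data$participant_id, .data$date)

  paths <- c(
    participants = file.path(out_dir, "participants.csv"),
    contacts = file.path(out_dir, "contacts.csv"),
    population = file.path(out_dir, "population.csv")
  )
  readr::write_csv(participants, paths[["participants"]])
  readr::write_csv(contacts, paths[["contacts"]])
  readr::write_csv(diary$population, paths[["population"]])
  invisible(paths)
}
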