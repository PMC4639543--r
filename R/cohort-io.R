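#' Column dictionary for cohort files
#'
#' Returns the versioned column dictionary (names, types, units, allowed
#' values) that cohort CSV files must follow. The dictionary ships with the
#' package as a JSON document under `extdata`.
#'
#' @param path Optional path to an alternative schema JSON document.
#' @return A list with elements `schema_version`, `missing_value` and
#'   `columns` (a tibble, one row per column).
#' @export
cohort_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_schema.json", package = "headburden")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cols <- purrr::map_dfr(raw$columns, function(col) {
    tibble::tibble(
      name = col$name,
      type = col$type,
      block = col$block %||% "core",
      required = isTRUE(col$required)
    )
  })
  list(
    schema_version = raw$schema_version,
    missing_value = raw$missing_value,
    columns = cols,
    raw = raw
  )
}

# Column groups used throughout the package
feature_cols <- function() {
  c(
    "headache_days_per_month", "attacks_per_month", "mean_attack_duration_h",
    "usual_intensity", "pain_unilateral", "pain_pulsating",
    "pain_moderate_or_severe", "pain_aggravated_by_activity",
    "nausea_or_vomiting", "photophobia", "phonophobia",
    "lifetime_attack_count_ge5", "duration_4_to_72h", "duration_30min_to_7d",
    "acute_medication_days_per_month", "acute_medication_class"
  )
}

lost_time_cols <- function() c("paid_days_lost_3m", "household_days_lost_3m")

economics_cols <- function() {
  c("consulted_last_year", "consultation_level", "expenditure_3m", "wtp")
}

cohort_cols <- function() {
  c(
    "participant_id", "age", "sex", "habitation", "monthly_income",
    "headache_last_year", feature_cols(), lost_time_cols(), economics_cols()
  )
}

cohort_col_types <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    age = readr::col_integer(),
    sex = readr::col_character(),
    habitation = readr::col_character(),
    monthly_income = readr::col_double(),
    headache_last_year = readr::col_logical(),
    headache_days_per_month = readr::col_double(),
    attacks_per_month = readr::col_double(),
    mean_attack_duration_h = readr::col_double(),
    usual_intensity = readr::col_character(),
    pain_unilateral = readr::col_logical(),
    pain_pulsating = readr::col_logical(),
    pain_moderate_or_severe = readr::col_logical(),
    pain_aggravated_by_activity = readr::col_logical(),
    nausea_or_vomiting = readr::col_logical(),
    photophobia = readr::col_logical(),
    phonophobia = readr::col_logical(),
    lifetime_attack_count_ge5 = readr::col_logical(),
    duration_4_to_72h = readr::col_logical(),
    duration_30min_to_7d = readr::col_logical(),
    acute_medication_days_per_month = readr::col_double(),
    acute_medication_class = readr::col_character(),
    paid_days_lost_3m = readr::col_double(),
    household_days_lost_3m = readr::col_double(),
    consulted_last_year = readr::col_logical(),
    consultation_level = readr::col_character(),
    expenditure_3m = readr::col_double(),
    wtp = readr::col_double()
  )
}

# Intensity labels accepted on input, mapped to the 1-3 code
intensity_label_map <- c(
  "not bad" = 1, "mild" = 1,
  "quite bad" = 2, "moderate" = 2,
  "very bad" = 3, "severe" = 3
)

parse_intensity <- function(x) {
  out <- suppressWarnings(as.integer(x))
  labelled <- is.na(out) & !is.na(x)
  if (any(labelled)) {
    key <- tolower(trimws(x[labelled]))
    out[labelled] <- unname(intensity_label_map[key])
  }
  out
}

#' Read a participant-level cohort from CSV
#'
#' Reads a cohort file in the interchange format described by
#' [cohort_schema()] (comma-separated, UTF-8, one header row, empty field as
#' the missing-value sentinel) and validates every row against the domain
#' invariants. Intensity may be given either as the 1-3 integer code or as
#' the questionnaire labels ("not bad"/"quite bad"/"very bad" or
#' mild/moderate/severe).
#'
#' @param path Path to a cohort CSV file.
#' @param schema_version Expected schema version string; reading stops if the
#'   file does not carry the expected columns.
#' @return A validated cohort tibble, one row per participant.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, schema_version = "1.0") {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  schema <- cohort_schema()
  if (!identical(schema$schema_version, schema_version)) {
    stop(
      "schema error: package dictionary version ", schema$schema_version,
      " does not match requested version ", schema_version,
      call. = FALSE
    )
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(cohort_cols(), header)
  if (length(missing) > 0) {
    stop(
      "schema error: missing mandatory column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df <- readr::read_csv(
    path,
    col_types = cohort_col_types(), na = "",
    show_col_types = FALSE, progress = FALSE
  )
  df$usual_intensity <- parse_intensity(df$usual_intensity)
  validate_cohort(df)
}

#' Write a cohort to CSV
#'
#' Serializes a validated cohort tibble to the interchange CSV format.
#' Missing numeric values are written as empty fields; a write/read
#' round-trip reproduces the cohort field-for-field.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort[, cohort_cols()], path, na = "")
  invisible(path)
}

#' Validate a cohort against the domain invariants
#'
#' Validation is total: every record is either accepted or rejected with a
#' field-level reason naming the row. No silent coercion is performed.
#' Checked invariants include the 18-65 eligibility window, range limits on
#' frequency/medication/lost-time fields, the presence of the
#' features/lost-time/economics blocks exactly when `headache_last_year` is
#' `TRUE` (monthly income being the only field a sufferer may leave
#' missing), and `consultation_level == "none"` exactly when
#' `consulted_last_year` is `FALSE`.
#'
#' @param cohort A cohort tibble (as produced by [read_cohort()] or
#'   [generate_cohort()]).
#' @return The cohort, invisibly coerced to a tibble, if valid; otherwise an
#'   error listing every violation with its row number and field.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing <- setdiff(cohort_cols(), names(cohort))
  if (length(missing) > 0) {
    stop(
      "schema error: missing mandatory column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  problems <- cohort_problems(cohort)
  if (nrow(problems) > 0) {
    msgs <- sprintf(
      "row %d, field %s: %s",
      problems$row, problems$field, problems$reason
    )
    n_show <- min(length(msgs), 20L)
    stop(
      "validation error: ", nrow(problems), " violation(s)\n",
      paste(msgs[seq_len(n_show)], collapse = "\n"),
      if (length(msgs) > n_show) "\n... (truncated)" else "",
      call. = FALSE
    )
  }
  cohort
}

#' Enumerate validation problems without raising an error
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `row`, `field`, `reason`; zero rows when
#'   the cohort is valid.
#' @export
cohort_problems <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  probs <- list()
  flag <- function(rows, field, reason) {
    if (any(rows, na.rm = TRUE)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = which(rows), field = field, reason = reason
      )
    }
  }
  n <- nrow(cohort)
  if (n == 0) {
    return(tibble::tibble(row = integer(), field = character(), reason = character()))
  }

  flag(is.na(cohort$participant_id), "participant_id", "missing identifier")
  flag(duplicated(cohort$participant_id), "participant_id", "duplicate identifier")
  flag(
    is.na(cohort$age) | cohort$age < 18 | cohort$age > 65, "age",
    "outside survey eligibility window 18-65 years"
  )
  flag(!cohort$sex %in% c("male", "female"), "sex", "must be 'male' or 'female'")
  flag(
    !cohort$habitation %in% c("urban", "rural"), "habitation",
    "must be 'urban' or 'rural'"
  )
  flag(
    !is.na(cohort$monthly_income) & cohort$monthly_income < 0,
    "monthly_income", "must be non-negative or missing"
  )
  flag(is.na(cohort$headache_last_year), "headache_last_year", "missing screening response")

  hx <- !is.na(cohort$headache_last_year) & cohort$headache_last_year

  # Blocks present iff screen-positive
  block_cols <- c(feature_cols(), lost_time_cols(), economics_cols())
  for (col in block_cols) {
    flag(
      !hx & !is.na(cohort[[col]]), col,
      "present although headache_last_year is FALSE"
    )
    flag(
      hx & is.na(cohort[[col]]), col,
      "missing although headache_last_year is TRUE"
    )
  }

  in_range <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)
  flag(
    in_range(cohort$headache_days_per_month, 0, 30),
    "headache_days_per_month", "must lie in [0, 30] days/month"
  )
  flag(
    in_range(cohort$acute_medication_days_per_month, 0, 30),
    "acute_medication_days_per_month", "must lie in [0, 30] days/month"
  )
  flag(
    !is.na(cohort$mean_attack_duration_h) & cohort$mean_attack_duration_h <= 0,
    "mean_attack_duration_h", "must be positive"
  )
  flag(
    !is.na(cohort$usual_intensity) & !cohort$usual_intensity %in% 1:3,
    "usual_intensity", "must be 1 (mild), 2 (moderate) or 3 (severe)"
  )
  flag(
    !is.na(cohort$acute_medication_class) &
      !cohort$acute_medication_class %in%
        c("simple_analgesic", "combination_or_specific", "none"),
    "acute_medication_class", "unknown medication class"
  )
  flag(
    in_range(cohort$paid_days_lost_3m, 0, 92),
    "paid_days_lost_3m", "must lie in [0, 92] days per quarter"
  )
  flag(
    in_range(cohort$household_days_lost_3m, 0, 92),
    "household_days_lost_3m", "must lie in [0, 92] days per quarter"
  )
  flag(
    !is.na(cohort$expenditure_3m) & cohort$expenditure_3m < 0,
    "expenditure_3m", "must be non-negative"
  )
  flag(!is.na(cohort$wtp) & cohort$wtp < 0, "wtp", "must be non-negative")
  flag(
    !is.na(cohort$consultation_level) &
      !cohort$consultation_level %in% c("primary_care", "specialist", "other", "none"),
    "consultation_level", "unknown consultation level"
  )
  # consultation_level == none  <=>  consulted_last_year == FALSE
  flag(
    hx & !is.na(cohort$consulted_last_year) & !is.na(cohort$consultation_level) &
      (cohort$consultation_level == "none") != (!cohort$consulted_last_year),
    "consultation_level",
    "must be 'none' exactly when consulted_last_year is FALSE"
  )

  if (length(probs) == 0) {
    return(tibble::tibble(row = integer(), field = character(), reason = character()))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row, .data$field)
}
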