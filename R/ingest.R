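# Ingest: read and validate the three CSV inputs into typed records.
#
# Readers are strict about schema (missing mandatory columns are fatal) and
# lenient about rows: a row violating a record invariant is rejected, logged
# once in a machine-readable issue log, and the remaining rows are kept, so
# rows_in = records_out + rejects always holds.

ADMISSION_COLS <- c(
  "admission_id", "patient_id", "unit_id", "care_level", "admit_ts",
  "discharge_ts", "age_years", "sex", "referring_clinic", "saps3_score",
  "saps3_emr", "imv_hours", "crrt_hours", "cvc_hours", "died_in_icu",
  "died_within_30d"
)
ADMINISTRATION_COLS <- c(
  "record_id", "admission_id", "timestamp", "atc_code", "amount",
  "amount_unit", "route"
)
DISPENSING_COLS <- c(
  "unit_id", "period_start", "period_end", "atc_code", "amount", "amount_unit"
)

AMOUNT_UNITS <- c("mg", "g", "MU")
ROUTES <- c("IV", "PO", "INH", "other")
CARE_LEVELS <- c("secondary", "tertiary")
SEXES <- c("female", "male", "other")
CLINIC_LABELS <- c(
  "internal_medicine", "general_surgery", "neurosurgery",
  "infectious_diseases", "neurology", "orthopedic_surgery",
  "oncology_haematology", "other"
)
ATC_PATTERN <- "^[A-V][0-9]{2}[A-Z]{2}[0-9]{2}$"

read_raw_csv <- function(path, required_cols, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE, na = c("", "NA")
  )
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s file %s is missing mandatory column(s): %s",
      what, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  raw
}

parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

# Apply ordered reject checks; each rejected row is logged exactly once with
# the first violated rule.
apply_rejects <- function(n, checks) {
  code <- rep(NA_character_, n)
  msg <- rep(NA_character_, n)
  for (chk in checks) {
    hit <- chk$mask & is.na(code)
    code[hit] <- chk$code
    msg[hit] <- chk$message
  }
  list(reject = !is.na(code), code = code, message = msg)
}

#' Read and validate ICU admission records
#'
#' Reads `admissions.csv` (one row per ICU admission) into typed records.
#' Rows violating a record invariant -- unparseable or inverted interval,
#' unknown care level, negative age, out-of-range SAPS 3 estimated mortality
#' -- are rejected and logged; unknown referring-clinic labels are mapped to
#' `"other"` with a warning entry.
#'
#' @param path path to a CSV file with the documented admission columns.
#' @return A list with `records` (tibble of validated admissions, timestamps
#'   as POSIXct wall-clock) and `issues` (tibble with columns `row`,
#'   `severity`, `code`, `message`).
#' @seealso [read_administrations()], [link_records()]
#' @export
read_admissions <- function(path) {
  raw <- read_raw_csv(path, ADMISSION_COLS, "admissions")
  n <- nrow(raw)
  issues <- empty_issues()

  rec <- tibble::tibble(
    admission_id = raw$admission_id,
    patient_id = raw$patient_id,
    unit_id = raw$unit_id,
    care_level = raw$care_level,
    admit_ts = parse_ts(raw$admit_ts),
    discharge_ts = parse_ts(raw$discharge_ts),
    age_years = suppressWarnings(as.integer(raw$age_years)),
    sex = raw$sex,
    referring_clinic = raw$referring_clinic,
    saps3_score = suppressWarnings(as.integer(raw$saps3_score)),
    saps3_emr = suppressWarnings(as.numeric(raw$saps3_emr)),
    imv_hours = suppressWarnings(as.numeric(raw$imv_hours)),
    crrt_hours = suppressWarnings(as.numeric(raw$crrt_hours)),
    cvc_hours = suppressWarnings(as.numeric(raw$cvc_hours)),
    died_in_icu = parse_logical(raw$died_in_icu),
    died_within_30d = parse_logical(raw$died_within_30d)
  )

  checks <- list(
    list(
      mask = is.na(rec$admission_id) | is.na(rec$patient_id),
      code = "missing_id", message = "missing admission or patient identifier"
    ),
    list(
      mask = is.na(rec$admit_ts) | is.na(rec$discharge_ts),
      code = "bad_timestamp", message = "unparseable admit/discharge timestamp"
    ),
    list(
      mask = !is.na(rec$admit_ts) & !is.na(rec$discharge_ts) &
        rec$admit_ts >= rec$discharge_ts,
      code = "inverted_interval", message = "discharge not after admission"
    ),
    list(
      mask = !(rec$care_level %in% CARE_LEVELS),
      code = "bad_care_level", message = "care_level not secondary/tertiary"
    ),
    list(
      mask = !is.na(rec$age_years) & rec$age_years < 0,
      code = "bad_age", message = "negative age"
    ),
    list(
      mask = !is.na(rec$saps3_emr) &
        (rec$saps3_emr < 0 | rec$saps3_emr > 1),
      code = "bad_emr", message = "saps3_emr outside [0,1]"
    )
  )
  rej <- apply_rejects(n, checks)
  issues <- add_issues(
    issues, which(rej$reject), "reject",
    rej$code[rej$reject], rej$message[rej$reject]
  )

  unknown_clinic <- !rej$reject &
    (is.na(rec$referring_clinic) | !(rec$referring_clinic %in% CLINIC_LABELS))
  issues <- add_issues(
    issues, which(unknown_clinic), "warn", "unknown_clinic",
    "unknown referring_clinic mapped to 'other'"
  )
  rec$referring_clinic[unknown_clinic] <- "other"

  unknown_sex <- !rej$reject & (is.na(rec$sex) | !(rec$sex %in% SEXES))
  issues <- add_issues(
    issues, which(unknown_sex), "warn", "unknown_sex",
    "unknown sex mapped to 'other'"
  )
  rec$sex[unknown_sex] <- "other"

  list(records = rec[!rej$reject, , drop = FALSE], issues = issues)
}

#' Read and validate medication-administration records
#'
#' Reads `administrations.csv` (one row per signed drug dose).  A dose with
#' an absent ATC code is kept with a `warn` entry (its linkage to the DOT
#' metric is missing but the record may still be attributable via a registry
#' override); a present but malformed ATC code, a negative amount, or an
#' unknown amount unit rejects the row.
#'
#' @inheritParams read_admissions
#' @param registry optional ATC registry (see [load_atc_registry()]); when
#'   given, well-formed codes not present in the registry are logged `warn`
#'   as unknown (the dose is kept and simply does not count downstream).
#' @return list with `records` and `issues`, as [read_admissions()].
#' @export
read_administrations <- function(path, registry = NULL) {
  raw <- read_raw_csv(path, ADMINISTRATION_COLS, "administrations")
  n <- nrow(raw)
  issues <- empty_issues()

  rec <- tibble::tibble(
    record_id = raw$record_id,
    admission_id = raw$admission_id,
    timestamp = parse_ts(raw$timestamp),
    atc_code = raw$atc_code,
    amount = suppressWarnings(as.numeric(raw$amount)),
    amount_unit = raw$amount_unit,
    route = raw$route
  )

  checks <- list(
    list(
      mask = is.na(rec$record_id) | is.na(rec$admission_id),
      code = "missing_id", message = "missing record or admission identifier"
    ),
    list(
      mask = is.na(rec$timestamp),
      code = "bad_timestamp", message = "unparseable administration timestamp"
    ),
    list(
      mask = is.na(rec$amount) | rec$amount < 0,
      code = "bad_amount", message = "amount missing or negative"
    ),
    list(
      mask = !(rec$amount_unit %in% AMOUNT_UNITS),
      code = "bad_unit", message = "amount_unit not one of mg/g/MU"
    ),
    list(
      mask = !is.na(rec$atc_code) & !grepl(ATC_PATTERN, rec$atc_code),
      code = "bad_atc", message = "malformed ATC code"
    )
  )
  rej <- apply_rejects(n, checks)
  issues <- add_issues(
    issues, which(rej$reject), "reject",
    rej$code[rej$reject], rej$message[rej$reject]
  )

  other_route <- !rej$reject &
    (is.na(rec$route) | !(rec$route %in% ROUTES))
  rec$route[other_route] <- "other"

  missing_atc <- !rej$reject & is.na(rec$atc_code)
  issues <- add_issues(
    issues, which(missing_atc), "warn", "missing_atc",
    "missing ATC linkage; dose kept but cannot count towards DOT"
  )
  if (!is.null(registry)) {
    unknown <- !rej$reject & !is.na(rec$atc_code) &
      !(rec$atc_code %in% registry$atc_code)
    issues <- add_issues(
      issues, which(unknown), "warn", "unknown_atc",
      "ATC code not in registry; kept, ignored by surveillance metrics"
    )
  }

  list(records = rec[!rej$reject, , drop = FALSE], issues = issues)
}

#' Read pharmacy dispensing records
#'
#' Dispensing data describe drug amounts supplied to the unit medicine shelf
#' per period; they are optional and only used by the metric-comparison
#' report.
#'
#' @inheritParams read_admissions
#' @return list with `records` and `issues`.
#' @export
read_dispensing <- function(path) {
  raw <- read_raw_csv(path, DISPENSING_COLS, "dispensing")
  n <- nrow(raw)
  issues <- empty_issues()

  rec <- tibble::tibble(
    unit_id = raw$unit_id,
    period_start = as.Date(parse_ts(raw$period_start)),
    period_end = as.Date(parse_ts(raw$period_end)),
    atc_code = raw$atc_code,
    amount = suppressWarnings(as.numeric(raw$amount)),
    amount_unit = raw$amount_unit
  )

  checks <- list(
    list(
      mask = is.na(rec$period_start) | is.na(rec$period_end) |
        rec$period_start > rec$period_end,
      code = "bad_period", message = "missing or inverted dispensing period"
    ),
    list(
      mask = is.na(rec$atc_code) | !grepl(ATC_PATTERN, rec$atc_code),
      code = "bad_atc", message = "missing or malformed ATC code"
    ),
    list(
      mask = is.na(rec$amount) | rec$amount < 0,
      code = "bad_amount", message = "amount missing or negative"
    ),
    list(
      mask = !(rec$amount_unit %in% AMOUNT_UNITS),
      code = "bad_unit", message = "amount_unit not one of mg/g/MU"
    )
  )
  rej <- apply_rejects(n, checks)
  issues <- add_issues(
    issues, which(rej$reject), "reject",
    rej$code[rej$reject], rej$message[rej$reject]
  )
  list(records = rec[!rej$reject, , drop = FALSE], issues = issues)
}

#' Link administrations to their admissions
#'
#' Attaches every administration to its admission.  Doses timestamped
#' outside the admission interval are clamped to the interval boundary and
#' logged `warn` (signing delays are common in EMRs; the configurable
#' tolerance distinguishes routine delays from grossly out-of-interval
#' registrations in the log).  Administrations whose `admission_id` does not
#' match any admission are orphans and rejected.
#'
#' @param admissions validated admission records.
#' @param administrations validated administration records.
#' @param tolerance_hours doses at most this far outside the interval are
#'   logged with code `clamped`; farther ones with `clamped_far`.  Both are
#'   kept (clamped), never dropped.
#' @return list with `records` (administrations augmented with admission
#'   context columns `unit_id`, `care_level`, `referring_clinic`, `sex`,
#'   `age_years`, clamped `timestamp`) and `issues`.
#' @export
link_records <- function(admissions, administrations, tolerance_hours = 1) {
  issues <- empty_issues()
  adm <- dplyr::select(
    admissions, "admission_id", "patient_id", "unit_id", "care_level",
    "referring_clinic", "sex", "age_years", "admit_ts", "discharge_ts"
  )
  linked <- dplyr::left_join(administrations, adm, by = "admission_id")

  orphan <- is.na(linked$admit_ts)
  issues <- add_issues(
    issues, which(orphan), "reject", "orphan",
    "administration references no known admission"
  )
  linked <- linked[!orphan, , drop = FALSE]

  early <- as.numeric(linked$admit_ts - linked$timestamp, units = "hours")
  late <- as.numeric(linked$timestamp - linked$discharge_ts, units = "hours")
  outside <- pmax(early, late, 0)
  near <- outside > 0 & outside <= tolerance_hours
  far <- outside > tolerance_hours
  issues <- add_issues(
    issues, which(near), "warn", "clamped",
    "dose timestamp outside admission interval within tolerance; clamped"
  )
  issues <- add_issues(
    issues, which(far), "warn", "clamped_far",
    "dose timestamp outside admission interval beyond tolerance; clamped"
  )
  linked$timestamp <- pmin(
    pmax(linked$timestamp, linked$admit_ts), linked$discharge_ts
  )

  list(records = linked, issues = issues)
}
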