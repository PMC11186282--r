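# Episode construction: the analysis unit for LOS, exposure and mortality.
#
# A readmission starting less than 48 h (strictly) after the previous
# discharge continues the same intensive-care episode; an exact 48 h gap
# starts a new one.  Transfers between units remain separate admissions --
# so drug doses always attribute to the administering unit -- but join the
# same episode when the gap rule applies.  The gap between a discharge and a
# merged readmission contributes neither patient-days nor LOS: only time
# under ICU care divides consumption.

#' Keep adult admissions only
#'
#' @param admissions validated admission records.
#' @return list with `kept` (admissions aged >= 18), `excluded_count`
#'   (admissions below 18, reported for the pharmacy-dispensing comparison)
#'   and `issues` (admissions with missing age are rejected and logged).
#' @export
filter_adults <- function(admissions) {
  issues <- empty_issues()
  no_age <- is.na(admissions$age_years)
  issues <- add_issues(
    issues, which(no_age), "reject", "missing_age",
    "age missing; cannot apply adult filter"
  )
  admissions <- admissions[!no_age, , drop = FALSE]
  minor <- admissions$age_years < 18
  list(
    kept = admissions[!minor, , drop = FALSE],
    excluded_count = sum(minor),
    issues = issues
  )
}

#' Sum fractional patient-days over admissions
#'
#' One patient-day is 24 hours of ICU care; partial stays count as
#' hours / 24 and are never rounded internally.
#'
#' @param admissions admission records (needs `admit_ts`, `discharge_ts`).
#' @return total patient-days as a decimal.
#' @examples
#' # a 36-hour stay is 1.5 patient-days
#' @export
patient_days <- function(admissions) {
  if (nrow(admissions) == 0) return(0)
  sum(as.numeric(
    admissions$discharge_ts - admissions$admit_ts,
    units = "hours"
  )) / 24
}

#' Merge readmissions into intensive-care episodes
#'
#' Within a patient, consecutive admissions whose gap (previous discharge to
#' next admission) is strictly below `gap_hours` share one episode.  Member
#' admissions are never fused: unit attribution of doses is preserved.
#' Overlapping admissions for one patient are data errors; the later one is
#' rejected and logged.
#'
#' @param admissions validated (adult) admission records.
#' @param gap_hours readmission window; default 48.
#' @return list with:
#'   * `episodes`: one row per episode -- `episode_id`, `patient_id`,
#'     `n_admissions`, `episode_start`, `episode_end`, `los_days`
#'     (sum of member admission hours / 24, gaps excluded), `los_gt_48h`
#'     (strictly more than two patient-days of care), `care_level_of_record`
#'     and demographics from the first admission, `died_in_icu` (any member),
#'     `died_within_30d` (last admission), `saps3_score`/`saps3_emr` (first
#'     admission);
#'   * `admissions`: the kept admissions with an `episode_id` column;
#'   * `issues`: rejected overlapping admissions.
#' @export
build_episodes <- function(admissions, gap_hours = 48) {
  issues <- empty_issues()
  adm <- admissions
  adm$.row <- seq_len(nrow(adm))
  adm <- adm[order(adm$patient_id, adm$admit_ts, adm$discharge_ts), ,
    drop = FALSE
  ]

  same_patient <- c(
    FALSE,
    adm$patient_id[-1] == adm$patient_id[-nrow(adm)]
  )
  if (nrow(adm) == 0) same_patient <- logical(0)

  # Drop overlapping admissions (compare against running max discharge).
  keep <- rep(TRUE, nrow(adm))
  last_end <- lubridate::NA_POSIXct_
  last_patient <- NA_character_
  for (i in seq_len(nrow(adm))) {
    if (!identical(adm$patient_id[i], last_patient)) {
      last_end <- lubridate::NA_POSIXct_
      last_patient <- adm$patient_id[i]
    }
    if (!is.na(last_end) && adm$admit_ts[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- max(last_end, adm$discharge_ts[i], na.rm = TRUE)
    }
  }
  issues <- add_issues(
    issues, adm$.row[!keep], "reject", "overlap",
    "admission overlaps an earlier admission of the same patient"
  )
  adm <- adm[keep, , drop = FALSE]

  # New episode when the patient changes or the gap reaches the threshold.
  gap_h <- c(NA_real_, as.numeric(
    adm$admit_ts[-1] - adm$discharge_ts[-nrow(adm)],
    units = "hours"
  ))
  if (nrow(adm) == 0) gap_h <- numeric(0)
  new_patient <- c(TRUE, adm$patient_id[-1] != adm$patient_id[-nrow(adm)])
  if (nrow(adm) == 0) new_patient <- logical(0)
  new_episode <- new_patient | gap_h >= gap_hours
  ep_index <- cumsum(new_episode)
  adm$episode_id <- sprintf("E%05d", ep_index)

  hours <- as.numeric(adm$discharge_ts - adm$admit_ts, units = "hours")
  episodes <- adm |>
    dplyr::mutate(.hours = hours) |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(
      patient_id = dplyr::first(.data$patient_id),
      n_admissions = dplyr::n(),
      episode_start = min(.data$admit_ts),
      episode_end = max(.data$discharge_ts),
      los_days = sum(.data$.hours) / 24,
      care_level_of_record = dplyr::first(.data$care_level),
      referring_clinic = dplyr::first(.data$referring_clinic),
      sex = dplyr::first(.data$sex),
      age_years = dplyr::first(.data$age_years),
      saps3_score = dplyr::first(.data$saps3_score),
      saps3_emr = dplyr::first(.data$saps3_emr),
      died_in_icu = if (all(is.na(.data$died_in_icu))) NA else
        any(.data$died_in_icu, na.rm = TRUE),
      died_within_30d = dplyr::last(.data$died_within_30d),
      .groups = "drop"
    ) |>
    dplyr::mutate(los_gt_48h = .data$los_days > 2)

  adm$.row <- NULL
  adm$.hours <- NULL
  list(episodes = episodes, admissions = adm, issues = issues)
}
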