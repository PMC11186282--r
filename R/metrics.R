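# Consumption metrics: DOT, LOT, administered DDD and derived rates.
#
# DOT counts one day of therapy per distinct antimicrobial agent per
# calendar day per admission, regardless of dose; LOT counts the calendar
# days on which any antimicrobial was given.  Day attribution follows the
# administration's wall-clock calendar date, not 24-h windows from
# admission.  Registry membership defines the surveilled set: doses with a
# missing, unknown or non-antimicrobial ATC code are ignored here (their
# share is reported by the data-quality summary).

#' Enumerate therapy days
#'
#' One row per (admission, calendar date, antimicrobial agent) with at least
#' one signed dose; the long form of the daily therapy-day table.  DOT is
#' its row count, LOT its distinct (admission, date) count.
#'
#' @param linked administrations linked to admissions ([link_records()]).
#' @param registry ATC registry ([load_atc_registry()]).
#' @return tibble with `admission_id`, `patient_id`, `date`, `atc_code`,
#'   `class_label`, `group`, plus admission context columns (`unit_id`,
#'   `care_level`, `referring_clinic`, `sex`, `age_years`).
#' @export
therapy_days <- function(linked, registry) {
  classes <- dplyr::distinct(
    registry, .data$atc_code, .data$class_label, .data$group
  )
  linked |>
    dplyr::filter(
      !is.na(.data$atc_code), .data$atc_code %in% classes$atc_code
    ) |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = AMC_TZ)) |>
    dplyr::distinct(
      .data$admission_id, .data$date, .data$atc_code,
      .keep_all = TRUE
    ) |>
    dplyr::left_join(classes, by = "atc_code") |>
    dplyr::select(
      "admission_id", "patient_id", "date", "atc_code", "class_label",
      "group", "unit_id", "care_level", "referring_clinic", "sex",
      "age_years"
    ) |>
    dplyr::arrange(.data$admission_id, .data$date, .data$atc_code)
}

#' Days of therapy
#'
#' @param days therapy-day table from [therapy_days()].
#' @return integer DOT: the number of distinct (admission, date, agent)
#'   triples.
#' @export
dot <- function(days) {
  nrow(dplyr::distinct(days, .data$admission_id, .data$date, .data$atc_code))
}

#' Length of therapy
#'
#' @inheritParams dot
#' @return integer LOT: the number of distinct (admission, date) pairs with
#'   at least one antimicrobial agent, irrespective of how many.
#' @export
lot <- function(days) {
  nrow(dplyr::distinct(days, .data$admission_id, .data$date))
}

#' Administered defined daily doses
#'
#' Sums DDD equivalents over all linked doses with a defined, commensurable
#' DDD.  Drugs without one (no WHO DDD, or dose units incommensurable with
#' the DDD unit) still count for DOT/LOT; their DOT share is returned so the
#' omission is visible in reports.
#'
#' @inheritParams therapy_days
#' @return list with `total` (DDD sum), `excluded_dot_share` (fraction of
#'   DOT attributable to undefined-DDD drugs) and `per_dose` (the linked
#'   doses restricted to the surveilled set, with a `ddd` column).
#' @export
ddd_administered <- function(linked, registry) {
  surveilled <- linked |>
    dplyr::filter(
      !is.na(.data$atc_code), .data$atc_code %in% registry$atc_code
    )
  if (nrow(surveilled) == 0) {
    return(list(
      total = 0, excluded_dot_share = NA_real_,
      per_dose = dplyr::mutate(surveilled, ddd = numeric(0))
    ))
  }
  surveilled$ddd <- suppressWarnings(ddd_equivalents(
    registry, surveilled$atc_code, surveilled$amount,
    surveilled$amount_unit, surveilled$route
  ))
  triples <- surveilled |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = AMC_TZ)) |>
    dplyr::group_by(.data$admission_id, .data$date, .data$atc_code) |>
    dplyr::summarise(defined = any(!is.na(.data$ddd)), .groups = "drop")
  list(
    total = sum(surveilled$ddd, na.rm = TRUE),
    excluded_dot_share = mean(!triples$defined),
    per_dose = surveilled
  )
}

#' Normalise a total per 1000 patient-days
#'
#' @param total numeric totals (DOT, LOT or DDD).
#' @param patient_days matching patient-day denominators.
#' @return `total / patient_days * 1000`; `NA` where the denominator is 0
#'   (an undefined rate is reported as absent, never as 0).
#' @examples
#' rate_per_1000_pd(14466, 11469) # ~1261 DOT per 1000 patient-days
#' @export
rate_per_1000_pd <- function(total, patient_days) {
  ifelse(patient_days > 0, total / patient_days * 1000, NA_real_)
}

#' Derived stratum ratios
#'
#' @param dot,lot,n_admissions,n_amu_admissions stratum totals (vectorised).
#' @return tibble with `lot_per_admission`, `lot_per_amu_admission` (average
#'   LOT among admissions with any antimicrobial use) and `dot_lot_ratio`
#'   (frequency of simultaneous exposure to more than one antimicrobial;
#'   absent when LOT is 0, never 0).
#' @export
derived_ratios <- function(dot, lot, n_admissions, n_amu_admissions) {
  tibble::tibble(
    lot_per_admission = ifelse(n_admissions > 0, lot / n_admissions, NA_real_),
    lot_per_amu_admission =
      ifelse(n_amu_admissions > 0, lot / n_amu_admissions, NA_real_),
    dot_lot_ratio = ifelse(lot > 0, dot / lot, NA_real_)
  )
}

# Age bands used for demographic stratification.
age_band <- function(age_years) {
  cut(age_years,
    breaks = c(18, 40, 60, 70, 80, Inf),
    labels = c("18-39", "40-59", "60-69", "70-79", "80+"),
    right = FALSE, include.lowest = TRUE
  ) |> as.character()
}

#' Per-admission metric totals
#'
#' The single source of truth behind every stratified table: DOT, LOT, DDD
#' and fractional patient-days for each admission.  Stratified totals are
#' sums of these rows, so any complete partition conserves the grand total.
#'
#' @inheritParams therapy_days
#' @param admissions admission records (adult, episode-annotated or not).
#' @return tibble, one row per admission, with `dot`, `lot`,
#'   `ddd_administered`, `patient_days`, `amu` (any antimicrobial use) and
#'   the admission's stratification columns (including `age_band` and
#'   `year`).
#' @export
admission_metrics <- function(admissions, linked, registry) {
  days <- therapy_days(linked, registry)
  ddd <- ddd_administered(linked, registry)

  per_dot <- days |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(
      dot = dplyr::n(),
      lot = dplyr::n_distinct(.data$date),
      .groups = "drop"
    )
  per_ddd <- ddd$per_dose |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(
      ddd_administered = sum(.data$ddd, na.rm = TRUE), .groups = "drop"
    )

  admissions |>
    dplyr::mutate(
      patient_days =
        as.numeric(.data$discharge_ts - .data$admit_ts, units = "hours") / 24,
      age_band = age_band(.data$age_years),
      year = lubridate::year(.data$admit_ts)
    ) |>
    dplyr::left_join(per_dot, by = "admission_id") |>
    dplyr::left_join(per_ddd, by = "admission_id") |>
    dplyr::mutate(
      dot = dplyr::coalesce(.data$dot, 0L),
      lot = dplyr::coalesce(.data$lot, 0L),
      ddd_administered = dplyr::coalesce(.data$ddd_administered, 0),
      amu = .data$dot > 0
    )
}

#' Stratified consumption metrics
#'
#' Aggregates [admission_metrics()] rows over any admission-level
#' stratification (care level, unit, referring clinic, sex, age band,
#' admission year, ...) and derives the normalised rates and ratios.
#'
#' @param adm_metrics output of [admission_metrics()].
#' @param by character vector of stratification columns; empty for the grand
#'   total.
#' @return tibble with the stratum keys and `dot`, `lot`,
#'   `ddd_administered`, `patient_days`, `n_admissions`, `n_amu_admissions`,
#'   `dot_rate`, `lot_rate`, `ddd_rate` (per 1000 patient-days),
#'   `dot_lot_ratio`, `lot_per_admission`, `lot_per_amu_admission`.
#' @export
stratum_metrics <- function(adm_metrics, by = character()) {
  out <- adm_metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dot = sum(.data$dot),
      lot = sum(.data$lot),
      ddd_administered = sum(.data$ddd_administered),
      patient_days = sum(.data$patient_days),
      n_admissions = dplyr::n(),
      n_amu_admissions = sum(.data$amu),
      .groups = "drop"
    )
  dplyr::bind_cols(
    out,
    tibble::tibble(
      dot_rate = rate_per_1000_pd(out$dot, out$patient_days),
      lot_rate = rate_per_1000_pd(out$lot, out$patient_days),
      ddd_rate = rate_per_1000_pd(out$ddd_administered, out$patient_days)
    ),
    derived_ratios(out$dot, out$lot, out$n_admissions, out$n_amu_admissions)
  )
}

#' Consumption by antimicrobial class
#'
#' DOT and administered DDD per drug class (optionally within care level or
#' another admission-level stratum), with rates normalised by the stratum's
#' full patient-day denominator.
#'
#' @inheritParams therapy_days
#' @param adm_metrics output of [admission_metrics()] (denominators).
#' @param by admission-level stratification columns (e.g. `"care_level"`).
#' @return tibble with `class_label`, `group`, stratum keys, `dot`,
#'   `ddd_administered`, `patient_days`, `dot_rate`, `ddd_rate`.
#' @export
class_consumption <- function(linked, registry, adm_metrics,
                              by = "care_level") {
  days <- therapy_days(linked, registry)
  ddd <- ddd_administered(linked, registry)
  classes <- dplyr::distinct(
    registry, .data$atc_code, .data$class_label, .data$group
  )

  denom <- adm_metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(patient_days = sum(.data$patient_days), .groups = "drop")

  dot_by <- days |>
    dplyr::group_by(
      dplyr::across(dplyr::all_of(c("class_label", "group", by)))
    ) |>
    dplyr::summarise(dot = dplyr::n(), .groups = "drop")
  ddd_by <- ddd$per_dose |>
    dplyr::left_join(classes, by = "atc_code") |>
    dplyr::group_by(
      dplyr::across(dplyr::all_of(c("class_label", "group", by)))
    ) |>
    dplyr::summarise(
      ddd_administered = sum(.data$ddd, na.rm = TRUE), .groups = "drop"
    )

  out <- dplyr::full_join(dot_by, ddd_by, by = c("class_label", "group", by))
  out <- if (length(by) == 0) {
    dplyr::mutate(out, patient_days = denom$patient_days[1])
  } else {
    dplyr::left_join(out, denom, by = by)
  }
  out |>
    dplyr::mutate(
      dot = dplyr::coalesce(.data$dot, 0L),
      ddd_administered = dplyr::coalesce(.data$ddd_administered, 0),
      dot_rate = rate_per_1000_pd(.data$dot, .data$patient_days),
      ddd_rate = rate_per_1000_pd(.data$ddd_administered, .data$patient_days)
    ) |>
    dplyr::arrange(dplyr::desc(.data$dot))
}
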