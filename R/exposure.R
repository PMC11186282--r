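# Antimicrobial drug-class exposure per intensive-care episode.
#
# Exposure counts distinct drug classes, not agents (two 3rd-generation
# cephalosporins are one exposure), over the whole episode: merged
# readmissions share one exposure history, because the 48-h merge exists to
# treat them as one care event.  The five-level bucket is none / one / two /
# three / more than three classes.  Stays are split at LOS > 48 h (strictly
# more than 2.0 patient-days), longer stays carrying a higher risk of
# healthcare-associated infection.

EXPOSURE_LEVELS <- c("none", "one", "two", "three", "more_than_three")

exposure_level <- function(n_classes) {
  factor(
    dplyr::case_when(
      n_classes == 0 ~ "none",
      n_classes == 1 ~ "one",
      n_classes == 2 ~ "two",
      n_classes == 3 ~ "three",
      TRUE ~ "more_than_three"
    ),
    levels = EXPOSURE_LEVELS, ordered = TRUE
  )
}

#' Classify episodes by antimicrobial-class exposure
#'
#' @param episodes episode table from [build_episodes()].
#' @param admissions episode-annotated admissions (same builder output).
#' @param days therapy-day table from [therapy_days()].
#' @return tibble, one row per episode: `episode_id`, `care_level`
#'   (of record), `los_days`, `los_bucket` (`"le48h"`/`"gt48h"`),
#'   `n_classes`, `level` (ordered factor), `classes` (semicolon-joined,
#'   sorted).
#' @export
classify_exposure <- function(episodes, admissions, days) {
  ep_classes <- days |>
    dplyr::left_join(
      dplyr::select(admissions, "admission_id", "episode_id"),
      by = "admission_id"
    ) |>
    dplyr::filter(!is.na(.data$episode_id)) |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(
      n_classes = dplyr::n_distinct(.data$class_label),
      classes = paste(sort(unique(.data$class_label)), collapse = ";"),
      .groups = "drop"
    )
  episodes |>
    dplyr::left_join(ep_classes, by = "episode_id") |>
    dplyr::mutate(
      n_classes = dplyr::coalesce(.data$n_classes, 0L),
      classes = dplyr::coalesce(.data$classes, ""),
      level = exposure_level(.data$n_classes),
      los_bucket = ifelse(.data$los_gt_48h, "gt48h", "le48h"),
      care_level = .data$care_level_of_record
    ) |>
    dplyr::select(
      "episode_id", "care_level", "los_days", "los_bucket",
      "n_classes", "level", "classes"
    )
}

#' Exposure contingency table
#'
#' Episode counts per care level, LOS bucket and exposure level, with the
#' proportion exposed to at least one antimicrobial class.  Bucket counts
#' always partition the episode set.
#'
#' @param exposure output of [classify_exposure()].
#' @param split_by_los also stratify by the 48-h LOS bucket (default TRUE).
#' @return tibble with stratum keys, `level`, `n`, `n_stratum` and
#'   `proportion` (of the stratum's episodes at that level).
#' @export
exposure_table <- function(exposure, split_by_los = TRUE) {
  keys <- c("care_level", if (split_by_los) "los_bucket")
  counts <- exposure |>
    dplyr::group_by(
      dplyr::across(dplyr::all_of(keys)), .data$level, .drop = FALSE
    ) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(!is.na(.data$level))
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      n_stratum = sum(.data$n),
      proportion = ifelse(.data$n_stratum > 0, .data$n / .data$n_stratum,
        NA_real_
      )
    ) |>
    dplyr::ungroup()
}

#' Per-class exposure proportions
#'
#' For each antimicrobial class and stratum: how many episodes were ever
#' exposed to that class, as a proportion of the stratum's episodes (e.g.
#' cephalosporin exposure among tertiary-care admissions).
#'
#' @inheritParams classify_exposure
#' @param split_by_los also stratify by the 48-h LOS bucket.
#' @return tibble with stratum keys, `class_label`, `n_exposed`,
#'   `n_stratum`, `proportion`.
#' @export
class_exposure_table <- function(episodes, admissions, days,
                                 split_by_los = FALSE) {
  keys <- c("care_level", if (split_by_los) "los_bucket")
  ep <- episodes |>
    dplyr::mutate(
      care_level = .data$care_level_of_record,
      los_bucket = ifelse(.data$los_gt_48h, "gt48h", "le48h")
    )
  strata <- ep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_stratum = dplyr::n(), .groups = "drop")
  exposed <- days |>
    dplyr::select("admission_id", "class_label") |>
    dplyr::left_join(
      dplyr::select(admissions, "admission_id", "episode_id"),
      by = "admission_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(ep, "episode_id", dplyr::all_of(keys)),
      by = "episode_id"
    ) |>
    dplyr::distinct(
      dplyr::across(dplyr::all_of(keys)), .data$class_label, .data$episode_id
    ) |>
    dplyr::group_by(
      dplyr::across(dplyr::all_of(c(keys, "class_label")))
    ) |>
    dplyr::summarise(n_exposed = dplyr::n(), .groups = "drop")
  exposed |>
    dplyr::left_join(strata, by = keys) |>
    dplyr::mutate(proportion = .data$n_exposed / .data$n_stratum) |>
    dplyr::arrange(dplyr::desc(.data$proportion))
}
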