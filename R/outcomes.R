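# Exposure-linked mortality: SAPS 3 predicted vs observed outcomes.
#
# The SAPS 3 estimated mortality rate (EMR) is a probability computed at
# admission from the severity score; comparing its per-stratum mean with
# observed ICU and 30-day mortality shows whether heavily exposed patients
# die more often than their admission physiology predicted.  Episodes
# missing EMR or vital status are omitted (no imputation) and counted.

#' Mortality and predicted mortality by exposure level
#'
#' One summary row per antimicrobial-exposure level: mean SAPS 3 EMR with a
#' normal-approximation 95% confidence interval (mean +/- 1.96 SE), and
#' observed ICU / 30-day mortality proportions.  Empty levels are emitted
#' with `n = 0` and absent statistics.
#'
#' @param episodes episode table from [build_episodes()].
#' @param exposure output of [classify_exposure()].
#' @return list with `summary` (tibble: `level`, `n`, `mean_emr`,
#'   `emr_ci_low`, `emr_ci_high`, `icu_mortality`, `mortality_30d`),
#'   `emr_values` (per-episode EMR by level, for density displays) and
#'   `n_excluded` (episodes lacking an EMR).
#' @export
exposure_mortality <- function(episodes, exposure) {
  joined <- episodes |>
    dplyr::inner_join(
      dplyr::select(exposure, "episode_id", "level"),
      by = "episode_id"
    )
  excluded <- sum(is.na(joined$saps3_emr))
  kept <- joined[!is.na(joined$saps3_emr), , drop = FALSE]

  summary <- kept |>
    dplyr::group_by(.data$level, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_emr = mean(.data$saps3_emr),
      se = stats::sd(.data$saps3_emr) / sqrt(dplyr::n()),
      icu_mortality = mean(.data$died_in_icu, na.rm = TRUE),
      mortality_30d = mean(.data$died_within_30d, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_emr = ifelse(.data$n > 0, .data$mean_emr, NA_real_),
      emr_ci_low = .data$mean_emr - 1.96 * .data$se,
      emr_ci_high = .data$mean_emr + 1.96 * .data$se,
      icu_mortality = ifelse(is.nan(.data$icu_mortality), NA_real_,
        .data$icu_mortality
      ),
      mortality_30d = ifelse(is.nan(.data$mortality_30d), NA_real_,
        .data$mortality_30d
      )
    ) |>
    dplyr::select(
      "level", "n", "mean_emr", "emr_ci_low", "emr_ci_high",
      "icu_mortality", "mortality_30d"
    )

  list(
    summary = summary,
    emr_values = dplyr::select(
      kept, "level", "episode_id", "saps3_emr"
    ),
    n_excluded = excluded
  )
}

#' Overall mortality summary
#'
#' @param episodes episode table.
#' @param by optional stratification columns (e.g.
#'   `"care_level_of_record"`); default overall plus per care level.
#' @return tibble with `n_episodes`, `icu_mortality`, `mortality_30d`
#'   (proportions over episodes with known status), `median_saps3`,
#'   `saps3_q1`, `saps3_q3`, `median_emr`, `emr_q1`, `emr_q3`.
#' @export
mortality_summary <- function(episodes, by = "care_level_of_record") {
  one <- function(df, label) {
    tibble::tibble(
      stratum = label,
      n_episodes = nrow(df),
      icu_mortality = mean(df$died_in_icu, na.rm = TRUE),
      mortality_30d = mean(df$died_within_30d, na.rm = TRUE),
      median_saps3 = stats::median(df$saps3_score, na.rm = TRUE),
      saps3_q1 = stats::quantile(df$saps3_score, 0.25, na.rm = TRUE,
        names = FALSE
      ),
      saps3_q3 = stats::quantile(df$saps3_score, 0.75, na.rm = TRUE,
        names = FALSE
      ),
      median_emr = stats::median(df$saps3_emr, na.rm = TRUE),
      emr_q1 = stats::quantile(df$saps3_emr, 0.25, na.rm = TRUE,
        names = FALSE
      ),
      emr_q3 = stats::quantile(df$saps3_emr, 0.75, na.rm = TRUE,
        names = FALSE
      )
    )
  }
  parts <- list(one(episodes, "all"))
  if (!is.null(by) && length(by) > 0) {
    groups <- split(episodes, episodes[[by]])
    parts <- c(parts, Map(one, groups, names(groups)))
  }
  dplyr::bind_rows(parts)
}
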