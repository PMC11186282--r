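# Standard surveillance reports.
#
# Every printed rate is rate_per_1000_pd() of the same stratum's totals --
# tables are views over admission_metrics(), never re-derivations -- and
# rendering rounds only at the edge: rates per 1000 patient-days to
# integers, percentages to one decimal in the population table and to
# integers in exposure tables, all half-up.

fmt_pct <- function(x, digits = 1) round_half_up(100 * x, digits)

#' Population characteristics table
#'
#' Per care level and overall: admission count, sex distribution, median
#' (IQR) age / LOS / SAPS 3 / EMR, admissions with LOS > 48 h, patient-days,
#' organ-support device usage, and per-admission ICU / 30-day mortality.
#'
#' @param admissions validated adult admission records.
#' @return tibble, one row per stratum (`all`, `secondary`, `tertiary`).
#' @export
population_table <- function(admissions) {
  one <- function(df, label) {
    pd <- as.numeric(df$discharge_ts - df$admit_ts, units = "hours") / 24
    med_iqr <- function(x) {
      stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    }
    age <- med_iqr(df$age_years)
    los <- med_iqr(pd)
    saps <- med_iqr(df$saps3_score)
    emr <- med_iqr(df$saps3_emr)
    imv_users <- !is.na(df$imv_hours) & df$imv_hours > 0
    crrt_users <- !is.na(df$crrt_hours) & df$crrt_hours > 0
    cvc_users <- !is.na(df$cvc_hours) & df$cvc_hours > 0
    tibble::tibble(
      stratum = label,
      n_admissions = nrow(df),
      n_female = sum(df$sex == "female"),
      pct_female = mean(df$sex == "female"),
      median_age = age[1], age_q1 = age[2], age_q3 = age[3],
      n_los_gt_48h = sum(pd > 2),
      patient_days = sum(pd),
      median_los = los[1], los_q1 = los[2], los_q3 = los[3],
      n_imv = sum(imv_users), pct_imv = mean(imv_users),
      median_imv_hours = stats::median(df$imv_hours[imv_users], na.rm = TRUE),
      n_crrt = sum(crrt_users), pct_crrt = mean(crrt_users),
      median_crrt_hours =
        stats::median(df$crrt_hours[crrt_users], na.rm = TRUE),
      median_cvc_hours = stats::median(df$cvc_hours[cvc_users], na.rm = TRUE),
      median_saps3 = saps[1], saps3_q1 = saps[2], saps3_q3 = saps[3],
      median_emr = emr[1], emr_q1 = emr[2], emr_q3 = emr[3],
      icu_mortality = mean(df$died_in_icu, na.rm = TRUE),
      mortality_30d = mean(df$died_within_30d, na.rm = TRUE)
    )
  }
  dplyr::bind_rows(
    one(admissions, "all"),
    one(admissions[admissions$care_level == "secondary", ], "secondary"),
    one(admissions[admissions$care_level == "tertiary", ], "tertiary")
  )
}

#' Referral-clinic characteristics table
#'
#' Admissions, patient-days (with counts among women) and median (IQR) LOS
#' per ICU care level and referring clinic.
#'
#' @param adm_metrics output of [admission_metrics()].
#' @return tibble keyed by `care_level`, `referring_clinic`.
#' @export
clinic_table <- function(adm_metrics) {
  adm_metrics |>
    dplyr::group_by(.data$care_level, .data$referring_clinic) |>
    dplyr::summarise(
      n_admissions = dplyr::n(),
      n_women = sum(.data$sex == "female"),
      patient_days = sum(.data$patient_days),
      patient_days_women = sum(.data$patient_days[.data$sex == "female"]),
      median_los = stats::median(.data$patient_days),
      los_q1 = stats::quantile(.data$patient_days, 0.25, names = FALSE),
      los_q3 = stats::quantile(.data$patient_days, 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Consumption per referring clinic with bootstrap confidence intervals
#'
#' DOT per 1000 patient-days per care level and referring clinic, with a
#' 95% percentile confidence interval from a nonparametric bootstrap that
#' resamples admissions within the clinic (ratio-of-sums statistic, so the
#' interval reflects both numerator and denominator variation).  Clinics
#' with no patient-days are omitted with a note attribute.
#'
#' @param adm_metrics output of [admission_metrics()].
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed making the resampling reproducible.
#' @return tibble with `care_level`, `referring_clinic`, `n_admissions`,
#'   `dot`, `patient_days`, `dot_rate`, `ci_low`, `ci_high`.
#' @export
clinic_consumption <- function(adm_metrics, n_boot = 1000, seed = 1) {
  set.seed(seed)
  groups <- adm_metrics |>
    dplyr::group_split(.data$care_level, .data$referring_clinic)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    total_pd <- sum(g$patient_days)
    base <- tibble::tibble(
      care_level = g$care_level[1],
      referring_clinic = g$referring_clinic[1],
      n_admissions = n,
      dot = sum(g$dot),
      patient_days = total_pd,
      dot_rate = rate_per_1000_pd(sum(g$dot), total_pd)
    )
    if (total_pd <= 0) {
      base$ci_low <- NA_real_
      base$ci_high <- NA_real_
      attr(base, "omitted") <- TRUE
      return(base)
    }
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    boot_rates <- colSums(matrix(g$dot[idx], n, n_boot)) /
      colSums(matrix(g$patient_days[idx], n, n_boot)) * 1000
    ci <- stats::quantile(boot_rates, c(0.025, 0.975),
      na.rm = TRUE, names = FALSE
    )
    base$ci_low <- ci[1]
    base$ci_high <- ci[2]
    base
  })
  out <- dplyr::bind_rows(rows)
  omitted <- out[is.na(out$ci_low) & out$patient_days <= 0, , drop = FALSE]
  out <- out[out$patient_days > 0, , drop = FALSE]
  if (nrow(omitted) > 0) {
    attr(out, "omitted_clinics") <- paste(
      omitted$care_level, omitted$referring_clinic
    )
  }
  out
}

#' Compare consumption metrics: DOT vs administered vs dispensed DDD
#'
#' Per drug: DOT rate, administered-DDD rate and (when dispensing data are
#' supplied) dispensed-DDD rate per 1000 patient-days, with a divergence
#' flag where the dispensed/administered DDD ratio exceeds a threshold --
#' the signature of shelf consumption not captured by signed doses (e.g.
#' perioperative prophylaxis drawn from the ICU shelf).
#'
#' To reduce bias, the dispensed denominator may include the patient-days of
#' admissions below 18 years (supplied via `patient_days_all`), since shelf
#' supply also covers them; the minors admission count is echoed.
#'
#' @param linked linked administrations ([link_records()]).
#' @param registry ATC registry.
#' @param patient_days_adult adult patient-day denominator.
#' @param dispensing optional dispensing records ([read_dispensing()]).
#' @param patient_days_all optional denominator including minors; defaults
#'   to `patient_days_adult`.
#' @param minors_count number of under-18 admissions behind the wider
#'   denominator (echoed in the table).
#' @param flag_ratio divergence threshold on dispensed/administered DDD
#'   (default 1.5).
#' @return tibble per drug with rates, `dispensed_administered_ratio` and
#'   `divergence_flag`; attribute `minors_count`.
#' @export
metric_comparison <- function(linked, registry, patient_days_adult,
                              dispensing = NULL, patient_days_all = NULL,
                              minors_count = 0, flag_ratio = 1.5) {
  patient_days_all <- patient_days_all %||% patient_days_adult
  days <- therapy_days(linked, registry)
  ddd <- ddd_administered(linked, registry)
  drugs <- dplyr::distinct(
    registry, .data$atc_code, .data$substance_name, .data$class_label
  )

  dot_drug <- days |>
    dplyr::group_by(.data$atc_code) |>
    dplyr::summarise(dot = dplyr::n(), .groups = "drop")
  ddd_drug <- ddd$per_dose |>
    dplyr::group_by(.data$atc_code) |>
    dplyr::summarise(
      ddd_administered = sum(.data$ddd, na.rm = TRUE), .groups = "drop"
    )

  out <- drugs |>
    dplyr::left_join(dot_drug, by = "atc_code") |>
    dplyr::left_join(ddd_drug, by = "atc_code") |>
    dplyr::mutate(
      dot = dplyr::coalesce(.data$dot, 0L),
      ddd_administered = dplyr::coalesce(.data$ddd_administered, 0),
      dot_rate = rate_per_1000_pd(.data$dot, patient_days_adult),
      ddd_administered_rate =
        rate_per_1000_pd(.data$ddd_administered, patient_days_adult)
    )

  if (!is.null(dispensing) && nrow(dispensing) > 0) {
    disp <- dispensing
    disp$ddd <- suppressWarnings(ddd_equivalents(
      registry, disp$atc_code, disp$amount, disp$amount_unit
    ))
    disp_drug <- disp |>
      dplyr::group_by(.data$atc_code) |>
      dplyr::summarise(
        ddd_dispensed = sum(.data$ddd, na.rm = TRUE), .groups = "drop"
      )
    out <- out |>
      dplyr::left_join(disp_drug, by = "atc_code") |>
      dplyr::mutate(
        ddd_dispensed = dplyr::coalesce(.data$ddd_dispensed, 0),
        ddd_dispensed_rate =
          rate_per_1000_pd(.data$ddd_dispensed, patient_days_all),
        dispensed_administered_ratio = dplyr::case_when(
          .data$ddd_administered > 0 ~
            .data$ddd_dispensed / .data$ddd_administered,
          .data$ddd_dispensed > 0 ~ Inf,
          TRUE ~ NA_real_
        ),
        divergence_flag = !is.na(.data$dispensed_administered_ratio) &
          .data$dispensed_administered_ratio > flag_ratio
      )
  }
  keep <- out$dot > 0 | out$ddd_administered > 0
  if ("ddd_dispensed" %in% names(out)) {
    keep <- keep | out$ddd_dispensed > 0
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "minors_count") <- minors_count
  dplyr::arrange(out, dplyr::desc(.data$dot))
}

#' Data-quality summary
#'
#' Reject and warning counts per reader, the missing-ATC-linkage share of
#' therapy days (per mille) and the undefined-DDD share of DOT.
#'
#' @param admission_issues,administration_issues,link_issues issue logs.
#' @param linked linked administrations.
#' @param registry ATC registry.
#' @param minors_count excluded under-18 admission count.
#' @return tibble of named indicators with values.
#' @export
quality_summary <- function(admission_issues, administration_issues,
                            link_issues, linked, registry,
                            minors_count = 0) {
  count <- function(log, sev) sum(log$severity == sev)
  missing_atc <- linked[is.na(linked$atc_code), , drop = FALSE]
  missing_days <- nrow(dplyr::distinct(
    dplyr::mutate(missing_atc, date = as.Date(.data$timestamp, tz = AMC_TZ)),
    .data$admission_id, .data$date
  ))
  total_dot <- dot(therapy_days(linked, registry))
  ddd <- ddd_administered(linked, registry)
  tibble::tibble(
    indicator = c(
      "admission_rejects", "admission_warnings",
      "administration_rejects", "administration_warnings",
      "orphan_doses", "clamped_doses",
      "doses_missing_atc", "missing_atc_dot_permille",
      "undefined_ddd_dot_share", "minors_excluded"
    ),
    value = c(
      count(admission_issues, "reject"), count(admission_issues, "warn"),
      count(administration_issues, "reject"),
      count(administration_issues, "warn"),
      sum(link_issues$code == "orphan"),
      sum(link_issues$code %in% c("clamped", "clamped_far")),
      nrow(missing_atc),
      if (missing_days + total_dot > 0) {
        1000 * missing_days / (missing_days + total_dot)
      } else {
        NA_real_
      },
      ddd$excluded_dot_share,
      minors_count
    )
  )
}

#' Assemble the full surveillance report bundle
#'
#' Runs the whole analysis pipeline on validated inputs and collects every
#' standard report table.
#'
#' @param admissions validated admissions (all ages; the adult filter is
#'   applied here).
#' @param administrations validated administrations.
#' @param registry ATC registry.
#' @param dispensing optional dispensing records.
#' @param admission_issues,administration_issues ingest issue logs (for the
#'   quality summary); empty logs if omitted.
#' @param n_boot,seed bootstrap settings for clinic confidence intervals.
#' @return object of class `amc_report`: list of tables (`population`,
#'   `clinics`, `metrics_by_level`, `class_consumption`,
#'   `clinic_consumption`, `exposure`, `exposure_levels`,
#'   `exposure_mortality`, `metric_comparison`, `quality`) plus the
#'   intermediate `episodes` and `adm_metrics`.
#' @export
build_report <- function(admissions, administrations, registry,
                         dispensing = NULL,
                         admission_issues = NULL,
                         administration_issues = NULL,
                         n_boot = 1000, seed = 1) {
  adults <- filter_adults(admissions)
  pd_all <- patient_days(admissions)
  eps <- build_episodes(adults$kept)
  link <- link_records(eps$admissions, administrations)
  adm_metrics <- admission_metrics(eps$admissions, link$records, registry)
  days <- therapy_days(link$records, registry)
  expo <- classify_exposure(eps$episodes, eps$admissions, days)

  structure(list(
    population = population_table(eps$admissions),
    clinic_table = clinic_table(adm_metrics),
    clinics = stratum_metrics(
      adm_metrics, c("care_level", "referring_clinic")
    ),
    metrics_by_level = stratum_metrics(adm_metrics, "care_level"),
    class_consumption = class_consumption(
      link$records, registry, adm_metrics
    ),
    clinic_consumption = clinic_consumption(
      adm_metrics, n_boot = n_boot, seed = seed
    ),
    exposure = expo,
    exposure_levels = exposure_table(expo),
    class_exposure = class_exposure_table(
      eps$episodes, eps$admissions, days, split_by_los = TRUE
    ),
    exposure_mortality = exposure_mortality(eps$episodes, expo),
    metric_comparison = metric_comparison(
      link$records, registry,
      patient_days_adult = sum(adm_metrics$patient_days),
      dispensing = dispensing,
      patient_days_all = pd_all,
      minors_count = adults$excluded_count
    ),
    quality = quality_summary(
      admission_issues %||% empty_issues(),
      administration_issues %||% empty_issues(),
      link$issues, link$records, registry,
      minors_count = adults$excluded_count
    ),
    episodes = eps$episodes,
    adm_metrics = adm_metrics,
    seed = seed
  ), class = "amc_report")
}

#' @export
print.amc_report <- function(x, ...) {
  lv <- x$metrics_by_level
  cat("AMC surveillance report\n")
  cat(sprintf(
    "  %d admissions, %d episodes, %.0f patient-days\n",
    nrow(x$adm_metrics), nrow(x$episodes), sum(x$adm_metrics$patient_days)
  ))
  for (i in seq_len(nrow(lv))) {
    cat(sprintf(
      "  %s: %d DOT (%s per 1000 patient-days), DOT/LOT %.2f\n",
      lv$care_level[i], lv$dot[i],
      format(round_half_up(lv$dot_rate[i])), lv$dot_lot_ratio[i]
    ))
  }
  invisible(x)
}

#' Render a report bundle to CSV files
#'
#' Writes the bundle deterministically: rates per 1000 patient-days rounded
#' half-up to integers, percentages to one decimal in the population table
#' and integers in exposure tables.  Re-rendering the same bundle is
#' byte-identical.
#'
#' @param bundle `amc_report` from [build_report()].
#' @param outdir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
render_report <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(seed = bundle$seed, n = nrow(bundle$adm_metrics)))
  paths <- character()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_report_csv(df, p, config_hash = hash)
    paths <<- c(paths, p)
  }

  pop <- bundle$population
  pop$pct_female <- fmt_pct(pop$pct_female)
  pop$pct_imv <- fmt_pct(pop$pct_imv)
  pop$pct_crrt <- fmt_pct(pop$pct_crrt)
  pop$icu_mortality <- fmt_pct(pop$icu_mortality)
  pop$mortality_30d <- fmt_pct(pop$mortality_30d)
  pop$patient_days <- round_half_up(pop$patient_days)
  put(pop, "population.csv")

  ct <- bundle$clinic_table
  ct$patient_days <- round_half_up(ct$patient_days)
  ct$patient_days_women <- round_half_up(ct$patient_days_women)
  put(ct, "clinic_table.csv")

  rnd_rates <- function(df) {
    for (col in intersect(
      c("dot_rate", "lot_rate", "ddd_rate", "ci_low", "ci_high",
        "ddd_administered_rate", "ddd_dispensed_rate"),
      names(df)
    )) {
      df[[col]] <- round_half_up(df[[col]])
    }
    df
  }
  put(rnd_rates(bundle$clinics), "clinics.csv")
  put(rnd_rates(bundle$metrics_by_level), "metrics.csv")
  put(rnd_rates(bundle$class_consumption), "class_consumption.csv")
  put(rnd_rates(bundle$clinic_consumption), "clinic_consumption.csv")

  expo <- bundle$exposure
  expo$level <- as.character(expo$level)
  put(expo, "exposure.csv")
  lv <- bundle$exposure_levels
  lv$level <- as.character(lv$level)
  lv$proportion <- fmt_pct(lv$proportion, 0)
  names(lv)[names(lv) == "proportion"] <- "pct"
  put(lv, "exposure_levels.csv")
  cx <- bundle$class_exposure
  cx$proportion <- fmt_pct(cx$proportion, 0)
  names(cx)[names(cx) == "proportion"] <- "pct"
  put(cx, "class_exposure.csv")

  em <- bundle$exposure_mortality$summary
  em$level <- as.character(em$level)
  em$icu_mortality <- fmt_pct(em$icu_mortality)
  em$mortality_30d <- fmt_pct(em$mortality_30d)
  put(em, "exposure_mortality.csv")

  put(rnd_rates(bundle$metric_comparison), "metric_comparison.csv")
  put(bundle$quality, "quality.csv")

  ep <- bundle$episodes
  ep$episode_start <- format_ts(ep$episode_start)
  ep$episode_end <- format_ts(ep$episode_end)
  put(
    ep[, c(
      "episode_id", "patient_id", "n_admissions", "episode_start",
      "episode_end", "los_days", "care_level_of_record", "died_in_icu",
      "died_within_30d"
    )],
    "episodes.csv"
  )
  invisible(paths)
}
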