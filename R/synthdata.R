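# Synthetic ICU dataset generator.
#
# Emulates the statistical structure of a four-year two-level ICU cohort:
# care-level and referring-clinic mix, per-clinic log-normal LOS, SAPS 3
# severity with a logistic estimated-mortality transform, Bernoulli(EMR)
# 30-day deaths, readmissions with a gap distribution straddling the 48-h
# merge window, inter-unit transfers, per-class prescribing hazards scaled
# by stay length and severity, nursing-round dose timestamps (06/12/18/24 h
# +/- jitter, deliberately exercising the calendar-day boundary), pharmacy
# dispensing inflated relative to signed doses, and two pandemic case-mix
# waves.  The generator computes per-admission and per-episode ground truth
# by direct enumeration in base R at generation time -- deliberately NOT via
# the metrics module -- so truth.json is an independent oracle for the whole
# pipeline.

#' Reference calibration targets
#'
#' Summary statistics of a published four-year Scandinavian two-level ICU
#' cohort (5608 admissions), used as the default calibration targets for the
#' generator: care-level and clinic mix, per-clinic median (IQR) LOS,
#' severity and mortality summaries, and total DOT per 1000 patient-days
#' per care level.
#'
#' @return nested list of targets consumed by [calibrate_generator()].
#' @export
reference_targets <- function() {
  clinics <- tibble::tribble(
    ~care_level, ~referring_clinic, ~n, ~los_median, ~los_q1, ~los_q3,
    "secondary", "internal_medicine", 1883, 1.0, 0.5, 2.4,
    "secondary", "general_surgery", 647, 1.0, 0.5, 2.6,
    "secondary", "orthopedic_surgery", 65, 1.3, 0.5, 3.2,
    "secondary", "other", 149, 0.6, 0.4, 1.0,
    "tertiary", "general_surgery", 810, 1.8, 0.9, 4.6,
    "tertiary", "internal_medicine", 594, 0.9, 0.4, 2.1,
    "tertiary", "neurosurgery", 516, 2.9, 0.9, 7.9,
    "tertiary", "infectious_diseases", 305, 3.5, 1.3, 8.7,
    "tertiary", "neurology", 243, 1.3, 0.6, 3.9,
    "tertiary", "orthopedic_surgery", 149, 2.2, 1.1, 5.9,
    "tertiary", "oncology_haematology", 64, 2.0, 1.0, 4.0,
    "tertiary", "other", 183, 1.0, 0.6, 2.5
  )
  list(
    period = as.Date(c("2018-01-01", "2021-12-31")),
    admissions = c(secondary = 2744, tertiary = 2864),
    clinics = clinics,
    female_fraction = 0.413,
    age = list(median = 65, q1 = 48, q3 = 75),
    los_median = c(secondary = 1.0, tertiary = 1.8),
    saps3 = list(
      secondary = list(offset = 38, shape = 1.4, scale = 11),
      tertiary = list(offset = 40, shape = 1.3, scale = 14)
    ),
    # EMR = plogis(a + b * SAPS3); reproduces median (IQR) EMR of
    # 0.08 / 0.14 at the median scores of the two care levels.
    emr_coef = c(a = -8.3, b = 0.115),
    icu_death_given_30d = 0.45,
    mortality_30d = 0.183,
    dot_rate_per_1000pd = c(secondary = 1177, tertiary = 1261),
    exposed_fraction = c(secondary = 0.47, tertiary = 0.66)
  )
}

# Drug panel: dosing behaviour of the surveilled agents in the generator.
synth_drug_panel <- function() {
  tibble::tribble(
    ~atc_code, ~doses_per_day, ~dose, ~dose_unit, ~route, ~w_sec, ~w_ter,
    "J01DD01", 3, 1, "g", "IV", 10, 16, # cefotaxime
    "J01DD04", 1, 2, "g", "IV", 6, 11, # ceftriaxone
    "J01DC02", 3, 1.5, "g", "IV", 5, 3, # cefuroxime
    "J01CR05", 3, 4, "g", "IV", 29, 17, # piperacillin/tazobactam
    "J01CE01", 3, 1, "g", "IV", 7, 4, # benzylpenicillin
    "J01CF02", 3, 2, "g", "IV", 2, 4, # cloxacillin
    "J01DH02", 4, 0.5, "g", "IV", 5, 9, # meropenem q6h
    "J01XA01", 2, 1, "g", "IV", 4, 6, # vancomycin
    "J01GB03", 1, 320, "mg", "IV", 4, 3, # gentamicin
    "J01MA02", 2, 0.4, "g", "IV", 6, 5, # ciprofloxacin
    "J01XD01", 1, 1.5, "g", "IV", 5, 4, # metronidazole
    "J01FF01", 3, 0.6, "g", "IV", 3, 2, # clindamycin
    "J01XX08", 2, 0.6, "g", "IV", 1, 2, # linezolid
    "J01EE01", 2, 0.8, "g", "IV", 2, 2, # co-trimoxazole (no DDD)
    "J01XB01", 3, 80, "mg", "IV", 0.5, 1, # colistin (MU-denominated DDD)
    "J02AC01", 1, 0.4, "g", "IV", 4, 4, # fluconazole
    "J02AX04", 1, 50, "mg", "IV", 2, 4, # caspofungin
    "J02AX05", 1, 100, "mg", "IV", 1, 2, # micafungin
    "J02AC03", 2, 0.3, "g", "IV", 0.5, 1 # voriconazole
  )
}

lognormal_from_median_iqr <- function(median, q1, q3) {
  c(meanlog = log(median), sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Calibrate a generator configuration to population targets
#'
#' Translates summary targets into generating parameters: clinic mix
#' proportions and per-clinic log-normal LOS parameters (matched in median
#' and IQR), severity and mortality models, and per-care-level prescribing
#' intensity.  Intensity is calibrated by a small internal pilot run: course
#' starts are approximately linear in the hazard scale, so the pilot DOT
#' rate is measured once and the intensity rescaled to the target rate.
#'
#' @param targets target list, by default [reference_targets()].
#' @param n_patients number of adult patients to generate.
#' @param seed integer seed; every downstream draw derives from it.
#' @return a `GeneratorConfig`-style list accepted by
#'   [generate_synthetic()].
#' @export
calibrate_generator <- function(targets = reference_targets(),
                                n_patients = 2000, seed = 1) {
  cl <- targets$clinics
  ln <- t(mapply(
    lognormal_from_median_iqr, cl$los_median, cl$los_q1, cl$los_q3
  ))
  cl$los_meanlog <- ln[, "meanlog"]
  cl$los_sdlog <- ln[, "sdlog"]
  cl$prob <- cl$n / sum(cl$n)

  # Per-clinic log-normals matched on median and IQR do not exactly
  # reproduce the care-level overall LOS median (real stay lengths are not
  # log-normal), so apply a common log-shift per care level that puts the
  # mixture median on target.
  if (!is.null(targets$los_median)) {
    for (lev in names(targets$los_median)) {
      sub <- cl$care_level == lev
      w <- cl$prob[sub] / sum(cl$prob[sub])
      target <- targets$los_median[[lev]]
      shift <- stats::uniroot(
        function(d) {
          sum(w * stats::plnorm(
            target, cl$los_meanlog[sub] + d, cl$los_sdlog[sub]
          )) - 0.5
        },
        c(-1.5, 1.5)
      )$root
      cl$los_meanlog[sub] <- cl$los_meanlog[sub] + shift
    }
  }

  config <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    start_date = targets$period[1],
    end_date = targets$period[2],
    care_mix = targets$admissions / sum(targets$admissions),
    clinics = cl,
    female_fraction = targets$female_fraction,
    age = targets$age,
    saps3 = targets$saps3,
    emr_coef = targets$emr_coef,
    icu_death_given_30d = targets$icu_death_given_30d,
    readmit_prob = 0.06,
    gap_meanlog = log(36), gap_sdlog = 0.9,
    transfer_prob = 0.15,
    intensity = c(secondary = 0.5, tertiary = 0.5),
    severity_slope = 0.012,
    course_extra_days_mean = 2,
    drug_panel = synth_drug_panel(),
    missing_atc_fraction = 0.006,
    minors_fraction = 0.12,
    dispensing_base_factor = 1.25,
    dispensing_cloxacillin_factor = 3.5,
    covid_waves = list(
      as.Date(c("2020-04-03", "2020-06-14")),
      as.Date(c("2021-02-08", "2021-05-28"))
    ),
    covid_admission_prob = 0.25
  )

  # Pilot calibration of prescribing intensity against the DOT-rate target:
  # course starts are near-linear in the hazard scale, so two fixed-point
  # iterations on a pilot cohort converge to within a few percent.
  pilot <- config
  pilot$n_patients <- 1200L
  pilot$seed <- (config$seed + 104729L) %% .Machine$integer.max
  pilot$minors_fraction <- 0
  for (iter in 1:2) {
    pilot$intensity <- config$intensity
    truth_adm <- generate_synthetic(pilot)$truth$admissions
    for (lev in c("secondary", "tertiary")) {
      sel <- truth_adm$care_level == lev
      pilot_rate <- 1000 * sum(truth_adm$dot[sel]) /
        sum(truth_adm$patient_days[sel])
      if (is.finite(pilot_rate) && pilot_rate > 0) {
        config$intensity[lev] <- config$intensity[lev] *
          targets$dot_rate_per_1000pd[lev] / pilot_rate
      }
    }
  }
  config
}

# --- independent ground-truth enumeration (base R only) ---------------------

truth_enumerate <- function(adm, doses, registry, gap_hours = 48) {
  with_atc <- doses[!is.na(doses$atc_code) & doses$atc_code != "", ,
    drop = FALSE
  ]
  reg <- as.data.frame(registry)
  reg_iv <- reg[is.na(reg$ddd_route) | reg$ddd_route == "IV", , drop = FALSE]
  reg_iv <- reg_iv[!duplicated(reg_iv$atc_code), , drop = FALSE]
  surveilled <- with_atc[with_atc$atc_code %in% reg$atc_code, , drop = FALSE]

  date <- format(surveilled$timestamp, "%Y-%m-%d", tz = AMC_TZ)
  triple <- paste(surveilled$admission_id, date, surveilled$atc_code)
  pair <- paste(surveilled$admission_id, date)
  first_triple <- !duplicated(triple)
  first_pair <- !duplicated(pair)

  dot_tab <- table(surveilled$admission_id[first_triple])
  lot_tab <- table(surveilled$admission_id[first_pair])

  m <- match(surveilled$atc_code, reg_iv$atc_code)
  ddd_val <- reg_iv$ddd_value[m]
  ddd_unit <- reg_iv$ddd_unit[m]
  amt <- surveilled$amount
  amt_conv <- ifelse(
    surveilled$amount_unit == ddd_unit, amt,
    ifelse(surveilled$amount_unit == "g" & ddd_unit == "mg", amt * 1000,
      ifelse(surveilled$amount_unit == "mg" & ddd_unit == "g", amt / 1000,
        NA_real_
      )
    )
  )
  ddd_dose <- amt_conv / ddd_val
  ddd_tab <- if (nrow(surveilled) > 0) {
    tapply(ddd_dose, surveilled$admission_id,
      function(x) sum(x, na.rm = TRUE)
    )
  } else {
    setNames(numeric(0), character(0))
  }

  truth_adm <- data.frame(
    admission_id = adm$admission_id,
    care_level = adm$care_level,
    patient_days = as.numeric(adm$discharge_ts - adm$admit_ts,
      units = "hours"
    ) / 24,
    dot = as.integer(dot_tab[adm$admission_id]),
    lot = as.integer(lot_tab[adm$admission_id]),
    ddd = as.numeric(ddd_tab[adm$admission_id]),
    stringsAsFactors = FALSE
  )
  truth_adm$dot[is.na(truth_adm$dot)] <- 0L
  truth_adm$lot[is.na(truth_adm$lot)] <- 0L
  truth_adm$ddd[is.na(truth_adm$ddd)] <- 0

  # Episode grouping by the 48-h rule, enumerated with a plain loop.
  ord <- order(adm$patient_id, adm$admit_ts)
  pid <- adm$patient_id[ord]
  a_ts <- adm$admit_ts[ord]
  d_ts <- adm$discharge_ts[ord]
  aid <- adm$admission_id[ord]
  group <- integer(length(ord))
  g <- 0L
  for (i in seq_along(ord)) {
    new_ep <- i == 1 || pid[i] != pid[i - 1] ||
      as.numeric(a_ts[i] - d_ts[i - 1], units = "hours") >= gap_hours
    if (new_ep) g <- g + 1L
    group[i] <- g
  }

  class_map <- reg$class_label[!duplicated(reg$atc_code)]
  names(class_map) <- reg$atc_code[!duplicated(reg$atc_code)]
  cls_by_adm <- if (nrow(surveilled) > 0) {
    tapply(
      as.character(class_map[surveilled$atc_code]),
      surveilled$admission_id,
      function(x) sort(unique(x))
    )
  } else {
    setNames(list(), character(0))
  }

  ep_rows <- lapply(split(seq_along(ord), group), function(ix) {
    ids <- aid[ix]
    classes <- sort(unique(unlist(cls_by_adm[ids])))
    m2 <- match(ids, truth_adm$admission_id)
    data.frame(
      episode_key = paste(sort(ids), collapse = "+"),
      n_admissions = length(ids),
      dot = sum(truth_adm$dot[m2]),
      lot = sum(truth_adm$lot[m2]),
      ddd = sum(truth_adm$ddd[m2]),
      los_days = sum(truth_adm$patient_days[m2]),
      n_classes = length(classes),
      level = c("none", "one", "two", "three")[
        pmin(length(classes), 3) + 1
      ],
      stringsAsFactors = FALSE
    )
  })
  truth_ep <- do.call(rbind, ep_rows)
  truth_ep$level[truth_ep$n_classes > 3] <- "more_than_three"
  rownames(truth_ep) <- NULL

  list(admissions = truth_adm, episodes = truth_ep)
}

# --- generation -------------------------------------------------------------

#' Generate a synthetic surveillance dataset
#'
#' Draws a complete admission / administration / dispensing dataset from a
#' generator configuration, together with independently enumerated ground
#' truth (per-admission and per-episode DOT, LOT, DDD, exposure) for oracle
#' testing.  The same seed yields byte-identical output.
#'
#' @param config configuration from [calibrate_generator()] (any field may
#'   be overridden before the call).
#' @param dir optional directory: writes `admissions.csv`,
#'   `administrations.csv`, `dispensing.csv` and `truth.json` there.
#' @return list with tibbles `admissions`, `administrations`, `dispensing`,
#'   plus `truth` (list with `admissions`, `episodes`, `covid_admissions`)
#'   and `config`.
#' @export
generate_synthetic <- function(config, dir = NULL) {
  stopifnot(
    is.numeric(config$seed), config$n_patients > 0,
    all(config$care_mix >= 0), abs(sum(config$care_mix) - 1) < 1e-8,
    all(config$clinics$prob >= 0),
    config$minors_fraction >= 0, config$minors_fraction < 1
  )
  set.seed(config$seed)
  registry <- load_atc_registry()
  panel <- config$drug_panel
  cl <- config$clinics

  n <- config$n_patients
  # Patients: care level, demographics.
  care_level_p <- sample(
    names(config$care_mix), n, replace = TRUE, prob = config$care_mix
  )
  sex_p <- ifelse(runif(n) < config$female_fraction, "female", "male")
  age_p <- pmax(18, pmin(97, round(95 - rlnorm(n, log(30), 0.55))))

  # Admission chains: geometric number of readmissions, capped.
  n_adm_p <- pmin(1L + stats::rgeom(n, 1 - config$readmit_prob), 4L)
  pat_idx <- rep(seq_len(n), n_adm_p)
  adm_seq <- sequence(n_adm_p)
  n_adm <- length(pat_idx)

  care_level <- care_level_p[pat_idx]
  # Transfers: a readmission may land in a different unit.
  transfer <- adm_seq > 1 & runif(n_adm) < config$transfer_prob

  clinic_of <- function(lev_vec) {
    out <- character(length(lev_vec))
    for (lev in unique(lev_vec)) {
      sub <- cl[cl$care_level == lev, , drop = FALSE]
      sel <- lev_vec == lev
      out[sel] <- sample(
        sub$referring_clinic, sum(sel), replace = TRUE,
        prob = sub$prob / sum(sub$prob)
      )
    }
    out
  }
  clinic <- clinic_of(care_level)

  unit_of <- function(lev, u) {
    ifelse(lev == "tertiary", "ICU_T1",
      ifelse(u < 0.6, "ICU_S1", "ICU_S2")
    )
  }
  unit_id <- unit_of(care_level, runif(n_adm))
  flip <- which(transfer)
  care_level[flip] <- ifelse(
    runif(length(flip)) < 0.5, care_level[flip],
    ifelse(care_level[flip] == "tertiary", "secondary", "tertiary")
  )
  unit_id[flip] <- unit_of(care_level[flip], runif(length(flip)))
  clinic[flip] <- clinic_of(care_level[flip])

  # LOS per admission from the clinic's log-normal.
  key <- paste(care_level, clinic)
  ckey <- paste(cl$care_level, cl$referring_clinic)
  mrow <- match(key, ckey)
  los_days <- rlnorm(n_adm, cl$los_meanlog[mrow], cl$los_sdlog[mrow])
  # Truncate to a plausible clinical range: at least two hours of care, at
  # most 60 days (the unbounded log-normal tail would otherwise produce
  # multi-month stays that dominate the patient-day denominator).
  los_days <- pmax(pmin(los_days, 60), 2 / 24)

  # Admission timestamps: first admissions uniform over the period,
  # readmission gaps log-normal around 36 h (straddling the 48-h window).
  span_days <- as.numeric(config$end_date - config$start_date) - 14
  first_admit <- as.POSIXct(config$start_date, tz = AMC_TZ) +
    runif(n, 0, span_days * 86400)
  gap_h <- rlnorm(n_adm, config$gap_meanlog, config$gap_sdlog)
  admit_ts <- as.POSIXct(rep(NA_real_, n_adm),
    origin = "1970-01-01", tz = AMC_TZ
  )
  discharge_ts <- admit_ts
  cur <- first_admit[pat_idx]
  for (j in seq_len(max(adm_seq))) {
    sel <- adm_seq == j
    if (j > 1) {
      prev <- adm_seq == (j - 1)
      prev_end <- rep(as.POSIXct(NA, tz = AMC_TZ), n)
      prev_end[pat_idx[prev]] <- discharge_ts[prev]
      cur <- prev_end[pat_idx] + gap_h * 3600
    }
    admit_ts[sel] <- cur[sel]
    discharge_ts[sel] <- admit_ts[sel] + los_days[sel] * 86400
  }
  admit_ts <- lubridate::round_date(admit_ts, "minute")
  discharge_ts <- lubridate::round_date(discharge_ts, "minute")
  los_days <- as.numeric(discharge_ts - admit_ts, units = "hours") / 24

  # Severity and outcomes.
  saps <- integer(n_adm)
  for (lev in c("secondary", "tertiary")) {
    p <- config$saps3[[lev]]
    sel <- care_level == lev
    saps[sel] <- pmin(
      100, round(p$offset + stats::rgamma(sum(sel), p$shape, scale = p$scale))
    )
  }
  emr <- round(
    stats::plogis(config$emr_coef[["a"]] + config$emr_coef[["b"]] * saps), 4
  )
  died_30d_p <- runif(n) < emr[match(seq_len(n), pat_idx)]
  died_30d <- died_30d_p[pat_idx] & adm_seq == n_adm_p[pat_idx]
  died_in_icu <- died_30d & runif(n_adm) < config$icu_death_given_30d
  # Deaths end the chain: a patient who dies has no later admissions --
  # enforced by attributing death to the last admission only (above).

  # Pandemic case-mix flag (tertiary medical admissions during the waves).
  adm_date <- as.Date(admit_ts, tz = AMC_TZ)
  in_wave <- rep(FALSE, n_adm)
  for (w in config$covid_waves) {
    in_wave <- in_wave | (adm_date >= w[1] & adm_date <= w[2])
  }
  is_covid <- in_wave & care_level == "tertiary" &
    clinic %in% c("internal_medicine", "infectious_diseases") &
    runif(n_adm) < config$covid_admission_prob

  admission_id <- sprintf("A%06d", seq_len(n_adm))
  admissions <- tibble::tibble(
    admission_id = admission_id,
    patient_id = sprintf("P%06d", pat_idx),
    unit_id = unit_id,
    care_level = care_level,
    admit_ts = admit_ts,
    discharge_ts = discharge_ts,
    age_years = age_p[pat_idx],
    sex = sex_p[pat_idx],
    referring_clinic = clinic,
    saps3_score = saps,
    saps3_emr = emr,
    imv_hours = ifelse(
      runif(n_adm) < ifelse(care_level == "tertiary", 0.572, 0.207),
      round(pmin(
        rlnorm(n_adm, log(ifelse(care_level == "tertiary", 54, 28)), 1.1),
        los_days * 24
      ), 1),
      NA_real_
    ),
    crrt_hours = ifelse(
      runif(n_adm) < ifelse(care_level == "tertiary", 0.034, 0.02),
      round(rlnorm(n_adm, log(80), 0.7), 1), NA_real_
    ),
    cvc_hours = ifelse(
      runif(n_adm) < 0.55,
      round(pmin(
        rlnorm(n_adm, log(ifelse(care_level == "tertiary", 86, 56)), 1.0),
        los_days * 24
      ), 1),
      NA_real_
    ),
    died_in_icu = died_in_icu,
    died_within_30d = died_30d
  )

  # --- prescribing ----------------------------------------------------------
  base_int <- config$intensity[care_level]
  covid_damp <- ifelse(is_covid, 0.7, 1)
  lambda <- base_int * pmin(los_days, 30)^0.7 *
    exp(config$severity_slope * (saps - 53)) * covid_damp
  n_courses <- rpois(n_adm, lambda)

  c_adm <- rep(seq_len(n_adm), n_courses)
  n_c <- length(c_adm)
  doses <- NULL
  if (n_c > 0) {
    drug_i <- integer(n_c)
    for (lev in c("secondary", "tertiary")) {
      sel <- care_level[c_adm] == lev
      wts <- if (lev == "secondary") panel$w_sec else panel$w_ter
      if (any(sel)) {
        drug_i[sel] <- sample(nrow(panel), sum(sel), replace = TRUE,
          prob = wts
        )
      }
    }
    # Start day (0-based, biased towards admission) and duration.
    max_day <- pmax(ceiling(los_days[c_adm]) - 1, 0)
    start_day <- floor(runif(n_c)^1.7 * (max_day + 1))
    duration <- 1 + rpois(n_c, config$course_extra_days_mean)

    day_of <- rep(seq_len(n_c), duration)
    day_off <- start_day[day_of] + sequence(duration) - 1
    adm_i <- c_adm[day_of]
    day_date <- as.Date(admit_ts[adm_i], tz = AMC_TZ) + day_off
    keep <- day_date <= as.Date(discharge_ts[adm_i], tz = AMC_TZ)
    day_of <- day_of[keep]
    day_off <- day_off[keep]
    adm_i <- adm_i[keep]
    day_date <- day_date[keep]

    dpd <- panel$doses_per_day[drug_i[day_of]]
    dose_row <- rep(seq_along(day_of), dpd)
    rounds <- list(c(8), c(8, 20), c(6, 12, 18), c(6, 12, 18, 24))
    hour <- unlist(lapply(dpd, function(k) rounds[[k]]), use.names = FALSE)
    hour <- hour + runif(length(hour), -0.75, 0.75)
    ts <- as.POSIXct(day_date[dose_row], tz = AMC_TZ) + hour * 3600
    ts <- lubridate::round_date(ts, "minute")
    adm_d <- adm_i[dose_row]
    ts <- pmin(pmax(ts, admit_ts[adm_d] + 60), discharge_ts[adm_d] - 60)

    di <- drug_i[day_of][dose_row]
    amount <- round(panel$dose[di] * runif(length(di), 0.8, 1.2), 3)
    doses <- tibble::tibble(
      admission_id = admission_id[adm_d],
      timestamp = ts,
      atc_code = panel$atc_code[di],
      amount = amount,
      amount_unit = panel$dose_unit[di],
      route = panel$route[di]
    )
    # A small fraction of doses lose their ATC linkage.
    drop_atc <- runif(nrow(doses)) < config$missing_atc_fraction
    doses$atc_code[drop_atc] <- NA_character_
    doses <- doses[order(doses$admission_id, doses$timestamp), , drop = FALSE]
  } else {
    doses <- tibble::tibble(
      admission_id = character(), timestamp = as.POSIXct(character(),
        tz = AMC_TZ
      ),
      atc_code = character(), amount = numeric(),
      amount_unit = character(), route = character()
    )
  }
  doses$record_id <- sprintf("R%07d", seq_len(nrow(doses)))
  doses <- doses[, c(
    "record_id", "admission_id", "timestamp", "atc_code", "amount",
    "amount_unit", "route"
  )]

  # --- ground truth (independent enumeration) -------------------------------
  truth <- truth_enumerate(admissions, doses, registry)
  truth$covid_admissions <- admission_id[is_covid]

  # --- dispensing -----------------------------------------------------------
  q_start <- seq(config$start_date, config$end_date, by = "3 months")
  doses_atc <- doses[!is.na(doses$atc_code), , drop = FALSE]
  if (nrow(doses_atc) > 0) {
    adm_unit <- admissions$unit_id[match(doses_atc$admission_id,
      admissions$admission_id
    )]
    qtr <- q_start[findInterval(as.Date(doses_atc$timestamp, tz = AMC_TZ),
      q_start
    )]
    agg <- stats::aggregate(
      doses_atc$amount,
      by = list(
        unit_id = adm_unit, period_start = qtr,
        atc_code = doses_atc$atc_code,
        amount_unit = doses_atc$amount_unit
      ),
      FUN = sum
    )
    factor <- config$dispensing_base_factor *
      exp(rnorm(nrow(agg), 0, 0.08))
    clox <- agg$atc_code == "J01CF02"
    factor[clox] <- factor[clox] * config$dispensing_cloxacillin_factor
    # quarter end = next quarter start - 1 day
    nxt <- q_start[match(agg$period_start, q_start) + 1]
    dispensing <- tibble::tibble(
      unit_id = agg$unit_id,
      period_start = agg$period_start,
      period_end = dplyr::coalesce(nxt - 1, config$end_date),
      atc_code = agg$atc_code,
      amount = round(agg$x * factor, 2),
      amount_unit = agg$amount_unit
    )
    dispensing <- dispensing[order(
      dispensing$unit_id, dispensing$period_start, dispensing$atc_code
    ), , drop = FALSE]
  } else {
    dispensing <- tibble::tibble(
      unit_id = character(), period_start = as.Date(character()),
      period_end = as.Date(character()), atc_code = character(),
      amount = numeric(), amount_unit = character()
    )
  }

  # --- minors (admission rows only; shelf supply covers them too) ----------
  n_minor <- round(config$minors_fraction * n_adm)
  if (n_minor > 0) {
    m_lev <- sample(names(config$care_mix), n_minor, replace = TRUE,
      prob = config$care_mix
    )
    m_admit <- as.POSIXct(config$start_date, tz = AMC_TZ) +
      runif(n_minor, 0, span_days * 86400)
    m_los <- rlnorm(n_minor, log(0.8), 0.8)
    minors <- tibble::tibble(
      admission_id = sprintf("AM%05d", seq_len(n_minor)),
      patient_id = sprintf("PM%05d", seq_len(n_minor)),
      unit_id = unit_of(m_lev, runif(n_minor)),
      care_level = m_lev,
      admit_ts = lubridate::round_date(m_admit, "minute"),
      discharge_ts = lubridate::round_date(m_admit + m_los * 86400, "minute"),
      age_years = sample(1:17, n_minor, replace = TRUE),
      sex = ifelse(runif(n_minor) < 0.45, "female", "male"),
      referring_clinic = sample(c("general_surgery", "other"), n_minor,
        replace = TRUE
      ),
      saps3_score = NA_integer_, saps3_emr = NA_real_,
      imv_hours = NA_real_, crrt_hours = NA_real_, cvc_hours = NA_real_,
      died_in_icu = FALSE, died_within_30d = FALSE
    )
    admissions <- dplyr::bind_rows(admissions, minors)
  }

  out <- list(
    admissions = admissions,
    administrations = doses,
    dispensing = dispensing,
    truth = truth,
    config = config
  )
  if (!is.null(dir)) write_synthetic(out, dir)
  invisible(out)
}

#' Write a generated dataset to CSV + truth.json
#'
#' @param sim output of [generate_synthetic()].
#' @param dir target directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adm <- sim$admissions
  adm$admit_ts <- format_ts(adm$admit_ts)
  adm$discharge_ts <- format_ts(adm$discharge_ts)
  doses <- sim$administrations
  doses$timestamp <- format_ts(doses$timestamp)
  paths <- c(
    file.path(dir, "admissions.csv"),
    file.path(dir, "administrations.csv"),
    file.path(dir, "dispensing.csv"),
    file.path(dir, "truth.json")
  )
  readr::write_csv(adm, paths[1], na = "")
  readr::write_csv(doses, paths[2], na = "")
  readr::write_csv(sim$dispensing, paths[3], na = "")
  truth <- sim$truth
  truth$config_seed <- sim$config$seed
  jsonlite::write_json(truth, paths[4], dataframe = "columns", digits = NA)
  invisible(paths)
}
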