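# Fixture builders and independent brute-force oracles used across tests.

ts <- function(x) as.POSIXct(x, tz = "UTC")

REG <- load_atc_registry()

make_admission <- function(admission_id = "A1", patient_id = admission_id,
                           unit_id = "ICU_T1", care_level = "tertiary",
                           admit_ts = ts("2020-03-01 10:00:00"),
                           discharge_ts = ts("2020-03-04 10:00:00"),
                           age_years = 60L, sex = "male",
                           referring_clinic = "general_surgery",
                           saps3_score = 50L, saps3_emr = 0.1,
                           imv_hours = NA_real_, crrt_hours = NA_real_,
                           cvc_hours = NA_real_,
                           died_in_icu = FALSE, died_within_30d = FALSE) {
  tibble::tibble(
    admission_id = admission_id, patient_id = patient_id,
    unit_id = unit_id, care_level = care_level,
    admit_ts = admit_ts, discharge_ts = discharge_ts,
    age_years = age_years, sex = sex,
    referring_clinic = referring_clinic,
    saps3_score = saps3_score, saps3_emr = saps3_emr,
    imv_hours = imv_hours, crrt_hours = crrt_hours, cvc_hours = cvc_hours,
    died_in_icu = died_in_icu, died_within_30d = died_within_30d
  )
}

make_dose <- function(record_id = "R1", admission_id = "A1",
                      timestamp = ts("2020-03-01 12:00:00"),
                      atc_code = "J01DD04", amount = 2,
                      amount_unit = "g", route = "IV") {
  tibble::tibble(
    record_id = record_id, admission_id = admission_id,
    timestamp = timestamp, atc_code = atc_code,
    amount = amount, amount_unit = amount_unit, route = route
  )
}

write_admissions_csv <- function(adm, path) {
  adm$admit_ts <- format(adm$admit_ts, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  adm$discharge_ts <- format(adm$discharge_ts, "%Y-%m-%d %H:%M:%S",
    tz = "UTC"
  )
  readr::write_csv(adm, path, na = "")
  path
}

write_doses_csv <- function(doses, path) {
  doses$timestamp <- format(doses$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(doses, path, na = "")
  path
}

# Link doses to admissions without going through CSV.
link_direct <- function(admissions, doses, ...) {
  link_records(admissions, doses, ...)$records
}

# Independent DOT oracle: count unique (admission, date, agent) triples with
# plain base R string keys.
oracle_dot <- function(doses, registry) {
  d <- doses[!is.na(doses$atc_code) &
    doses$atc_code %in% registry$atc_code, , drop = FALSE]
  length(unique(paste(
    d$admission_id, format(d$timestamp, "%Y-%m-%d", tz = "UTC"), d$atc_code
  )))
}

oracle_lot <- function(doses, registry) {
  d <- doses[!is.na(doses$atc_code) &
    doses$atc_code %in% registry$atc_code, , drop = FALSE]
  length(unique(paste(
    d$admission_id, format(d$timestamp, "%Y-%m-%d", tz = "UTC")
  )))
}

# Brute-force episode partition: connected components of the graph with an
# edge between any two admissions of a patient whose discharge-to-admit gap
# (in either direction) is inside the window.
oracle_episode_partition <- function(adm, gap_hours = 48) {
  n <- nrow(adm)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || adm$patient_id[i] != adm$patient_id[j]) next
      gap <- as.numeric(adm$admit_ts[j] - adm$discharge_ts[i],
        units = "hours"
      )
      if (gap >= 0 && gap < gap_hours) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(adm$admission_id, roots)
}

# Canonical form of a partition for comparison: sorted list of sorted keys.
partition_key <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = "+"), "")))
}

# Small reusable synthetic configuration (calibrated once per test run).
small_config <- local({
  cache <- NULL
  function(n_patients = 150, seed = 1) {
    if (is.null(cache)) {
      cache <<- calibrate_generator(n_patients = n_patients, seed = seed)
    }
    cfg <- cache
    cfg$n_patients <- as.integer(n_patients)
    cfg$seed <- as.integer(seed)
    cfg
  }
})
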