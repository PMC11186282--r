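test_that("therapy days are distinct per agent and calendar date", {
  adm <- make_admission("A1",
    admit_ts = ts("2020-03-01 00:30:00"),
    discharge_ts = ts("2020-03-03 12:00:00")
  )
  doses <- dplyr::bind_rows(
    make_dose("R1", timestamp = ts("2020-03-01 08:00:00")),
    make_dose("R2", timestamp = ts("2020-03-01 20:00:00")), # same agent+day
    make_dose("R3", timestamp = ts("2020-03-01 23:50:00"),
      atc_code = "J01DH02", amount = 0.5
    ),
    make_dose("R4", timestamp = ts("2020-03-02 00:10:00"),
      atc_code = "J01DH02", amount = 0.5
    ) # crosses midnight -> second day
  )
  days <- therapy_days(link_direct(adm, doses), REG)
  expect_equal(nrow(days), 3) # (ceftriaxone d1), (meropenem d1), (meropenem d2)
  expect_equal(dot(days), 3)
  expect_equal(lot(days), 2)
})

test_that("DOT and LOT match the definition on the worked two-day example", {
  adm <- make_admission("A1",
    admit_ts = ts("2020-03-01 00:00:00"),
    discharge_ts = ts("2020-03-04 00:00:00")
  )
  doses <- dplyr::bind_rows(
    make_dose("R1", timestamp = ts("2020-03-01 08:00:00")), # ceftriaxone
    make_dose("R2", timestamp = ts("2020-03-01 12:00:00"),
      atc_code = "J01XA01", amount = 1
    ), # vancomycin
    make_dose("R3", timestamp = ts("2020-03-02 08:00:00")) # ceftriaxone
  )
  days <- therapy_days(link_direct(adm, doses), REG)
  expect_equal(dot(days), 3)
  expect_equal(lot(days), 2)
  # empty input
  expect_equal(dot(days[0, ]), 0)
  expect_equal(lot(days[0, ]), 0)
})

test_that("random dose sets agree with the brute-force triple-count oracle", {
  set.seed(5)
  adm <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_admission(sprintf("A%d", i), sprintf("P%d", i),
      admit_ts = ts("2020-03-01 00:00:00"),
      discharge_ts = ts("2020-03-10 00:00:00")
    )
  }))
  codes <- c("J01DD04", "J01DH02", "J01XA01", "J02AC01", "A02BC01", NA)
  doses <- dplyr::bind_rows(lapply(1:200, function(i) {
    make_dose(sprintf("R%d", i),
      admission_id = sample(adm$admission_id, 1),
      timestamp = ts("2020-03-01 00:00:00") + runif(1, 0, 9 * 86400),
      atc_code = sample(codes, 1), amount = runif(1, 0.1, 4)
    )
  }))
  linked <- link_direct(adm, doses)
  days <- therapy_days(linked, REG)
  expect_equal(dot(days), oracle_dot(linked, REG))
  expect_equal(lot(days), oracle_lot(linked, REG))
})

test_that("administered DDD sums per-dose equivalents and reports omissions", {
  adm <- make_admission("A1",
    admit_ts = ts("2020-03-01 00:00:00"),
    discharge_ts = ts("2020-03-05 00:00:00")
  )
  doses <- dplyr::bind_rows(
    make_dose("R1", timestamp = ts("2020-03-01 08:00:00"), amount = 2),
    make_dose("R2", timestamp = ts("2020-03-02 08:00:00"), amount = 2),
    # co-trimoxazole: DOT yes, DDD undefined
    make_dose("R3", timestamp = ts("2020-03-01 09:00:00"),
      atc_code = "J01EE01", amount = 0.8
    )
  )
  res <- ddd_administered(link_direct(adm, doses), REG)
  expect_equal(res$total, 2) # 4 g ceftriaxone / 2 g DDD
  expect_equal(res$excluded_dot_share, 1 / 3) # 1 of 3 therapy days undefined
})

test_that("a regimen of only undefined-DDD drugs gives DDD 0 and share 1", {
  adm <- make_admission("A1")
  doses <- dplyr::bind_rows(
    make_dose("R1", atc_code = "J01EE01", amount = 0.8),
    make_dose("R2", atc_code = "J01EE01", amount = 0.8,
      timestamp = ts("2020-03-02 08:00:00")
    )
  )
  res <- ddd_administered(link_direct(adm, doses), REG)
  expect_equal(res$total, 0)
  expect_equal(res$excluded_dot_share, 1)
})

test_that("rates per 1000 patient-days follow the printed convention", {
  expect_equal(round_half_up(rate_per_1000_pd(14466, 11469)), 1261)
  expect_equal(round_half_up(rate_per_1000_pd(8322, 7068)), 1177)
  expect_equal(rate_per_1000_pd(0, 500), 0)
  expect_true(is.na(rate_per_1000_pd(10, 0)))
  # scale consistency
  expect_equal(
    rate_per_1000_pd(14466, 11469), rate_per_1000_pd(2 * 14466, 2 * 11469)
  )
})

test_that("derived ratios divide stratum totals and stay absent at zero", {
  r <- derived_ratios(
    dot = 15, lot = 10, n_admissions = 5, n_amu_admissions = 3
  )
  expect_equal(r$lot_per_admission, 2)
  expect_equal(r$lot_per_amu_admission, 10 / 3)
  expect_equal(r$dot_lot_ratio, 1.5)
  z <- derived_ratios(0, 0, 0, 0)
  expect_true(all(is.na(unlist(z))))
})

test_that("dose splitting changes neither DOT/LOT nor total DDD", {
  adm <- make_admission("A1")
  whole <- make_dose("R1", amount = 2,
    timestamp = ts("2020-03-01 08:00:00")
  )
  split2 <- dplyr::bind_rows(
    make_dose("R1a", amount = 1, timestamp = ts("2020-03-01 08:00:00")),
    make_dose("R1b", amount = 1, timestamp = ts("2020-03-01 20:00:00"))
  )
  d1 <- therapy_days(link_direct(adm, whole), REG)
  d2 <- therapy_days(link_direct(adm, split2), REG)
  expect_equal(dot(d1), dot(d2))
  expect_equal(lot(d1), lot(d2))
  expect_equal(
    ddd_administered(link_direct(adm, whole), REG)$total,
    ddd_administered(link_direct(adm, split2), REG)$total
  )
})

test_that("stratified totals conserve the grand total across partitions", {
  cfg <- small_config(n_patients = 120, seed = 3)
  sim <- generate_synthetic(cfg)
  adults <- filter_adults(sim$admissions)
  eps <- build_episodes(adults$kept)
  linked <- link_direct(eps$admissions, sim$administrations)
  am <- admission_metrics(eps$admissions, linked, REG)
  grand <- stratum_metrics(am)
  for (by in list("care_level", "referring_clinic", "sex", "age_band",
    c("care_level", "referring_clinic"))) {
    strat <- stratum_metrics(am, by)
    expect_equal(sum(strat$dot), grand$dot)
    expect_equal(sum(strat$lot), grand$lot)
    expect_equal(sum(strat$ddd_administered), grand$ddd_administered)
    expect_equal(sum(strat$patient_days), grand$patient_days)
    expect_equal(sum(strat$n_admissions), grand$n_admissions)
  }
  # class partition conserves DOT and DDD
  cc <- class_consumption(linked, REG, am, by = character())
  expect_equal(sum(cc$dot), grand$dot)
  expect_equal(sum(cc$ddd_administered), grand$ddd_administered)
  # DOT >= LOT everywhere
  expect_true(all(stratum_metrics(am, "care_level")$dot >=
    stratum_metrics(am, "care_level")$lot))
})
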