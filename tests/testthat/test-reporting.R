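test_that("half-up rounding matches printed-report conventions", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3) # base round() would give 2
  expect_equal(round_half_up(1261.31), 1261)
  expect_equal(round_half_up(41.28, 1), 41.3)
  expect_equal(round_half_up(-0.5), -1)
})

test_that("population table summarises admissions per care level", {
  adm <- dplyr::bind_rows(
    make_admission("A1", "P1", sex = "female", age_years = 70L,
      imv_hours = 50
    ),
    make_admission("A2", "P2", sex = "male", age_years = 60L),
    make_admission("A3", "P3", care_level = "secondary", sex = "female",
      age_years = 40L,
      admit_ts = ts("2020-03-01 00:00:00"),
      discharge_ts = ts("2020-03-01 12:00:00")
    )
  )
  tab <- population_table(adm)
  all_row <- tab[tab$stratum == "all", ]
  expect_equal(all_row$n_admissions, 3)
  expect_equal(all_row$pct_female, 2 / 3)
  expect_equal(all_row$median_age, 60)
  expect_equal(all_row$n_los_gt_48h, 2)
  expect_equal(all_row$n_imv, 1)
  tert <- tab[tab$stratum == "tertiary", ]
  expect_equal(tert$n_admissions, 2)
  expect_equal(tert$patient_days, 6)
  # degenerate single admission: medians equal the value
  single <- population_table(adm[3, ])
  expect_equal(single$median_age[single$stratum == "all"], 40)
})

test_that("clinic consumption equals stratum metrics and its CI honours variance", {
  # identical admissions -> zero-width interval
  adm <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_admission(sprintf("A%d", i), sprintf("P%d", i))
  }))
  doses <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_dose(sprintf("R%d", i), sprintf("A%d", i))
  }))
  eps <- build_episodes(adm)
  am <- admission_metrics(eps$admissions, link_direct(eps$admissions, doses),
    REG
  )
  cc <- clinic_consumption(am, n_boot = 200, seed = 4)
  expect_equal(cc$ci_low, cc$ci_high)
  expect_equal(cc$ci_low, cc$dot_rate)
  # consistency with the stratified metric table
  sm <- stratum_metrics(am, c("care_level", "referring_clinic"))
  expect_equal(cc$dot_rate, sm$dot_rate)
})

test_that("bootstrap interval approximates the exhaustive resample law", {
  # five admissions: all 5^5 resamples are enumerable
  adm <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_admission(sprintf("A%d", i), sprintf("P%d", i),
      discharge_ts = ts("2020-03-01 10:00:00") + i * 86400
    )
  }))
  doses <- dplyr::bind_rows(lapply(1:5, function(i) {
    # one therapy day each, so resampled rates 1000 * n / (sum of stays) vary
    make_dose(sprintf("R%d", i), sprintf("A%d", i),
      timestamp = ts("2020-03-01 12:00:00")
    )
  }))
  eps <- build_episodes(adm)
  am <- admission_metrics(eps$admissions, link_direct(eps$admissions, doses),
    REG
  )
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  rates <- apply(grid, 1, function(ix) {
    1000 * sum(am$dot[ix]) / sum(am$patient_days[ix])
  })
  exact <- quantile(rates, c(0.025, 0.975), names = FALSE)
  cc <- clinic_consumption(am, n_boot = 4000, seed = 10)
  spread <- diff(range(rates))
  expect_lt(abs(cc$ci_low - exact[1]), 0.1 * spread)
  expect_lt(abs(cc$ci_high - exact[2]), 0.1 * spread)
})

test_that("metric comparison flags dispensing divergence", {
  adm <- make_admission("A1",
    admit_ts = ts("2020-03-01 00:00:00"),
    discharge_ts = ts("2020-03-11 00:00:00")
  )
  doses <- dplyr::bind_rows(
    make_dose("R1", amount = 2), # ceftriaxone 1 DDD
    make_dose("R2", amount = 2, timestamp = ts("2020-03-02 08:00:00"))
  )
  linked <- link_direct(adm, doses)
  disp <- tibble::tibble(
    unit_id = "ICU_T1",
    period_start = as.Date("2020-01-01"), period_end = as.Date("2020-03-31"),
    atc_code = c("J01DD04", "J01CF02"),
    amount = c(4.4, 60), amount_unit = "g"
  )
  mc <- metric_comparison(linked, REG, patient_days(adm), dispensing = disp)
  ctx <- mc[mc$atc_code == "J01DD04", ]
  expect_equal(ctx$ddd_administered, 2)
  expect_equal(ctx$ddd_dispensed, 2.2)
  expect_false(ctx$divergence_flag) # ratio 1.1 under the 1.5 threshold
  # dispensed but never administered: flagged, infinite ratio
  clox <- mc[mc$atc_code == "J01CF02", ]
  expect_equal(clox$ddd_administered, 0)
  expect_true(clox$divergence_flag)
  # identical totals -> ratio exactly 1, no flag
  disp2 <- disp[1, ]
  disp2$amount <- 4
  mc2 <- metric_comparison(linked, REG, patient_days(adm), dispensing = disp2)
  expect_equal(mc2$dispensed_administered_ratio[mc2$atc_code == "J01DD04"], 1)
  expect_false(mc2$divergence_flag[mc2$atc_code == "J01DD04"])
})

test_that("quality summary reports the missing-ATC linkage share", {
  adm <- make_admission("A1",
    admit_ts = ts("2020-03-01 00:00:00"),
    discharge_ts = ts("2020-03-11 00:00:00")
  )
  doses <- dplyr::bind_rows(
    make_dose("R1"), # 1 DOT
    make_dose("R2", timestamp = ts("2020-03-02 08:00:00")), # 1 DOT
    make_dose("R3", atc_code = NA_character_,
      timestamp = ts("2020-03-05 08:00:00")
    ) # 1 missing-linkage day
  )
  linked <- link_direct(adm, doses)
  q <- quality_summary(
    empty_log <- tibble::tibble(
      row = integer(), severity = character(), code = character(),
      message = character()
    ),
    empty_log, empty_log, linked, REG
  )
  get <- function(k) q$value[q$indicator == k]
  expect_equal(get("doses_missing_atc"), 1)
  expect_equal(get("missing_atc_dot_permille"), 1000 * 1 / 3)
  expect_equal(get("undefined_ddd_dot_share"), 0)
})

test_that("report rendering is deterministic byte for byte", {
  cfg <- small_config(n_patients = 80, seed = 6)
  sim <- generate_synthetic(cfg)
  bundle <- build_report(sim$admissions, sim$administrations, REG,
    dispensing = sim$dispensing, n_boot = 100, seed = 2
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_report(bundle, d1)
  bundle2 <- build_report(sim$admissions, sim$administrations, REG,
    dispensing = sim$dispensing, n_boot = 100, seed = 2
  )
  p2 <- render_report(bundle2, d2)
  expect_equal(basename(p1), basename(p2))
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]), label = p1[i])
  }
  # outputs carry a provenance header
  expect_match(readLines(p1[1], n = 1), "^# amcsurv")
})

test_that("printed rates in rendered tables equal the metric module's rates", {
  cfg <- small_config(n_patients = 80, seed = 6)
  sim <- generate_synthetic(cfg)
  bundle <- build_report(sim$admissions, sim$administrations, REG,
    n_boot = 50, seed = 2
  )
  outdir <- withr::local_tempdir()
  render_report(bundle, outdir)
  printed <- readr::read_csv(file.path(outdir, "metrics.csv"),
    comment = "#", show_col_types = FALSE
  )
  expect_equal(
    printed$dot_rate,
    round_half_up(rate_per_1000_pd(
      bundle$metrics_by_level$dot, bundle$metrics_by_level$patient_days
    ))
  )
})
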