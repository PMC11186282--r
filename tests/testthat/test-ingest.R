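test_that("well-formed admission files read cleanly and typed", {
  adm <- dplyr::bind_rows(
    make_admission("A1"), make_admission("A2", patient_id = "P2"),
    make_admission("A3", patient_id = "P3", care_level = "secondary",
      unit_id = "ICU_S1"
    )
  )
  path <- write_admissions_csv(adm, withr::local_tempfile(fileext = ".csv"))
  res <- read_admissions(path)
  expect_equal(nrow(res$records), 3)
  expect_equal(nrow(res$issues), 0)
  expect_s3_class(res$records$admit_ts, "POSIXct")
  expect_type(res$records$died_in_icu, "logical")
})

test_that("invariant-violating admission rows are rejected, kept rows conserved", {
  adm <- dplyr::bind_rows(
    make_admission("A1"),
    make_admission("A2",
      admit_ts = ts("2020-03-05 10:00:00"),
      discharge_ts = ts("2020-03-04 10:00:00")
    ), # inverted
    make_admission("A3", saps3_emr = 1.7),
    make_admission("A4", care_level = "hospice")
  )
  path <- write_admissions_csv(adm, withr::local_tempfile(fileext = ".csv"))
  res <- read_admissions(path)
  expect_equal(nrow(res$records), 1)
  rejects <- res$issues[res$issues$severity == "reject", ]
  expect_equal(nrow(rejects), 3)
  expect_setequal(
    rejects$code, c("inverted_interval", "bad_emr", "bad_care_level")
  )
  # record conservation: every input row is either kept or rejected once
  expect_equal(nrow(res$records) + nrow(rejects), nrow(adm))
})

test_that("malformed timestamps reject exactly the bad rows", {
  adm <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_admission(sprintf("A%02d", i), patient_id = sprintf("P%02d", i))
  }))
  raw <- adm
  raw$admit_ts <- format(raw$admit_ts, "%Y-%m-%d %H:%M:%S")
  raw$discharge_ts <- format(raw$discharge_ts, "%Y-%m-%d %H:%M:%S")
  raw$admit_ts[3] <- "not-a-time"
  raw$discharge_ts[7] <- "2020-13-45 99:00:00"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path, na = "")
  res <- read_admissions(path)
  expect_equal(nrow(res$records), 8)
  expect_equal(sum(res$issues$severity == "reject"), 2)
  expect_true(all(res$issues$code[res$issues$severity == "reject"] ==
    "bad_timestamp"))
})

test_that("missing file and missing mandatory column are fatal", {
  expect_error(read_admissions("/nonexistent/x.csv"), "not found")
  bad <- tibble::tibble(admission_id = "A1", patient_id = "P1")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_error(read_admissions(path), "mandatory column")
})

test_that("administration reader keeps missing-ATC doses with a warning", {
  doses <- dplyr::bind_rows(
    make_dose("R1"),
    make_dose("R2", atc_code = NA_character_),
    make_dose("R3", amount = -5), # reject
    make_dose("R4", atc_code = "XYZ"), # malformed pattern -> reject
    make_dose("R5", atc_code = "J01XX99") # well-formed but unknown
  )
  path <- write_doses_csv(doses, withr::local_tempfile(fileext = ".csv"))
  res <- read_administrations(path, REG)
  expect_equal(nrow(res$records), 3)
  expect_equal(sum(res$issues$severity == "reject"), 2)
  warns <- res$issues[res$issues$severity == "warn", ]
  expect_setequal(warns$code, c("missing_atc", "unknown_atc"))
  expect_true("R2" %in% res$records$record_id)
})

test_that("reading back a canonical written file reproduces the records", {
  adm <- dplyr::bind_rows(
    make_admission("A1", saps3_emr = 0.123),
    make_admission("A2", patient_id = "P2", age_years = 81L, sex = "female")
  )
  p1 <- write_admissions_csv(adm, withr::local_tempfile(fileext = ".csv"))
  first <- read_admissions(p1)$records
  p2 <- write_admissions_csv(first, withr::local_tempfile(fileext = ".csv"))
  second <- read_admissions(p2)$records
  expect_equal(first, second)
})

test_that("linking clamps out-of-interval doses and rejects orphans", {
  adm <- make_admission("A1",
    admit_ts = ts("2020-03-01 10:00:00"),
    discharge_ts = ts("2020-03-03 10:00:00")
  )
  doses <- dplyr::bind_rows(
    make_dose("R1", timestamp = ts("2020-03-01 11:00:00")), # inside
    make_dose("R2", timestamp = ts("2020-03-03 10:30:00")), # 30 min late
    make_dose("R3", timestamp = ts("2020-03-05 10:00:00")), # far late
    make_dose("R4", admission_id = "GHOST")
  )
  res <- link_records(adm, doses, tolerance_hours = 1)
  expect_equal(nrow(res$records), 3)
  expect_equal(res$issues$code[res$issues$severity == "reject"], "orphan")
  r2 <- res$records[res$records$record_id == "R2", ]
  expect_equal(r2$timestamp, ts("2020-03-03 10:00:00"))
  expect_true("clamped" %in% res$issues$code)
  expect_true("clamped_far" %in% res$issues$code)
  # the in-interval dose generates no issue
  expect_false(any(grepl("R1", res$issues$message)))
  r3 <- res$records[res$records$record_id == "R3", ]
  expect_equal(r3$timestamp, ts("2020-03-03 10:00:00"))
})

test_that("dispensing reader validates periods and codes", {
  disp <- tibble::tibble(
    unit_id = c("ICU_T1", "ICU_T1", "ICU_S1"),
    period_start = c("2020-01-01", "2020-04-01", "2020-04-01"),
    period_end = c("2020-03-31", "2020-01-01", "2020-06-30"),
    atc_code = c("J01DD04", "J01DD04", "bad"),
    amount = c(1000, 500, 100),
    amount_unit = c("g", "g", "g")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(disp, path)
  res <- read_dispensing(path)
  expect_equal(nrow(res$records), 1)
  expect_setequal(
    res$issues$code[res$issues$severity == "reject"],
    c("bad_period", "bad_atc")
  )
})
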