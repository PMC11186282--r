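# Daily consumption series and cubic-spline trend over calendar time.
#
# The response is DOT per 1000 patient-days per calendar day, smoothed with
# an unpenalised cubic regression spline with 8 interior knots placed at
# empirical date quantiles, fitted by least squares with a Gaussian response
# on the rate scale (the scale on which the trend is displayed).  Knot count
# and placement are configurable.

#' Build the daily consumption series
#'
#' For each calendar date: DOT summed across units, fractional occupied
#' bed-days (each admission contributes its overlap with the date, in
#' hours / 24) and the daily DOT rate per 1000 patient-days (absent when no
#' patient-days that date).
#'
#' @param admissions admission records defining occupancy.
#' @param days therapy-day table from [therapy_days()].
#' @param date_range optional `Date` vector of length 2; defaults to the
#'   span of the admissions.
#' @param overlay_ids optional admission ids (e.g. a case-mix cohort such as
#'   pandemic admissions); `overlay_count` counts how many are present each
#'   date.
#' @return tibble with `date`, `dot`, `patient_days`, `dot_rate`,
#'   `overlay_count`.
#' @export
daily_series <- function(admissions, days, date_range = NULL,
                         overlay_ids = NULL) {
  if (is.null(date_range)) {
    date_range <- c(
      min(as.Date(admissions$admit_ts, tz = AMC_TZ)),
      max(as.Date(admissions$discharge_ts, tz = AMC_TZ))
    )
  }
  dates <- seq(date_range[1], date_range[2], by = "day")

  occupancy <- function(adm) {
    if (nrow(adm) == 0) {
      return(tibble::tibble(date = dates, pd = 0, n_present = 0L))
    }
    first <- as.Date(adm$admit_ts, tz = AMC_TZ)
    last <- as.Date(adm$discharge_ts - 1e-6, tz = AMC_TZ)
    ndays <- pmax(as.integer(last - first) + 1L, 1L)
    idx <- rep(seq_len(nrow(adm)), ndays)
    date <- first[idx] + (sequence(ndays) - 1L)
    day_start <- lubridate::force_tz(
      as.POSIXct(date, tz = AMC_TZ), AMC_TZ
    )
    hours <- as.numeric(
      pmin(adm$discharge_ts[idx], day_start + 86400) -
        pmax(adm$admit_ts[idx], day_start),
      units = "hours"
    )
    tibble::tibble(date = date, pd = hours / 24) |>
      dplyr::filter(.data$date >= date_range[1], .data$date <= date_range[2]) |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(
        pd = sum(.data$pd), n_present = dplyr::n(), .groups = "drop"
      )
  }

  occ <- occupancy(admissions)
  dot_daily <- days |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(dot = dplyr::n(), .groups = "drop")
  overlay <- if (is.null(overlay_ids)) {
    tibble::tibble(date = dates, overlay_count = 0L)
  } else {
    occ_o <- occupancy(
      admissions[admissions$admission_id %in% overlay_ids, , drop = FALSE]
    )
    tibble::tibble(date = occ_o$date, overlay_count = occ_o$n_present)
  }

  tibble::tibble(date = dates) |>
    dplyr::left_join(
      dplyr::select(occ, "date", patient_days = "pd"),
      by = "date"
    ) |>
    dplyr::left_join(dot_daily, by = "date") |>
    dplyr::left_join(overlay, by = "date") |>
    dplyr::mutate(
      patient_days = dplyr::coalesce(.data$patient_days, 0),
      dot = dplyr::coalesce(.data$dot, 0L),
      overlay_count = dplyr::coalesce(.data$overlay_count, 0L),
      dot_rate = rate_per_1000_pd(.data$dot, .data$patient_days)
    )
}

#' Fit a cubic-spline consumption trend
#'
#' Least-squares cubic regression spline of the daily DOT rate on calendar
#' time, with `n_knots` interior knots at empirical date quantiles and a
#' pointwise 95% confidence band from the fit covariance.  The fitted curve
#' is twice continuously differentiable between knots; because cubic
#' polynomials are nested in the basis, a cubic (or constant) generating
#' curve is recovered exactly up to noise.
#'
#' @param series daily series from [daily_series()].
#' @param n_knots number of interior knots (default 8).
#' @return object of class `amc_trend_fit`: list with `series` (input rows
#'   plus `fitted`, `ci_low`, `ci_high` where the rate is defined), `knots`
#'   (as dates), and `model` (the underlying `lm`).
#' @export
fit_trend <- function(series, n_knots = 8) {
  ok <- !is.na(series$dot_rate)
  if (sum(ok) < n_knots + 4) {
    stop(sprintf(
      "trend fit needs at least %d dates with a defined rate, got %d",
      n_knots + 4, sum(ok)
    ), call. = FALSE)
  }
  x <- as.numeric(series$date - min(series$date[ok]))
  dat <- data.frame(x = x[ok], y = series$dot_rate[ok])
  knots <- stats::quantile(
    dat$x,
    probs = seq_len(n_knots) / (n_knots + 1), names = FALSE
  )
  boundary <- range(dat$x)
  model <- stats::lm(
    y ~ splines::bs(x, knots = knots, degree = 3, Boundary.knots = boundary),
    data = dat
  )
  pred <- stats::predict(model, newdata = data.frame(x = x[ok]),
    se.fit = TRUE
  )
  out <- series
  out$fitted <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  out$fitted[ok] <- pred$fit
  out$ci_low[ok] <- pred$fit - 1.96 * pred$se.fit
  out$ci_high[ok] <- pred$fit + 1.96 * pred$se.fit
  structure(
    list(
      series = out,
      knots = min(series$date[ok]) + knots,
      model = model
    ),
    class = "amc_trend_fit"
  )
}

#' @export
print.amc_trend_fit <- function(x, ...) {
  ok <- !is.na(x$series$fitted)
  cat(sprintf(
    "Cubic-spline consumption trend: %d days fitted, %d interior knots\n",
    sum(ok), length(x$knots)
  ))
  cat(sprintf(
    "  fitted DOT/1000 pd range: %.0f to %.0f\n",
    min(x$series$fitted[ok]), max(x$series$fitted[ok])
  ))
  invisible(x)
}
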