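# Internal helpers shared across modules.

# All clinical timestamps are wall-clock local time; they are stored as UTC
# POSIXct so that calendar-day arithmetic never crosses a DST fold.
AMC_TZ <- "UTC"

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; surveillance reports round half
#' up, matching how printed rates and percentages are conventionally
#' tabulated.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Parse an ISO-8601 timestamp at minute or second precision
#'
#' @param x character vector.
#' @return POSIXct (UTC-naive wall-clock); `NA` where unparseable.
#' @keywords internal
#' @noRd
parse_ts <- function(x) {
  out <- lubridate::parse_date_time(
    x,
    orders = c("Ymd HMS", "Ymd HM", "Ymd"),
    tz = AMC_TZ, quiet = TRUE
  )
  out[is.na(x) | trimws(x) == ""] <- lubridate::NA_POSIXct_
  out
}

# An empty, schema-complete issue log.
empty_issues <- function() {
  tibble::tibble(
    row = integer(), severity = character(),
    code = character(), message = character()
  )
}

add_issues <- function(log, rows, severity, code, message) {
  if (length(rows) == 0) return(log)
  dplyr::bind_rows(log, tibble::tibble(
    row = as.integer(rows), severity = severity,
    code = code, message = message
  ))
}

#' Write a report CSV with a provenance header
#'
#' Output files carry a single `#`-prefixed provenance line (tool version and
#' a hash of the generating configuration) so that any exported table can be
#' traced back to the run that produced it.  Readers should skip lines
#' starting with `#`.
#'
#' @param x data frame.
#' @param path output file.
#' @param config_hash optional character scalar identifying the run.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path, config_hash = NULL) {
  header <- sprintf(
    "# amcsurv %s%s",
    as.character(utils::packageVersion("amcsurv")),
    if (is.null(config_hash)) "" else paste0(" config=", config_hash)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con,
    sep = ",", row.names = FALSE, qmethod = "double",
    na = ""
  )
  invisible(path)
}

# Deterministic short hash of a configuration-like object (no external
# digest dependency; a polynomial rolling hash over the deparsed object
# suffices for provenance labelling).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

format_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = AMC_TZ)
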