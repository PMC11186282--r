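# ATC/DDD registry: classification and defined-daily-dose reference.
#
# The bundled table is a curated subset of the WHO ATC/DDD index (2023
# values) covering the systemic antimicrobials in routine ICU use (J01, J02,
# plus rifampicin).  Registry membership defines the surveilled set: a code
# that does not resolve is either a non-antimicrobial or unknown and is
# ignored by the consumption metrics.  The file is user-replaceable; class
# labels sit at the ATC 4th level with explicit overrides (e.g. 2nd- vs
# 3rd-generation cephalosporins are split within J01D).

#' Load an ATC/DDD registry
#'
#' @param path TSV with columns `atc_code`, `substance_name`, `class_label`,
#'   `group`, `ddd_value`, `ddd_unit`, `ddd_route`; several rows per code are
#'   allowed for route-specific DDDs.  Default: the bundled curated table.
#' @return tibble of registry entries.  `ddd_value` may be `NA` for drugs
#'   without a defined DDD (e.g. sulfamethoxazole/trimethoprim); such drugs
#'   still count for DOT/LOT but are excluded from DDD sums.
#' @export
load_atc_registry <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "atc_registry.tsv", package = "amcsurv")
  reg <- readr::read_tsv(
    path,
    col_types = readr::cols(
      atc_code = readr::col_character(),
      substance_name = readr::col_character(),
      class_label = readr::col_character(),
      group = readr::col_character(),
      ddd_value = readr::col_double(),
      ddd_unit = readr::col_character(),
      ddd_route = readr::col_character()
    ),
    progress = FALSE
  )
  stopifnot(
    all(grepl(ATC_PATTERN, reg$atc_code)),
    all(reg$group %in% c("antibacterial", "antifungal")),
    all(is.na(reg$ddd_value) | reg$ddd_value > 0),
    all(is.na(reg$ddd_value) == is.na(reg$ddd_unit)),
    all(nzchar(reg$class_label))
  )
  reg
}

#' Look up an ATC code in the registry
#'
#' Returns the route-specific entry when the registry distinguishes routes,
#' otherwise any entry for the code.  Not-found is a value (`NULL`), not an
#' error: it signals a non-antimicrobial or unknown code.
#'
#' @param registry registry tibble from [load_atc_registry()].
#' @param atc_code 7-character ATC 5th-level code.
#' @param route administration route (`IV`, `PO`, `INH`, `other`).
#' @return one-row tibble, or `NULL` if the code is not surveilled.
#' @export
atc_lookup <- function(registry, atc_code, route = "IV") {
  hits <- registry[registry$atc_code == atc_code, , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  route_hit <- hits[!is.na(hits$ddd_route) & hits$ddd_route == route, ,
    drop = FALSE
  ]
  if (nrow(route_hit) > 0) return(route_hit[1, , drop = FALSE])
  hits[1, , drop = FALSE]
}

# Convert an amount between mass units; MU (million units) is a biological
# unit and never commensurable with mass.
convert_amount <- function(amount, from, to) {
  factor <- dplyr::case_when(
    from == to ~ 1,
    from == "g" & to == "mg" ~ 1000,
    from == "mg" & to == "g" ~ 0.001,
    TRUE ~ NA_real_
  )
  amount * factor
}

#' Convert administered amounts to DDD equivalents
#'
#' Vectorised over doses.  The amount is converted to the DDD unit and
#' divided by the route-specific DDD value.  The result is `NA` (undefined,
#' with a warning) when the drug has no defined DDD or when the amount unit
#' is incommensurable with the DDD unit (e.g. a dose recorded in mg against
#' an MU-denominated DDD, or vice versa) -- never a silent zero.
#'
#' @inheritParams atc_lookup
#' @param amount non-negative dose amounts.
#' @param amount_unit `mg`, `g` or `MU`, recycled with `amount`.
#' @param route recycled with `amount`.
#' @return numeric vector of DDD equivalents; `NA` where undefined.
#' @examples
#' reg <- load_atc_registry()
#' ddd_equivalents(reg, "J01DD04", 4, "g")  # ceftriaxone, DDD 2 g -> 2.0
#' @export
ddd_equivalents <- function(registry, atc_code, amount, amount_unit,
                            route = "IV") {
  n <- max(length(atc_code), length(amount))
  atc_code <- rep_len(atc_code, n)
  amount <- rep_len(amount, n)
  amount_unit <- rep_len(amount_unit, n)
  route <- rep_len(route, n)
  stopifnot(all(is.na(amount) | amount >= 0))

  out <- rep(NA_real_, n)
  incommensurable <- rep(FALSE, n)
  keys <- unique(data.frame(atc_code, route, stringsAsFactors = FALSE))
  for (k in seq_len(nrow(keys))) {
    entry <- atc_lookup(registry, keys$atc_code[k], keys$route[k])
    idx <- which(atc_code == keys$atc_code[k] & route == keys$route[k])
    if (is.null(entry) || is.na(entry$ddd_value)) next
    conv <- convert_amount(amount[idx], amount_unit[idx], entry$ddd_unit)
    out[idx] <- conv / entry$ddd_value
    incommensurable[idx] <- is.na(conv) & !is.na(amount[idx])
  }
  if (any(incommensurable)) {
    warning(
      sprintf(
        "%d dose(s) with amount units incommensurable with the DDD unit; ",
        sum(incommensurable)
      ),
      "DDD undefined for these, excluded from DDD sums", call. = FALSE
    )
  }
  out
}
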