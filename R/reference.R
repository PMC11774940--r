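#' Published summary table for the ten-city Indian study
#'
#' City-level summary estimates reported for the ten-city Indian
#' time-series study (2008-2019): mean (SD) PM2.5, attributable fraction,
#' attributable deaths and attributable deaths per year with 95% CIs, plus
#' a totals row. Shipped as a plain-text reference table; used for
#' arithmetic self-consistency checks (the city attributable-death column
#' must sum to the printed total) and as targets for the synthetic
#' generator's city exposure distributions.
#'
#' @return Data frame with one row per city and a `Total` row.
#' @export
reference_city_table <- function() {
  path <- system.file("extdata", "city_reference_table.csv",
                      package = "airmort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Study-level exceedance counts for the ten-city study
#'
#' Reported day counts across all cities: total study days and days on
#' which daily PM2.5 exceeded the 15 ug/m3 24-h guideline value.
#'
#' @return Named list: `days_total`, `days_above_guideline`,
#'   `exceedance_percent` (computed, one decimal).
#' @export
reference_exceedance <- function() {
  days_total <- 27146L
  days_above <- 27091L
  list(days_total = days_total, days_above_guideline = days_above,
       exceedance_percent = round(100 * days_above / days_total, 1))
}
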