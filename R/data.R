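#' Published thermal summaries for ten Dictyota species
#'
#' Per-species geographic range and sea-surface-temperature summaries
#' reported for ten molecularly delimited Dictyota (brown algae) lineages:
#' record count, latitudinal and longitudinal range (degrees), means over
#' records of the per-record maximum/mean/minimum SST (deg C), and the
#' maximum thermal tolerance range (largest per-record maximum SST minus
#' smallest per-record minimum SST). Useful as a real-data check of the
#' tolerance-vs-range regression: the longitudinal regression on these ten
#' rows gives an R-squared of about 0.83.
#'
#' @return a `species_thermal_summary` data.frame with columns `species`,
#'   `n`, `lat_range`, `lon_range`, `max_C`, `mean_C`, `min_C`,
#'   `max_range_C`.
#' @export
dictyota_thermal_summary <- function() {
  path <- system.file("extdata", "dictyota_thermal_summary.csv",
                      package = "delimtherm", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("species_thermal_summary", class(df))
  df
}
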