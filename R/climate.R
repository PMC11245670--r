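#' Minimum relative humidity from dewpoint and maximum temperature
#'
#' Magnus-form saturation vapour pressure ratio: the day's minimum relative
#' humidity is approximated from the dewpoint temperature paired with the
#' daily maximum air temperature.
#'
#' @param dewpoint Dewpoint temperature, degrees Celsius.
#' @param t_max Daily maximum air temperature, degrees Celsius.
#' @return Relative humidity in percent. Physically inconsistent records
#'   (dewpoint above the maximum temperature) are clamped to 100 and counted
#'   in the `"clamped"` attribute.
#' @export
rh_from_dewpoint <- function(dewpoint, t_max) {
  rh <- 100 * exp(17.625 * dewpoint / (243.04 + dewpoint)) /
    exp(17.625 * t_max / (243.04 + t_max))
  bad <- !is.na(rh) & rh > 100
  rh[bad] <- 100
  structure(rh, clamped = sum(bad))
}

#' Maximum temperature-humidity index
#'
#' THI_max combines the daily maximum temperature with the minimum relative
#' humidity; the humidity term vanishes at 14.4 C.
#'
#' @param t_max Daily maximum temperature, degrees Celsius.
#' @param rh_min Minimum relative humidity, percent (0-100).
#' @return THI_max in index points.
#' @export
thi_max <- function(t_max, rh_min) {
  stopifnot(all(rh_min >= 0 & rh_min <= 100, na.rm = TRUE))
  0.8 * t_max + (rh_min / 100) * (t_max - 14.4) + 46.4
}

#' Derive RH and THI columns for a daily weather table
#'
#' @param weather Data frame with columns `station_id`, `date`, `t_max`,
#'   `dewpoint`.
#' @return The input with `rh_min` and `thi_max` columns appended.
#' @export
add_thi <- function(weather) {
  rh <- rh_from_dewpoint(weather$dewpoint, weather$t_max)
  weather$rh_min <- as.numeric(rh)
  weather$thi_max <- thi_max(weather$t_max, weather$rh_min)
  weather
}

#' Station-year quality control on observation completeness
#'
#' A station-year is complete when the fraction of calendar days with an
#' observation is at least 90%; the rule is a strict "more than 10% missing"
#' exclusion, so exactly 10% missing is retained.
#'
#' @param weather Daily weather table (`station_id`, `date`).
#' @param mode `"multi"` drops failing station-years; `"single"` keeps every
#'   station-year but flags failures (research-herd variant, where the lone
#'   matched station is retained even with a gappy year).
#' @return Tibble with one row per station-year: `station_id`, `year`,
#'   `days_present`, `days_in_year`, `completeness`, `retained`, `flagged`.
#' @export
qc_stations <- function(weather, mode = c("multi", "single")) {
  mode <- match.arg(mode)
  yr <- as.integer(format(weather$date, "%Y"))
  tab <- dplyr::summarise(
    dplyr::group_by(dplyr::tibble(station_id = weather$station_id, year = yr,
                                  date = weather$date),
                    .data$station_id, .data$year),
    days_present = dplyr::n_distinct(.data$date), .groups = "drop")
  tab$days_in_year <- ifelse(is_leap_year(tab$year), 366L, 365L)
  tab$completeness <- tab$days_present / tab$days_in_year
  fails <- (1 - tab$completeness) > 0.10
  tab$retained <- if (mode == "multi") !fails else TRUE
  tab$flagged <- fails
  tab
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Match each farm to its nearest weather station
#'
#' Great-circle (haversine) distance on a spherical Earth between farm point
#' locations and station coordinates.
#'
#' @param farms Data frame with `farm_id`, `lat`, `lon`.
#' @param stations Data frame with `station_id`, `lat`, `lon`; typically the
#'   stations passing [qc_stations()] in at least one year.
#' @return Tibble `farm_id`, `station_id`, `distance_km`.
#' @export
match_nearest_station <- function(farms, stations) {
  if (nrow(stations) == 0) stop("no weather stations available for matching")
  d <- geosphere::distm(cbind(farms$lon, farms$lat),
                        cbind(stations$lon, stations$lat),
                        fun = geosphere::distHaversine)
  idx <- apply(d, 1, which.min)
  dplyr::tibble(farm_id = farms$farm_id,
                station_id = stations$station_id[idx],
                distance_km = d[cbind(seq_len(nrow(farms)), idx)] / 1000)
}

#' Mean THI_max over a closed date interval
#'
#' Missing days are simply absent from the mean; a window with no available
#' days yields `NA`.
#'
#' @param weather Daily weather table of one station with `date` and
#'   `thi_max` columns.
#' @param start,end Closed interval bounds (Dates).
#' @return Mean THI_max in index points, or `NA` if no days are available.
#' @export
mean_thi <- function(weather, start, end) {
  if (end < start) stop("empty date range")
  v <- weather$thi_max[weather$date >= start & weather$date <= end]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}
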