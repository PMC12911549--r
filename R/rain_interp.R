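#' Read a station table
#'
#' CSV with header columns `station_id`, `lat`, `lon`.
#'
#' @param path File path.
#' @return data.frame with unique, validated stations.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("station_id", "lat", "lon"), "station file")
  validate_stations(df)
}

validate_stations <- function(stations) {
  check_columns(stations, c("station_id", "lat", "lon"), "stations")
  if (anyDuplicated(stations$station_id))
    stopf("stations: duplicate station_id",
          class = "stormcohort_validation_error")
  check_latlon(stations$lat, stations$lon, "stations")
  stations
}

#' Read daily station precipitation
#'
#' CSV with header columns `station_id`, `date` (ISO-8601), `precip_mm`.
#' GHCN-Daily distributes precipitation in tenths of millimetres; set
#' `ghcn_tenths = TRUE` to divide by 10 at read time. Missing observations
#' are empty/NA cells, never zero.
#'
#' @param path File path.
#' @param ghcn_tenths Logical; input is in tenths of mm (GHCN-Daily
#'   convention).
#' @return data.frame `station_id`, `date` (Date), `precip_mm` (mm, NA =
#'   missing).
#' @export
read_daily_rain <- function(path, ghcn_tenths = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("station_id", "date", "precip_mm"), "daily rain file")
  df$date <- as.Date(df$date)
  df$precip_mm <- as.numeric(df$precip_mm)
  if (ghcn_tenths) df$precip_mm <- df$precip_mm / 10
  validate_daily_rain(df)
}

validate_daily_rain <- function(daily_rain) {
  check_columns(daily_rain, c("station_id", "date", "precip_mm"),
                "daily rain")
  if (!inherits(daily_rain$date, "Date"))
    daily_rain$date <- as.Date(daily_rain$date)
  if (any(daily_rain$precip_mm < 0, na.rm = TRUE))
    stopf("daily rain: negative precipitation",
          class = "stormcohort_validation_error")
  if (anyDuplicated(daily_rain[c("station_id", "date")]))
    stopf("daily rain: more than one record per station-date",
          class = "stormcohort_validation_error")
  daily_rain
}

#' Inverse-distance-weighted rainfall at a point
#'
#' Estimates one day's precipitation at an area centroid from surrounding
#' station observations: `sum(w_i r_i) / sum(w_i)` with `w_i = d_i^-power`
#' over stations within the search radius that report a value that day.
#' Stations with missing values are excluded from the weights (GHCN
#' missingness is not zero rain). If a reporting station lies within 1 m of
#' the centroid its value is returned directly (the weight would be
#' numerically infinite). If fewer than `min_stations` reporting stations
#' fall inside the radius, the radius doubles until the quorum is met, up to
#' `max_radius_km`; at the cap any in-radius stations are used, and only a
#' day with no reporting station within the cap is an error.
#'
#' @param lat,lon Centroid coordinates, decimal degrees.
#' @param date Day (Date or ISO string).
#' @param stations Station table (`station_id`, `lat`, `lon`).
#' @param daily_rain Daily precipitation table (`station_id`, `date`,
#'   `precip_mm`).
#' @param power IDW exponent (> 0); default 2.
#' @param radius_km Initial search radius; default 150 km.
#' @param min_stations Station quorum before the radius stops growing;
#'   default 3.
#' @param max_radius_km Hard cap on the search radius; default 600 km.
#' @return Estimated precipitation in mm (scalar).
#' @export
idw_estimate <- function(lat, lon, date, stations, daily_rain,
                         power = 2, radius_km = 150, min_stations = 3,
                         max_radius_km = 600) {
  if (!is.numeric(power) || power <= 0)
    stopf("idw_estimate: power must be positive",
          class = "stormcohort_validation_error")
  stations <- validate_stations(stations)
  date <- as.Date(date)
  day <- daily_rain[daily_rain$date == date & !is.na(daily_rain$precip_mm), ]
  if (nrow(day) == 0)
    stopf("idw_estimate: no station reports a value on %s", format(date),
          class = "stormcohort_missing_data_error")
  obs <- merge(day, stations, by = "station_id")
  d <- haversine_km(lat, lon, obs$lat, obs$lon)
  if (any(d < 0.001))  # within 1 m: take the co-located gauge directly
    return(obs$precip_mm[which.min(d)])
  r <- radius_km
  repeat {
    sel <- d <= r
    if (sum(sel) >= min_stations || r >= max_radius_km) break
    r <- min(2 * r, max_radius_km)
  }
  if (!any(sel))
    stopf("idw_estimate: no reporting station within %g km on %s",
          max_radius_km, format(date),
          class = "stormcohort_missing_data_error")
  w <- d[sel]^(-power)
  sum(w * obs$precip_mm[sel]) / sum(w)
}

#' Daily rainfall series at area centroids
#'
#' Applies [idw_estimate()] to every area-date combination, producing the
#' long-format centroid rainfall table consumed by the exposure stage.
#'
#' @param areas data.frame `area_id`, `lat`, `lon`.
#' @param stations,daily_rain As in [idw_estimate()].
#' @param dates Days to estimate; default all dates present in `daily_rain`.
#' @param ... Passed to [idw_estimate()] (power, radii, quorum).
#' @return data.frame `area_id`, `date`, `precip_mm_est`.
#' @export
centroid_rain_series <- function(areas, stations, daily_rain, dates = NULL,
                                 ...) {
  check_columns(areas, c("area_id", "lat", "lon"), "areas")
  daily_rain <- validate_daily_rain(daily_rain)
  if (is.null(dates)) dates <- sort(unique(daily_rain$date))
  dates <- as.Date(dates)
  grid <- expand.grid(ai = seq_len(nrow(areas)), date = dates)
  est <- mapply(function(ai, dt) {
    idw_estimate(areas$lat[ai], areas$lon[ai], dt, stations, daily_rain, ...)
  }, grid$ai, grid$date)
  out <- data.frame(
    area_id = areas$area_id[grid$ai],
    date = as.Date(grid$date),
    precip_mm_est = as.numeric(est)
  )
  out[order(out$area_id, out$date), , drop = FALSE]
}

#' Cumulative rainfall over the approach-anchored window
#'
#' Sums the estimated daily rainfall over the four calendar days from two
#' days before to one day after the closest approach of the storm centre
#' (`D-2, D-1, D, D+1`). Every window day must be present in the series;
#' absent days raise an error naming the missing dates rather than silently
#' truncating the accumulation.
#'
#' @param series One area's rainfall series (`date`, `precip_mm_est`), e.g.
#'   one `area_id` slice of [centroid_rain_series()].
#' @param approach_date Anchor day `D` (Date or ISO string).
#' @param days_before,days_after Window extent in days (defaults 2 and 1).
#' @return Cumulative rainfall in mm (scalar).
#' @export
window_rain <- function(series, approach_date, days_before = 2,
                        days_after = 1) {
  check_columns(series, c("date", "precip_mm_est"), "rain series")
  approach_date <- as.Date(approach_date)
  wanted <- seq(approach_date - days_before, approach_date + days_after,
                by = "day")
  idx <- match(wanted, as.Date(series$date))
  if (anyNA(idx) || anyNA(series$precip_mm_est[idx]))
    stopf("window_rain: no rainfall estimate for date(s) %s",
          paste(format(wanted[is.na(idx) | is.na(series$precip_mm_est[idx])]),
                collapse = ", "),
          class = "stormcohort_missing_data_error")
  sum(series$precip_mm_est[idx])
}
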