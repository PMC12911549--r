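#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over points; the two inputs are recycled to a common
#' length.
#'
#' @param lat1,lon1 Numeric, decimal degrees (WGS84) of the first point(s).
#' @param lat2,lon2 Numeric, decimal degrees of the second point(s).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(29.7, -95.4, 29.7, -95.4)  # 0
#' haversine_km(0, 0, 0, 1)                # one degree of longitude at the
#'                                         # equator, 2*pi*R/360 = 111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1, "haversine_km point a")
  check_latlon(lat2, lon2, "haversine_km point b")
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371.0088))
}

#' Construct a storm best track
#'
#' @param timestamp Timestamps (POSIXct or ISO-8601 strings), interpreted as
#'   UTC; must be strictly increasing.
#' @param lat,lon Storm-centre coordinates in decimal degrees. Longitudes are
#'   kept in \[-180, 180\]; tracks crossing the antimeridian are rejected
#'   (the package targets Gulf-of-Mexico-scale storms).
#' @return A `storm_track`: a data.frame with columns `timestamp`, `lat`,
#'   `lon`.
#' @export
storm_track <- function(timestamp, lat, lon) {
  timestamp <- as_utc(timestamp)
  check_latlon(lat, lon, "storm_track")
  if (length(timestamp) != length(lat))
    stopf("storm_track: timestamp and coordinates differ in length",
          class = "stormcohort_validation_error")
  if (length(timestamp) >= 2 && any(diff(as.numeric(timestamp)) <= 0))
    stopf("storm_track: timestamps must be strictly increasing",
          class = "stormcohort_validation_error")
  if (length(lon) >= 2 && any(abs(diff(lon)) > 180))
    stopf("storm_track: track appears to cross the antimeridian; not supported",
          class = "stormcohort_validation_error")
  structure(
    data.frame(timestamp = timestamp, lat = lat, lon = lon),
    class = c("storm_track", "data.frame")
  )
}

#' Read a storm best track from file
#'
#' Two dialects are supported. `"csv"` expects a header with columns
#' `timestamp` (ISO-8601, UTC), `lat`, `lon`. `"hurdat2"` expects the
#' HURDAT2 data rows (no storm header line): comma-separated
#' `YYYYMMDD, HHMM, record-id, status, latitude` with `N`/`S` suffix,
#' `longitude` with `E`/`W` suffix, further fields ignored.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"hurdat2"`.
#' @return A [storm_track()].
#' @export
read_track <- function(path, format = c("csv", "hurdat2")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    check_columns(df, c("timestamp", "lat", "lon"), "track file")
    return(storm_track(df$timestamp, df$lat, df$lon))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  bad <- vapply(parts, length, 1L) < 6L
  if (any(bad))
    stopf("hurdat2 track: %d line(s) with fewer than 6 fields", sum(bad),
          class = "stormcohort_validation_error")
  fld <- function(i) trimws(vapply(parts, `[[`, "", i))
  ts <- as.POSIXct(paste(fld(1), fld(2)), format = "%Y%m%d %H%M", tz = "UTC")
  lat_raw <- fld(5)
  lon_raw <- fld(6)
  hem <- function(x, pos, neg) {
    suf <- toupper(substring(x, nchar(x)))
    val <- as.numeric(substring(x, 1, nchar(x) - 1))
    if (any(!suf %in% c(pos, neg)) || anyNA(val))
      stopf("hurdat2 track: malformed coordinate field",
            class = "stormcohort_validation_error")
    ifelse(suf == neg, -val, val)
  }
  storm_track(ts, hem(lat_raw, "N", "S"), hem(lon_raw, "E", "W"))
}

#' Densify a storm track to a fixed time step
#'
#' Piecewise-linear interpolation of latitude and longitude against time.
#' Best tracks are 6-hourly; hurricane-exposure work conventionally refines
#' them to 15-minute resolution before computing closest approaches, so that
#' the discretisation error in approach distance and timing is negligible at
#' small-area scale.
#'
#' The output has `floor(span / step) + 1` points starting at the first fix;
#' when the track span is a multiple of the step (always the case for
#' 6-hourly fixes at the 15-minute default) the final point coincides with
#' the last source fix.
#'
#' @param track A [storm_track()] with at least 2 fixes.
#' @param step_minutes Output resolution in minutes (default 15).
#' @return An `interpolated_track` (a `storm_track` subclass) with attributes
#'   `step_minutes` and `source_fixes`.
#' @export
interpolate_track <- function(track, step_minutes = 15) {
  if (!inherits(track, "storm_track"))
    track <- storm_track(track$timestamp, track$lat, track$lon)
  if (nrow(track) < 2)
    stopf("interpolate_track: need at least 2 fixes",
          class = "stormcohort_validation_error")
  if (!is.numeric(step_minutes) || step_minutes <= 0)
    stopf("interpolate_track: step_minutes must be positive",
          class = "stormcohort_validation_error")
  t0 <- as.numeric(track$timestamp)
  span <- t0[length(t0)] - t0[1]
  step <- step_minutes * 60
  tout <- t0[1] + step * seq.int(0, floor(span / step))
  out <- storm_track(
    as.POSIXct(tout, origin = "1970-01-01", tz = "UTC"),
    stats::approx(t0, track$lat, xout = tout)$y,
    stats::approx(t0, track$lon, xout = tout)$y
  )
  structure(out,
            class = c("interpolated_track", class(out)),
            step_minutes = step_minutes,
            source_fixes = nrow(track))
}

#' Closest approach of a storm track to a point
#'
#' Scans the interpolated track for the fix nearest the area centroid
#' (haversine distance); ties are broken by the earliest timestamp. The
#' approach date — the anchor for the cumulative-rain window — is the
#' calendar day of the approach time under a fixed UTC-offset convention
#' (default UTC-6, local standard time for the Texas/Louisiana study
#' region).
#'
#' @param itrack An [interpolate_track()] result (any nonempty
#'   `storm_track` is accepted).
#' @param lat,lon Centroid coordinates, decimal degrees.
#' @param area_id Identifier copied into the output.
#' @param tz_offset_hours Offset applied before taking the calendar date.
#' @return One-row data.frame: `area_id`, `distance_km`, `approach_time`
#'   (POSIXct UTC), `approach_date` (Date).
#' @export
closest_approach <- function(itrack, lat, lon, area_id,
                             tz_offset_hours = -6) {
  if (is.null(itrack) || nrow(itrack) == 0)
    stopf("closest_approach: empty track",
          class = "stormcohort_validation_error")
  check_latlon(lat, lon, "closest_approach centroid")
  d <- haversine_km(lat, lon, itrack$lat, itrack$lon)
  i <- which.min(d)  # which.min returns the first (earliest) minimiser
  data.frame(
    area_id = area_id,
    distance_km = d[i],
    approach_time = itrack$timestamp[i],
    approach_date = local_date(itrack$timestamp[i], tz_offset_hours)
  )
}

#' Closest-approach table for a set of area centroids
#'
#' @param itrack Interpolated storm track.
#' @param areas data.frame with columns `area_id`, `lat`, `lon`.
#' @inheritParams closest_approach
#' @return data.frame with one row per area (see [closest_approach()]).
#' @export
closest_approach_table <- function(itrack, areas, tz_offset_hours = -6) {
  check_columns(areas, c("area_id", "lat", "lon"), "areas")
  out <- do.call(rbind, lapply(seq_len(nrow(areas)), function(i) {
    closest_approach(itrack, areas$lat[i], areas$lon[i], areas$area_id[i],
                     tz_offset_hours)
  }))
  rownames(out) <- NULL
  out
}
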