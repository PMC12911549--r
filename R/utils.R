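#' @keywords internal
"_PACKAGE"

## Internal validation helpers shared across modules.

stopf <- function(fmt, ..., class = "stormcohort_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_latlon <- function(lat, lon, what = "coordinate") {
  if (!is.numeric(lat) || !is.numeric(lon) || length(lat) != length(lon))
    stopf("%s: lat and lon must be numeric vectors of equal length", what,
          class = "stormcohort_validation_error")
  if (anyNA(lat) || anyNA(lon))
    stopf("%s: missing lat/lon values", what,
          class = "stormcohort_validation_error")
  if (any(lat < -90 | lat > 90))
    stopf("%s: latitude outside [-90, 90]", what,
          class = "stormcohort_validation_error")
  if (any(lon < -180 | lon > 180))
    stopf("%s: longitude outside [-180, 180]", what,
          class = "stormcohort_validation_error")
  invisible(TRUE)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", what,
          paste(miss, collapse = ", "),
          class = "stormcohort_validation_error")
  invisible(TRUE)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x))  # ISO-8601 "T" separator / "Z" suffix
    x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(x, tz = "UTC")
  if (anyNA(out))
    stopf("unparseable timestamp(s): %s",
          paste(utils::head(x[is.na(out)], 3), collapse = ", "),
          class = "stormcohort_validation_error")
  out
}

## Calendar date of a UTC instant under a fixed utc-offset convention.
## Daily rain gauges report local days; the study region sits at UTC-6
## (central standard time), the package default everywhere a timestamp
## must be collapsed to a day.
local_date <- function(time_utc, tz_offset_hours = -6) {
  as.Date(as_utc(time_utc) + tz_offset_hours * 3600, tz = "UTC")
}
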