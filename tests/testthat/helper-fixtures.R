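# Shared fixtures and independent mini-oracles, built in code.

# Independent haversine (explicit formula), kept separate from the package
# implementation so geometry tests are a genuine dual route.
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# Straight west-to-east track along latitude 30: 2017-08-25 00:00 UTC to
# 2017-08-29 00:00 UTC (4 days), fixes every 24 h, lon -97 .. -89.
fixture_track <- function() {
  storm_track(
    as.POSIXct("2017-08-25 00:00:00", tz = "UTC") + 86400 * 0:4,
    lat = rep(30, 5),
    lon = seq(-97, -89, length.out = 5)
  )
}

# Three areas under the straight track, four stations with constant known
# daily rain. Station S4 is far enough to fall outside the default search
# radius of the nearer areas.
fixture_areas <- function() {
  data.frame(area_id = c("Z1", "Z2", "Z3"),
             lat = c(30.0, 30.0, 29.0),
             lon = c(-95.0, -92.0, -95.0))
}

fixture_stations <- function() {
  data.frame(station_id = c("S1", "S2", "S3", "S4"),
             lat = c(30.5, 29.5, 30.0, 29.0),
             lon = c(-95.0, -95.0, -96.0, -92.0))
}

# Constant rain per station per day over the whole fixture period.
fixture_daily_rain <- function(mm = c(S1 = 30, S2 = 20, S3 = 60, S4 = 5)) {
  dates <- seq(as.Date("2017-08-22"), as.Date("2017-09-01"), by = "day")
  expand_station <- function(id) data.frame(
    station_id = id, date = dates, precip_mm = mm[[id]])
  do.call(rbind, lapply(names(mm), expand_station))
}

# A small hand-specifiable survival dataset as build_cohort-style data.
make_surv_df <- function(time, event, x = NULL) {
  df <- data.frame(time_days = time, event = as.logical(event))
  if (!is.null(x)) df$x <- x
  df
}

# Small analytic-cohort-like data frame for model tests.
make_cohort_df <- function(n, p_exposed = 0.5, rate = 0.1, seed = 1,
                           n_areas = 10) {
  set.seed(seed)
  exposed <- stats::rbinom(n, 1, p_exposed) == 1
  t <- stats::rexp(n, -log(1 - rate) / 365)
  data.frame(
    beneficiary_id = sprintf("B%05d", seq_len(n)),
    area_id = sample(sprintf("A%02d", seq_len(n_areas)), n, replace = TRUE),
    exposed = exposed,
    time_days = pmin(t, 365),
    event = t <= 365
  )
}

# Independent brute-force Breslow log partial likelihood for one covariate.
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_breslow_coef <- function(time, event, x) {
  stats::optimize(function(b) oracle_breslow_loglik(b, time, event, x),
                  c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}

# Independent log-rank statistic: loop over distinct event times with
# hypergeometric expectations and variances.
oracle_logrank <- function(time, event, group) {
  tt <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Independent Moran's I by explicit double loop.
oracle_morans_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}
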