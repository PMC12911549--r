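#' Simulation configuration
#'
#' Defaults emulate the structure of a Gulf-coast Medicare cohort struck by
#' an extreme-rainfall hurricane: cohort marginals follow the published
#' order of magnitude for such populations (mean age 75.8 y, SD 7.3; 56.3%
#' female; 7.7% dual-eligible; ADRD 12.5%, CHF 17.2%, COPD 13.9%, DM 30.8%,
#' CKD 27.4%; 2.7% relocating during follow-up), the storm crosses the
#' region over 7 days with 6-hourly fixes, and one-year baseline mortality
#' at the covariate reference is 4%. These are emulation targets for the
#' generator, not reproductions of any restricted dataset.
#'
#' The mortality process is proportional-hazards by construction: subject
#' hazard `lambda_0 * exp(beta_E * exposed + beta' x + b_area)` with a
#' constant (exponential) baseline over the year, area effects
#' `b_area ~ Normal(0, frailty_sd^2)` — i.e. log-normal shared frailty —
#' and administrative censoring at 365 days.
#'
#' @param seed Integer seed; the whole generator is a deterministic function
#'   of `(config, seed)`.
#' @param n_areas,n_stations,n_beneficiaries Problem sizes.
#' @param region Named numeric: `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param storm Named list: `start_lat`, `start_lon`, `end_lat`, `end_lon`,
#'   `duration_days`, `fix_hours`, `bow_deg` (lateral curvature of the
#'   track), `landfall_date`.
#' @param rain Named list: `peak_mm_per_day`, `decay_scale_km`,
#'   `background_mm`, `noise_dispersion` (coefficient of variation of the
#'   multiplicative gamma noise; 0 = deterministic), `pad_days` (rain-record
#'   days generated before/after the track span so approach windows are
#'   always covered).
#' @param cohort Named list of marginals: `age_mean`, `age_sd` (truncated at
#'   65), `female_p`, `race_p` (named probabilities: nh_white, nh_black,
#'   hispanic, other), `dual_p`, `condition_p` (named: adrd, chf, copd, dm,
#'   ckd), `extra_comorbidity_mean` (Poisson count of further chronic
#'   conditions beyond the five flags), `relocate_p`, `rurality_p` (named:
#'   metro, micro, rural).
#' @param survival Named list: `baseline_mortality` (one-year probability at
#'   the covariate reference), `true_log_hr_exposure`, `log_hr` (named
#'   covariate log-hazard-ratios: age_per_year, male, nh_black, hispanic,
#'   other, dual, comorbidity, micro, rural), `frailty_sd`, and optionally
#'   `interaction_log_hr` (named by condition flag, e.g. `c(adrd = 0.26)`:
#'   additional exposure log-HR for members of that flag, for studying
#'   subgroup-specific effects; default none).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_areas = 120L,
                       n_stations = 60L,
                       n_beneficiaries = 20000L,
                       region = c(lon_min = -97, lon_max = -89.5,
                                  lat_min = 27, lat_max = 33),
                       storm = list(start_lat = 25.0, start_lon = -96.5,
                                    end_lat = 33.5, end_lon = -89.0,
                                    duration_days = 7, fix_hours = 6,
                                    bow_deg = 1.5,
                                    landfall_date = "2017-08-25"),
                       rain = list(peak_mm_per_day = 120,
                                   decay_scale_km = 80,
                                   background_mm = 2,
                                   noise_dispersion = 0.3,
                                   pad_days = 3),
                       cohort = list(age_mean = 75.8, age_sd = 7.3,
                                     female_p = 0.563,
                                     race_p = c(nh_white = 0.744,
                                                nh_black = 0.093,
                                                hispanic = 0.128,
                                                other = 0.035),
                                     dual_p = 0.077,
                                     condition_p = c(adrd = 0.125,
                                                     chf = 0.172,
                                                     copd = 0.139,
                                                     dm = 0.308,
                                                     ckd = 0.274),
                                     extra_comorbidity_mean = 2.0,
                                     relocate_p = 0.027,
                                     rurality_p = c(metro = 0.778,
                                                    micro = 0.119,
                                                    rural = 0.103)),
                       survival = list(baseline_mortality = 0.04,
                                       true_log_hr_exposure = log(1.05),
                                       log_hr = c(age_per_year = 0.085,
                                                  male = 0.35,
                                                  nh_black = 0.10,
                                                  hispanic = 0.00,
                                                  other = 0.00,
                                                  dual = 0.30,
                                                  comorbidity = 0.12,
                                                  micro = 0.05,
                                                  rural = 0.08),
                                       frailty_sd = 0.1)) {
  cfg <- list(seed = as.integer(seed), n_areas = as.integer(n_areas),
              n_stations = as.integer(n_stations),
              n_beneficiaries = as.integer(n_beneficiaries),
              region = region, storm = storm, rain = rain,
              cohort = cohort, survival = survival)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_areas < 1 || cfg$n_stations < 1 || cfg$n_beneficiaries < 1)
    stopf("sim_config: n_areas, n_stations, n_beneficiaries must be positive",
          class = "stormcohort_validation_error")
  probs <- c(cfg$cohort$female_p, cfg$cohort$race_p, cfg$cohort$dual_p,
             cfg$cohort$condition_p, cfg$cohort$relocate_p,
             cfg$cohort$rurality_p, cfg$survival$baseline_mortality)
  if (any(probs < 0 | probs > 1))
    stopf("sim_config: probabilities must lie in [0, 1]",
          class = "stormcohort_validation_error")
  if (abs(sum(cfg$cohort$race_p) - 1) > 1e-8 ||
      abs(sum(cfg$cohort$rurality_p) - 1) > 1e-8)
    stopf("sim_config: race_p and rurality_p must each sum to 1",
          class = "stormcohort_validation_error")
  if (cfg$survival$frailty_sd < 0)
    stopf("sim_config: frailty_sd must be nonnegative",
          class = "stormcohort_validation_error")
  if (cfg$storm$duration_days <= 0 || cfg$storm$fix_hours <= 0)
    stopf("sim_config: degenerate storm geometry",
          class = "stormcohort_validation_error")
  if (cfg$rain$noise_dispersion < 0)
    stopf("sim_config: noise_dispersion must be nonnegative",
          class = "stormcohort_validation_error")
  invisible(cfg)
}

## Independent sub-streams per generator stage so that, e.g., regenerating
## rainfall does not shift the cohort draw. Offsets kept small; seeds stay
## far below .Machine$integer.max.
sim_seed <- function(cfg, stage) {
  offset <- c(areas = 11L, stations = 23L, rain = 37L, cohort = 53L)[[stage]]
  (cfg$seed %% 1000000L) * 1000L + offset
}

#' Generate the synthetic storm track
#'
#' A smooth track from the configured start to end point over
#' `duration_days` at `fix_hours` spacing: linear motion plus a sinusoidal
#' lateral bow of `bow_deg` degrees, mimicking the curved path of a
#' landfalling Gulf hurricane. Deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return A [storm_track()] with `duration_days * 24 / fix_hours + 1`
#'   fixes; the first starts at 00:00 UTC on `landfall_date`.
#' @export
generate_storm <- function(config) {
  validate_sim_config(config)
  s <- config$storm
  n_fix <- as.integer(s$duration_days * 24 / s$fix_hours) + 1L
  f <- seq(0, 1, length.out = n_fix)
  t0 <- as.POSIXct(paste(s$landfall_date, "00:00:00"), tz = "UTC")
  storm_track(
    t0 + (f * s$duration_days * 86400),
    s$start_lat + f * (s$end_lat - s$start_lat) + s$bow_deg * sin(pi * f),
    s$start_lon + f * (s$end_lon - s$start_lon)
  )
}

#' Generate synthetic area centroids
#'
#' Centroids uniform over the configured region; rurality drawn from the
#' configured marginals (rurality is an area-level attribute, shared by all
#' beneficiaries of an area, as with ZCTA-level rural-urban commuting-area
#' codes).
#'
#' @param config A [sim_config()].
#' @return data.frame `area_id`, `lat`, `lon`, `rurality`.
#' @export
generate_areas <- function(config) {
  validate_sim_config(config)
  r <- config$region
  set.seed(sim_seed(config, "areas"))
  n <- config$n_areas
  data.frame(
    area_id = sprintf("A%04d", seq_len(n)),
    lat = stats::runif(n, r[["lat_min"]], r[["lat_max"]]),
    lon = stats::runif(n, r[["lon_min"]], r[["lon_max"]]),
    rurality = sample(names(config$cohort$rurality_p), n, replace = TRUE,
                      prob = config$cohort$rurality_p)
  )
}

#' Generate synthetic rain-gauge stations
#'
#' @param config A [sim_config()].
#' @return data.frame `station_id`, `lat`, `lon`, uniform over the region.
#' @export
generate_stations <- function(config) {
  validate_sim_config(config)
  r <- config$region
  set.seed(sim_seed(config, "stations"))
  n <- config$n_stations
  data.frame(
    station_id = sprintf("S%04d", seq_len(n)),
    lat = stats::runif(n, r[["lat_min"]], r[["lat_max"]]),
    lon = stats::runif(n, r[["lon_min"]], r[["lon_max"]])
  )
}

## Deterministic mean rainfall surface for one station-day: background plus
## a peak decaying exponentially with the station's distance to that local
## day's track positions; days with no track positions see background only.
station_day_mean <- function(config, track, station_lat, station_lon, date,
                             tz_offset_hours = -6) {
  track_days <- local_date(track$timestamp, tz_offset_hours)
  sel <- track_days == date
  if (!any(sel)) return(config$rain$background_mm)
  d <- min(haversine_km(station_lat, station_lon,
                        track$lat[sel], track$lon[sel]))
  config$rain$background_mm +
    config$rain$peak_mm_per_day * exp(-d / config$rain$decay_scale_km)
}

#' Generate synthetic daily station rainfall
#'
#' Station-day precipitation is the deterministic mean surface (see
#' [sim_config()]) times multiplicative gamma noise with unit mean and
#' coefficient of variation `noise_dispersion` (dispersion 0 gives the mean
#' surface exactly). The record is complete — every station reports every
#' day — spanning the track's local-date range padded by `pad_days` on each
#' side so that every possible approach window is covered.
#'
#' @param config A [sim_config()].
#' @param track A [storm_track()] (usually [generate_storm()] output).
#' @param stations Station table.
#' @param tz_offset_hours Calendar-day convention; default -6.
#' @return data.frame `station_id`, `date`, `precip_mm`.
#' @export
generate_rainfall <- function(config, track, stations,
                              tz_offset_hours = -6) {
  validate_sim_config(config)
  stations <- validate_stations(stations)
  track_days <- local_date(track$timestamp, tz_offset_hours)
  dates <- seq(min(track_days) - config$rain$pad_days,
               max(track_days) + config$rain$pad_days, by = "day")
  grid <- expand.grid(si = seq_len(nrow(stations)), date = dates)
  mu <- mapply(function(si, dt) {
    station_day_mean(config, track, stations$lat[si], stations$lon[si],
                     dt, tz_offset_hours)
  }, grid$si, as.Date(grid$date))
  disp <- config$rain$noise_dispersion
  set.seed(sim_seed(config, "rain"))
  noise <- if (disp == 0) rep(1, length(mu))
           else stats::rgamma(length(mu), shape = 1 / disp^2,
                              rate = 1 / disp^2)
  out <- data.frame(
    station_id = stations$station_id[grid$si],
    date = as.Date(grid$date),
    precip_mm = mu * noise
  )
  out[order(out$station_id, out$date), , drop = FALSE]
}

#' Generate a synthetic beneficiary cohort with known mortality effects
#'
#' Covariates are drawn independently from the configured marginals; the
#' comorbidity count is the number of flagged index conditions plus a
#' Poisson count of further chronic conditions, so the count is never below
#' the number of flags. Event times are exponential with subject hazard
#' `lambda_0 * exp(true_log_hr_exposure * exposed + beta' x + b_area)`,
#' `b_area ~ Normal(0, frailty_sd^2)`, and `lambda_0` set so the one-year
#' mortality of a reference subject (age at the configured mean, female,
#' non-Hispanic White, Medicare-only, zero comorbidities, metro,
#' unexposed) equals `baseline_mortality`. Follow-up is administratively
#' censored at 365 days. Relocation flags are drawn independently of the
#' event process: relocation affects cohort inclusion only.
#'
#' @param config A [sim_config()].
#' @param exposure_table Output of [build_exposure_table()] (needs
#'   `area_id`, `exposed`); the `areas` table supplies rurality.
#' @param areas Area table from [generate_areas()].
#' @return list with `beneficiaries` (covariates incl. `area_id`,
#'   condition flags, `n_comorbidities`, `rurality`, `relocated`) and
#'   `survival` (`beneficiary_id`, `time_days`, `event`).
#' @export
generate_cohort <- function(config, exposure_table, areas) {
  validate_sim_config(config)
  check_columns(exposure_table, c("area_id", "exposed"), "exposure table")
  check_columns(areas, c("area_id", "rurality"), "areas")
  n <- config$n_beneficiaries
  co <- config$cohort
  sv <- config$survival
  set.seed(sim_seed(config, "cohort"))

  area_idx <- sample(nrow(areas), n, replace = TRUE)
  area_id <- areas$area_id[area_idx]

  # age ~ Normal(age_mean, age_sd) truncated below at 65 via inverse CDF
  p_lo <- stats::pnorm(65, co$age_mean, co$age_sd)
  age <- stats::qnorm(stats::runif(n, p_lo, 1), co$age_mean, co$age_sd)

  sex <- ifelse(stats::rbinom(n, 1, co$female_p) == 1, "female", "male")
  race <- sample(names(co$race_p), n, replace = TRUE, prob = co$race_p)
  dual <- stats::rbinom(n, 1, co$dual_p) == 1
  flags <- sapply(co$condition_p, function(p) stats::rbinom(n, 1, p) == 1)
  colnames(flags) <- names(co$condition_p)
  n_comorb <- rowSums(flags) + stats::rpois(n, co$extra_comorbidity_mean)
  relocated <- stats::rbinom(n, 1, co$relocate_p) == 1

  exposed <- exposure_table$exposed[match(area_id, exposure_table$area_id)]
  if (anyNA(exposed))
    stopf("generate_cohort: area(s) missing from exposure table",
          class = "stormcohort_validation_error")

  frail <- stats::rnorm(nrow(areas), 0, sv$frailty_sd)
  lambda0 <- -log(1 - sv$baseline_mortality) / 365
  b <- sv$log_hr
  lp <- sv$true_log_hr_exposure * exposed +
    b[["age_per_year"]] * (age - co$age_mean) +
    b[["male"]] * (sex == "male") +
    b[["nh_black"]] * (race == "nh_black") +
    b[["hispanic"]] * (race == "hispanic") +
    b[["other"]] * (race == "other") +
    b[["dual"]] * dual +
    b[["comorbidity"]] * n_comorb +
    b[["micro"]] * (areas$rurality[area_idx] == "micro") +
    b[["rural"]] * (areas$rurality[area_idx] == "rural") +
    frail[area_idx]
  ia <- sv$interaction_log_hr
  for (flag in names(ia))
    lp <- lp + ia[[flag]] * exposed * flags[, flag]
  t_event <- stats::rexp(n, lambda0 * exp(lp))
  event <- t_event <= 365
  time_days <- pmin(t_event, 365)

  beneficiaries <- data.frame(
    beneficiary_id = sprintf("B%07d", seq_len(n)),
    area_id = area_id,
    age = age,
    sex = sex,
    race_ethnicity = race,
    dual_eligible = dual,
    adrd = flags[, "adrd"], chf = flags[, "chf"], copd = flags[, "copd"],
    dm = flags[, "dm"], ckd = flags[, "ckd"],
    n_comorbidities = n_comorb,
    rurality = areas$rurality[area_idx],
    relocated = relocated
  )
  survival <- data.frame(
    beneficiary_id = beneficiaries$beneficiary_id,
    time_days = time_days,
    event = event
  )
  list(beneficiaries = beneficiaries, survival = survival)
}

#' Write a complete set of synthetic pipeline inputs
#'
#' Generates the four input tables (storm track, stations, daily rain,
#' beneficiaries) and writes them as CSV to `out_dir`. The beneficiary file
#' carries a `death_date` (landfall + whole days survived, empty when
#' censored) and `censor_date`, the form in which an administrative-claims
#' extract would arrive; [build_cohort()] reconstructs follow-up time from
#' them via [elapsed_days()].
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects (`track`, `areas`,
#'   `stations`, `daily_rain`, `exposure`, `beneficiaries`, `survival`).
#' @export
simulate_inputs <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  track <- generate_storm(config)
  areas <- generate_areas(config)
  stations <- generate_stations(config)
  daily_rain <- generate_rainfall(config, track, stations)
  exposure <- build_exposure_table(areas, stations, daily_rain, track)
  gen <- generate_cohort(config, exposure, areas)

  landfall <- as.Date(config$storm$landfall_date)
  ben <- gen$beneficiaries
  ben$death_date <- ifelse(
    gen$survival$event,
    format(landfall + floor(gen$survival$time_days)), "")
  ben$censor_date <- format(landfall + 365)

  w <- function(df, f) utils::write.csv(
    df, file.path(out_dir, f), row.names = FALSE)
  w(data.frame(timestamp = format(track$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
               lat = track$lat, lon = track$lon), "track.csv")
  w(areas, "areas.csv")
  w(stations, "stations.csv")
  w(daily_rain, "daily_rain.csv")
  w(ben, "beneficiaries.csv")
  invisible(list(track = track, areas = areas, stations = stations,
                 daily_rain = daily_rain, exposure = exposure,
                 beneficiaries = gen$beneficiaries,
                 survival = gen$survival))
}
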