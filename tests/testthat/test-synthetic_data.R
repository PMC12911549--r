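small_cfg <- function(n_beneficiaries = 2000, ...)
  sim_config(n_areas = 30, n_stations = 20,
             n_beneficiaries = n_beneficiaries, ...)

test_that("generated storm has the configured endpoints and fix count", {
  cfg <- small_cfg()
  tr <- generate_storm(cfg)
  # 7 days at 6-h fixes: 28 intervals + 1
  expect_equal(nrow(tr), 29)
  expect_equal(tr$lat[1], cfg$storm$start_lat)
  expect_equal(tr$lon[1], cfg$storm$start_lon)
  expect_equal(tr$lat[29], cfg$storm$end_lat)  # sin(pi * 1) bow vanishes
  expect_equal(tr$lon[29], cfg$storm$end_lon)
  expect_identical(tr, generate_storm(cfg))  # deterministic
  bad <- cfg; bad$storm$duration_days <- 0
  expect_error(generate_storm(bad), "degenerate")
})

test_that("rainfall far from the track is background; zero dispersion is exact", {
  cfg <- small_cfg()
  cfg$rain$noise_dispersion <- 0
  tr <- generate_storm(cfg)
  st <- data.frame(station_id = c("FAR", "PAD"),
                   lat = c(cfg$storm$start_lat, 30),
                   lon = c(cfg$storm$start_lon + 40, -94))  # ~3800 km east
  dr <- generate_rainfall(cfg, tr, st)
  far <- dr[dr$station_id == "FAR", ]
  expect_equal(far$precip_mm, rep(cfg$rain$background_mm, nrow(far)),
               tolerance = 1e-6)
  # deterministic field equals the mean surface: regeneration is identical
  expect_identical(dr, generate_rainfall(cfg, tr, st))
  # padding days before the track (the first track fix falls on the local
  # day before landfall under UTC-6) carry background rain only
  pad <- dr[dr$date < as.Date(cfg$storm$landfall_date) - 1, ]
  expect_equal(pad$precip_mm, rep(cfg$rain$background_mm, nrow(pad)))
})

test_that("Monte-Carlo station-day mean matches the closed-form surface", {
  cfg <- small_cfg()
  tr <- generate_storm(cfg)
  st <- data.frame(station_id = "S", lat = 30, lon = -94)
  day <- as.Date(cfg$storm$landfall_date) + 3
  cfg0 <- cfg; cfg0$rain$noise_dispersion <- 0
  mu <- generate_rainfall(cfg0, tr, st)
  mu <- mu$precip_mm[mu$date == day]
  draws <- vapply(1:500, function(i) {
    ci <- cfg; ci$seed <- 60000 + i
    d <- generate_rainfall(ci, tr, st)
    d$precip_mm[d$date == day]
  }, numeric(1))
  # gamma noise: sd of one draw = dispersion * mu
  se <- cfg$rain$noise_dispersion * mu / sqrt(500)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("cohort generation is deterministic and respects type invariants", {
  cfg <- small_cfg()
  areas <- generate_areas(cfg)
  expt <- data.frame(area_id = areas$area_id,
                     exposed = seq_len(nrow(areas)) %% 2 == 0)
  g1 <- generate_cohort(cfg, expt, areas)
  g2 <- generate_cohort(cfg, expt, areas)
  expect_identical(g1, g2)
  expect_true(all(g1$beneficiaries$age >= 65))
  expect_true(all(g1$beneficiaries$n_comorbidities >=
                    rowSums(g1$beneficiaries[, c("adrd", "chf", "copd",
                                                 "dm", "ckd")])))
  expect_true(all(g1$survival$time_days > 0))
  expect_true(all(g1$survival$time_days <= 365))
  expect_true(all(g1$survival$time_days[!g1$survival$event] == 365))
})

test_that("null effects give equal exposed/unexposed mortality", {
  cfg <- sim_config(n_areas = 30, n_stations = 20, n_beneficiaries = 50000,
                    seed = 77)
  cfg$survival$true_log_hr_exposure <- 0
  cfg$survival$log_hr[] <- 0
  cfg$survival$frailty_sd <- 0
  areas <- generate_areas(cfg)
  expt <- data.frame(area_id = areas$area_id,
                     exposed = seq_len(nrow(areas)) %% 2 == 0)
  g <- generate_cohort(cfg, expt, areas)
  exposed <- g$beneficiaries$area_id %in% expt$area_id[expt$exposed]
  p1 <- mean(g$survival$event[exposed])
  p0 <- mean(g$survival$event[!exposed])
  se <- sqrt(p0 * (1 - p0) * (1 / sum(exposed) + 1 / sum(!exposed)))
  expect_lt(abs(p1 - p0), 3 * se)
  # and the observed rate matches the exponential closed form
  p_target <- cfg$survival$baseline_mortality
  se_p <- sqrt(p_target * (1 - p_target) / length(exposed))
  expect_lt(abs(mean(g$survival$event) - p_target), 3 * se_p)
})

test_that("covariate marginals match the configuration at scale", {
  cfg <- sim_config(n_areas = 50, n_stations = 20, n_beneficiaries = 50000,
                    seed = 5)
  areas <- generate_areas(cfg)
  expt <- data.frame(area_id = areas$area_id,
                     exposed = seq_len(nrow(areas)) %% 2 == 0)
  ben <- generate_cohort(cfg, expt, areas)$beneficiaries
  n <- nrow(ben)
  within3se <- function(obs_p, p) {
    expect_lt(abs(obs_p - p), 3 * sqrt(p * (1 - p) / n))
  }
  within3se(mean(ben$sex == "female"), cfg$cohort$female_p)
  within3se(mean(ben$dual_eligible), cfg$cohort$dual_p)
  within3se(mean(ben$adrd), cfg$cohort$condition_p[["adrd"]])
  within3se(mean(ben$ckd), cfg$cohort$condition_p[["ckd"]])
  within3se(mean(ben$race_ethnicity == "hispanic"),
            cfg$cohort$race_p[["hispanic"]])
  within3se(mean(ben$relocated), cfg$cohort$relocate_p)
  # truncated-normal age: mean of the parent normal conditioned on >= 65
  a <- (65 - cfg$cohort$age_mean) / cfg$cohort$age_sd
  mu_trunc <- cfg$cohort$age_mean +
    cfg$cohort$age_sd * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(ben$age) - mu_trunc),
            3 * cfg$cohort$age_sd / sqrt(n))
})

test_that("simulate_inputs writes a complete, reloadable input set", {
  cfg <- small_cfg(n_beneficiaries = 500, seed = 9)
  dir <- file.path(tempdir(), "siminputs")
  gen <- simulate_inputs(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("track.csv", "areas.csv", "stations.csv", "daily_rain.csv",
           "beneficiaries.csv")))))
  tr <- read_track(file.path(dir, "track.csv"))
  expect_equal(nrow(tr), 29)
  ben <- read.csv(file.path(dir, "beneficiaries.csv"))
  expect_equal(nrow(ben), 500)
  # death/censor dates reconstruct the simulated event indicator
  expect_equal(nzchar(ben$death_date) & !is.na(ben$death_date),
               gen$survival$event)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_areas = 0), "positive")
  cfg <- small_cfg()
  cfg$cohort$dual_p <- 1.4
  expect_error(validate_sim_config(cfg), "probabilities")
  cfg2 <- small_cfg()
  cfg2$survival$frailty_sd <- -1
  expect_error(validate_sim_config(cfg2), "frailty_sd")
})
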