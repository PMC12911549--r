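test_that("haversine distance matches closed forms", {
  expect_equal(haversine_km(29.7, -95.4, 29.7, -95.4), 0)
  # quarter great circle, pi/2 * R
  expect_equal(haversine_km(0, 0, 0, 90), pi / 2 * 6371.0088,
               tolerance = 1e-9)
  # one degree of longitude at the equator, 2*pi*R/360
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-9)
  expect_equal(round(haversine_km(0, 0, 0, 1), 3), 111.195)
  # symmetry
  expect_equal(haversine_km(10, 20, -30, 40), haversine_km(-30, 40, 10, 20))
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
})

test_that("haversine satisfies the triangle inequality on random triples", {
  set.seed(42)
  for (i in 1:50) {
    lat <- runif(3, -90, 90)
    lon <- runif(3, -180, 180)
    ab <- haversine_km(lat[1], lon[1], lat[2], lon[2])
    bc <- haversine_km(lat[2], lon[2], lat[3], lon[3])
    ac <- haversine_km(lat[1], lon[1], lat[3], lon[3])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("haversine agrees with an independent implementation", {
  set.seed(7)
  lat <- runif(20, -80, 80); lon <- runif(20, -170, 170)
  expect_equal(haversine_km(lat[1:10], lon[1:10], lat[11:20], lon[11:20]),
               oracle_haversine_km(lat[1:10], lon[1:10], lat[11:20],
                                   lon[11:20]),
               tolerance = 1e-9)
})

test_that("track validation rejects malformed input", {
  expect_error(storm_track("2017-08-25", 30, -95)[2, ], NA)
  expect_error(
    storm_track(c("2017-08-25 06:00", "2017-08-25 00:00"), c(30, 30),
                c(-95, -94)),
    "strictly increasing")
  expect_error(
    storm_track(c("2017-08-25 00:00", "2017-08-25 06:00"), c(30, 30),
                c(179, -179)),
    "antimeridian")
  expect_error(interpolate_track(fixture_track()[1, , drop = FALSE]),
               "at least 2 fixes")
})

test_that("track interpolation is linear with preserved endpoints", {
  tr <- storm_track(c("2017-08-25 00:00:00", "2017-08-25 06:00:00"),
                    c(10, 12), c(-95, -93))
  it <- interpolate_track(tr, 15)
  expect_equal(nrow(it), 360 / 15 + 1)  # 6 h at 15-min step
  expect_equal(it$timestamp[1], tr$timestamp[1])
  expect_equal(it$lat[1], 10)
  expect_equal(it$lat[nrow(it)], 12)
  expect_equal(it$lon[nrow(it)], -93)
  # midpoint of a straight segment
  mid <- which(it$timestamp == tr$timestamp[1] + 3 * 3600)
  expect_equal(it$lat[mid], 11)
  expect_equal(it$lon[mid], -94)
  # consecutive stamps differ by exactly the step
  expect_true(all(diff(as.numeric(it$timestamp)) == 15 * 60))
})

test_that("closest approach minimises distance with earliest-time ties", {
  it <- interpolate_track(fixture_track(), 15)
  # centroid equal to a track fix -> zero distance at that fix time
  ca <- closest_approach(it, 30, -95, "Z1")
  expect_equal(ca$distance_km, 0)
  expect_equal(ca$approach_time,
               as.POSIXct("2017-08-26 00:00:00", tz = "UTC"))
  # UTC-6 convention: 2017-08-26 00:00 UTC is still Aug 25 locally
  expect_equal(ca$approach_date, as.Date("2017-08-25"))

  # brute-force scan oracle on a small arbitrary track
  set.seed(3)
  tr <- storm_track(as.POSIXct("2017-08-25", tz = "UTC") + 3600 * 0:4,
                    runif(5, 28, 32), sort(runif(5, -97, -90)))
  d <- oracle_haversine_km(29.3, -93.7, tr$lat, tr$lon)
  ca2 <- closest_approach(tr, 29.3, -93.7, "X")
  expect_equal(ca2$distance_km, min(d), tolerance = 1e-9)
  expect_equal(ca2$approach_time, tr$timestamp[which.min(d)])

  # two equidistant fixes: earlier timestamp wins
  tr3 <- storm_track(as.POSIXct("2017-08-25", tz = "UTC") + 3600 * 0:2,
                     c(30, 31, 30), c(-95, -95, -95))
  ca3 <- closest_approach(tr3, 29.5, -95, "T")
  expect_equal(ca3$approach_time, tr3$timestamp[1])
  expect_error(closest_approach(tr3[0, ], 30, -95, "E"), "empty track")
})

test_that("closest approach is invariant to track reversal and monotone in step", {
  it <- interpolate_track(fixture_track(), 15)
  rev_tr <- fixture_track()
  rev_tr <- storm_track(rev_tr$timestamp, rev(rev_tr$lat), rev(rev_tr$lon))
  it_rev <- interpolate_track(rev_tr, 15)
  for (pt in list(c(29.2, -96.1), c(31.0, -91.5), c(30.4, -93.3))) {
    d_fwd <- closest_approach(it, pt[1], pt[2], "a")$distance_km
    d_rev <- closest_approach(it_rev, pt[1], pt[2], "a")$distance_km
    expect_equal(d_fwd, d_rev, tolerance = 1e-9)
    # refining the step never increases the minimum distance
    it5 <- interpolate_track(fixture_track(), 5)
    expect_lte(closest_approach(it5, pt[1], pt[2], "a")$distance_km,
               d_fwd + 1e-12)
  }
})

test_that("track readers parse both dialects", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(timestamp = c("2017-08-25T00:00:00Z",
                                     "2017-08-25T06:00:00Z"),
                       lat = c(25.1, 25.9), lon = c(-94.2, -94.9)),
            csv, row.names = FALSE)
  tr <- read_track(csv)
  expect_s3_class(tr, "storm_track")
  expect_equal(tr$lat, c(25.1, 25.9))

  hd <- tempfile(fileext = ".txt")
  writeLines(c(
    "20170825, 0000,  , HU, 25.1N,  94.2W,  115,  938",
    "20170825, 0600,  , HU, 25.9N,  94.9W,  115,  937"), hd)
  tr2 <- read_track(hd, format = "hurdat2")
  expect_equal(tr2$lat, c(25.1, 25.9))
  expect_equal(tr2$lon, c(-94.2, -94.9))
  expect_equal(tr2$timestamp,
               as.POSIXct(c("2017-08-25 00:00", "2017-08-25 06:00"),
                          tz = "UTC"))
})
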