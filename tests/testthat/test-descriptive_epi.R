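two_by_two <- function(de, ne, du, nu) {
  # cohort data realising a 2x2 table: deaths/size per exposure group
  data.frame(
    exposed = rep(c(TRUE, FALSE), c(ne, nu)),
    event = c(rep(c(TRUE, FALSE), c(de, ne - de)),
              rep(c(TRUE, FALSE), c(du, nu - du))),
    time_days = 365
  )
}

test_that("epi measures reproduce the textbook 2x2 arithmetic", {
  m <- epi_measures(two_by_two(20, 1000, 10, 1000))
  expect_equal(m$rate_exposed, 0.02)
  expect_equal(m$rate_unexposed, 0.01)
  expect_equal(m$relative_risk, 2)
  expect_equal(m$attributable_fraction_exposed, 0.5)
  expect_equal(m$attributable_deaths, 10)
})

test_that("equal rates give a null contrast", {
  m <- epi_measures(two_by_two(15, 300, 25, 500))
  expect_equal(m$relative_risk, 1)
  expect_equal(m$attributable_fraction_exposed, 0)
  expect_equal(m$attributable_deaths, 0)
})

test_that("epi measures match a brute-force 2x2 calculator on random tables", {
  set.seed(21)
  for (i in 1:30) {
    ne <- sample(50:500, 1); nu <- sample(50:500, 1)
    de <- sample(1:(ne - 1), 1); du <- sample(1:(nu - 1), 1)
    m <- epi_measures(two_by_two(de, ne, du, nu))
    rr <- (de / ne) / (du / nu)
    expect_equal(m$relative_risk, rr, tolerance = 1e-12)
    expect_equal(m$attributable_fraction_exposed, (rr - 1) / rr,
                 tolerance = 1e-12)
    expect_equal(m$attributable_deaths, ne * (de / ne - du / nu),
                 tolerance = 1e-12)
    # the two attributable-deaths formulations coincide
    expect_equal(m$attributable_deaths,
                 m$attributable_fraction_exposed * de, tolerance = 1e-10)
  }
})

test_that("degenerate groups are reported, not silently computed", {
  expect_error(epi_measures(two_by_two(5, 100, 0, 100)),
               "zero unexposed deaths")
  df <- two_by_two(5, 100, 5, 100)
  expect_error(epi_measures(df[df$exposed, ]), "empty exposure group")
})

test_that("attributable deaths decompose exactly over strata with common unexposed rates", {
  # two strata, equal unexposed rate 0.1 by construction: the stratified
  # decomposition must sum to the whole-cohort value exactly
  a <- two_by_two(30, 200, 10, 100)   # stratum 1
  b <- two_by_two(24, 300, 40, 400)   # stratum 2
  a$stratum <- "s1"; b$stratum <- "s2"
  whole <- rbind(a, b)
  ad <- function(df) epi_measures(df)$attributable_deaths
  expect_equal(ad(a) + ad(b), ad(whole), tolerance = 1e-10)
})

test_that("KM product-limit values match the hand-computed 5-subject example", {
  # times 2, 3+, 4, 5, 5: S(2) = 4/5, S(4) = 4/5 * 2/3, S(5) = 0
  km <- km_curve(c(2, 3, 4, 5, 5), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(2, 4, 5))
  expect_equal(ev$survival, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
  expect_equal(ev$cuminc, 1 - ev$survival, tolerance = 1e-12)
})

test_that("KM without censoring equals the empirical CDF; all-censored is flat", {
  set.seed(4)
  t <- sample(1:200, 60, replace = TRUE)
  km <- km_curve(t, rep(TRUE, 60))
  expect_equal(km$cuminc, ecdf(t)(km$time), tolerance = 1e-12)
  flat <- km_curve(t, rep(FALSE, 60))
  expect_true(all(flat$cuminc == 0))
  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("survival is non-increasing and cumulative incidence stays in [0,1]", {
  set.seed(14)
  t <- rexp(300, 1 / 200)
  km <- km_curve(pmin(t, 365), t <= 365)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$cuminc >= 0 & km$cuminc <= 1))
})

test_that("log-rank matches the observed-minus-expected oracle and is symmetric", {
  set.seed(8)
  ga <- make_surv_df(sample(seq(1, 360, by = 7), 40, replace = FALSE),
                     rbinom(40, 1, 0.7))
  gb <- make_surv_df(sample(seq(3, 362, by = 7), 40, replace = FALSE),
                     rbinom(40, 1, 0.5))
  res <- logrank_test(ga, gb)
  oracle <- oracle_logrank(c(ga$time_days, gb$time_days),
                           c(ga$event, gb$event) == 1,
                           rep(c(1, 0), c(40, 40)))
  expect_equal(res$statistic, oracle, tolerance = 1e-8)
  swapped <- logrank_test(gb, ga)
  expect_equal(res$statistic, swapped$statistic, tolerance = 1e-12)
  # identical groups: zero statistic, p = 1
  null <- logrank_test(ga, ga)
  expect_equal(null$statistic, 0, tolerance = 1e-12)
  expect_equal(null$p_value, 1)
  expect_error(logrank_test(make_surv_df(1:3, c(0, 0, 0)),
                            make_surv_df(1:3, c(0, 0, 0))), "no events")
})

test_that("table one applies the footnote test mapping", {
  set.seed(31)
  n <- 400
  df <- data.frame(
    exposed = rep(c(TRUE, FALSE), each = n / 2),
    age = rnorm(n, 75, 7),
    n_comorbidities = rpois(n, 3),
    sex = sample(c("female", "male"), n, replace = TRUE),
    dual_eligible = rbinom(n, 1, 0.1) == 1
  )
  t1 <- table_one(df, continuous = c("age", "n_comorbidities"),
                  categorical = c("sex", "dual_eligible"))
  expect_setequal(unique(t1$variable),
                  c("age", "n_comorbidities", "sex", "dual_eligible"))
  expect_setequal(t1$test[t1$variable == "age"], c("t-test", "Mann-Whitney"))
  # chi-squared statistic equals the hand-computed Pearson statistic
  tab <- table(df$sex, df$exposed)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pearson <- sum((tab - expected)^2 / expected)
  got <- t1$statistic[t1$variable == "sex" & !is.na(t1$statistic)]
  expect_equal(got, pearson, tolerance = 1e-10)
})

test_that("identical exposure groups yield null table-one tests", {
  base <- data.frame(age = c(70, 75, 80, 85), sex = c("f", "f", "m", "m"))
  df <- rbind(cbind(base, exposed = TRUE), cbind(base, exposed = FALSE))
  t1 <- table_one(df, continuous = "age", categorical = "sex")
  expect_equal(t1$p_value[t1$test == "t-test"], 1)
  expect_equal(t1$statistic[t1$test == "t-test"], 0)
  expect_equal(t1$statistic[t1$test == "chi-squared" &
                              !is.na(t1$statistic)], 0)
})

test_that("constant variables are skipped with a note", {
  df <- data.frame(exposed = c(TRUE, TRUE, FALSE, FALSE),
                   age = c(70, 70, 70, 70), sex = "f")
  t1 <- table_one(df, continuous = "age", categorical = "sex")
  expect_true(all(grepl("skipped", t1$test)))
})
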