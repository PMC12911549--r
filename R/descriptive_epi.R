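#' Unadjusted population-level mortality measures
#'
#' For a cohort (optionally restricted to a subgroup), computes one-year
#' mortality by exposure status and the classical unadjusted contrasts:
#' relative risk `RR = rate_exposed / rate_unexposed`, attributable
#' fraction among the exposed `AF = (RR - 1) / RR`, and attributable
#' deaths `n_exposed * (rate_exposed - rate_unexposed)` (algebraically
#' `AF * deaths_exposed`) — the exposed-group deaths in excess of those
#' expected at the unexposed rate. "Rates" are one-year cumulative
#' incidence proportions, consistent with a fixed 365-day follow-up.
#' Negative attributable quantities are reported as computed, not floored.
#'
#' @param cohort An `analytic_cohort` or its data (needs `exposed`,
#'   `event`).
#' @param subset Optional logical vector (or subgroup filter function
#'   taking the data and returning one) restricting the computation.
#' @param label Subgroup label carried into the output.
#' @return An `epi_measures` object (also a one-row data.frame):
#'   counts, rates, `relative_risk`, `attributable_fraction_exposed`,
#'   `attributable_deaths`.
#' @export
epi_measures <- function(cohort, subset = NULL, label = "overall") {
  df <- cohort_data(cohort)
  check_columns(df, c("exposed", "event"), "cohort data")
  if (!is.null(subset)) {
    if (is.function(subset)) subset <- subset(df)
    df <- df[subset, , drop = FALSE]
  }
  n_exp <- sum(df$exposed)
  n_une <- sum(!df$exposed)
  if (n_exp == 0 || n_une == 0)
    stopf("epi_measures [%s]: empty exposure group", label,
          class = "stormcohort_degenerate_group_error")
  d_exp <- sum(df$event[df$exposed])
  d_une <- sum(df$event[!df$exposed])
  if (d_une == 0)
    stopf("epi_measures [%s]: zero unexposed deaths; relative risk undefined",
          label, class = "stormcohort_degenerate_group_error")
  r_exp <- d_exp / n_exp
  r_une <- d_une / n_une
  rr <- r_exp / r_une
  out <- data.frame(
    subgroup = label,
    n_exposed = n_exp, deaths_exposed = d_exp,
    n_unexposed = n_une, deaths_unexposed = d_une,
    rate_exposed = r_exp, rate_unexposed = r_une,
    relative_risk = rr,
    attributable_fraction_exposed = (rr - 1) / rr,
    attributable_deaths = n_exp * (r_exp - r_une)
  )
  class(out) <- c("epi_measures", "data.frame")
  out
}

#' Unadjusted measures across vulnerable subgroups
#'
#' @param cohort An `analytic_cohort` or its data.
#' @param subgroups A named list of filter functions (data -> logical), as
#'   produced by [default_subgroups()].
#' @return data.frame with one [epi_measures()] row per subgroup; subgroups
#'   with an empty exposure arm or no unexposed deaths are skipped with a
#'   warning.
#' @export
epi_measures_by_subgroup <- function(cohort, subgroups = default_subgroups()) {
  rows <- lapply(names(subgroups), function(nm) {
    tryCatch(epi_measures(cohort, subgroups[[nm]]$filter, label = nm),
             stormcohort_degenerate_group_error = function(e) {
               warning(conditionMessage(e)); NULL
             })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier cumulative incidence
#'
#' Product-limit estimate of mortality cumulative incidence
#' (`1 - S(t)`) over the follow-up year, with administrative censoring at
#' 365 days treated as right censoring.
#'
#' @param time_days Follow-up times (> 0).
#' @param event Logical event indicators.
#' @return data.frame `time`, `n_risk`, `n_event`, `survival`, `cuminc`.
#' @export
km_curve <- function(time_days, event) {
  if (length(time_days) == 0)
    stopf("km_curve: empty input", class = "stormcohort_validation_error")
  if (any(time_days <= 0))
    stopf("km_curve: nonpositive follow-up time",
          class = "stormcohort_validation_error")
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, cuminc = 1 - fit$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank comparison of survival between two groups
#' (e.g., exposed vs unexposed), two-sided p from the chi-square reference.
#'
#' @param group_a,group_b data.frames with columns `time_days`, `event`.
#' @return list: `statistic` (chi-square), `df` (1), `p_value`.
#' @export
logrank_test <- function(group_a, group_b) {
  check_columns(group_a, c("time_days", "event"), "group_a")
  check_columns(group_b, c("time_days", "event"), "group_b")
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stopf("logrank_test: empty group",
          class = "stormcohort_validation_error")
  time <- c(group_a$time_days, group_b$time_days)
  event <- c(group_a$event, group_b$event)
  if (sum(event) == 0)
    stopf("logrank_test: no events; statistic undefined",
          class = "stormcohort_degenerate_group_error")
  grp <- rep(c("a", "b"), c(nrow(group_a), nrow(group_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- as.numeric(sd$chisq)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## One table_one row set for a continuous variable: mean (SD) with t-test,
## median (IQR) with Mann-Whitney.
t1_continuous <- function(x, exposed, name) {
  msd <- function(v) sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
  miqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
  }
  if (stats::sd(x) == 0) {
    return(data.frame(
      variable = name, level = c("mean (SD)", "median (IQR)"),
      overall = c(msd(x), miqr(x)), exposed = NA, unexposed = NA,
      test = "skipped: constant variable", statistic = NA_real_,
      p_value = NA_real_))
  }
  tt <- stats::t.test(x[exposed], x[!exposed])
  mw <- stats::wilcox.test(x[exposed], x[!exposed], exact = FALSE)
  data.frame(
    variable = name,
    level = c("mean (SD)", "median (IQR)"),
    overall = c(msd(x), miqr(x)),
    exposed = c(msd(x[exposed]), miqr(x[exposed])),
    unexposed = c(msd(x[!exposed]), miqr(x[!exposed])),
    test = c("t-test", "Mann-Whitney"),
    statistic = c(unname(tt$statistic), unname(mw$statistic)),
    p_value = c(tt$p.value, mw$p.value)
  )
}

## One table_one row set for a categorical variable: n (%) per level,
## Pearson chi-squared without continuity correction on the full table.
t1_categorical <- function(x, exposed, name) {
  x <- as.factor(x)
  npct <- function(v, lev) sprintf("%d (%.1f)", sum(v == lev),
                                   100 * mean(v == lev))
  if (nlevels(droplevels(x)) < 2) {
    return(data.frame(
      variable = name, level = levels(x),
      overall = vapply(levels(x), function(l) npct(x, l), ""),
      exposed = NA, unexposed = NA,
      test = "skipped: constant variable", statistic = NA_real_,
      p_value = NA_real_))
  }
  tab <- table(x, exposed)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(
    variable = name,
    level = levels(x),
    overall = vapply(levels(x), function(l) npct(x, l), ""),
    exposed = vapply(levels(x), function(l) npct(x[exposed], l), ""),
    unexposed = vapply(levels(x), function(l) npct(x[!exposed], l), ""),
    test = "chi-squared",
    statistic = c(unname(cs$statistic), rep(NA_real_, nlevels(x) - 1)),
    p_value = c(cs$p.value, rep(NA_real_, nlevels(x) - 1))
  )
}

#' Characteristics table by exposure status
#'
#' A Table-1-style summary: for each variable, overall and by-exposure
#' summaries with the conventional tests — t-test for means, Mann-Whitney
#' for medians, Pearson chi-squared (no continuity correction) for
#' proportions. Constant variables are reported but their test is skipped
#' with a note.
#'
#' @param cohort An `analytic_cohort` or its data.
#' @param continuous,categorical Character vectors of column names; the
#'   defaults cover the standard cohort layout and keep only columns
#'   actually present.
#' @return data.frame: `variable`, `level`, `overall`, `exposed`,
#'   `unexposed`, `test`, `statistic`, `p_value`.
#' @export
table_one <- function(cohort,
                      continuous = c("age", "n_comorbidities",
                                     "cumulative_in"),
                      categorical = c("sex", "race_ethnicity",
                                      "dual_eligible", "rurality", "adrd",
                                      "chf", "copd", "dm", "ckd")) {
  df <- cohort_data(cohort)
  check_columns(df, "exposed", "cohort data")
  if (nrow(df) == 0)
    stopf("table_one: empty cohort", class = "stormcohort_validation_error")
  exposed <- df$exposed
  rows <- c(
    lapply(intersect(continuous, names(df)),
           function(v) t1_continuous(df[[v]], exposed, v)),
    lapply(intersect(categorical, names(df)),
           function(v) t1_categorical(df[[v]], exposed, v))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
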