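#' Follow-up days from dates
#'
#' Integer days between landfall and the death or censoring date. Deaths on
#' the landfall day itself are assigned 0.5 days so that event times stay
#' strictly positive (the standard convention for events tied at the time
#' origin). Censoring is administrative at 365 days.
#'
#' @param date Death date or censoring date (Date or ISO string),
#'   vectorised; must lie within `[landfall, landfall + 365]`.
#' @param landfall_date The exposure origin (Date or ISO string).
#' @return Numeric vector of follow-up days in (0, 365].
#' @export
elapsed_days <- function(date, landfall_date) {
  date <- as.Date(date)
  landfall_date <- as.Date(landfall_date)
  d <- as.numeric(date - landfall_date)
  if (anyNA(d) || any(d < 0) || any(d > 365))
    stopf("elapsed_days: date(s) outside [landfall, landfall + 365 days]",
          class = "stormcohort_validation_error")
  ifelse(d == 0, 0.5, d)
}

#' Build the analytic cohort
#'
#' Joins beneficiaries to their survival records and area exposure and
#' applies the inclusion rules in a fixed order — (1) age at least 65,
#' (2) complete covariates (complete-case analysis), (3) unless
#' `include_relocated`, no relocation during follow-up — recording the
#' number excluded by each rule in an exclusion ledger. The order is fixed
#' so that ledgers are comparable across runs; each subject is counted
#' against the first rule that removes it.
#'
#' If survival records carry `death_date`/`censor_date` instead of
#' `time_days`/`event`, follow-up is reconstructed with [elapsed_days()]
#' from `landfall_date`.
#'
#' @param beneficiaries Beneficiary table (see [generate_cohort()]); must
#'   have unique `beneficiary_id` and an `area_id` present in
#'   `exposure_table`.
#' @param survival Survival table keyed by `beneficiary_id`, either
#'   (`time_days`, `event`) or (`death_date`, `censor_date`).
#' @param exposure_table Per-area exposure (needs `area_id`, `exposed`;
#'   `cumulative_mm` and `cumulative_in` are carried through when present).
#' @param include_relocated Keep beneficiaries who relocated during
#'   follow-up (sensitivity analyses); default FALSE.
#' @param landfall_date Needed only for the date-based survival form.
#' @param covariate_cols Columns checked for missingness; defaults to the
#'   model covariates.
#' @param missing_warn_prop Warn if the complete-case exclusion exceeds
#'   this proportion of the input (default 0.03, above which the
#'   missing-completely-at-random assumption deserves scrutiny).
#' @return An `analytic_cohort`: list with `data` (joined rows) and
#'   `ledger` (named exclusion counts: `age`, `missing`, `relocated`).
#' @export
build_cohort <- function(beneficiaries, survival, exposure_table,
                         include_relocated = FALSE, landfall_date = NULL,
                         covariate_cols = c("age", "sex", "race_ethnicity",
                                            "n_comorbidities", "rurality"),
                         missing_warn_prop = 0.03) {
  check_columns(beneficiaries, c("beneficiary_id", "area_id"),
                "beneficiaries")
  if (anyDuplicated(beneficiaries$beneficiary_id))
    stopf("build_cohort: duplicate beneficiary_id",
          class = "stormcohort_validation_error")
  if (anyDuplicated(survival$beneficiary_id))
    stopf("build_cohort: duplicate survival records",
          class = "stormcohort_validation_error")
  check_columns(exposure_table, c("area_id", "exposed"), "exposure table")

  if (!all(c("time_days", "event") %in% names(survival))) {
    check_columns(survival, c("beneficiary_id", "death_date", "censor_date"),
                  "survival")
    if (is.null(landfall_date))
      stopf("build_cohort: landfall_date required for date-based survival",
            class = "stormcohort_validation_error")
    died <- !is.na(survival$death_date) & nzchar(as.character(survival$death_date))
    survival$event <- died
    end_date <- ifelse(died, as.character(survival$death_date),
                       as.character(survival$censor_date))
    survival$time_days <- elapsed_days(end_date, landfall_date)
  }

  si <- match(beneficiaries$beneficiary_id, survival$beneficiary_id)
  if (anyNA(si))
    stopf("build_cohort: beneficiaries without survival records",
          class = "stormcohort_validation_error")
  ei <- match(beneficiaries$area_id, exposure_table$area_id)
  if (anyNA(ei))
    stopf("build_cohort: area_id(s) absent from exposure table: %s",
          paste(utils::head(unique(
            beneficiaries$area_id[is.na(ei)]), 5), collapse = ", "),
          class = "stormcohort_validation_error")

  df <- beneficiaries
  df$time_days <- survival$time_days[si]
  df$event <- survival$event[si]
  df$exposed <- exposure_table$exposed[ei]
  for (col in intersect(c("cumulative_mm", "cumulative_in", "distance_km"),
                        names(exposure_table)))
    df[[col]] <- exposure_table[[col]][ei]

  n_in <- nrow(df)
  ledger <- c(age = 0L, missing = 0L, relocated = 0L)

  keep <- !is.na(df$age) & df$age >= 65
  ledger[["age"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  present <- intersect(covariate_cols, names(df))
  complete <- stats::complete.cases(df[, present, drop = FALSE])
  ledger[["missing"]] <- sum(!complete)
  if (ledger[["missing"]] > missing_warn_prop * n_in)
    warning(sprintf(
      "build_cohort: %.1f%% of rows removed as incomplete cases; %s",
      100 * ledger[["missing"]] / n_in,
      "the missing-completely-at-random assumption may not be tenable"))
  df <- df[complete, , drop = FALSE]

  if (!include_relocated && "relocated" %in% names(df)) {
    drop <- df$relocated %in% TRUE
    ledger[["relocated"]] <- sum(drop)
    df <- df[!drop, , drop = FALSE]
  }

  rownames(df) <- NULL
  structure(list(data = df, ledger = ledger, n_input = n_in,
                 include_relocated = include_relocated),
            class = "analytic_cohort")
}

#' @export
print.analytic_cohort <- function(x, ...) {
  cat(sprintf("Analytic cohort: %d of %d beneficiaries retained\n",
              nrow(x$data), x$n_input))
  cat(sprintf("  excluded  age<65: %d  incomplete: %d  relocated: %d\n",
              x$ledger[["age"]], x$ledger[["missing"]],
              x$ledger[["relocated"]]))
  cat(sprintf("  exposed: %d (%.1f%%)  deaths: %d (%.2f%%)\n",
              sum(x$data$exposed),
              100 * mean(x$data$exposed),
              sum(x$data$event),
              100 * mean(x$data$event)))
  invisible(x)
}

cohort_data <- function(cohort) {
  if (inherits(cohort, "analytic_cohort")) cohort$data
  else as.data.frame(cohort)
}
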