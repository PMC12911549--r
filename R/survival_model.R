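#' Standard vulnerable-subgroup definitions
#'
#' The subgroup set used throughout the pipeline: the whole cohort, the five
#' index chronic conditions (ADRD, CHF, COPD, DM, CKD), the oldest old
#' (age 85+), dual-eligible beneficiaries, and the Non-Hispanic Black and
#' Hispanic/Latino populations. Each entry has a `filter` (data -> logical
#' membership), `drop_covariates` (model terms removed within the subgroup:
#' race-defined subgroups drop the race covariate, since it is constant or
#' near-constant there), and `comorbidity_exclude` (a condition flag whose
#' contribution is removed from the comorbidity-count covariate inside its
#' own subgroup, where it no longer varies as a comorbidity).
#'
#' @return Named list of subgroup specifications.
#' @export
default_subgroups <- function() {
  cond <- function(flag) list(
    filter = function(df) df[[flag]] %in% TRUE,
    drop_covariates = character(),
    comorbidity_exclude = flag
  )
  list(
    overall = list(filter = function(df) rep(TRUE, nrow(df)),
                   drop_covariates = character(),
                   comorbidity_exclude = NULL),
    adrd = cond("adrd"),
    chf = cond("chf"),
    copd = cond("copd"),
    dm = cond("dm"),
    ckd = cond("ckd"),
    age_85_plus = list(filter = function(df) df$age >= 85,
                       drop_covariates = character(),
                       comorbidity_exclude = NULL),
    dual_eligible = list(filter = function(df) df$dual_eligible %in% TRUE,
                         drop_covariates = character(),
                         comorbidity_exclude = NULL),
    nh_black = list(
      filter = function(df) df$race_ethnicity == "nh_black",
      drop_covariates = "race_ethnicity",
      comorbidity_exclude = NULL),
    hispanic = list(
      filter = function(df) df$race_ethnicity == "hispanic",
      drop_covariates = "race_ethnicity",
      comorbidity_exclude = NULL)
  )
}

#' Cox proportional hazards with area-level gamma shared frailty
#'
#' The adjusted exposure-mortality model: a Cox proportional hazards fit
#' with a multiplicative gamma-distributed shared frailty on small areas,
#' estimated by penalized partial likelihood with an EM outer loop for the
#' frailty variance theta (Breslow tie handling by default). With
#' `frailty = FALSE` (or theta estimated at 0) the model reduces exactly to
#' the ordinary Cox partial likelihood. Hazard ratios are the exponentiated
#' coefficients with Wald 95% confidence intervals (z = 1.96).
#'
#' Default covariates follow the standard adjustment set: exposure, age
#' (continuous), sex, race/ethnicity, comorbidity count, rurality.
#'
#' @param cohort An `analytic_cohort` or its data (needs `time_days`,
#'   `event`, the covariates, and the cluster column).
#' @param covariates Character vector of model terms.
#' @param cluster Column defining the shared-frailty clusters; default
#'   `"area_id"`.
#' @param frailty Include the frailty term (default TRUE).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_frailty_fit`: list with `coef`, `se`, `hr`, `ci_low`,
#'   `ci_high` (named by term), `theta` (frailty variance; 0 without
#'   frailty), `loglik`, `iter`, `converged`, `n`, `n_events`,
#'   `n_clusters`, and the underlying `coxph` fit.
#' @export
fit_cox_frailty <- function(cohort,
                            covariates = c("exposed", "age", "sex",
                                           "race_ethnicity",
                                           "n_comorbidities", "rurality"),
                            cluster = "area_id", frailty = TRUE,
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  df <- cohort_data(cohort)
  check_columns(df, c("time_days", "event", covariates,
                      if (frailty) cluster), "cohort data")
  if (sum(df$event) < 1)
    stopf("fit_cox_frailty: no events",
          class = "stormcohort_degenerate_group_error")
  if (frailty && length(unique(df[[cluster]])) < 2)
    stopf("fit_cox_frailty: need at least 2 clusters for a frailty term",
          class = "stormcohort_degenerate_group_error")
  # drop covariates that do not vary (constant within a subgroup)
  varies <- vapply(covariates, function(v) length(unique(df[[v]])) > 1,
                   logical(1))
  covariates <- covariates[varies]
  if (length(covariates) == 0)
    stopf("fit_cox_frailty: no varying covariates",
          class = "stormcohort_degenerate_group_error")
  # reference levels: female, non-Hispanic White, metro
  relevel_if <- function(col, ref) {
    if (col %in% names(df) && !is.numeric(df[[col]])) {
      f <- as.factor(df[[col]])
      if (ref %in% levels(f)) f <- stats::relevel(f, ref)
      df[[col]] <<- f
    }
  }
  relevel_if("sex", "female")
  relevel_if("race_ethnicity", "nh_white")
  relevel_if("rurality", "metro")
  rhs <- paste(covariates, collapse = " + ")
  if (frailty)
    rhs <- paste0(rhs, " + survival::frailty(", cluster,
                  ", distribution = 'gamma')")
  fml <- stats::as.formula(
    paste("survival::Surv(time_days, event) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         model = TRUE)
  sm <- summary(fit)$coefficients
  keep <- !grepl("frailty\\(", rownames(sm))
  coef <- sm[keep, "coef"]
  se <- sm[keep, "se(coef)"]
  names(coef) <- names(se) <- rownames(sm)[keep]
  theta <- 0
  iter <- fit$iter[1]
  if (frailty) {
    hist <- fit$history[[1]]
    theta <- unname(utils::tail(hist$theta, 1))
    if (is.null(theta) || !length(theta)) theta <- unname(hist$theta)
    iter <- sum(fit$iter)
  }
  if (any(!is.finite(se)) || any(!is.finite(coef)))
    stopf("fit_cox_frailty: non-finite estimates (separation/collinearity?)",
          class = "stormcohort_degenerate_group_error")
  structure(list(
    coef = coef, se = se,
    hr = exp(coef),
    ci_low = exp(coef - 1.96 * se),
    ci_high = exp(coef + 1.96 * se),
    theta = theta,
    loglik = unname(utils::tail(fit$loglik, 1)),
    iter = iter,
    converged = TRUE,
    n = nrow(df), n_events = sum(df$event),
    n_clusters = if (frailty) length(unique(df[[cluster]])) else NA_integer_,
    covariates = covariates, ties = ties, frailty = frailty,
    fit = fit
  ), class = "cox_frailty_fit")
}

#' @export
print.cox_frailty_fit <- function(x, ...) {
  cat(sprintf(
    "Cox %s model: n = %d, events = %d%s\n",
    if (x$frailty) "shared-frailty (gamma)" else "proportional hazards",
    x$n, x$n_events,
    if (x$frailty) sprintf(", clusters = %d, theta = %.4g",
                           x$n_clusters, x$theta) else ""))
  tab <- data.frame(HR = sprintf("%.2f", x$hr),
                    `95% CI` = sprintf("(%.2f, %.2f)", x$ci_low, x$ci_high),
                    check.names = FALSE)
  rownames(tab) <- names(x$hr)
  print(tab)
  invisible(x)
}

## Exposure-term names as they appear in coxph output (logical or factor).
exposure_term <- function(fit) {
  nm <- names(fit$coef)
  hit <- grep("^exposed", nm)
  if (!length(hit))
    stopf("no exposure term in fit", class = "stormcohort_error")
  nm[hit[1]]
}

#' Exposure hazard ratios across vulnerable subgroups
#'
#' Refits the adjusted frailty model within each subgroup and reports the
#' exposure hazard ratio with its 95% CI — the forest-plot table. Subgroup
#' specifications control covariate handling (see [default_subgroups()]):
#' race-defined subgroups drop the race covariate, and within a
#' condition-defined subgroup that condition's flag is subtracted from the
#' comorbidity-count covariate. Subgroups too sparse to fit (< 2 clusters,
#' no events, or a degenerate exposure split) are reported with a skip
#' reason rather than failing the run.
#'
#' @param cohort An `analytic_cohort` or its data.
#' @param subgroups Named list of subgroup specifications.
#' @param covariates,cluster,frailty,ties Passed to [fit_cox_frailty()].
#' @return data.frame: `subgroup`, `n`, `events`, `hr`, `ci_low`,
#'   `ci_high`, `theta`, `converged`, `note`.
#' @export
subgroup_hrs <- function(cohort, subgroups = default_subgroups(),
                         covariates = c("exposed", "age", "sex",
                                        "race_ethnicity",
                                        "n_comorbidities", "rurality"),
                         cluster = "area_id", frailty = TRUE,
                         ties = "breslow") {
  df <- cohort_data(cohort)
  rows <- lapply(names(subgroups), function(nm) {
    spec <- subgroups[[nm]]
    sub <- df[spec$filter(df), , drop = FALSE]
    covs <- setdiff(covariates, spec$drop_covariates)
    if (!is.null(spec$comorbidity_exclude) &&
        "n_comorbidities" %in% names(sub))
      sub$n_comorbidities <-
        sub$n_comorbidities - (sub[[spec$comorbidity_exclude]] %in% TRUE)
    res <- tryCatch({
      f <- fit_cox_frailty(sub, covariates = covs, cluster = cluster,
                           frailty = frailty, ties = ties)
      term <- exposure_term(f)
      data.frame(subgroup = nm, n = f$n, events = f$n_events,
                 hr = unname(f$hr[term]), ci_low = unname(f$ci_low[term]),
                 ci_high = unname(f$ci_high[term]), theta = f$theta,
                 converged = f$converged, note = "")
    }, stormcohort_degenerate_group_error = function(e) {
      data.frame(subgroup = nm, n = nrow(sub),
                 events = sum(sub$event %in% TRUE),
                 hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 theta = NA_real_, converged = FALSE,
                 note = paste("skipped:", conditionMessage(e)))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
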