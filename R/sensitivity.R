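#' E-value for unmeasured confounding
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to fully
#' explain away an observed association: `E = RR + sqrt(RR * (RR - 1))`,
#' with protective ratios inverted first (`RR -> 1/RR`). For the confidence
#' interval, the limit closer to the null is transformed the same way; if
#' the interval crosses the null the CI E-value is 1. With a rare outcome
#' (one-year mortality of a few percent) the hazard ratio approximates the
#' risk ratio and is used directly.
#'
#' @param hr Observed hazard ratio (> 0).
#' @param ci_low,ci_high Optional 95% CI limits.
#' @return An `evalue_result`: list with `e_point` and (when a CI is given)
#'   `e_ci`.
#' @export
evalue <- function(hr, ci_low = NULL, ci_high = NULL) {
  if (!is.numeric(hr) || length(hr) != 1 || is.na(hr) || hr <= 0)
    stopf("evalue: hr must be a positive number",
          class = "stormcohort_validation_error")
  e_of <- function(rr) {
    rr <- max(rr, 1 / rr)  # direction-free strength of association
    rr + sqrt(rr * (rr - 1))
  }
  out <- list(e_point = e_of(hr), e_ci = NA_real_)
  if (!is.null(ci_low) && !is.null(ci_high)) {
    if (any(c(ci_low, ci_high) <= 0) || ci_low > hr || ci_high < hr)
      stopf("evalue: CI must be positive and bracket hr",
            class = "stormcohort_validation_error")
    out$e_ci <- if (ci_low <= 1 && ci_high >= 1) 1
                else if (hr > 1) e_of(ci_low) else e_of(ci_high)
  }
  structure(out, class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("E-value: point %.3f", x$e_point))
  if (!is.na(x$e_ci)) cat(sprintf(", CI limit %.3f", x$e_ci))
  cat("\n")
  invisible(x)
}

#' Row-standardised k-nearest-neighbour spatial weights
#'
#' Builds an n-by-n weight matrix from area centroids: each area's k
#' nearest neighbours by great-circle distance receive weight 1, rows are
#' then standardised to sum to 1. The default k = 5 is the conventional
#' neighbourhood size when polygon adjacency is unavailable and only
#' centroids are known.
#'
#' @param lat,lon Centroid coordinates.
#' @param k Number of neighbours; default 5.
#' @return n x n numeric matrix with zero diagonal, rows summing to 1.
#' @export
knn_weights <- function(lat, lon, k = 5) {
  n <- length(lat)
  if (n < 2 || k < 1 || k > n - 1)
    stopf("knn_weights: need 2 <= k+1 <= n areas",
          class = "stormcohort_validation_error")
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- haversine_km(lat[i], lon[i], lat, lon)
    d[i] <- Inf
    W[i, order(d)[seq_len(k)]] <- 1
  }
  W / rowSums(W)
}

#' Rook-adjacency weights on a regular grid
#'
#' Row-standardised rook (edge-sharing) contiguity weights for an
#' `nrow x ncol` grid, cells numbered row-major. Mainly for checking the
#' spatial statistics on analytically tractable layouts (e.g. a
#' checkerboard).
#'
#' @param nrow,ncol Grid dimensions.
#' @return Row-standardised weight matrix.
#' @export
rook_weights <- function(nrow, ncol) {
  n <- nrow * ncol
  W <- matrix(0, n, n)
  idx <- function(r, c) (r - 1) * ncol + c
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    i <- idx(r, c)
    if (r > 1) W[i, idx(r - 1, c)] <- 1
    if (r < nrow) W[i, idx(r + 1, c)] <- 1
    if (c > 1) W[i, idx(r, c - 1)] <- 1
    if (c < ncol) W[i, idx(r, c + 1)] <- 1
  }
  W / rowSums(W)
}

## Moran's I statistic for given deviations and weights.
moran_stat <- function(z, W) {
  length(z) / sum(W) * as.numeric(z %*% W %*% z) / sum(z^2)
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of area-level values:
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Significance is assessed by seeded Monte-Carlo permutation of the values
#' over the areas (default 999 permutations); the two-sided p doubles the
#' smaller tail (capped at 1), and a normal-theory z-score against the
#' permutation moments is reported alongside. Weights come either from an
#' explicit matrix `W` or from centroids via [knn_weights()].
#'
#' @param values Numeric area-level values (e.g. area-averaged residuals);
#'   must not be constant.
#' @param lat,lon Centroids (used when `W` is NULL).
#' @param W Optional weight matrix.
#' @param k Neighbours for [knn_weights()]; default 5.
#' @param nperm Permutations; default 999.
#' @param seed Permutation seed; default 1.
#' @return A `morans_result`: list with `I`, `expected` (`-1/(n-1)`),
#'   `sd_perm`, `z`, `p_value` (two-sided permutation), `p_upper`
#'   (one-sided, `P(I* >= I)`), `nperm`, `scheme`.
#' @export
morans_i <- function(values, lat = NULL, lon = NULL, W = NULL, k = 5,
                     nperm = 999, seed = 1) {
  n <- length(values)
  if (n < 3)
    stopf("morans_i: need at least 3 areas",
          class = "stormcohort_validation_error")
  if (stats::sd(values) == 0)
    stopf("morans_i: constant values; statistic undefined",
          class = "stormcohort_degenerate_input_error")
  scheme <- "user-supplied W"
  if (is.null(W)) {
    if (is.null(lat) || is.null(lon))
      stopf("morans_i: supply either W or centroids",
            class = "stormcohort_validation_error")
    W <- knn_weights(lat, lon, k)
    scheme <- sprintf("row-standardised %d-nearest-neighbour", k)
  }
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != n)
    stopf("morans_i: W must be an n x n matrix",
          class = "stormcohort_validation_error")
  z <- values - mean(values)
  I_obs <- moran_stat(z, W)
  set.seed(seed)
  I_perm <- vapply(seq_len(nperm),
                   function(i) moran_stat(sample(z), W), numeric(1))
  p_up <- (1 + sum(I_perm >= I_obs)) / (1 + nperm)
  p_lo <- (1 + sum(I_perm <= I_obs)) / (1 + nperm)
  structure(list(
    I = I_obs, expected = -1 / (n - 1),
    sd_perm = stats::sd(I_perm),
    z = (I_obs - mean(I_perm)) / stats::sd(I_perm),
    p_value = min(1, 2 * min(p_up, p_lo)),
    p_upper = p_up,
    nperm = nperm, scheme = scheme
  ), class = "morans_result")
}

#' @export
print.morans_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), z = %.2f, p = %.4f [%s, %d permutations]\n",
              x$I, x$expected, x$z, x$p_value, x$scheme, x$nperm))
  invisible(x)
}

#' Area-averaged martingale residuals
#'
#' Martingale residuals (observed event minus model-expected cumulative
#' hazard at exit) from a fitted Cox model, averaged within each area —
#' the area-level quantity screened for residual spatial autocorrelation.
#'
#' @param fit A converged [fit_cox_frailty()] result.
#' @param cohort The cohort the model was fitted on.
#' @return data.frame `area_id`, `n`, `mean_residual`.
#' @export
residuals_by_area <- function(fit, cohort) {
  if (!inherits(fit, "cox_frailty_fit"))
    stopf("residuals_by_area: fit must be a cox_frailty_fit",
          class = "stormcohort_validation_error")
  if (!isTRUE(fit$converged))
    stopf("residuals_by_area: refusing residuals from a non-converged fit",
          class = "stormcohort_validation_error")
  df <- cohort_data(cohort)
  check_columns(df, "area_id", "cohort data")
  r <- stats::residuals(fit$fit, type = "martingale")
  if (length(r) != nrow(df))
    stopf("residuals_by_area: cohort does not match the fitted data",
          class = "stormcohort_validation_error")
  agg <- stats::aggregate(r, by = list(area_id = df$area_id),
                          FUN = function(v) c(n = length(v), m = mean(v)))
  data.frame(area_id = agg$area_id, n = agg$x[, "n"],
             mean_residual = agg$x[, "m"])
}

#' Relocation-inclusive sensitivity re-analysis
#'
#' Primary analyses exclude beneficiaries who relocated during follow-up;
#' this refits the whole subgroup hazard-ratio suite including them and
#' reports the two runs side by side, the standard check that
#' post-storm relocation (a potential selection mechanism) does not drive
#' the estimates.
#'
#' @param beneficiaries,survival,exposure_table Pipeline inputs (see
#'   [build_cohort()]).
#' @param subgroups Subgroup specifications.
#' @param ... Passed to [build_cohort()] (e.g. `landfall_date`) — not to
#'   the model.
#' @return data.frame: subgroup rows with `hr_primary`, `ci_low_primary`,
#'   `ci_high_primary`, `hr_relocated`, `ci_low_relocated`,
#'   `ci_high_relocated`, and the two cohort sizes.
#' @export
relocation_sensitivity <- function(beneficiaries, survival, exposure_table,
                                   subgroups = default_subgroups(), ...) {
  prim <- build_cohort(beneficiaries, survival, exposure_table,
                       include_relocated = FALSE, ...)
  incl <- build_cohort(beneficiaries, survival, exposure_table,
                       include_relocated = TRUE, ...)
  a <- subgroup_hrs(prim, subgroups)
  b <- subgroup_hrs(incl, subgroups)
  data.frame(
    subgroup = a$subgroup,
    n_primary = a$n, hr_primary = a$hr,
    ci_low_primary = a$ci_low, ci_high_primary = a$ci_high,
    n_relocated = b$n, hr_relocated = b$hr,
    ci_low_relocated = b$ci_low, ci_high_relocated = b$ci_high
  )
}
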