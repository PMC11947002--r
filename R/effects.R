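#' Linear-interpolation sample percentile
#'
#' The fixed quantile convention used throughout the package (R's
#' type-7 linear-interpolation sample quantile) for anchoring relative
#' risks at temperature percentiles.
#'
#' @param series Non-empty numeric vector.
#' @param p Percent in `[0, 100]`.
#' @return The percentile value(s).
#' @export
empirical_percentile <- function(series, p) {
  series <- series[is.finite(series)]
  if (length(series) == 0L) abort("empty series")
  if (any(p < 0 | p > 100)) abort("`p` must be in [0, 100]")
  as.numeric(quantile(series, p / 100, type = 7, names = FALSE))
}

#' Percentile anchors of a temperature distribution
#'
#' The three temperatures the reported contrasts are anchored at: the
#' 2.5th, 50th (reference) and 97.5th percentile of the day-weighted
#' temperature series. The `source` records which distribution they
#' came from (a single zone, a region's pooled days, or the state).
#'
#' @param series Daily temperature series (degrees C).
#' @param source Label: `"zone"`, `"region"` or `"state"`.
#' @return Object of class `percentile_anchors`: `p2_5`, `p50`,
#'   `p97_5`, `source`.
#' @export
percentile_anchors <- function(series, source = "region") {
  qs <- empirical_percentile(series, c(2.5, 50, 97.5))
  structure(
    list(p2_5 = qs[1], p50 = qs[2], p97_5 = qs[3], source = source,
         series = series),
    class = "percentile_anchors"
  )
}

# cumulative contrast rows: a(x) = [R(x) - R(x0)] kron lag colsums,
# exposure index fastest, matching the cross-basis column ordering
cumulative_contrast <- function(temps, ref, spec) {
  R <- evaluate_exposure_basis(temps, spec)
  R0 <- evaluate_exposure_basis(ref, spec)
  D <- sweep(R, 2, drop(R0))
  s <- lag_basis_colsums(spec)
  do.call(cbind, lapply(seq_along(s), function(k) D * s[k]))
}

#' Overall cumulative exposure-response curve
#'
#' Reduces the fitted exposure-lag surface to the overall (lag-summed)
#' cumulative exposure-response: for each grid temperature `x`,
#' `log RR(x) = a(x) . beta_cb` with
#' `a(x) = [R(x) - R(x0)] (x) s`, `s_k = sum_l C_k(l)`, and the
#' delta-method standard error `sqrt(a V a')` from the quasi-scaled
#' covariance. 95% intervals use the normal 1.96 multiplier. At the
#' reference the curve is exactly `RR = 1` with zero standard error.
#' The minimum-risk temperature (MERT) is the grid argmin of RR, ties
#' broken toward the lowest temperature.
#'
#' @param fit A `casets_fit`.
#' @param anchors A [percentile_anchors()]; the reference is the
#'   median anchor.
#' @param grid Temperature grid; default 200 equally spaced points
#'   between the exposure-basis boundary knots. Grid points outside the
#'   boundary are refused (the natural spline extrapolates linearly
#'   there, so risks would be unflagged extrapolation).
#' @param conf_mult Normal CI multiplier (default 1.96).
#' @return Object of class `cumulative_curve`: tibble columns
#'   `temp_c`, `log_rr`, `se`, `rr`, `rr_low`, `rr_high`; attributes
#'   `reference_temp` and `mert`.
#' @export
cumulative_curve <- function(fit, anchors, grid = NULL,
                             conf_mult = 1.96) {
  stopifnot(inherits(fit, "casets_fit"),
            inherits(anchors, "percentile_anchors"))
  spec <- fit$cbspec
  bnd <- spec$exposure$boundary
  if (is.null(grid)) {
    grid <- seq(bnd[1], bnd[2], length.out = 200)
  }
  if (any(grid < bnd[1] - 1e-9 | grid > bnd[2] + 1e-9)) {
    abort("grid extends outside the exposure basis boundary")
  }
  ref <- anchors$p50
  cc <- cb_coef(fit)
  A <- cumulative_contrast(grid, ref, spec)
  log_rr <- drop(A %*% cc$beta)
  se <- sqrt(pmax(rowSums((A %*% cc$vcov) * A), 0))
  curve <- tibble(
    temp_c = grid, log_rr = log_rr, se = se,
    rr = exp(log_rr),
    rr_low = exp(log_rr - conf_mult * se),
    rr_high = exp(log_rr + conf_mult * se)
  )
  out <- structure(curve, class = c("cumulative_curve", class(curve)))
  attr(out, "reference_temp") <- ref
  attr(out, "mert") <- find_mert(out)
  out
}

#' Relative risk at a temperature percentile
#'
#' Evaluates the cumulative contrast at the temperature sitting at
#' percentile `p` of the anchor distribution, relative to the median
#' anchor. Values are returned at full precision; round only when
#' rendering tables.
#'
#' @param fit A `casets_fit`.
#' @param anchors A [percentile_anchors()].
#' @param p Percent (2.5 and 97.5 are the conventional report points).
#' @param conf_mult Normal CI multiplier.
#' @return Tibble with one row: `percentile`, `temp_c`, `rr`,
#'   `rr_low`, `rr_high`, `se_log`.
#' @export
rr_at <- function(fit, anchors, p, conf_mult = 1.96) {
  stopifnot(inherits(anchors, "percentile_anchors"))
  temp <- vapply(p, function(pp) {
    if (isTRUE(all.equal(pp, 2.5))) anchors$p2_5
    else if (isTRUE(all.equal(pp, 50))) anchors$p50
    else if (isTRUE(all.equal(pp, 97.5))) anchors$p97_5
    else empirical_percentile(anchors$series, pp)
  }, numeric(1))
  spec <- fit$cbspec
  bnd <- spec$exposure$boundary
  temp <- pmin(pmax(temp, bnd[1]), bnd[2])
  cc <- cb_coef(fit)
  A <- cumulative_contrast(temp, anchors$p50, spec)
  log_rr <- drop(A %*% cc$beta)
  se <- sqrt(pmax(rowSums((A %*% cc$vcov) * A), 0))
  tibble(
    percentile = p, temp_c = temp,
    rr = exp(log_rr),
    rr_low = exp(log_rr - conf_mult * se),
    rr_high = exp(log_rr + conf_mult * se),
    se_log = se
  )
}

#' Minimum-risk temperature of a cumulative curve
#'
#' Grid argmin of the relative risk, optionally restricted to a search
#' range; exact ties are broken toward the lowest temperature.
#'
#' @param curve A [cumulative_curve()].
#' @param search_range Optional `(low, high)` temperature interval.
#' @return The minimum-risk temperature, degrees C.
#' @export
find_mert <- function(curve, search_range = NULL) {
  tt <- curve$temp_c
  rr <- curve$rr
  if (!is.null(search_range)) {
    keep <- tt >= search_range[1] & tt <= search_range[2]
    if (!any(keep)) abort("no grid points inside `search_range`")
    tt <- tt[keep]; rr <- rr[keep]
  }
  ord <- order(rr, tt)  # lowest temperature wins ties
  tt[ord[1]]
}
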