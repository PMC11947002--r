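#' Assemble the case time-series design matrix
#'
#' Builds every right-hand-side block of the case time-series model:
#' the temperature-by-lag cross-basis, a natural cubic spline of
#' relative humidity (`rh_df` columns, default 2), a natural cubic
#' spline of day-of-year (`doy_df` columns, default 3) interacted with
#' year indicators (one spline copy per observed year, ascending), and
#' six day-of-week indicators (Sunday is the reference level). The
#' intercept and every slowly varying zone-level term are absorbed by
#' the zone-by-year-by-month strata, so no block carries an intercept
#' column. Rows with incomplete lag history (the first `max_lag` days
#' of each zone) are masked out of the likelihood.
#'
#' Columns without variation inside any stratum carry no information
#' under conditional estimation (the strata absorb them); they are
#' detected (within-stratum variance below `1e-12` on the used rows)
#' and dropped with a warning naming them.
#'
#' @param panel A zone-day panel (see [simulate_counts()] /
#'   [read_case_panel()]): needs `zone_id`, `date`, `count`, `tavg_c`,
#'   `rh_pct`, `year`, `month`, `doy`, `dow`, `stratum`, spanning at
#'   least two distinct years.
#' @param cbspec A [cross_basis_spec()]; the exposure spec is resolved
#'   against the panel's temperatures if not already resolved.
#' @param rh_df Degrees of freedom of the relative-humidity spline.
#' @param doy_df Degrees of freedom of the day-of-year spline (per
#'   year level).
#' @return Object of class `casets_design`: response `y`, matrix `X`,
#'   block index `blocks`, `stratum` factor, logical `mask` of
#'   complete-lag rows, the resolved `cbspec`, and names of dropped
#'   columns.
#' @export
build_design <- function(panel, cbspec = cross_basis_spec(),
                         rh_df = 2, doy_df = 3) {
  need <- c("zone_id", "date", "count", "tavg_c", "rh_pct", "year",
            "month", "doy", "dow", "stratum")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    abort(paste("panel is missing columns:", paste(miss, collapse = ", ")))
  }
  panel <- dplyr::arrange(as_tibble(panel), .data$zone_id, .data$date)
  if (anyDuplicated(panel[, c("zone_id", "date")])) {
    abort("panel has duplicate (zone_id, date) rows")
  }
  years <- sort(unique(panel$year))
  if (length(years) < 2L) {
    abort("panel must span at least two distinct years")
  }
  if (any(!is.finite(panel$rh_pct))) abort("relative humidity is missing")

  cb <- cross_basis(panel$tavg_c, cbspec, zone = panel$zone_id)
  mask <- cb$complete

  rh_block <- natural_cubic_basis(panel$rh_pct, spline_spec(df = rh_df))
  colnames(rh_block) <- paste0("rh", seq_len(ncol(rh_block)))

  doy_basis <- natural_cubic_basis(
    panel$doy, spline_spec(df = doy_df, boundary = c(1, 366))
  )
  doy_block <- do.call(cbind, lapply(years, function(yy) {
    b <- doy_basis * (panel$year == yy)
    colnames(b) <- paste0("doy", seq_len(ncol(b)), ".y", yy)
    b
  }))

  dow_block <- vapply(2:7, function(d) as.numeric(panel$dow == d),
                      numeric(nrow(panel)))
  colnames(dow_block) <- paste0("dow", 2:7)

  X <- cbind(cb$values, rh_block, doy_block, dow_block)
  blocks <- list(
    cb = seq_len(ncol(cb$values)),
    rh = ncol(cb$values) + seq_len(ncol(rh_block)),
    doy_year = ncol(cb$values) + ncol(rh_block) + seq_len(ncol(doy_block)),
    dow = ncol(cb$values) + ncol(rh_block) + ncol(doy_block) +
      seq_len(ncol(dow_block))
  )
  blocks <- lapply(blocks, function(ix) setNames(ix, colnames(X)[ix]))

  stratum <- factor(panel$stratum)

  # inestimable columns: constant within every stratum on the used rows
  Xu <- X[mask, , drop = FALSE]
  su <- droplevels(stratum[mask])
  g <- as.integer(su)
  ns <- tabulate(g)
  colsum <- rowsum(Xu, g)
  sqsum <- rowsum(Xu^2, g)
  within_ss <- colSums(sqsum - colsum^2 / ns)
  dropped <- colnames(X)[within_ss / nrow(Xu) < 1e-12]
  if (length(dropped)) {
    warn(paste("dropping column(s) without within-stratum variation:",
               paste(dropped, collapse = ", ")))
    keep <- setdiff(colnames(X), dropped)
    X <- X[, keep, drop = FALSE]
    blocks <- lapply(blocks, function(ix) ix[names(ix) %in% keep])
    # reindex
    blocks <- lapply(blocks, function(ix) {
      setNames(match(names(ix), colnames(X)), names(ix))
    })
  }

  structure(
    list(y = panel$count, X = X, blocks = blocks, stratum = stratum,
         mask = mask, cbspec = cb$spec, dropped = dropped,
         years = years, n_zones = length(unique(panel$zone_id))),
    class = "casets_design"
  )
}

# profile the stratum intercepts: alpha_s = log(Y_s / sum_s exp(eta))
profiled_mu <- function(eta, y, g, ysum) {
  denom <- rowsum(exp(eta), g)[, 1]
  alpha <- log(ysum) - log(denom)
  exp(eta + alpha[g])
}

poisson_ll <- function(y, mu) sum(y * log(mu + (y == 0 & mu == 0)) - mu -
                                    lgamma(y + 1))

#' Fit the conditional quasi-Poisson case time-series model
#'
#' Maximizes the Poisson log-likelihood with the stratum intercepts
#' profiled out (equivalently, the conditional likelihood given stratum
#' count totals — the case time-series estimator). The coefficient
#' vector is identical to the maximum-likelihood estimate of a Poisson
#' regression with one explicit dummy per stratum, but the strata are
#' absorbed by mean-centering inside the Newton iterations, so the fit
#' scales to thousands of strata without materializing the dummies.
#' Standard errors are quasi-Poisson: the inverse information is scaled
#' by the Pearson dispersion
#' `phi = sum((y - mu)^2 / mu) / (n - p - n_strata)`.
#'
#' Strata whose counts are all zero contribute nothing to the
#' conditional likelihood and are dropped (reported in
#' `n_strata_dropped`); masked incomplete-lag rows are excluded.
#'
#' @param design A [build_design()] result.
#' @param tol Convergence tolerance on the relative log-likelihood
#'   change.
#' @param maxit Maximum Newton iterations (with step-halving on
#'   divergence).
#' @return Object of class `casets_fit`: `beta`, `vcov`
#'   (quasi-scaled), `vcov_unscaled`, `dispersion`, `loglik` (Poisson,
#'   at the fitted values), `qaic`, `n_rows_used`, `n_strata_used`,
#'   `n_strata_dropped`, `blocks`, `cbspec`, convergence info.
#' @export
fit_conditional_quasipoisson <- function(design, tol = 1e-9,
                                         maxit = 100L) {
  stopifnot(inherits(design, "casets_design"))
  use <- design$mask
  y <- design$y[use]
  X <- design$X[use, , drop = FALSE]
  s <- droplevels(design$stratum[use])
  g <- as.integer(s)
  ysum <- rowsum(y, g)[, 1]

  # all-zero strata carry no information under conditioning
  zero_strata <- which(ysum == 0)
  n_dropped <- length(zero_strata)
  if (n_dropped > 0) {
    keep <- !(g %in% zero_strata)
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    s <- droplevels(s[keep]); g <- as.integer(s)
    ysum <- rowsum(y, g)[, 1]
  }
  n <- length(y)
  p <- ncol(X)
  S <- length(ysum)
  if (S < 1L) abort("no stratum with positive total count")

  beta <- numeric(p)
  eta <- drop(X %*% beta)
  mu <- profiled_mu(eta, y, g, ysum)
  ll <- poisson_ll(y, mu)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  repeat {
    iter <- iter + 1L
    w <- mu
    wsum <- rowsum(w, g)[, 1]
    xbar <- rowsum(X * w, g) / wsum
    Xc <- X - xbar[g, , drop = FALSE]
    info <- crossprod(Xc * sqrt(w))
    score <- drop(crossprod(X, y - mu))
    delta <- tryCatch(
      solve(info, score),
      error = function(e) {
        abort(paste0(
          "information matrix is singular; an inestimable column may ",
          "remain (within-stratum collinearity). Columns: ",
          paste(colnames(X), collapse = ", ")
        ))
      }
    )
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- drop(X %*% beta_new)
      mu_new <- profiled_mu(eta_new, y, g, ysum)
      ll_new <- poisson_ll(y, mu_new)
      if (is.finite(ll_new) && (ll_new >= ll - 1e-12)) break
      step <- step / 2
      if (step < 2^-20) {
        abort(sprintf("step-halving failed at iteration %d", iter))
      }
    }
    done <- abs(ll_new - ll) < tol * (abs(ll) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; ll <- ll_new
    if (done) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  if (!converged) {
    abort(sprintf("no convergence after %d iterations", maxit))
  }
  # information at the optimum
  w <- mu
  wsum <- rowsum(w, g)[, 1]
  xbar <- rowsum(X * w, g) / wsum
  Xc <- X - xbar[g, , drop = FALSE]
  info <- crossprod(Xc * sqrt(w))

  resid_df <- n - p - S
  if (resid_df <= 0) abort("non-positive residual degrees of freedom")
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / resid_df
  vcov_unscaled <- solve(info)
  vcov_unscaled <- (vcov_unscaled + t(vcov_unscaled)) / 2
  dimnames(vcov_unscaled) <- list(colnames(X), colnames(X))
  vcov <- vcov_unscaled * phi
  names(beta) <- colnames(X)

  fit <- structure(
    list(
      beta = beta, vcov = vcov, vcov_unscaled = vcov_unscaled,
      dispersion = phi, loglik = ll,
      n_rows_used = n, n_strata_used = S, n_strata_dropped = n_dropped,
      n_params = p, blocks = design$blocks, cbspec = design$cbspec,
      converged = converged, iterations = iter
    ),
    class = "casets_fit"
  )
  fit$qaic <- qaic(fit)
  fit
}

#' Quasi-AIC of a fitted case time-series model
#'
#' `QAIC = -2 loglik / phi_ref + 2 (p + 1)`, where `p` counts the
#' profiled regression coefficients and the `+ 1` accounts for the
#' estimated dispersion. The absorbed strata are not counted: their
#' number is identical across candidate models fitted to one panel, so
#' the constant cancels in comparisons. When several candidates are
#' compared, `phi_ref` should come from the richest model.
#'
#' @param fit A `casets_fit`.
#' @param phi_ref Reference dispersion (> 0); defaults to the fit's own.
#' @return The QAIC value.
#' @export
qaic <- function(fit, phi_ref = fit$dispersion) {
  stopifnot(phi_ref > 0)
  -2 * fit$loglik / phi_ref + 2 * (fit$n_params + 1)
}

#' Cross-basis coefficients and covariance of a fit
#'
#' @param fit A `casets_fit`.
#' @return List with `beta` (cross-basis sub-vector) and `vcov`
#'   (quasi-scaled sub-matrix), in the stored column ordering.
#' @export
cb_coef <- function(fit) {
  ix <- fit$blocks$cb
  if (length(ix) != fit$cbspec$exposure$df * fit$cbspec$lag$df) {
    abort("cross-basis block is incomplete (columns were dropped)")
  }
  list(beta = fit$beta[ix], vcov = fit$vcov[ix, ix, drop = FALSE])
}

#' @export
print.casets_fit <- function(x, ...) {
  cat("Conditional quasi-Poisson case time-series fit\n")
  cat(sprintf("  rows used: %d   strata used: %d (dropped all-zero: %d)\n",
              x$n_rows_used, x$n_strata_used, x$n_strata_dropped))
  cat(sprintf("  coefficients: %d   dispersion: %.3f   QAIC: %.1f\n",
              x$n_params, x$dispersion, x$qaic))
  invisible(x)
}
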