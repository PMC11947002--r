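#' Region-level cross-basis estimate
#'
#' The unit of meta-analytic pooling: a region label, the cross-basis
#' coefficient sub-vector with its (quasi-scaled) covariance, and the
#' fingerprint of the basis it was estimated on. Estimates can only be
#' pooled when their fingerprints match (same knots, boundaries and
#' column ordering), which in practice means the regions shared a
#' statewide knot placement.
#'
#' @param region Region label.
#' @param beta Coefficient vector.
#' @param vcov Covariance matrix.
#' @param fingerprint Basis fingerprint string (see
#'   [cb_fingerprint()]); pass the fit's spec or the string.
#' @return Object of class `region_estimate`.
#' @export
region_estimate <- function(region, beta, vcov, fingerprint) {
  beta <- as.numeric(beta)
  vcov <- as.matrix(vcov)
  if (nrow(vcov) != length(beta) || ncol(vcov) != length(beta)) {
    abort("`vcov` dimensions must match `beta`")
  }
  if (inherits(fingerprint, "cross_basis_spec")) {
    fingerprint <- cb_fingerprint(fingerprint)
  }
  structure(
    list(region = region, beta = beta, vcov = vcov,
         fingerprint = fingerprint),
    class = "region_estimate"
  )
}

#' Extract a region estimate from a fitted model
#'
#' @param fit A `casets_fit`.
#' @param region Region label to attach.
#' @return A [region_estimate()] of the cross-basis block.
#' @export
as_region_estimate <- function(fit, region) {
  cc <- cb_coef(fit)
  region_estimate(region, cc$beta, cc$vcov, cb_fingerprint(fit$cbspec))
}

check_poolable <- function(estimates) {
  if (!length(estimates)) abort("need at least one estimate")
  ok <- vapply(estimates, inherits, logical(1), "region_estimate")
  if (!all(ok)) abort("all inputs must be `region_estimate`s")
  fps <- vapply(estimates, `[[`, character(1), "fingerprint")
  if (length(unique(fps)) != 1L) {
    abort("basis fingerprints differ; refit the regions on one shared basis")
  }
  ps <- vapply(estimates, function(e) length(e$beta), integer(1))
  if (length(unique(ps)) != 1L) abort("coefficient lengths differ")
  invisible(estimates)
}

#' Fixed-effect multivariate inverse-variance pooling
#'
#' `beta_p = (sum V_r^-1)^-1 sum V_r^-1 beta_r`,
#' `V_p = (sum V_r^-1)^-1`: the multivariate fixed-effect
#' meta-analytic combination of region-specific cross-basis coefficient
#' vectors. A single input is returned unchanged (relabelled).
#'
#' @param estimates List of [region_estimate()]s with identical basis
#'   fingerprints and invertible covariances.
#' @param label Label of the pooled estimate.
#' @return A [region_estimate()] labelled `label`.
#' @export
pool_fixed <- function(estimates, label = "pooled") {
  check_poolable(estimates)
  W <- lapply(estimates, function(e) {
    tryCatch(solve(e$vcov), error = function(err) {
      abort(sprintf("singular covariance for region %s", e$region))
    })
  })
  S <- Reduce(`+`, W)
  Vp <- solve(S)
  bp <- drop(Vp %*% Reduce(`+`, Map(function(w, e) w %*% e$beta,
                                    W, estimates)))
  Vp <- (Vp + t(Vp)) / 2
  region_estimate(label, bp, Vp, estimates[[1]]$fingerprint)
}

#' Random-effects pooling by a multivariate moment estimator
#'
#' Estimates the between-region covariance `Psi` by a weighted method
#' of moments and then pools with weights `(V_r + Psi)^-1`. With
#' `W_r = V_r^-1`, `S = sum W_r`, `d_r = beta_r - beta_fixed` and
#' `M_r = W_r - W_r S^-1 W_r`, the expectation identity
#' `E[sum_r W_r d_r d_r'] = sum_r M_r V_r + (sum_r M_r) Psi`
#' gives `Psi = (sum M_r)^-1 (sum W_r d_r d_r' - sum M_r V_r)`, which
#' is symmetrized and eigenvalue-truncated to positive semi-definite.
#' In the one-dimensional case this solves exactly the classical
#' DerSimonian-Laird moment equation.
#'
#' @param estimates List of at least 2 (ideally >= 3)
#'   [region_estimate()]s.
#' @param label Label of the pooled estimate.
#' @return A [region_estimate()] with an extra element `psi`, the
#'   estimated between-region covariance.
#' @export
pool_random_mm <- function(estimates, label = "pooled") {
  check_poolable(estimates)
  m <- length(estimates)
  if (m < 2L) abort("random-effects pooling needs at least 2 estimates")
  fixed <- pool_fixed(estimates)
  W <- lapply(estimates, function(e) solve(e$vcov))
  S <- Reduce(`+`, W)
  Sinv <- solve(S)
  M <- Map(function(w) w - w %*% Sinv %*% w, W)
  P <- Reduce(`+`, Map(function(w, e) {
    d <- e$beta - fixed$beta
    w %*% d %*% t(d)
  }, W, estimates))
  A <- Reduce(`+`, Map(function(mm, e) mm %*% e$vcov, M, estimates))
  Msum <- Reduce(`+`, M)
  psi <- solve(Msum, P - A)
  psi <- (psi + t(psi)) / 2
  eg <- eigen(psi, symmetric = TRUE)
  psi <- eg$vectors %*% diag(pmax(eg$values, 0), nrow = length(eg$values)) %*%
    t(eg$vectors)
  psi <- (psi + t(psi)) / 2

  Wr <- lapply(estimates, function(e) solve(e$vcov + psi))
  Sr <- Reduce(`+`, Wr)
  Vp <- solve(Sr)
  bp <- drop(Vp %*% Reduce(`+`, Map(function(w, e) w %*% e$beta,
                                    Wr, estimates)))
  out <- region_estimate(label, bp, (Vp + t(Vp)) / 2,
                         estimates[[1]]$fingerprint)
  out$psi <- psi
  out
}
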