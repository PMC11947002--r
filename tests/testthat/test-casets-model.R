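make_panel <- function(n_zones = 3, years = 2, seed = 1, ...) {
  simulate_case_panel(null_config(n_zones, years = years, seed = seed, ...))
}

test_that("design blocks have the documented shapes", {
  panel <- make_panel(2, seed = 5)
  d <- build_design(panel)
  expect_equal(length(d$blocks$rh), 2L)              # RH spline df = 2
  expect_equal(length(d$blocks$doy_year), 3L * 2L)   # doy df = 3 per year
  expect_equal(length(d$blocks$dow), 6L)             # Sunday reference
  # default 4-column exposure basis x 3-column lag basis (lag keeps
  # its intercept so same-day effects are unconstrained)
  expect_equal(length(d$blocks$cb), 4L * 3L)
  # Sunday rows are all-zero in the DOW block
  sun <- panel$dow[order(panel$zone_id, panel$date)] == 1
  expect_true(all(d$X[sun, d$blocks$dow] == 0))
  # incomplete lag rows are masked: 7 per zone
  expect_equal(sum(!d$mask), 7L * 2L)
})

test_that("stratum-absorbed estimates equal the explicit-dummy Poisson fit", {
  panel <- make_panel(5, seed = 11)
  d <- build_design(panel)
  fit <- fit_conditional_quasipoisson(d)
  oracle <- dummy_glm_fit(d)
  expect_lt(max(abs(fit$beta - oracle$beta)), 1e-6)
  expect_lt(
    max(abs(fit$vcov_unscaled - oracle$vcov_unscaled)) /
      max(abs(oracle$vcov_unscaled)),
    1e-6
  )
  expect_equal(fit$dispersion, oracle$dispersion, tolerance = 1e-6)
})

test_that("Pearson dispersion is near 1 for Poisson-generated data", {
  panel <- make_panel(7, seed = 23, overdispersion = 1)
  expect_gte(nrow(panel), 5000)
  fit <- fit_conditional_quasipoisson(build_design(panel))
  expect_gte(fit$dispersion, 0.9)
  expect_lte(fit$dispersion, 1.1)
})

test_that("a column constant within every stratum is refused", {
  panel <- make_panel(3, seed = 31)
  d <- build_design(panel)
  # a zone-level attribute (e.g. an ICE value entered as a covariate)
  # is constant inside every zone-by-month stratum
  ordered_panel <- dplyr::arrange(panel, zone_id, date)
  zone_attr <- as.numeric(factor(ordered_panel$zone_id)) * 0.3
  d$X <- cbind(d$X, zone_ice = zone_attr)
  d$blocks$extra <- stats::setNames(ncol(d$X), "zone_ice")
  expect_error(fit_conditional_quasipoisson(d), "singular|inestimable")
})

test_that("all-zero-count strata do not affect the estimates", {
  panel <- make_panel(4, seed = 41)
  zap <- panel$zone_id == "Z002" & panel$year == 2016 & panel$month %in% 3:4
  panel$count[zap] <- 0L
  d <- build_design(panel)
  fit_full <- fit_conditional_quasipoisson(d)
  expect_equal(fit_full$n_strata_dropped, 2L)
  # remove the zero strata from the design by hand: same basis, same
  # lags, just fewer rows in the likelihood
  ordered_panel <- dplyr::arrange(panel, zone_id, date)
  zap_o <- ordered_panel$zone_id == "Z002" & ordered_panel$year == 2016 &
    ordered_panel$month %in% 3:4
  d_cut <- d
  d_cut$y <- d$y[!zap_o]
  d_cut$X <- d$X[!zap_o, , drop = FALSE]
  d_cut$stratum <- d$stratum[!zap_o]
  d_cut$mask <- d$mask[!zap_o]
  fit_cut <- fit_conditional_quasipoisson(d_cut)
  expect_lt(max(abs(fit_full$beta - fit_cut$beta)), 1e-8)
})

test_that("quasi scaling multiplies the covariance by the dispersion only", {
  panel <- make_panel(3, seed = 43, overdispersion = 2)
  fit <- fit_conditional_quasipoisson(build_design(panel))
  expect_equal(fit$vcov, fit$vcov_unscaled * fit$dispersion,
               tolerance = 1e-12)
  # Wald z changes exactly by sqrt(phi) between scaled and unscaled
  z_scaled <- fit$beta / sqrt(diag(fit$vcov))
  z_unscaled <- fit$beta / sqrt(diag(fit$vcov_unscaled))
  expect_equal(unname(z_unscaled / z_scaled),
               rep(sqrt(fit$dispersion), length(z_scaled)),
               tolerance = 1e-10)
})

test_that("shifting temperatures and knots together leaves the RR curve unchanged", {
  panel <- make_panel(3, seed = 47)
  spec1 <- cross_basis_spec()
  spec1$exposure <- resolve_spline_spec(spec1$exposure, panel$tavg_c)
  fit1 <- fit_conditional_quasipoisson(build_design(panel, spec1))
  a1 <- percentile_anchors(panel$tavg_c)
  grid1 <- seq(spec1$exposure$boundary[1], spec1$exposure$boundary[2],
               length.out = 50)
  c1 <- cumulative_curve(fit1, a1, grid = grid1)

  shift <- 10
  panel2 <- dplyr::mutate(panel, tavg_c = tavg_c + shift,
                          dewpoint_c = dewpoint_c + shift)
  panel2$rh_pct <- panel$rh_pct  # keep the confounder identical
  spec2 <- spec1
  spec2$exposure$knots <- spec1$exposure$knots + shift
  spec2$exposure$boundary <- spec1$exposure$boundary + shift
  fit2 <- fit_conditional_quasipoisson(build_design(panel2, spec2))
  a2 <- percentile_anchors(panel2$tavg_c)
  c2 <- cumulative_curve(fit2, a2, grid = grid1 + shift)
  expect_lt(max(abs(c2$log_rr - c1$log_rr)), 1e-8)
  expect_lt(max(abs(c2$se - c1$se)), 1e-8)
})

test_that("QAIC reduces to AIC at unit dispersion and penalizes parameters", {
  panel <- make_panel(3, seed = 53)
  fit <- fit_conditional_quasipoisson(build_design(panel))
  expect_equal(qaic(fit, phi_ref = 1),
               -2 * fit$loglik + 2 * (fit$n_params + 1),
               tolerance = 1e-12)
  smaller <- fit
  smaller$n_params <- fit$n_params - 3L
  expect_lt(qaic(smaller, phi_ref = 1), qaic(fit, phi_ref = 1))
})

test_that("QAIC prefers the generating lag flexibility over under/over-fits", {
  # truth constructed inside the span of the 2-interior-knot lag basis
  # (with intercept), outside the span of the 1-knot candidate
  lag_bnd <- log(c(0, 7) + 1)
  spec_true <- cross_basis_spec(
    lag = spline_spec(knots = log(c(1, 3) + 1), boundary = lag_bnd,
                      intercept = TRUE)
  )
  C <- lag_basis_matrix(spec_true)
  target <- c(0.1, 1, 0.1, 0.05, 0.5, 0.4, 0.05, 0.02)
  w <- drop(C %*% qr.solve(C, target))
  w <- w / sum(w)
  expect_true(all(w >= 0))

  candidates <- list(
    under = spline_spec(knots = log(2), boundary = lag_bnd,
                        intercept = TRUE),
    true = spline_spec(knots = log(c(1, 3) + 1), boundary = lag_bnd,
                       intercept = TRUE),
    over = spline_spec(knots = log(c(1, 2, 4) + 1), boundary = lag_bnd,
                       intercept = TRUE)
  )
  # moderate day-to-day temperature autocorrelation and a strong effect
  # so the data are informative about the lag profile, not only about
  # the cumulative total
  selected <- vapply(1:30, function(s) {
    surf <- effect_surface(
      exposure_fn = function(t) log(1.8) / 16 * (t - 16.3),
      lag_weights = w, reference = 16.3
    )
    cfg <- sim_config(n_zones = 30, temp_ar1_rho = 0.3,
                      date_start = "2016-01-01",
                      date_end = "2017-12-31", true_surface = surf,
                      seed = s)
    panel <- simulate_case_panel(cfg)
    fits <- lapply(candidates, function(ls) {
      fit_conditional_quasipoisson(
        build_design(panel, cross_basis_spec(lag = ls))
      )
    })
    qs <- vapply(fits, qaic, numeric(1),
                 phi_ref = fits$over$dispersion)
    names(qs)[which.min(qs)]
  }, character(1))
  expect_gte(mean(selected == "true"), 0.6)
})
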