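#' Join a count panel to a zone-day exposure panel
#'
#' Combines per-zone-day counts (e.g. from [aggregate_counts()]) with
#' the exposure panel (temperature, dewpoint, region) and derives
#' relative humidity, calendar fields and the zone-by-year-by-month
#' stratum key, giving an analysis-ready panel.
#'
#' @param counts Tibble `zone_id`, `date`, `count`.
#' @param exposures Tibble `zone_id`, `date`, `tavg_c`, `dewpoint_c`,
#'   and optionally `region`.
#' @return A zone-day panel tibble.
#' @export
assemble_panel <- function(counts, exposures) {
  panel <- dplyr::inner_join(counts, exposures, by = c("zone_id", "date"))
  if (nrow(panel) < nrow(counts)) {
    warn(sprintf("%d count row(s) had no exposure data and were dropped",
                 nrow(counts) - nrow(panel)))
  }
  panel |>
    dplyr::arrange(.data$zone_id, .data$date) |>
    dplyr::mutate(
      rh_pct = relative_humidity(.data$tavg_c, .data$dewpoint_c),
      year = as.integer(strftime(.data$date, "%Y")),
      month = as.integer(strftime(.data$date, "%m")),
      doy = as.integer(strftime(.data$date, "%j")),
      dow = as.integer(strftime(.data$date, "%w")) + 1L,
      stratum = paste(.data$zone_id, .data$year, .data$month, sep = ":")
    )
}

# fit one panel and summarize RRs at the requested percentiles
analyze_one <- function(panel, cbspec, percentiles, rh_df, doy_df,
                        anchor_source) {
  anchors <- percentile_anchors(panel$tavg_c, source = anchor_source)
  design <- build_design(panel, cbspec, rh_df = rh_df, doy_df = doy_df)
  fit <- fit_conditional_quasipoisson(design)
  curve <- cumulative_curve(fit, anchors)
  rrs <- rr_at(fit, anchors, percentiles)
  list(fit = fit, anchors = anchors, curve = curve, rrs = rrs,
       mert = attr(curve, "mert"))
}

result_rows <- function(stratum, subgroup, res, n_visits, n_zones) {
  tibble(
    stratum = stratum, subgroup = subgroup,
    percentile = res$rrs$percentile,
    rr = res$rrs$rr, rr_low = res$rrs$rr_low, rr_high = res$rrs$rr_high,
    n_visits = n_visits, n_zones = n_zones, mert = res$mert,
    status = "ok"
  )
}

insufficient_rows <- function(stratum, subgroup, percentiles, n_visits,
                              n_zones, reason) {
  tibble(
    stratum = stratum, subgroup = subgroup, percentile = percentiles,
    rr = NA_real_, rr_low = NA_real_, rr_high = NA_real_,
    n_visits = n_visits, n_zones = n_zones, mert = NA_real_,
    status = paste0("insufficient: ", reason)
  )
}

#' Region-stratified case time-series analysis
#'
#' Runs the full regional design on an analysis-ready panel: each
#' region is fitted separately (cross-basis, conditional quasi-Poisson,
#' cumulative relative risks at the requested percentiles against the
#' regional median, minimum-risk temperature), and a state-level row is
#' produced by a single statewide fit (`state_mode = "statewide"`),
#' by fixed-effect pooling of the regional cross-basis coefficients
#' (`"pooled"`), or both. All fits share one statewide knot placement
#' so that regional coefficient vectors are poolable and comparable.
#' A failing region is reported as insufficient without aborting the
#' others.
#'
#' @param panel Zone-day panel with a `region` column.
#' @param percentiles Percent points to report (default 2.5 and 97.5;
#'   the median is always the reference).
#' @param state_mode `"statewide"`, `"pooled"` or `"both"`.
#' @param cbspec Cross-basis spec; resolved once against the statewide
#'   temperature distribution.
#' @param rh_df,doy_df Covariate spline degrees of freedom.
#' @return A results tibble: `stratum`, `subgroup`, `percentile`,
#'   `rr`, `rr_low`, `rr_high`, `n_visits`, `n_zones`, `mert`,
#'   `status`. Full precision; round only when rendering.
#' @export
run_region_analysis <- function(panel,
                                percentiles = c(2.5, 97.5),
                                state_mode = c("statewide", "pooled",
                                               "both"),
                                cbspec = cross_basis_spec(),
                                rh_df = 2, doy_df = 3) {
  state_mode <- match.arg(state_mode)
  if (!"region" %in% names(panel)) abort("panel needs a `region` column")
  cbspec$exposure <- resolve_spline_spec(cbspec$exposure, panel$tavg_c)

  regions <- unique(panel$region)
  region_res <- list()
  rows <- list()
  for (rg in regions) {
    sub <- panel[panel$region == rg, ]
    nz <- length(unique(sub$zone_id))
    nv <- sum(sub$count)
    res <- tryCatch(
      analyze_one(sub, cbspec, percentiles, rh_df, doy_df, "region"),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[rg]] <- insufficient_rows(rg, "total", percentiles, nv, nz,
                                      conditionMessage(res))
    } else {
      region_res[[rg]] <- res
      rows[[rg]] <- result_rows(rg, "total", res, nv, nz)
    }
  }

  nz_all <- length(unique(panel$zone_id))
  nv_all <- sum(panel$count)
  if (state_mode %in% c("statewide", "both")) {
    res <- tryCatch(
      analyze_one(panel, cbspec, percentiles, rh_df, doy_df, "state"),
      error = function(e) e
    )
    rows[["state"]] <- if (inherits(res, "error")) {
      insufficient_rows("state", "total", percentiles, nv_all, nz_all,
                        conditionMessage(res))
    } else {
      result_rows("state", "total", res, nv_all, nz_all)
    }
  }
  if (state_mode %in% c("pooled", "both") && length(region_res) >= 1) {
    ests <- purrr::imap(region_res, function(r, nm) {
      as_region_estimate(r$fit, nm)
    })
    pooled <- pool_fixed(unname(ests))
    anchors <- percentile_anchors(panel$tavg_c, source = "state")
    rrs <- rr_at_estimate(pooled, cbspec, anchors, percentiles)
    curve_rr <- rr_at_estimate(
      pooled, cbspec, anchors,
      p = NULL,
      grid = seq(cbspec$exposure$boundary[1], cbspec$exposure$boundary[2],
                 length.out = 200)
    )
    rows[["pooled"]] <- tibble(
      stratum = "state_pooled", subgroup = "total",
      percentile = rrs$percentile, rr = rrs$rr, rr_low = rrs$rr_low,
      rr_high = rrs$rr_high, n_visits = nv_all, n_zones = nz_all,
      mert = curve_rr$temp_c[which.min(curve_rr$rr)], status = "ok"
    )
  }
  dplyr::bind_rows(rows)
}

#' Relative risks from a pooled coefficient vector
#'
#' Evaluates cumulative contrasts directly from a
#' [region_estimate()] (e.g. the output of [pool_fixed()]) and the
#' shared basis spec, without a `casets_fit` object.
#'
#' @param estimate A [region_estimate()].
#' @param spec The shared resolved [cross_basis_spec()].
#' @param anchors A [percentile_anchors()].
#' @param p Percent points; `NULL` to use `grid` instead.
#' @param grid Optional explicit temperature grid.
#' @param conf_mult Normal CI multiplier.
#' @return Tibble `percentile` (or `temp_c`), `rr`, `rr_low`,
#'   `rr_high`.
#' @export
rr_at_estimate <- function(estimate, spec, anchors, p = c(2.5, 97.5),
                           grid = NULL, conf_mult = 1.96) {
  if (is.null(p)) {
    temps <- grid
  } else {
    temps <- empirical_percentile(anchors$series, p)
    bnd <- spec$exposure$boundary
    temps <- pmin(pmax(temps, bnd[1]), bnd[2])
  }
  A <- cumulative_contrast(temps, anchors$p50, spec)
  log_rr <- drop(A %*% estimate$beta)
  se <- sqrt(pmax(rowSums((A %*% estimate$vcov) * A), 0))
  out <- tibble(
    temp_c = temps, rr = exp(log_rr),
    rr_low = exp(log_rr - conf_mult * se),
    rr_high = exp(log_rr + conf_mult * se)
  )
  if (!is.null(p)) out <- dplyr::mutate(out, percentile = p, .before = 1)
  out
}

subgroup_filter_args <- function(sg) {
  switch(sg,
    total = list(),
    substance = list(icd_group = "substance"),
    mood = list(icd_group = "mood"),
    anxiety = list(icd_group = "anxiety"),
    male = list(sex = "male"),
    female = list(sex = "female"),
    age_0_25 = list(age_range = c(0, 25)),
    age_26_49 = list(age_range = c(26, 49)),
    age_50_64 = list(age_range = c(50, 64)),
    age_65plus = list(age_range = c(65, Inf)),
    abort(sprintf("unknown subgroup: %s", sg))
  )
}

#' Subgroup-stratified analysis
#'
#' Refits the case time-series model on stratified data:
#' individual-level strata (diagnosis block, sex, age bins) re-count
#' the line-level records under the corresponding filter; community
#' strata (ICE income / race quartiles) subset the zones belonging to
#' each quartile while keeping all mental-health visits, mirroring the
#' convention that only the diagnosis subgroups restrict the outcome
#' codes. Strata whose total visit count falls below `min_total` are
#' reported as insufficient rather than fitted.
#'
#' @param records Line-level visit records (see [aggregate_counts()]).
#' @param exposures Zone-day exposure panel (`zone_id`, `date`,
#'   `tavg_c`, `dewpoint_c`, optionally `region`).
#' @param crosswalk Zip-to-zone crosswalk (`zip5`, `zone_id`,
#'   `weight`).
#' @param ice An [ice_table()] result, required for ICE subgroups.
#' @param subgroups Character vector from the supported vocabulary:
#'   `total`, `substance`, `mood`, `anxiety`, `male`, `female`,
#'   `age_0_25`, `age_26_49`, `age_50_64`, `age_65plus`,
#'   `ice_income_Q1..Q4`, `ice_race_Q1..Q4`.
#' @param percentiles Percent points to report.
#' @param min_total Minimum stratum visit total to attempt a fit.
#' @param cbspec,rh_df,doy_df Model settings; the exposure knots are
#'   resolved once on the full exposure panel and reused across
#'   subgroups for comparability.
#' @return A results tibble as in [run_region_analysis()].
#' @export
run_subgroups <- function(records, exposures, crosswalk, ice = NULL,
                          subgroups = c("total", "substance", "mood",
                                        "anxiety", "male", "female"),
                          percentiles = c(2.5, 97.5),
                          min_total = 1000,
                          cbspec = cross_basis_spec(),
                          rh_df = 2, doy_df = 3) {
  cbspec$exposure <- resolve_spline_spec(cbspec$exposure,
                                         exposures$tavg_c)
  zones <- sort(unique(exposures$zone_id))
  date_range <- range(exposures$date)
  rows <- list()
  for (sg in subgroups) {
    ice_m <- regmatches(sg, regexec("^ice_(income|race)_(Q[1-4])$", sg))[[1]]
    if (length(ice_m) == 3L) {
      if (is.null(ice)) abort("ICE subgroups need an `ice` table")
      qcol <- paste0(ice_m[2], "_quartile")
      sg_zones <- ice$zone_id[!is.na(ice[[qcol]]) &
                                ice[[qcol]] == ice_m[3]]
      sg_zones <- intersect(sg_zones, zones)
      counts <- aggregate_counts(records, crosswalk,
                                 date_range = date_range,
                                 zones = sg_zones)
    } else {
      args <- subgroup_filter_args(sg)
      counts <- do.call(aggregate_counts, c(
        list(records = records, crosswalk = crosswalk,
             date_range = date_range, zones = zones), args
      ))
      sg_zones <- zones
    }
    nv <- sum(counts$count)
    nz <- length(sg_zones)
    if (nz == 0L) {
      rows[[sg]] <- insufficient_rows("state", sg, percentiles, nv, 0L,
                                      "no zones in stratum")
      next
    }
    if (nv < min_total) {
      rows[[sg]] <- insufficient_rows("state", sg, percentiles, nv, nz,
                                      sprintf("fewer than %d visits",
                                              min_total))
      next
    }
    panel <- assemble_panel(counts,
                            exposures[exposures$zone_id %in% sg_zones, ])
    res <- tryCatch(
      analyze_one(panel, cbspec, percentiles, rh_df, doy_df, "state"),
      error = function(e) e
    )
    rows[[sg]] <- if (inherits(res, "error")) {
      insufficient_rows("state", sg, percentiles, nv, nz,
                        conditionMessage(res))
    } else {
      result_rows("state", sg, res, nv, nz)
    }
  }
  dplyr::bind_rows(rows)
}

#' Render a results table for reporting
#'
#' Rounds relative risks to two decimals and formats the confidence
#' interval, leaving the stored table at full precision.
#'
#' @param results A results tibble from [run_region_analysis()] /
#'   [run_subgroups()].
#' @return Tibble with a formatted `rr_ci` column.
#' @export
format_results <- function(results) {
  results |>
    dplyr::mutate(
      rr_ci = ifelse(
        is.na(.data$rr), .data$status,
        sprintf("%.2f (%.2f-%.2f)", .data$rr, .data$rr_low,
                .data$rr_high)
      )
    ) |>
    dplyr::select("stratum", "subgroup", "percentile", "rr_ci",
                  "n_visits", "n_zones", "mert")
}
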