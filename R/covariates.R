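#' Relative humidity from dewpoint and air temperature
#'
#' Computes RH (%) from daily mean temperature and dewpoint using the
#' August-Roche-Magnus saturation vapour pressure approximation
#' `e(T) = exp(17.625 T / (243.04 + T))`:
#' `RH = 100 e(dewpoint) / e(tavg)`. Rows where the dewpoint exceeds
#' the air temperature (physically impossible, occasionally produced by
#' independent interpolation of the two fields) are clamped to 100%
#' with a warning.
#'
#' @param tavg_c Daily mean air temperature, degrees C.
#' @param dewpoint_c Dewpoint temperature, degrees C.
#' @return Relative humidity in percent, in `(0, 100]`.
#' @export
relative_humidity <- function(tavg_c, dewpoint_c) {
  if (!all(is.finite(tavg_c)) || !all(is.finite(dewpoint_c))) {
    abort("temperature and dewpoint must be finite")
  }
  bad <- dewpoint_c > tavg_c
  if (any(bad)) {
    warn(sprintf("dewpoint > tavg on %d row(s); RH clamped to 100%%",
                 sum(bad)))
  }
  es <- function(t) exp(17.625 * t / (243.04 + t))
  pmin(100 * es(dewpoint_c) / es(tavg_c), 100)
}

#' Index of Concentration at the Extremes
#'
#' `ICE = (A - P) / T`: the number of persons in the advantaged extreme
#' (e.g. top income quintile, or white residents) minus the number in
#' the disadvantaged extreme (bottom quintile, or Black residents),
#' divided by the total population. Ranges from -1 (all disadvantaged)
#' to +1 (all advantaged).
#'
#' @param advantaged Persons in the advantaged extreme (>= 0).
#' @param disadvantaged Persons in the disadvantaged extreme (>= 0).
#' @param total Total population with known status (> 0); zones with
#'   `total = 0` get `NA` with a warning.
#' @return Numeric in `[-1, 1]` (NA where undefined).
#' @export
ice <- function(advantaged, disadvantaged, total) {
  if (any(advantaged < 0, na.rm = TRUE) ||
      any(disadvantaged < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  if (any(advantaged + disadvantaged > total + 1e-9, na.rm = TRUE)) {
    abort("advantaged + disadvantaged must not exceed total")
  }
  zero <- !is.na(total) & total <= 0
  if (any(zero)) {
    warn(sprintf("total population is zero for %d zone(s); ICE set to NA",
                 sum(zero)))
  }
  out <- (advantaged - disadvantaged) / total
  out[zero] <- NA_real_
  out
}

#' Quartile labels for zone-level ICE values
#'
#' Cuts zone ICE values at their sample quartiles (linear-interpolation
#' quantiles, intervals closed on the right). Orientation follows the
#' conventional reporting of these metrics: Q1 is the *highest* ICE
#' quartile (most advantaged / majority white), Q4 the lowest. With
#' degenerate cuts (ties collapsing the quartile boundaries) affected
#' zones take the most advantaged label consistent with their value, so
#' an all-equal vector is labelled Q1 throughout.
#'
#' @param values Numeric ICE values (>= 4 non-missing).
#' @return Factor with levels `Q1..Q4`, `NA` where `values` is `NA`.
#' @export
ice_quartiles <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) abort("need at least 4 non-missing values")
  qs <- quantile(values[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- rep(NA_character_, length(values))
  v <- values[ok]
  # descending orientation: above the 75th percentile -> Q1, etc.
  # right-closed intervals on the original scale mean a value exactly at
  # a cut joins the *lower* interval, i.e. the more advantaged label.
  l <- rep("Q1", length(v))
  l[v <= qs[3]] <- "Q2"
  l[v <= qs[2]] <- "Q3"
  l[v <= qs[1]] <- "Q4"
  # degenerate cuts: ties at a collapsed boundary take the most
  # advantaged of the labels sharing that boundary value
  if (qs[1] == qs[2]) l[v == qs[1]] <- "Q3"
  if (qs[2] == qs[3]) l[v == qs[2]] <- "Q2"
  if (qs[3] == max(v)) l[v == qs[3]] <- "Q1"
  if (qs[1] == qs[2] && qs[2] == qs[3]) l[v == qs[1]] <- "Q1"
  lab[ok] <- l
  factor(lab, levels = paste0("Q", 1:4))
}

#' Build a zone ICE table with quartile labels
#'
#' @param zones Data frame with columns `zone_id`, and per metric the
#'   advantaged / disadvantaged / total counts:
#'   `income_adv`, `income_dis`, `income_total`,
#'   `race_adv`, `race_dis`, `race_total`.
#' @return Tibble with `zone_id`, `ice_income`, `ice_race`,
#'   `income_quartile`, `race_quartile`.
#' @export
ice_table <- function(zones) {
  need <- c("zone_id", "income_adv", "income_dis", "income_total",
            "race_adv", "race_dis", "race_total")
  miss <- setdiff(need, names(zones))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  out <- tibble(
    zone_id = zones$zone_id,
    ice_income = ice(zones$income_adv, zones$income_dis, zones$income_total),
    ice_race = ice(zones$race_adv, zones$race_dis, zones$race_total)
  )
  out$income_quartile <- ice_quartiles(out$ice_income)
  out$race_quartile <- ice_quartiles(out$ice_race)
  out
}

#' Area-weighted aggregation of gridded values to zones
#'
#' Collapses grid-cell values (e.g. 4 km gridded daily temperature) to
#' zone values with a precomputed cell-to-zone weight table:
#' `sum(w_g x_g) / sum(w_g)` per zone. Weights are typically
#' intersection areas; any rescaling of the weights leaves the result
#' unchanged.
#'
#' @param grid Data frame with columns `cell_id`, `value`.
#' @param weights Data frame with columns `cell_id`, `zone_id`,
#'   `weight` (>= 0; every zone needs positive total weight).
#' @return Tibble `zone_id`, `value`.
#' @export
area_weighted_mean <- function(grid, weights) {
  if (any(weights$weight < 0)) abort("weights must be non-negative")
  joined <- dplyr::inner_join(weights, grid, by = "cell_id")
  out <- joined |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(
      wsum = sum(.data$weight),
      value = sum(.data$weight * .data$value) / sum(.data$weight),
      .groups = "drop"
    )
  if (any(out$wsum <= 0)) {
    abort(paste("zone(s) with zero total weight:",
                paste(out$zone_id[out$wsum <= 0], collapse = ", ")))
  }
  dplyr::select(out, "zone_id", "value")
}

#' Classify an ICD-10 code into the mental-disorder subgroups
#'
#' Parses the leading letter and two digits (suffixes after the decimal
#' point are ignored; bare three-character codes are allowed) and maps
#' the F00-F99 chapter into the analysis subgroups: F10-F19 psychoactive
#' substance use, F30-F39 mood disorders, F40-F49 anxiety disorders,
#' any other F code `other_mbd` (counted in totals only). Non-F or
#' unparseable codes are `excluded`.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Factor with levels `substance`, `mood`, `anxiety`,
#'   `other_mbd`, `excluded`.
#' @export
classify_icd10 <- function(code) {
  code <- trimws(as.character(code))
  m <- regmatches(code, regexec("^([A-Za-z])([0-9]{2})", code))
  out <- vapply(m, function(g) {
    if (length(g) != 3L) return("excluded")
    if (toupper(g[2]) != "F") return("excluded")
    num <- as.integer(g[3])
    if (num >= 10 && num <= 19) "substance"
    else if (num >= 30 && num <= 39) "mood"
    else if (num >= 40 && num <= 49) "anxiety"
    else "other_mbd"
  }, character(1))
  n_bad <- sum(out == "excluded")
  if (n_bad > 0) {
    inform(sprintf("%d record(s) excluded (non-F00-F99 or unparseable)",
                   n_bad))
  }
  factor(out, levels = c("substance", "mood", "anxiety", "other_mbd",
                         "excluded"))
}

#' Aggregate line-level visit records to a zone-day count panel
#'
#' Applies subgroup filters (diagnosis block, age range, sex) to
#' line-level ED visit records, maps 5-digit zip codes to analysis
#' zones through a crosswalk (one-to-many zips resolved to the
#' largest-weight zone), and counts visits per zone-day over the full
#' date range, filling zero-visit days explicitly. Total counts are
#' conserved: the panel sums to the number of retained records.
#'
#' @param records Data frame with columns `admission_date` (Date),
#'   `zip5`, `icd10_code`, `age_years`, `sex` (`"male"`/`"female"`).
#' @param crosswalk Data frame `zip5`, `zone_id`, `weight`; zips absent
#'   from the crosswalk are dropped with a message.
#' @param date_range Length-2 Date vector for the panel; defaults to
#'   the record range.
#' @param zones Zones forming the panel; defaults to the crosswalk
#'   zones observed in the retained records.
#' @param icd_group Optional subset of
#'   `c("substance", "mood", "anxiety", "other_mbd")`; default keeps
#'   the whole F00-F99 chapter.
#' @param age_range Optional inclusive integer age range `c(lo, hi)`.
#' @param sex Optional `"male"` or `"female"`.
#' @return Tibble `zone_id`, `date`, `count` covering every zone-day.
#' @export
aggregate_counts <- function(records, crosswalk,
                             date_range = NULL, zones = NULL,
                             icd_group = NULL, age_range = NULL,
                             sex = NULL) {
  stopifnot(all(c("admission_date", "zip5", "icd10_code", "age_years",
                  "sex") %in% names(records)))
  records <- as_tibble(records)
  records$admission_date <- as.Date(records$admission_date)
  if (is.null(date_range)) date_range <- range(records$admission_date)
  date_range <- as.Date(date_range)
  if (date_range[1] > date_range[2]) abort("empty date range")

  grp <- classify_icd10(records$icd10_code)
  keep <- grp != "excluded"
  if (!is.null(icd_group)) keep <- keep & grp %in% icd_group
  if (!is.null(age_range)) {
    keep <- keep & records$age_years >= age_range[1] &
      records$age_years <= age_range[2]
  }
  if (!is.null(sex)) keep <- keep & records$sex == sex
  rec <- records[keep & !is.na(keep), ]

  # one-to-many zip -> zone resolved by largest weight
  cw <- as_tibble(crosswalk) |>
    dplyr::group_by(.data$zip5) |>
    dplyr::slice_max(.data$weight, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("zip5", "zone_id")
  n_before <- nrow(rec)
  rec <- dplyr::inner_join(rec, cw, by = "zip5")
  if (nrow(rec) < n_before) {
    inform(sprintf("%d record(s) dropped: zip not in crosswalk",
                   n_before - nrow(rec)))
  }
  rec <- rec[rec$admission_date >= date_range[1] &
               rec$admission_date <= date_range[2], ]

  if (is.null(zones)) zones <- sort(unique(cw$zone_id))
  skeleton <- tidyr::expand_grid(
    zone_id = zones,
    date = seq(date_range[1], date_range[2], by = "day")
  )
  counted <- rec |>
    dplyr::count(.data$zone_id, date = .data$admission_date,
                 name = "count")
  skeleton |>
    dplyr::left_join(counted, by = c("zone_id", "date")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
}
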