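#' True exposure-lag-response surface for simulation
#'
#' A generative truth for recovery tests: a cumulative exposure-response
#' function on the log-RR scale (zero at its reference temperature) and
#' a vector of eight non-negative lag weights summing to one that
#' distribute the cumulative effect over lags 0-7.
#'
#' @param exposure_fn Function mapping temperature (degrees C) to the
#'   *cumulative* log relative risk vs `reference`.
#' @param lag_weights Numeric length `max_lag + 1`, non-negative,
#'   summing to 1. Default: geometric decay (more effect at short lags).
#' @param reference Reference temperature at which `exposure_fn` is 0.
#' @param max_lag Lag window length (default 7).
#' @return Object of class `effect_surface`.
#' @export
effect_surface <- function(exposure_fn = function(t) rep(0, length(t)),
                           lag_weights = NULL,
                           reference = 0,
                           max_lag = 7L) {
  if (is.null(lag_weights)) {
    lag_weights <- 0.6^(0:max_lag)
    lag_weights <- lag_weights / sum(lag_weights)
  }
  if (length(lag_weights) != max_lag + 1L) {
    abort(sprintf("`lag_weights` must have length %d", max_lag + 1L))
  }
  if (any(lag_weights < 0) || abs(sum(lag_weights) - 1) > 1e-12) {
    abort("`lag_weights` must be non-negative and sum to 1")
  }
  if (abs(exposure_fn(reference)) > 1e-12) {
    abort("`exposure_fn(reference)` must be 0")
  }
  structure(
    list(exposure_fn = exposure_fn, lag_weights = lag_weights,
         reference = reference, max_lag = as.integer(max_lag)),
    class = "effect_surface"
  )
}

#' True cumulative relative risk of a simulation surface
#'
#' @param surface An [effect_surface()].
#' @param temp Temperature(s), degrees C.
#' @return `exp(exposure_fn(temp))`; equals 1 at the reference.
#' @export
true_cumulative_rr <- function(surface, temp) {
  stopifnot(inherits(surface, "effect_surface"))
  exp(surface$exposure_fn(temp))
}

#' Simulation configuration for the synthetic zone-day panel
#'
#' Defaults emulate a four-year, state-wide emergency department panel
#' over three physiographic regions with a humid-subtropical climate:
#' regional annual mean temperatures of 13.5/16.3/17.6 degrees C
#' (mountains / piedmont / coast), a 12 degree seasonal sinusoid peaking
#' in mid July, AR(1) day-to-day anomalies, dewpoint a few degrees
#' below air temperature (relative humidity around 70%), and roughly
#' five visits per zone-day with mild overdispersion.
#'
#' @param n_zones Number of zones.
#' @param region_labels Region per zone; default splits zones
#'   proportionally across Mountains / Piedmont / Coast (1:3:2, roughly
#'   the state's zone shares).
#' @param date_start,date_end Panel date range; must span at least two
#'   full years so the zone-by-year-by-month strata are populated.
#' @param temp_mean_annual Named numeric, annual mean temperature per
#'   region (degrees C).
#' @param temp_seasonal_amplitude Seasonal sinusoid amplitude (degrees C).
#' @param temp_ar1_rho AR(1) coefficient of daily anomalies, in `[0, 1)`.
#' @param temp_noise_sd AR(1) innovation standard deviation (degrees C).
#' @param dewpoint_depression_mean,dewpoint_depression_sd Mean / SD of
#'   the (non-negative) dewpoint depression draw (degrees C).
#' @param baseline_rate Expected visits per zone-day at covariate zero.
#' @param stratum_sd SD of zone-by-year-by-month log-baseline deviations.
#' @param dow_effects Seven log-rate offsets, Sunday first.
#' @param seasonal_effect_amplitude Amplitude of the smooth seasonal
#'   log-rate term (peaks at the start of January).
#' @param overdispersion Variance inflation factor `>= 1`; 1 gives
#'   Poisson counts, otherwise gamma-mixed Poisson (negative binomial)
#'   with `Var = overdispersion * mean`.
#' @param true_surface An [effect_surface()]; default is a null surface.
#' @param seed Master integer seed; per-zone substreams are derived
#'   from it so that adding zones does not perturb existing ones.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_zones = 10,
                       region_labels = NULL,
                       date_start = as.Date("2016-01-01"),
                       date_end = as.Date("2019-12-31"),
                       temp_mean_annual = c(Mountains = 13.5,
                                            Piedmont = 16.3,
                                            Coast = 17.6),
                       temp_seasonal_amplitude = 12,
                       temp_ar1_rho = 0.7,
                       temp_noise_sd = 2.5,
                       dewpoint_depression_mean = 5,
                       dewpoint_depression_sd = 3,
                       baseline_rate = 5,
                       stratum_sd = 0.1,
                       dow_effects = c(0.05, 0, -0.02, -0.02, -0.01,
                                       0.01, 0.04),
                       seasonal_effect_amplitude = 0.05,
                       overdispersion = 1.5,
                       true_surface = effect_surface(),
                       seed = 1L) {
  n_zones <- as.integer(n_zones)
  if (is.null(region_labels)) {
    shares <- c(Mountains = 1, Piedmont = 3, Coast = 2) / 6
    cum <- cumsum(shares)
    frac <- (seq_len(n_zones) - 0.5) / n_zones
    region_labels <- names(shares)[findInterval(frac, c(0, cum),
                                                rightmost.closed = TRUE)]
  }
  if (length(region_labels) != n_zones) {
    abort("`region_labels` must have one entry per zone")
  }
  if (!all(region_labels %in% names(temp_mean_annual))) {
    abort("every region label needs an entry in `temp_mean_annual`")
  }
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (as.numeric(date_end - date_start) < 2 * 365 - 1) {
    abort("date range must span at least two full years")
  }
  if (baseline_rate <= 0) abort("`baseline_rate` must be > 0")
  if (overdispersion < 1) abort("`overdispersion` must be >= 1")
  if (temp_ar1_rho < 0 || temp_ar1_rho >= 1) {
    abort("`temp_ar1_rho` must be in [0, 1)")
  }
  if (length(dow_effects) != 7L) abort("`dow_effects` must have length 7")
  structure(
    list(
      n_zones = n_zones,
      zone_ids = sprintf("Z%03d", seq_len(n_zones)),
      region_labels = region_labels,
      date_start = date_start, date_end = date_end,
      temp_mean_annual = temp_mean_annual,
      temp_seasonal_amplitude = temp_seasonal_amplitude,
      temp_ar1_rho = temp_ar1_rho,
      temp_noise_sd = temp_noise_sd,
      dewpoint_depression_mean = dewpoint_depression_mean,
      dewpoint_depression_sd = dewpoint_depression_sd,
      baseline_rate = baseline_rate,
      stratum_sd = stratum_sd,
      dow_effects = dow_effects,
      seasonal_effect_amplitude = seasonal_effect_amplitude,
      overdispersion = overdispersion,
      true_surface = true_surface,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# deterministic per-zone substream seeds (two per zone: temperature
# stream, count stream, interleaved): the prefix property of a fixed
# master stream means zone k's seeds are unchanged when n_zones grows
zone_seeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sample.int(.Machine$integer.max, 2L * config$n_zones)
}

sim_dates <- function(config) {
  seq(config$date_start, config$date_end, by = "day")
}

# seasonal temperature cycle, peaking around July 20 (doy 201)
seasonal_temp <- function(doy, amplitude) {
  amplitude * cos(2 * pi * (doy - 201) / 365.25)
}

#' Simulate one zone's daily temperature and dewpoint series
#'
#' Mean temperature is the zone's regional annual mean plus a seasonal
#' sinusoid plus stationary AR(1) noise; the dewpoint is the
#' temperature minus a non-negative depression draw, so
#' `dewpoint <= tavg` on every day (derived RH is then always <= 100%).
#' Reproducible: each zone has its own substream of the master seed.
#'
#' @param config A [sim_config()].
#' @param zone Zone id (e.g. `"Z001"`) or integer index.
#' @return Tibble `date`, `tavg_c`, `dewpoint_c`.
#' @export
simulate_temperature <- function(config, zone) {
  stopifnot(inherits(config, "sim_config"))
  zi <- if (is.numeric(zone)) as.integer(zone) else {
    match(zone, config$zone_ids)
  }
  if (is.na(zi) || zi < 1L || zi > config$n_zones) {
    abort(sprintf("unknown zone id: %s", as.character(zone)))
  }
  dates <- sim_dates(config)
  n <- length(dates)
  doy <- as.integer(strftime(dates, "%j"))
  m <- config$temp_mean_annual[[config$region_labels[zi]]]

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(zone_seeds(config)[2L * zi - 1L])

  rho <- config$temp_ar1_rho
  sd_i <- config$temp_noise_sd
  eps <- numeric(n)
  if (sd_i > 0) {
    e <- rnorm(n, 0, sd_i)
    eps[1] <- e[1] / sqrt(1 - rho^2)  # stationary start
    if (n > 1) for (t in 2:n) eps[t] <- rho * eps[t - 1] + e[t]
  }
  tavg <- m + seasonal_temp(doy, config$temp_seasonal_amplitude) + eps
  depression <- pmax(0, rnorm(n, config$dewpoint_depression_mean,
                              config$dewpoint_depression_sd))
  tibble(date = dates, tavg_c = tavg, dewpoint_c = tavg - depression)
}

#' Simulate all zones' temperature series
#'
#' @inheritParams simulate_temperature
#' @return Tibble `zone_id`, `region`, `date`, `tavg_c`, `dewpoint_c`.
#' @export
simulate_temperatures <- function(config) {
  purrr::map_dfr(seq_len(config$n_zones), function(zi) {
    dplyr::mutate(
      simulate_temperature(config, zi),
      zone_id = config$zone_ids[zi],
      region = config$region_labels[zi],
      .before = 1
    )
  })
}

#' Simulate zone-day counts over temperature series
#'
#' Draws daily counts whose log-mean is the case time-series data
#' generating process: a zone-by-year-by-month baseline stratum, a
#' day-of-week offset, a smooth seasonal sinusoid in day-of-year, and
#' the injected lagged temperature effect
#' `sum_l lag_weights[l] * exposure_fn(temp[t - l])`. The first
#' `max_lag` days of each zone pad the missing history by repeating the
#' first observed temperature (the fitter instead drops those rows; on
#' long series the two conventions agree up to negligible edge effects).
#' Counts are Poisson, or gamma-mixed Poisson (negative binomial with
#' `size = mu / (phi - 1)`, hence `Var = phi * mu`) when
#' `overdispersion = phi > 1`.
#'
#' @param config A [sim_config()].
#' @param temps Optional temperature panel from
#'   [simulate_temperatures()]; simulated from `config` when `NULL`.
#'   Must cover every zone-day.
#' @return A zone-day panel tibble: `zone_id`, `region`, `date`,
#'   `count`, `tavg_c`, `dewpoint_c`, `rh_pct`, `year`, `month`, `doy`,
#'   `dow`, `stratum`.
#' @export
simulate_counts <- function(config, temps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(temps)) temps <- simulate_temperatures(config)
  dates <- sim_dates(config)
  for (z in config$zone_ids) {
    have <- temps$date[temps$zone_id == z]
    if (!all(dates %in% have)) {
      abort(sprintf("missing temperature days for zone %s", z))
    }
  }
  temps <- dplyr::arrange(temps, .data$zone_id, .data$date)
  surface <- config$true_surface
  L <- surface$max_lag

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  seeds <- zone_seeds(config)

  panels <- purrr::map(seq_len(config$n_zones), function(zi) {
    z <- config$zone_ids[zi]
    tz <- temps[temps$zone_id == z, ]
    n <- nrow(tz)
    doy <- as.integer(strftime(tz$date, "%j"))
    year <- as.integer(strftime(tz$date, "%Y"))
    month <- as.integer(strftime(tz$date, "%m"))
    dow <- as.integer(strftime(tz$date, "%w")) + 1L  # Sunday = 1

    # count-side substream, disjoint from the temperature substream
    set.seed(seeds[2L * zi])

    # lagged cumulative effect with repeated-first-value padding
    fx <- surface$exposure_fn(tz$tavg_c)
    eff <- numeric(n)
    for (l in 0:L) {
      idx <- pmax(seq_len(n) - l, 1L)
      eff <- eff + surface$lag_weights[l + 1L] * fx[idx]
    }

    ym <- paste(year, month, sep = "-")
    ym_levels <- unique(ym)
    strat_dev <- if (config$stratum_sd > 0) {
      rnorm(length(ym_levels), 0, config$stratum_sd)
    } else {
      rep(0, length(ym_levels))
    }
    names(strat_dev) <- ym_levels

    log_mu <- log(config$baseline_rate) + strat_dev[ym] +
      config$dow_effects[dow] +
      config$seasonal_effect_amplitude * cos(2 * pi * (doy - 1) / 365.25) +
      eff
    mu <- exp(log_mu)
    phi <- config$overdispersion
    count <- if (phi > 1) {
      rnbinom(n, size = mu / (phi - 1), mu = mu)
    } else {
      rpois(n, mu)
    }
    tibble(
      zone_id = z, region = config$region_labels[zi], date = tz$date,
      count = as.integer(count), tavg_c = tz$tavg_c,
      dewpoint_c = tz$dewpoint_c,
      rh_pct = relative_humidity(tz$tavg_c, tz$dewpoint_c),
      year = year, month = month, doy = doy, dow = dow,
      stratum = paste(z, year, month, sep = ":")
    )
  })
  dplyr::bind_rows(panels)
}

#' Simulate a full case time-series panel
#'
#' Convenience wrapper: temperatures then counts, returning the
#' analysis-ready zone-day panel.
#'
#' @inheritParams simulate_counts
#' @return See [simulate_counts()].
#' @export
simulate_case_panel <- function(config) {
  simulate_counts(config, simulate_temperatures(config))
}

#' Write a simulated panel and its generative truth to disk
#'
#' @param panel A panel from [simulate_case_panel()].
#' @param config The [sim_config()] that produced it.
#' @param panel_path CSV output path for the panel.
#' @param truth_path Optional JSON output path for the surface truth
#'   (reference temperature and lag weights; the exposure function is
#'   tabulated on a temperature grid).
#' @return `panel_path`, invisibly.
#' @export
write_case_panel <- function(panel, config, panel_path,
                             truth_path = NULL) {
  out <- panel[, c("zone_id", "date", "count", "tavg_c", "dewpoint_c",
                   "region")]
  utils::write.csv(out, panel_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    s <- config$true_surface
    grid <- seq(min(panel$tavg_c), max(panel$tavg_c), length.out = 101)
    jsonlite::write_json(
      list(reference = s$reference, lag_weights = s$lag_weights,
           temp_grid = grid, cumulative_log_rr = s$exposure_fn(grid)),
      truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(panel_path)
}

#' Read a zone-day panel from CSV
#'
#' Re-derives the calendar fields, relative humidity and stratum key
#' from the stored columns.
#'
#' @param path CSV with columns `zone_id`, `date`, `count`, `tavg_c`,
#'   `dewpoint_c`, `region`.
#' @return A zone-day panel tibble as from [simulate_counts()].
#' @export
read_case_panel <- function(path) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  raw$date <- as.Date(raw$date)
  raw |>
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
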