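#' Natural cubic spline specification
#'
#' A `spline_spec` describes one marginal basis of the model: a natural
#' cubic spline given either by its degrees of freedom (interior knots
#' then placed at equally spaced sample quantiles when the spec is
#' resolved against data) or by explicit interior knots, plus boundary
#' knots beyond which the basis extrapolates linearly.
#'
#' With the natural (second-derivative-zero) constraints and no
#' intercept column, `df = length(knots) + 1`.
#'
#' @param df Integer degrees of freedom (columns of the basis). Ignored
#'   when `knots` is given.
#' @param knots Numeric vector of interior knots, strictly inside
#'   `boundary`.
#' @param boundary Length-2 numeric: boundary knots `(low, high)`. When
#'   `NULL`, taken as the data range at resolution time.
#' @param intercept Include an intercept column? Defaults to `FALSE`
#'   because in the case time-series model all intercepts are absorbed
#'   by the strata.
#' @param type `"ns"` (natural cubic spline, the default) or the
#'   degenerate one-column marginals `"linear"` (`R(x) = x`) and
#'   `"constant"` (`R(x) = 1`), which exist mainly for closed-form
#'   reductions of the cross-basis (a linear-by-constant cross-basis
#'   is the moving sum over the lag window).
#' @return An object of class `spline_spec`.
#' @seealso [natural_cubic_basis()], [cross_basis_spec()]
#' @export
spline_spec <- function(df = NULL, knots = NULL, boundary = NULL,
                        intercept = FALSE,
                        type = c("ns", "linear", "constant")) {
  type <- match.arg(type)
  if (type != "ns") {
    return(structure(
      list(df = 1L, knots = numeric(0),
           boundary = if (is.null(boundary)) NULL else as.numeric(boundary),
           intercept = FALSE, type = type),
      class = "spline_spec"
    ))
  }
  if (is.null(df) && is.null(knots)) {
    abort("one of `df` or `knots` must be supplied")
  }
  if (!is.null(boundary)) {
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2L || !all(is.finite(boundary)) ||
        boundary[1] >= boundary[2]) {
      abort("`boundary` must be (low, high) with low < high")
    }
  }
  if (!is.null(knots)) {
    knots <- sort(as.numeric(knots))
    if (!is.null(boundary) &&
        (any(knots <= boundary[1]) || any(knots >= boundary[2]))) {
      abort("interior knots must lie strictly inside the boundary")
    }
    df <- length(knots) + 1L + as.integer(intercept)
  } else {
    df <- as.integer(df)
    if (df < 1L) abort("`df` must be >= 1")
  }
  structure(
    list(df = df, knots = knots, boundary = boundary,
         intercept = isTRUE(intercept), type = "ns"),
    class = "spline_spec"
  )
}

# evaluate any marginal basis type
basis_eval <- function(x, spec) {
  switch(spec$type,
    ns = natural_cubic_basis(x, spec),
    linear = matrix(as.numeric(x), ncol = 1,
                    dimnames = list(NULL, "s1")),
    constant = matrix(1, nrow = length(x), ncol = 1,
                      dimnames = list(NULL, "s1"))
  )
}

#' Resolve a spline specification against data
#'
#' Fills in data-dependent pieces of a [spline_spec()]: a `NULL`
#' boundary becomes the data range, and when only `df` was given the
#' interior knots are placed at equally spaced quantiles of `x`
#' (e.g. `df = 4` without intercept puts knots at the 25th/50th/75th
#' percentiles). A resolved spec is frozen: re-resolving it against new
#' data is a no-op, which is what lets a fitted model be re-evaluated at
#' new temperatures.
#'
#' @param spec A [spline_spec()].
#' @param x Numeric data vector.
#' @return A fully resolved `spline_spec` (explicit knots and boundary).
#' @export
resolve_spline_spec <- function(spec, x) {
  stopifnot(inherits(spec, "spline_spec"))
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("no finite data to resolve spline spec against")
  if (is.null(spec$boundary)) spec$boundary <- range(x)
  if (spec$type != "ns") return(spec)
  if (is.null(spec$knots)) {
    n_interior <- spec$df - 1L - as.integer(spec$intercept)
    if (n_interior < 0L) abort("`df` too small for an intercept basis")
    if (n_interior > 0L) {
      probs <- seq_len(n_interior) / (n_interior + 1)
      kn <- as.numeric(quantile(x, probs, type = 7, names = FALSE))
      # clamp strictly inside the boundary to keep ns() well defined
      eps <- 1e-8 * diff(spec$boundary)
      kn <- pmin(pmax(kn, spec$boundary[1] + eps), spec$boundary[2] - eps)
      spec$knots <- kn
    } else {
      spec$knots <- numeric(0)
    }
  }
  spec
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the `n x df` basis matrix of the natural cubic spline
#' described by `spec`, evaluated at `x`. The spanned space is cubic
#' between knots with zero second derivative at and beyond the boundary
#' knots, so evaluation outside the boundary continues the tangent line.
#'
#' @param x Numeric vector of evaluation points (finite).
#' @param spec A resolved [spline_spec()]; an unresolved spec is
#'   resolved against `x` first.
#' @return Numeric matrix with `length(x)` rows and `spec$df` columns.
#' @export
natural_cubic_basis <- function(x, spec) {
  if (!all(is.finite(x))) abort("`x` must be finite")
  if (spec$type != "ns") abort("spec is not a natural cubic spline")
  spec <- resolve_spline_spec(spec, x)
  if (length(spec$knots) &&
      (any(spec$knots <= spec$boundary[1]) ||
       any(spec$knots >= spec$boundary[2]))) {
    abort("interior knots must lie strictly inside the boundary")
  }
  b <- splines::ns(
    x,
    knots = if (length(spec$knots)) spec$knots else NULL,
    Boundary.knots = spec$boundary,
    intercept = spec$intercept
  )
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

#' Cross-basis specification for a distributed lag non-linear model
#'
#' Describes the bi-dimensional exposure-lag basis `cb()`: a natural
#' cubic spline over temperature (the exposure dimension) tensored with
#' a natural cubic spline over lags `0..max_lag`. The default lag basis
#' places one interior knot at lag 1 with knots on the `log(lag + 1)`
#' scale, giving more resolution at short delays over a 0-7 day window.
#' The default exposure basis uses interior knots at the 25th/50th/75th
#' percentiles of the series it is resolved against, with boundary
#' knots at the series range.
#'
#' @param exposure [spline_spec()] for the exposure (temperature)
#'   dimension. Default: `spline_spec(df = 4)` (three quantile knots).
#' @param lag [spline_spec()] for the lag dimension, on the transformed
#'   lag scale. Default: one interior knot at lag 1.
#' @param max_lag Maximum lag in days (window `0..max_lag`).
#' @param lag_knot_scale `"log"` (knots and evaluation on `log(l + 1)`)
#'   or `"linear"`.
#' @return An object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(exposure = spline_spec(df = 4),
                             lag = NULL,
                             max_lag = 7L,
                             lag_knot_scale = c("log", "linear")) {
  lag_knot_scale <- match.arg(lag_knot_scale)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) abort("`max_lag` must be >= 1")
  tr <- if (lag_knot_scale == "log") function(l) log(l + 1) else identity
  if (is.null(lag)) {
    # the lag dimension keeps its intercept: the lag-constant component
    # of the surface is a genuine covariate (an 8-day moving average of
    # the exposure basis), not an overall intercept the strata absorb;
    # without it the ns() basis would pin the same-day effect to zero
    lag <- spline_spec(knots = tr(1), boundary = tr(c(0, max_lag)),
                       intercept = TRUE)
  }
  structure(
    list(exposure = exposure, lag = lag, max_lag = max_lag,
         lag_knot_scale = lag_knot_scale),
    class = "cross_basis_spec"
  )
}

lag_transform <- function(spec, l) {
  if (spec$lag_knot_scale == "log") log(l + 1) else l
}

#' Lag basis evaluated at the integer lags
#'
#' @param spec A [cross_basis_spec()].
#' @return `(max_lag + 1) x vl` matrix: row `l + 1` is the lag basis at
#'   lag `l`.
#' @export
lag_basis_matrix <- function(spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  lags <- 0:spec$max_lag
  basis_eval(lag_transform(spec, lags), spec$lag)
}

#' Column sums of the lag basis over the lag window
#'
#' The vector `s` with `s_k = sum_{l=0}^{L} C_k(l)`, used to reduce the
#' fitted exposure-lag surface to the overall cumulative
#' exposure-response.
#'
#' @inheritParams lag_basis_matrix
#' @return Numeric vector of length `vl`.
#' @export
lag_basis_colsums <- function(spec) {
  colSums(lag_basis_matrix(spec))
}

#' Matrix of lagged exposures
#'
#' Column `l + 1` holds `x[t - l]`. The first `max_lag` rows of each
#' zone have incomplete lag history and are flagged; lagging never
#' crosses zone boundaries.
#'
#' @param x Numeric exposure series, ordered by date within zone.
#' @param max_lag Integer maximum lag.
#' @param zone Optional vector identifying the zone of each row
#'   (contiguous blocks); `NULL` treats `x` as a single series.
#' @return `length(x) x (max_lag + 1)` matrix with a logical attribute
#'   `"complete"` marking rows whose full lag history is available.
#' @export
lag_matrix <- function(x, max_lag, zone = NULL) {
  n <- length(x)
  max_lag <- as.integer(max_lag)
  if (is.null(zone)) zone <- rep(1L, n)
  if (length(zone) != n) abort("`zone` must match `x` in length")
  zid <- as.integer(factor(zone, levels = unique(zone)))
  if (is.unsorted(zid)) {
    abort("rows must be grouped by zone (contiguous blocks)")
  }
  Q <- matrix(NA_real_, n, max_lag + 1L)
  complete <- rep(TRUE, n)
  for (z in unique(zid)) {
    idx <- which(zid == z)
    xz <- x[idx]
    nz <- length(xz)
    for (l in 0:max_lag) {
      Q[idx, l + 1L] <- c(rep(NA_real_, min(l, nz)), head(xz, max(nz - l, 0)))
    }
    complete[idx[seq_len(min(max_lag, nz))]] <- FALSE
  }
  colnames(Q) <- paste0("lag", 0:max_lag)
  attr(Q, "complete") <- complete
  Q
}

#' Build the temperature-by-lag cross-basis
#'
#' Computes `W[t, (j, k)] = sum_{l=0}^{L} R_j(x[t - l]) * C_k(l)` where
#' `R` is the exposure-dimension natural spline and `C` the lag-dimension
#' spline at integer lags. Columns are ordered with the exposure index
#' varying fastest (`(k - 1) * vx + j`), a convention that is stored and
#' re-used when curves are predicted or coefficients pooled. Rows with
#' incomplete lag history (the first `max_lag` days of each zone) carry
#' `NA` lags internally and are flagged for exclusion from fitting.
#'
#' @param x Numeric exposure series, date-ordered within zone.
#' @param spec A [cross_basis_spec()]; an unresolved exposure spec is
#'   resolved against `x` (knots at quantiles, boundary at the range)
#'   and the resolved spec is stored for later re-evaluation.
#' @param zone Optional zone identifier per row; see [lag_matrix()].
#' @return An object of class `cross_basis`: list with `values`
#'   (`n x (vx * vl)` matrix, `NA` on incomplete rows), `complete`
#'   (logical), and the resolved `spec`.
#' @export
cross_basis <- function(x, spec = cross_basis_spec(), zone = NULL) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  spec$exposure <- resolve_spline_spec(spec$exposure, x)
  Q <- lag_matrix(x, spec$max_lag, zone)
  complete <- attr(Q, "complete")
  C <- lag_basis_matrix(spec)
  vx <- spec$exposure$df
  vl <- ncol(C)
  n <- length(x)
  W <- matrix(0, n, vx * vl)
  for (l in 0:spec$max_lag) {
    xl <- Q[, l + 1L]
    ok <- !is.na(xl)
    Rl <- matrix(0, n, vx)
    if (any(ok)) Rl[ok, ] <- basis_eval(xl[ok], spec$exposure)
    for (k in seq_len(vl)) {
      cols <- (k - 1L) * vx + seq_len(vx)
      W[, cols] <- W[, cols] + Rl * C[l + 1L, k]
    }
  }
  W[!complete, ] <- NA_real_
  colnames(W) <- paste0(
    "cb.x", rep(seq_len(vx), times = vl), ".l", rep(seq_len(vl), each = vx)
  )
  structure(
    list(values = W, complete = complete, spec = spec),
    class = "cross_basis"
  )
}

#' Evaluate the exposure-dimension basis at new temperatures
#'
#' Uses the resolved spec stored at fit time, so the basis agrees
#' exactly with the one inside [cross_basis()].
#'
#' @param temps Numeric temperatures.
#' @param spec A resolved [cross_basis_spec()] (e.g. from a fitted
#'   model); an unresolved exposure spec is an error because the knots
#'   would not match the fit.
#' @return `length(temps) x vx` matrix.
#' @export
evaluate_exposure_basis <- function(temps, spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  if (spec$exposure$type == "ns" &&
      (is.null(spec$exposure$knots) || is.null(spec$exposure$boundary))) {
    abort("exposure spec is unresolved; use the spec stored in the fit")
  }
  basis_eval(temps, spec$exposure)
}

#' Serialize / deserialize a cross-basis specification
#'
#' Round-trips the resolved spec (knots, boundaries, lag scale, column
#' ordering convention) through JSON so fitting and prediction can be
#' decoupled across sessions.
#'
#' @param spec A [cross_basis_spec()].
#' @param json A JSON string produced by `cb_spec_to_json()`.
#' @return `cb_spec_to_json()`: a JSON string. `cb_spec_from_json()`:
#'   a `cross_basis_spec`.
#' @export
cb_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  jsonlite::toJSON(
    list(
      exposure = spec$exposure[c("df", "knots", "boundary", "intercept",
                                 "type")],
      lag = spec$lag[c("df", "knots", "boundary", "intercept", "type")],
      max_lag = spec$max_lag,
      lag_knot_scale = spec$lag_knot_scale,
      column_order = "exposure_fastest"
    ),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

#' @rdname cb_spec_to_json
#' @export
cb_spec_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  mk <- function(s) {
    sp <- spline_spec(
      df = s$df,
      knots = if (length(s$knots)) as.numeric(s$knots) else NULL,
      boundary = if (length(s$boundary)) as.numeric(s$boundary) else NULL,
      intercept = isTRUE(s$intercept),
      type = s$type %||% "ns"
    )
    if (sp$type != "ns" && length(s$boundary)) {
      sp$boundary <- as.numeric(s$boundary)
    }
    sp
  }
  spec <- cross_basis_spec(
    exposure = mk(o$exposure), lag = mk(o$lag),
    max_lag = o$max_lag, lag_knot_scale = o$lag_knot_scale
  )
  spec
}

#' Fingerprint of a resolved cross-basis spec
#'
#' Estimates pooled across regions must share one basis (same knots,
#' boundaries and column ordering); the fingerprint string is what
#' [pool_fixed()] compares.
#'
#' @param spec A resolved [cross_basis_spec()].
#' @return A character scalar.
#' @export
cb_fingerprint <- function(spec) {
  fmt <- function(v) {
    if (is.null(v) || !length(v)) "" else paste(signif(v, 10), collapse = ",")
  }
  paste(
    "x", fmt(spec$exposure$knots),
    "b", fmt(spec$exposure$boundary),
    "l", fmt(spec$lag$knots),
    "lb", fmt(spec$lag$boundary),
    "L", spec$max_lag, spec$lag_knot_scale,
    "t", spec$exposure$type, spec$lag$type,
    sep = "|"
  )
}
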