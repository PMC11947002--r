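#' Tidy a case time-series fit
#'
#' One row per retained coefficient, broom-style.
#'
#' @param x A `casets_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `block`, `estimate`, `std.error`,
#'   `statistic` (Wald z under the quasi-scaled covariance).
#' @export
tidy.casets_fit <- function(x, ...) {
  block <- rep(names(x$blocks), lengths(x$blocks))
  term <- unlist(lapply(x$blocks, names), use.names = FALSE)
  ord <- match(names(x$beta), term)
  se <- sqrt(diag(x$vcov))
  tibble(
    term = names(x$beta),
    block = block[ord],
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(x$beta / se)
  )
}

#' One-row summary of a case time-series fit
#'
#' @param x A `casets_fit`.
#' @param ... Unused.
#' @return Tibble with `nobs`, `n_strata`, `n_strata_dropped`,
#'   `n_params`, `dispersion`, `logLik`, `qaic`, `iterations`.
#' @export
glance.casets_fit <- function(x, ...) {
  tibble(
    nobs = x$n_rows_used,
    n_strata = x$n_strata_used,
    n_strata_dropped = x$n_strata_dropped,
    n_params = x$n_params,
    dispersion = x$dispersion,
    logLik = x$loglik,
    qaic = x$qaic,
    iterations = x$iterations
  )
}

#' Tidy a cumulative exposure-response curve
#'
#' @param x A [cumulative_curve()].
#' @param ... Unused.
#' @return The curve as a plain tibble.
#' @export
tidy.cumulative_curve <- function(x, ...) {
  as_tibble(unclass(x)[c("temp_c", "log_rr", "se", "rr", "rr_low",
                         "rr_high")])
}

#' One-row summary of a cumulative curve
#'
#' @param x A [cumulative_curve()].
#' @param ... Unused.
#' @return Tibble `reference_temp`, `mert`, `rr_min`, `rr_max`.
#' @export
glance.cumulative_curve <- function(x, ...) {
  tibble(
    reference_temp = attr(x, "reference_temp"),
    mert = attr(x, "mert"),
    rr_min = min(x$rr),
    rr_max = max(x$rr)
  )
}

#' Plot a cumulative exposure-response curve
#'
#' Relative risk with its 95% band over the temperature grid, the
#' reference (median) temperature and the minimum-risk temperature
#' marked as vertical lines.
#'
#' @param object A [cumulative_curve()].
#' @param anchors Optional [percentile_anchors()] whose 2.5th/97.5th
#'   percentiles are drawn as dashed guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cumulative_curve <- function(object, anchors = NULL, ...) {
  df <- tidy.cumulative_curve(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$temp_c)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rr_low, ymax = .data$rr_high),
      fill = "firebrick", alpha = 0.2
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rr), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = attr(object, "mert"),
                        colour = "black") +
    ggplot2::labs(
      x = "Daily mean temperature (°C)",
      y = "Cumulative relative risk (lag 0-7)",
      caption = sprintf("reference %.1f °C, minimum-risk %.1f °C",
                        attr(object, "reference_temp"),
                        attr(object, "mert"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(anchors)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(anchors$p2_5, anchors$p97_5),
      colour = "grey50", linetype = "dashed"
    )
  }
  p
}

#' Plot relative risks from a results table
#'
#' Forest-style display of the `rr (rr_low, rr_high)` cells of a
#' results table, faceted by percentile.
#'
#' @param results Results tibble from [run_region_analysis()] or
#'   [run_subgroups()].
#' @return A ggplot object.
#' @export
plot_results <- function(results) {
  df <- results[results$status == "ok", ]
  df$cell <- paste(df$stratum, df$subgroup, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr, y = .data$cell)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$rr_low, xmax = .data$rr_high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~percentile, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Relative risk vs median temperature", y = NULL) +
    ggplot2::theme_minimal()
}
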