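#' Published regional visit summary for North Carolina, 2016-2019
#'
#' The published summary counts of mental and behavioral disorder
#' (ICD-10 F00-F99) emergency department visits by physiographic
#' region of North Carolina over 2016-2019: total population, all-MBD
#' visits, and the psychoactive substance use / mood / anxiety
#' diagnosis blocks, plus the statewide row. Shipped as a plain-text
#' table; useful as a consistency check that regional aggregation
#' conserves totals (`check_region_totals()`).
#'
#' @return Tibble with columns `region`, `population`, `visits_total`,
#'   `visits_substance`, `visits_mood`, `visits_anxiety`; three region
#'   rows plus the `North Carolina` state row.
#' @export
nc_visit_summary <- function() {
  path <- system.file("extdata", "nc_mbd_region_summary.csv",
                      package = "casetemps", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' Regional-to-state aggregation check
#'
#' Sums the three regional rows of a visit summary and compares them
#' with the state row — the basic conservation property of line-level
#' to panel aggregation (every visit belongs to exactly one region).
#'
#' @param summary A table shaped like [nc_visit_summary()].
#' @return Tibble with one row per count column: `measure`,
#'   `region_sum`, `state_total`, `matches`.
#' @export
check_region_totals <- function(summary = nc_visit_summary()) {
  state <- summary[summary$region == "North Carolina", ]
  regions <- summary[summary$region != "North Carolina", ]
  meas <- setdiff(names(summary), "region")
  tibble(
    measure = meas,
    region_sum = vapply(meas, function(m) sum(regions[[m]]), numeric(1)),
    state_total = vapply(meas, function(m) state[[m]][1], numeric(1))
  ) |>
    dplyr::mutate(matches = .data$region_sum == .data$state_total)
}
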