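#' Average annual proportional rate of change
#'
#' The study's two-point estimator: the total proportional change between two
#' observations, divided by the number of years separating them,
#' `((value_present - value_past) / value_past) / n_years`. Negative values
#' mean the indicator improved (mortality fell). The result is returned
#' unrounded; rounding belongs to report time.
#'
#' @param value_past Indicator level at the start of the window (> 0).
#' @param value_present Indicator level at the end of the window (>= 0).
#' @param n_years Years between the two observations (>= 1).
#' @return The average annual proportional change (per year). Vectorised.
#' @export
#' @examples
#' average_annual_change(34.00, 18.20, 20) # about -0.023, prints as -0.02
#' average_annual_change(0.60, 0.14, 20)   # about -0.038, prints as -0.04
average_annual_change <- function(value_past, value_present, n_years) {
  if (any(!is.finite(value_past)) || any(value_past <= 0)) {
    abort("value_past must be positive: the rate is undefined at or below zero")
  }
  if (any(!is.finite(value_present)) || any(value_present < 0)) {
    abort("value_present must be a non-negative number")
  }
  if (any(!is.finite(n_years)) || any(n_years < 1)) {
    abort("n_years must be at least 1")
  }
  ((value_present - value_past) / value_past) / n_years
}

#' Estimate a windowed trend from an indicator series
#'
#' Applies [average_annual_change()] to the observations at the window
#' bounds of each (unit, indicator) series. When the observation at
#' `window_start` is missing, the earliest available year inside the window
#' is used instead (and symmetrically the latest available year when
#' `window_end` is missing); the years actually used and the resulting span
#' are recorded. A series with fewer than two usable observations in the
#' window yields a non-assessable row (`assessable = FALSE`) rather than an
#' error, so missing districts propagate cleanly.
#'
#' @param series Long tibble with columns `unit_id`, `indicator`, `year`,
#'   `value` (see [read_indicator_series()]).
#' @param window_start,window_end Requested window bounds (years).
#' @param basis Optional label recorded in the result (e.g. `"prewar"`,
#'   `"conflict"`).
#' @return A tibble, one row per (unit, indicator): `rate`, requested
#'   `window_start`/`window_end`, actual `year_start`/`year_end`, `n_years`,
#'   `value_start`, `value_end`, `assessable`, `basis`.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   unit_id = "NATIONAL", indicator = "MMR",
#'   year = c(1972, 1982), value = c(1.3, 0.6)
#' )
#' estimate_window_trend(s, 1972, 1982) # rate about -0.054
estimate_window_trend <- function(series, window_start, window_end, basis = NA_character_) {
  stopifnot(is.data.frame(series), window_start < window_end)
  need <- c("unit_id", "indicator", "year", "value")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols) > 0) {
    abort(paste0("series lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  one <- function(df) {
    w <- df[df$year >= window_start & df$year <= window_end & !is.na(df$value), ]
    if (nrow(w) < 2) {
      return(tibble::tibble(
        rate = NA_real_, year_start = NA_integer_, year_end = NA_integer_,
        n_years = NA_integer_, value_start = NA_real_, value_end = NA_real_,
        assessable = FALSE, reason = "fewer than two usable observations in window"
      ))
    }
    ys <- min(w$year)
    ye <- max(w$year)
    vs <- w$value[w$year == ys][1]
    ve <- w$value[w$year == ye][1]
    if (vs <= 0) {
      return(tibble::tibble(
        rate = NA_real_, year_start = as.integer(ys), year_end = as.integer(ye),
        n_years = as.integer(ye - ys), value_start = vs, value_end = ve,
        assessable = FALSE, reason = "rate undefined: start value is zero"
      ))
    }
    tibble::tibble(
      rate = average_annual_change(vs, ve, ye - ys),
      year_start = as.integer(ys), year_end = as.integer(ye),
      n_years = as.integer(ye - ys), value_start = vs, value_end = ve,
      assessable = TRUE, reason = NA_character_
    )
  }
  out <- series |>
    dplyr::group_by(.data$unit_id, .data$indicator) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  out$window_start <- as.integer(window_start)
  out$window_end <- as.integer(window_end)
  out$basis <- basis
  dplyr::relocate(out, "unit_id", "indicator", "rate")
}

#' Lost momentum in annual decline
#'
#' Expresses the slowdown of an indicator's improvement as the difference
#' between the pre-war and wartime annual percentage declines, both rounded
#' to reporting precision before differencing (the convention of the source
#' analysis). The pre-war decline is the compound rate back-solved from the
#' counterfactual endpoint; the wartime decline is the two-point average
#' annual change between baseline and the actual endpoint.
#'
#' For the national IMR (baseline 34.00, actual 18.20, 10-yr counterfactual
#' 16.83, 20 years) this yields declines of 3.5 and 2.3 percent per year and
#' a lost momentum of 1.2 percentage points.
#'
#' @param baseline_value Indicator level at the baseline year.
#' @param actual_value Achieved level at the endpoint.
#' @param counterfactual_value Projected level at the endpoint.
#' @param n_years Projection horizon in years.
#' @param digits Rounding used before differencing (default 1).
#' @return One-row tibble: `prewar_decline_pct`, `wartime_decline_pct`,
#'   `lost_pct`.
#' @export
#' @examples
#' lost_momentum(34.00, 18.20, 16.83, 20)
lost_momentum <- function(baseline_value, actual_value, counterfactual_value,
                          n_years, digits = 1) {
  prewar <- round(-100 * back_solve_rate(baseline_value, counterfactual_value,
                                         n_years, "compound"), digits)
  wartime <- round(-100 * average_annual_change(baseline_value, actual_value,
                                                n_years), digits)
  tibble::tibble(
    prewar_decline_pct = prewar,
    wartime_decline_pct = wartime,
    lost_pct = prewar - wartime
  )
}
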