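#' Project a baseline value forward under a rate and shape
#'
#' Functional forms (`t` = years elapsed, `V0` = baseline value, `r` = rate
#' per year):
#' * `compound`: `V0 * (1 + r)^t` (default; reproduces the published
#'   national counterfactuals)
#' * `linear`: `V0 * (1 + r * t)`
#' * `exponential`: `V0 * exp(r * t)`
#' * `logarithmic`: `V0 * (1 + r * log(1 + t))`
#'
#' All shapes anchor at the baseline (`t = 0` returns `V0`) and share the
#' same first-order slope at small `r`. Negative projections are allowed
#' (a worsening linear path can cross zero) but raise a warning.
#'
#' @param baseline_value Positive baseline level.
#' @param rate Annual proportional rate of change.
#' @param years_elapsed Non-negative years since baseline. Vectorised.
#' @param shape One of [projection_shapes()].
#' @return Projected value(s).
#' @export
#' @examples
#' project_value(0.60, -0.08, 20)             # 0.113..., prints 0.11
#' project_value(34, -0.04, 20)               # 15.03...
#' project_value(34, -0.04, 20, "linear")     # 6.8
project_value <- function(baseline_value, rate, years_elapsed,
                          shape = c("compound", "linear", "exponential", "logarithmic")) {
  shape <- match.arg(shape)
  if (any(!is.finite(baseline_value)) || any(baseline_value <= 0)) {
    abort("baseline_value must be positive")
  }
  if (any(!is.finite(years_elapsed)) || any(years_elapsed < 0)) {
    abort("years_elapsed must be non-negative")
  }
  if (any(!is.finite(rate))) abort("rate must be finite")
  if (shape == "compound" && any(rate <= -1)) {
    abort("compound projection undefined for rate <= -1")
  }
  out <- switch(shape,
    compound = baseline_value * (1 + rate)^years_elapsed,
    linear = baseline_value * (1 + rate * years_elapsed),
    exponential = baseline_value * exp(rate * years_elapsed),
    logarithmic = baseline_value * (1 + rate * log1p(years_elapsed))
  )
  if (any(out < 0)) {
    warn(paste0("projection crossed zero under shape '", shape, "'"))
  }
  out
}

#' Back-solve the rate implied by a projection
#'
#' The unique rate such that `project_value(baseline, rate, t, shape)`
#' equals `target`. Used to reconcile printed counterfactual endpoints with
#' printed (rounded) trend columns.
#'
#' @param baseline_value,target_value Positive levels.
#' @param years_elapsed Positive projection horizon.
#' @param shape One of [projection_shapes()].
#' @return The implied annual rate.
#' @export
#' @examples
#' back_solve_rate(34, 15.04, 20) # about -0.0400
#' back_solve_rate(0.60, 0.11, 20) # about -0.081
back_solve_rate <- function(baseline_value, target_value, years_elapsed,
                            shape = c("compound", "linear", "exponential", "logarithmic")) {
  shape <- match.arg(shape)
  if (any(!is.finite(baseline_value)) || any(baseline_value <= 0) ||
      any(!is.finite(target_value)) || any(target_value <= 0)) {
    abort("baseline_value and target_value must be positive")
  }
  if (any(!is.finite(years_elapsed)) || any(years_elapsed <= 0)) {
    abort("years_elapsed must be positive")
  }
  ratio <- target_value / baseline_value
  switch(shape,
    compound = ratio^(1 / years_elapsed) - 1,
    linear = (ratio - 1) / years_elapsed,
    exponential = log(ratio) / years_elapsed,
    logarithmic = (ratio - 1) / log1p(years_elapsed)
  )
}

#' Year-by-year counterfactual trajectory
#'
#' @param baseline_value Positive baseline level.
#' @param rate Annual rate.
#' @param baseline_year,end_year Trajectory span (inclusive).
#' @param shape One of [projection_shapes()].
#' @return A tibble with columns `year`, `value`.
#' @export
#' @examples
#' project_trajectory(34, -0.04, 1982, 2002)
project_trajectory <- function(baseline_value, rate, baseline_year, end_year,
                               shape = "compound") {
  stopifnot(baseline_year <= end_year)
  years <- seq(baseline_year, end_year)
  tibble::tibble(
    year = as.integer(years),
    value = project_value(baseline_value, rate, years - baseline_year, shape)
  )
}

endpoint_for <- function(meta_row, indicator, default_endpoint) {
  col <- if (indicator == "IMR") "imr_endpoint_year" else "mmr_endpoint_year"
  ep <- meta_row[[col]]
  if (is.null(ep) || length(ep) == 0 || is.na(ep)) default_endpoint else ep
}

#' Build counterfactual endpoints for every unit and indicator
#'
#' Runs the full projection stage on a long observation panel: estimates the
#' pre-war trend over the configured window, projects the baseline-year
#' observation to each unit's endpoint year under the configured shape, and
#' pairs the result with the observed endpoint. Units created after the
#' start of the pre-war window, and units lacking a baseline observation or
#' a usable pre-war trend, propagate as non-assessable rows (never errors),
#' matching the "Unable to determine" entries of the published tables.
#'
#' @param series Long tibble (`unit_id`, `indicator`, `year`, `value`).
#' @param meta Unit metadata (see [read_unit_meta()] / [sri_lanka_meta()]).
#' @param config A [study_config()].
#' @return A tibble, one row per (unit, indicator), with the pre-war rate,
#'   conflict-window rate, baseline and endpoint values, the counterfactual
#'   endpoint, and assessability flags.
#' @export
build_counterfactual <- function(series, meta, config = study_config()) {
  stopifnot(is.data.frame(series), is.data.frame(meta))
  window_start <- config$baseline_year - config$prewar_window_years

  prewar <- estimate_window_trend(series, window_start, config$baseline_year,
                                  basis = "prewar")

  pairs <- dplyr::distinct(series, .data$unit_id, .data$indicator)
  meta_idx <- meta[match(pairs$unit_id, meta$unit_id), , drop = FALSE]
  unknown <- pairs$unit_id[is.na(meta_idx$unit_id)]
  if (length(unknown) > 0) {
    abort(paste0(
      "units missing from metadata: ", paste(unique(unknown), collapse = ", ")
    ))
  }

  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    uid <- pairs$unit_id[i]
    ind <- pairs$indicator[i]
    mrow <- meta_idx[i, ]
    ep_year <- endpoint_for(mrow, ind, config$endpoint_year)
    horizon <- ep_year - config$baseline_year

    obs <- series[series$unit_id == uid & series$indicator == ind, ]
    baseline_value <- obs$value[obs$year == config$baseline_year][1]
    actual_value <- obs$value[obs$year == ep_year][1]

    pw <- prewar[prewar$unit_id == uid & prewar$indicator == ind, ]
    late <- !is.na(mrow$creation_year) && mrow$creation_year > window_start

    reason <- NA_character_
    if (late) {
      reason <- "unit created after the start of the pre-war window"
    } else if (nrow(pw) == 0 || !pw$assessable) {
      reason <- if (nrow(pw) == 0) "no observations" else pw$reason
    } else if (is.na(baseline_value) || length(baseline_value) == 0) {
      reason <- "no baseline-year observation"
    }
    assessable <- is.na(reason)

    cf <- if (assessable) {
      project_value(baseline_value, pw$rate, horizon, config$projection_shape)
    } else {
      NA_real_
    }
    tibble::tibble(
      unit_id = uid, indicator = ind,
      baseline_year = config$baseline_year,
      baseline_value = ifelse(length(baseline_value) == 0, NA_real_, baseline_value),
      endpoint_year = as.integer(ep_year),
      n_years = as.integer(horizon),
      rate_prewar = if (assessable) pw$rate else NA_real_,
      shape = config$projection_shape,
      counterfactual = cf,
      actual = ifelse(length(actual_value) == 0, NA_real_, actual_value),
      assessable = assessable,
      reason = reason
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$unit_id, .data$indicator)
}

#' Projection-shape sensitivity analysis
#'
#' Recomputes the endpoint classification under each requested functional
#' form and reports whether the shapes agree. The endpoint flag under each
#' shape compares the observed endpoint to the projection of the same
#' baseline and pre-war rate under that shape. `consistent` is `TRUE` when
#' all defined (assessable) flags are identical, and `NA` for units where no
#' flag is defined.
#'
#' @param table A district-style table with columns `unit_id`, `indicator`,
#'   `baseline`, `actual`, `rate_prewar`, `endpoint_year` (see
#'   [district_table()]), or the output of [build_counterfactual()] (columns
#'   `baseline_value`/`rate_prewar`/`actual`/`endpoint_year` are recognised).
#' @param shapes At least two of [projection_shapes()].
#' @param config A [study_config()] (supplies the baseline year and the tie
#'   tolerance).
#' @return A tibble with one flag column per shape (`flag_<shape>`) and a
#'   `consistent` column; the attribute `"summary"` counts assessable and
#'   consistent rows.
#' @export
#' @examples
#' sensitivity_analysis(district_table("IMR"))
sensitivity_analysis <- function(table,
                                 shapes = c("compound", "linear", "exponential", "logarithmic"),
                                 config = study_config()) {
  shapes <- match.arg(shapes, projection_shapes(), several.ok = TRUE)
  if (length(shapes) < 2) abort("sensitivity analysis needs at least two shapes")
  if ("baseline_value" %in% names(table) && !"baseline" %in% names(table)) {
    table$baseline <- table$baseline_value
  }
  need <- c("unit_id", "indicator", "baseline", "actual", "rate_prewar", "endpoint_year")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("sensitivity table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  horizon <- table$endpoint_year - config$baseline_year

  out <- dplyr::select(table, "unit_id", "indicator")
  for (sh in shapes) {
    ok <- !is.na(table$baseline) & table$baseline > 0 & !is.na(table$rate_prewar) &
      !is.na(table$actual) & !(sh == "compound" & table$rate_prewar <= -1)
    proj <- rep(NA_real_, nrow(table))
    if (any(ok)) {
      proj[ok] <- suppressWarnings(
        project_value(table$baseline[ok], table$rate_prewar[ok], horizon[ok], sh)
      )
    }
    out[[paste0("flag_", sh)]] <- classify_endpoint(
      table$actual, proj,
      lower_is_better = TRUE, tolerance = config$tie_tolerance
    )
  }
  flag_cols <- paste0("flag_", shapes)
  out$consistent <- purrr::pmap_lgl(out[flag_cols], function(...) {
    fl <- c(...)
    fl <- fl[fl != "not_assessable"]
    if (length(fl) == 0) NA else length(unique(fl)) == 1
  })
  attr(out, "summary") <- list(
    shapes = shapes,
    n = nrow(out),
    n_assessable = sum(!is.na(out$consistent)),
    n_consistent = sum(out$consistent, na.rm = TRUE)
  )
  out
}

#' Reconcile printed counterfactuals with printed rates
#'
#' The published district tables print rounded rates and rounded
#' counterfactual endpoints computed from unrounded internal inputs, so the
#' two need not agree. For each assessable row this report recomputes the
#' counterfactual from the printed rate, back-solves the rate implied by the
#' printed counterfactual, and records the absolute discrepancy. Nothing is
#' silently resolved: the report is the honest surface for cells that cannot
#' be reproduced from printed inputs.
#'
#' @param table A standard district table ([district_table()]).
#' @param config A [study_config()].
#' @return A tibble: `unit_id`, `indicator`, `printed_rate`, `printed_cf`,
#'   `recomputed_cf`, `back_solved_rate`, `abs_discrepancy`.
#' @export
#' @examples
#' reconcile_counterfactuals(district_table("MMR"))
reconcile_counterfactuals <- function(table, config = study_config()) {
  horizon <- table$endpoint_year - config$baseline_year
  ok <- !is.na(table$baseline) & !is.na(table$rate_prewar) & !is.na(table$counterfactual)
  recomputed <- rep(NA_real_, nrow(table))
  solved <- rep(NA_real_, nrow(table))
  recomputed[ok] <- suppressWarnings(project_value(
    table$baseline[ok], table$rate_prewar[ok], horizon[ok], config$projection_shape
  ))
  solved[ok] <- back_solve_rate(
    table$baseline[ok], table$counterfactual[ok], horizon[ok], config$projection_shape
  )
  tibble::tibble(
    unit_id = table$unit_id,
    indicator = table$indicator,
    printed_rate = table$rate_prewar,
    printed_cf = table$counterfactual,
    recomputed_cf = recomputed,
    back_solved_rate = solved,
    abs_discrepancy = abs(table$counterfactual - recomputed)
  )
}
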