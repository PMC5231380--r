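compare_with_tolerance <- function(x, y, tolerance) {
  out <- rep("not_assessable", length(x))
  ok <- !is.na(x) & !is.na(y)
  out[ok & x > y + tolerance] <- "worse"
  out[ok & x < y - tolerance] <- "better"
  out[ok & abs(x - y) <= tolerance] <- "same"
  out
}

#' Classify the change in the rate of improvement
#'
#' A conflict-period rate of change that is higher (less negative) than the
#' pre-war rate means improvement slowed or reversed: `"worse"`. Lower means
#' faster improvement: `"better"`. Differences within `tolerance` are
#' `"same"`; missing inputs give `"not_assessable"`.
#'
#' @param rate_prewar,rate_conflict Annual proportional rates (negative =
#'   improving). Vectorised.
#' @param tolerance Non-negative tie tolerance (default 0: strict).
#' @return Character flags in `worse`/`better`/`same`/`not_assessable`.
#' @export
#' @examples
#' classify_rate_change(-0.066, -0.019) # "worse": improvement slowed
#' classify_rate_change(-0.027, -0.038) # "better"
classify_rate_change <- function(rate_prewar, rate_conflict, tolerance = 0) {
  stopifnot(tolerance >= 0)
  compare_with_tolerance(rate_conflict, rate_prewar, tolerance)
}

#' Classify the endpoint level against the counterfactual
#'
#' For lower-is-better indicators (mortality), an actual endpoint above the
#' counterfactual is `"worse"`; below is `"better"`; within `tolerance` is
#' `"same"`. Either value missing gives `"not_assessable"`.
#'
#' @param actual,counterfactual Endpoint levels. Vectorised.
#' @param lower_is_better Direction of the indicator (default TRUE).
#' @param tolerance Non-negative tie tolerance.
#' @return Character flags.
#' @export
#' @examples
#' classify_endpoint(17.6, 11.6) # "worse"
#' classify_endpoint(6.0, 12.7)  # "better"
#' classify_endpoint(4.7, 4.7)   # "same"
classify_endpoint <- function(actual, counterfactual, lower_is_better = TRUE,
                              tolerance = 0) {
  stopifnot(tolerance >= 0)
  if (lower_is_better) {
    compare_with_tolerance(actual, counterfactual, tolerance)
  } else {
    compare_with_tolerance(counterfactual, actual, tolerance)
  }
}

#' Interpretation label from a pair of flags
#'
#' Maps the (rate flag, endpoint flag) pair to the summary vocabulary of the
#' published district tables: "Rate and IMR are worse", "Rate is worse; MMR
#' is better", "Rate is worse; MMR is same", "Rate is better; MMR is worse",
#' and so on. A missing rate flag yields "Unable to determine"; a defined
#' rate with a missing endpoint yields "Rate is worse" / "Rate is better"
#' (the form the tables print when only the rate could be assessed).
#'
#' @param rate_flag,endpoint_flag Flags from [classify_rate_change()] /
#'   [classify_endpoint()]. Vectorised.
#' @param indicator `"IMR"` or `"MMR"` (names the endpoint in the label).
#' @return Character labels.
#' @export
#' @examples
#' interpret_flags("worse", "better", "IMR") # "Rate is worse; IMR is better"
#' interpret_flags("not_assessable", "worse", "IMR") # "Unable to determine"
interpret_flags <- function(rate_flag, endpoint_flag, indicator) {
  rate_flag <- as_flag(rate_flag)
  endpoint_flag <- as_flag(endpoint_flag)
  indicator <- check_indicator(indicator)
  n <- max(length(rate_flag), length(endpoint_flag), length(indicator))
  rate_flag <- rep_len(rate_flag, n)
  endpoint_flag <- rep_len(endpoint_flag, n)
  indicator <- rep_len(indicator, n)
  dplyr::case_when(
    rate_flag == "not_assessable" ~ "Unable to determine",
    endpoint_flag == "not_assessable" ~ paste0("Rate is ", rate_flag),
    rate_flag == endpoint_flag ~ paste0("Rate and ", indicator, " are ", rate_flag),
    TRUE ~ paste0("Rate is ", rate_flag, "; ", indicator, " is ", endpoint_flag)
  )
}

#' Parse a printed interpretation label back into flags
#'
#' Inverse of [interpret_flags()], tolerant of the wording variants used
#' across the published tables ("outcome" for the endpoint, and "Rate is
#' worse" with no endpoint clause).
#'
#' @param label Character vector of printed labels.
#' @return A tibble with columns `rate_flag`, `endpoint_flag`.
#' @export
#' @examples
#' label_to_flags("Rate is worse; MMR is better")
#' label_to_flags("Rate and outcome are worse")
label_to_flags <- function(label) {
  label <- trimws(as.character(label))
  parse_one <- function(lb) {
    if (is.na(lb) || grepl("^unable", lb, ignore.case = TRUE)) {
      return(c("not_assessable", "not_assessable"))
    }
    lb <- tolower(lb)
    both <- regmatches(lb, regexec("^rate and [a-z]+ are (worse|better|same)$", lb))[[1]]
    if (length(both) == 2) return(c(both[2], both[2]))
    split <- regmatches(
      lb,
      regexec("^rate is (worse|better|same); [a-z]+ is (worse|better|same)$", lb)
    )[[1]]
    if (length(split) == 3) return(c(split[2], split[3]))
    only <- regmatches(lb, regexec("^rate is (worse|better|same)$", lb))[[1]]
    if (length(only) == 2) return(c(only[2], "not_assessable"))
    abort(paste0("unrecognised interpretation label: ", lb))
  }
  parsed <- t(vapply(label, parse_one, character(2), USE.NAMES = FALSE))
  tibble::tibble(rate_flag = parsed[, 1], endpoint_flag = parsed[, 2])
}

#' Classify a standard district table
#'
#' Applies the rate and endpoint classifications to a table of printed (or
#' computed) rates, actual and counterfactual endpoints (see
#' [district_table()] or [build_counterfactual()]), and attaches the
#' interpretation label.
#'
#' @param table A tibble with columns `unit_id`, `indicator`, `rate_prewar`,
#'   `rate_conflict`, `actual`, `counterfactual` (a `rate_conflict` column is
#'   optional in [build_counterfactual()] output and is derived there).
#' @param tolerance Tie tolerance (default 0).
#' @return The table with `rate_flag`, `endpoint_flag`, `label` appended.
#' @export
#' @examples
#' classify_units(district_table("IMR"))
classify_units <- function(table, tolerance = 0) {
  need <- c("unit_id", "indicator", "rate_prewar", "rate_conflict",
            "actual", "counterfactual")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("classification input lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  table$rate_flag <- classify_rate_change(table$rate_prewar, table$rate_conflict,
                                          tolerance)
  table$endpoint_flag <- classify_endpoint(table$actual, table$counterfactual,
                                           lower_is_better = TRUE,
                                           tolerance = tolerance)
  table$label <- interpret_flags(table$rate_flag, table$endpoint_flag,
                                 table$indicator)
  table
}

#' Conflict impact index (0--4)
#'
#' One point per component in which a district did worse than its
#' counterfactual: IMR rate of change, IMR endpoint, MMR rate of change, MMR
#' endpoint. `"same"` and `"better"` score zero; non-assessable components
#' score zero but are recorded, and a district where all four components are
#' non-assessable gets a non-assessable weight rather than a zero.
#'
#' @param classification A classified table (rows per unit x indicator with
#'   `rate_flag` and `endpoint_flag`, e.g. from [classify_units()]).
#' @return A tibble, one row per unit: the four component flags, `weight`
#'   (integer 0--4, `NA` when not assessable), `n_missing_components`, and
#'   `weight_class` (vocabulary of the published histogram: none / minimal /
#'   noticeable / high).
#' @export
#' @examples
#' cls <- rbind(classify_units(district_table("IMR")),
#'              classify_units(district_table("MMR")))
#' impact_index(cls)
impact_index <- function(classification) {
  wide <- classification |>
    dplyr::select("unit_id", "indicator", "rate_flag", "endpoint_flag") |>
    tidyr::pivot_wider(
      names_from = "indicator",
      values_from = c("rate_flag", "endpoint_flag"),
      values_fill = "not_assessable"
    )
  for (cc in c("rate_flag_IMR", "endpoint_flag_IMR", "rate_flag_MMR", "endpoint_flag_MMR")) {
    if (!cc %in% names(wide)) wide[[cc]] <- "not_assessable"
  }
  comp <- wide[c("rate_flag_IMR", "endpoint_flag_IMR", "rate_flag_MMR", "endpoint_flag_MMR")]
  n_missing <- rowSums(sapply(comp, function(x) x == "not_assessable"))
  weight <- rowSums(sapply(comp, function(x) x == "worse"))
  weight[n_missing == 4] <- NA_integer_
  tibble::tibble(
    unit_id = wide$unit_id,
    rate_flag_imr = wide$rate_flag_IMR,
    endpoint_flag_imr = wide$endpoint_flag_IMR,
    rate_flag_mmr = wide$rate_flag_MMR,
    endpoint_flag_mmr = wide$endpoint_flag_MMR,
    n_missing_components = as.integer(n_missing),
    weight = as.integer(weight),
    weight_class = weight_class(weight)
  ) |>
    dplyr::arrange(.data$unit_id)
}

#' Weight class vocabulary
#'
#' @param weight Integer impact weights (0--4, `NA` allowed).
#' @return `"not_assessable"`, `"none"` (0), `"minimal"` (1--2),
#'   `"noticeable"` (3) or `"high"` (4).
#' @export
weight_class <- function(weight) {
  dplyr::case_when(
    is.na(weight) ~ "not_assessable",
    weight == 0 ~ "none",
    weight <= 2 ~ "minimal",
    weight == 3 ~ "noticeable",
    TRUE ~ "high"
  )
}

#' Headline tallies over districts
#'
#' Counts, over district units only (the `NATIONAL` pseudo-unit and any
#' `conflict_class == "national"` rows are excluded), per indicator:
#' endpoint-worse districts; endpoint-worse districts outside the conflict
#' zone (`conflict_class != "high"`, i.e. intermittent and no-conflict);
#' rate-worse districts; and districts whose rate is worse while the
#' endpoint is not (better, same, or not assessable). A weight histogram is
#' included when an index table is supplied.
#'
#' @param classification Classified rows per unit x indicator (`rate_flag`,
#'   `endpoint_flag`).
#' @param meta Unit metadata providing `conflict_class`.
#' @param index Optional [impact_index()] output for the weight histogram.
#' @return A list with `counts` (tibble: `indicator`, `metric`, `n`) and
#'   `weights` (tibble: `weight`, `n`; `NA` weight = not assessable).
#' @export
#' @examples
#' cls <- classify_units(district_table("IMR"))
#' tally_classifications(cls, sri_lanka_meta())
tally_classifications <- function(classification, meta, index = NULL) {
  df <- dplyr::left_join(
    dplyr::select(
      classification, "unit_id", "indicator", "rate_flag", "endpoint_flag"
    ),
    dplyr::select(meta, "unit_id", "conflict_class"),
    by = "unit_id"
  )
  df <- dplyr::filter(
    df, .data$unit_id != "NATIONAL",
    is.na(.data$conflict_class) | .data$conflict_class != "national"
  )
  counts <- df |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(
      endpoint_worse = sum(.data$endpoint_flag == "worse"),
      endpoint_worse_outside_zone = sum(
        .data$endpoint_flag == "worse" & .data$conflict_class != "high"
      ),
      rate_worse = sum(.data$rate_flag == "worse"),
      rate_worse_endpoint_not_worse = sum(
        .data$rate_flag == "worse" & .data$endpoint_flag != "worse"
      ),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"indicator", names_to = "metric", values_to = "n")
  counts$n <- as.integer(counts$n)

  weights <- NULL
  if (!is.null(index)) {
    idx <- dplyr::filter(index, .data$unit_id != "NATIONAL")
    weights <- idx |>
      dplyr::count(.data$weight, name = "n") |>
      dplyr::arrange(.data$weight)
  }
  list(counts = counts, weights = weights)
}

#' Reconcile computed labels against printed labels
#'
#' Joins computed and printed interpretation labels on (unit, indicator) and
#' lists every disagreement with both values. The published tables are not
#' perfectly consistent with their own printed columns (for example a
#' "same" verdict printed for an endpoint far from its counterfactual);
#' discrepancies are surfaced here, never silently resolved.
#'
#' @param computed Tibble with `unit_id`, `indicator`, `label` (e.g. from
#'   [classify_units()]).
#' @param printed Tibble with `unit_id`, `indicator`, `label` (e.g. from
#'   [printed_labels()]).
#' @return A tibble of disagreements: `unit_id`, `indicator`,
#'   `computed_label`, `printed_label`. Zero rows when all labels agree.
#' @export
#' @examples
#' cls <- classify_units(district_table("MMR"))
#' reconcile_labels(cls, printed_labels("MMR"))
reconcile_labels <- function(computed, printed) {
  joined <- dplyr::inner_join(
    dplyr::select(computed, "unit_id", "indicator", computed_label = "label"),
    dplyr::select(printed, "unit_id", "indicator", printed_label = "label"),
    by = c("unit_id", "indicator")
  )
  dplyr::filter(joined, .data$computed_label != .data$printed_label)
}
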