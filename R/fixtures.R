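fixture_files <- function() {
  c(
    table2 = "table2_national.csv",
    table3 = "table3_imr_districts.csv",
    table4 = "table4_imr_labels.csv",
    table5 = "table5_mmr_districts.csv",
    table6 = "table6_mmr_labels.csv",
    table9 = "table9_impact_histogram.csv",
    national_series = "national_series.csv"
  )
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "momentumcf")
  if (p == "") abort(paste0("packaged fixture missing: ", file))
  p
}

# "n/a" and blank cells in the packaged tables become NA; the verbatim token
# survives in the shipped CSV, which is the provenance record.
parse_printed_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "n/a", "N/A", "NA")] <- NA_character_
  as.numeric(x)
}

#' Load a packaged table fixture
#'
#' Returns the published study tables exactly as printed (typed, with `n/a`
#' cells as `NA`); nothing is recomputed. District fixtures additionally gain
#' a canonical `unit_id` column (the printed spelling stays in `district`)
#' and a normalised `conflict_class`.
#'
#' Available fixtures: `table2` (national actual/counterfactual outcomes and
#' trends), `table3` (district IMR), `table4` (district IMR summary labels),
#' `table5` (district MMR, with 1999-endpoint flags), `table6` (district MMR
#' summary labels), `table9` (conflict-impact weight histogram as printed),
#' and `national_series` (long-format national anchor values).
#'
#' @param name Fixture name, e.g. `"table3"`.
#' @return A tibble.
#' @export
#' @examples
#' load_fixture("table3")
#' load_fixture("table2")
load_fixture <- function(name) {
  files <- fixture_files()
  if (!is.character(name) || length(name) != 1 || !name %in% names(files)) {
    abort(paste0(
      "unknown fixture '", paste(name, collapse = ","), "'; available: ",
      paste(names(files), collapse = ", ")
    ))
  }
  tb <- readr::read_csv(fixture_path(files[[name]]),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  num_cols <- switch(name,
    table2 = c("year", "actual", "counterfactual_5yr", "counterfactual_10yr",
               "trend_prewar_5yr", "trend_prewar_10yr", "trend_conflict"),
    table3 = c("imr_1982", "imr_2002", "counterfactual_2002",
               "rate_prewar", "rate_conflict"),
    table5 = c("mmr_1982", "mmr_2002", "counterfactual_2002",
               "rate_prewar", "rate_conflict"),
    table9 = "n_districts",
    national_series = c("year", "value"),
    character(0)
  )
  for (cc in num_cols) tb[[cc]] <- parse_printed_numeric(tb[[cc]])
  if ("endpoint_1999" %in% names(tb)) {
    tb$endpoint_1999 <- toupper(tb$endpoint_1999) == "TRUE"
  }
  if ("district" %in% names(tb)) {
    tb$unit_id <- canonical_unit_id(tb$district)
    tb$conflict_class <- normalize_conflict_class(tb$conflict_class)
  }
  if ("year" %in% names(tb)) tb$year <- as.integer(tb$year)
  tb
}

#' Fixture manifest
#'
#' Table-of-origin record for every packaged fixture file.
#'
#' @return A tibble with columns `file`, `origin`, `notes`.
#' @export
fixture_manifest <- function() {
  m <- jsonlite::read_json(fixture_path("manifest.json"))
  tibble::tibble(
    file = names(m),
    origin = purrr::map_chr(m, "origin"),
    notes = purrr::map_chr(m, "notes")
  )
}

#' District analysis table in standard form
#'
#' Reshapes the packaged district fixtures (IMR from `table3` + labels from
#' `table4`; MMR from `table5`/`table6`) into the standard columns every
#' downstream stage consumes: baseline and endpoint levels, the printed
#' counterfactual, the printed pre-war and conflict-period rates, the
#' endpoint year actually available (1999 for the footnoted MMR rows), and
#' the printed interpretation label.
#'
#' @param indicator `"IMR"` or `"MMR"`.
#' @return A tibble with columns `unit_id`, `indicator`, `conflict_class`,
#'   `baseline`, `actual`, `counterfactual`, `rate_prewar`, `rate_conflict`,
#'   `endpoint_year`, `printed_label`.
#' @export
#' @examples
#' district_table("IMR")
district_table <- function(indicator = c("IMR", "MMR")) {
  indicator <- match.arg(indicator)
  if (indicator == "IMR") {
    raw <- load_fixture("table3")
    lab <- dplyr::select(load_fixture("table4"), "unit_id", printed_label = "label")
    out <- tibble::tibble(
      unit_id = raw$unit_id,
      indicator = "IMR",
      conflict_class = raw$conflict_class,
      baseline = raw$imr_1982,
      actual = raw$imr_2002,
      counterfactual = raw$counterfactual_2002,
      rate_prewar = raw$rate_prewar,
      rate_conflict = raw$rate_conflict,
      endpoint_year = 2002L
    )
  } else {
    raw <- load_fixture("table5")
    lab <- dplyr::select(load_fixture("table6"), "unit_id", printed_label = "label")
    out <- tibble::tibble(
      unit_id = raw$unit_id,
      indicator = "MMR",
      conflict_class = raw$conflict_class,
      baseline = raw$mmr_1982,
      actual = raw$mmr_2002,
      counterfactual = raw$counterfactual_2002,
      rate_prewar = raw$rate_prewar,
      rate_conflict = raw$rate_conflict,
      endpoint_year = ifelse(raw$endpoint_1999, 1999L, 2002L)
    )
  }
  dplyr::left_join(out, lab, by = "unit_id")
}

#' National analysis table in standard form
#'
#' The national actual/counterfactual outcomes and printed trends, one row
#' per indicator and endpoint year.
#'
#' @return A tibble (columns as in [load_fixture()]'s `table2` plus nothing
#'   recomputed).
#' @export
national_table <- function() {
  load_fixture("table2")
}

#' Printed interpretation labels
#'
#' The published per-district summary labels ("Rate and IMR are worse",
#' "Unable to determine", ...) as a standard records set, used for
#' label-based tallies and for reconciliation against computed labels.
#'
#' @param indicator `"IMR"` or `"MMR"`.
#' @return A tibble with columns `unit_id`, `indicator`, `label`.
#' @export
#' @examples
#' printed_labels("MMR")
printed_labels <- function(indicator = c("IMR", "MMR")) {
  indicator <- match.arg(indicator)
  tb <- load_fixture(if (indicator == "IMR") "table4" else "table6")
  tibble::tibble(unit_id = tb$unit_id, indicator = indicator, label = tb$label)
}
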