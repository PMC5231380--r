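#' Read a long-format indicator series CSV
#'
#' Expects columns `unit_id`, `indicator`, `year`, `value` (extra columns are
#' preserved). Values are deaths per 1,000 live births. Blank values are
#' treated as missing observations: the rows are dropped and counted in the
#' load report attached to the result. Non-numeric value text (for example
#' `"n/a"`) is a hard error naming the offending rows, as are duplicate
#' (unit, indicator, year) rows whose values conflict; duplicate rows with
#' identical values collapse to one observation.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `unit_id` (canonicalised spelling),
#'   `indicator` (`"IMR"`/`"MMR"`), `year` (integer), `value` (double), plus
#'   any extra input columns, sorted by unit, indicator, year. The attribute
#'   `"load_report"` records `n_rows_read`, `n_missing_dropped`,
#'   `n_duplicates_collapsed` and `n_series`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "unit_id,indicator,year,value",
#'   "Jaffna,IMR,1982,17", "Jaffna,IMR,2002,6", "Jaffna,IMR,1999,"
#' ), f)
#' s <- read_indicator_series(f)
#' attr(s, "load_report")$n_missing_dropped
read_indicator_series <- function(path) {
  if (!file.exists(path)) abort(paste0("series file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      unit_id = readr::col_character(),
      indicator = readr::col_character(),
      year = readr::col_integer(),
      value = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c("unit_id", "indicator", "year", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("series CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort("no series loaded: series CSV has no data rows")

  raw$.row <- seq_len(nrow(raw)) + 1L # header is row 1 in the file

  blank <- is.na(raw$value) | trimws(raw$value) == ""
  kept <- raw[!blank, , drop = FALSE]

  val <- suppressWarnings(as.numeric(kept$value))
  bad <- which(is.na(val))
  if (length(bad) > 0) {
    abort(paste0(
      "non-numeric value(s) in series CSV at file row(s) ",
      paste(kept$.row[bad], collapse = ", "), ": ",
      paste(unique(kept$value[bad]), collapse = ", ")
    ))
  }
  kept$value <- val
  if (any(kept$value < 0)) {
    abort(paste0(
      "negative value(s) in series CSV at file row(s) ",
      paste(kept$.row[kept$value < 0], collapse = ", ")
    ))
  }

  kept$unit_id <- canonical_unit_id(kept$unit_id)
  kept$indicator <- check_indicator(kept$indicator)
  if (anyNA(kept$year)) abort("missing or non-integer year in series CSV")

  dup <- dplyr::group_by(kept, .data$unit_id, .data$indicator, .data$year)
  conflicts <- dplyr::filter(dup, dplyr::n_distinct(.data$value) > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0(
      "conflicting duplicate observations at file row(s) ",
      paste(conflicts$.row, collapse = ", "), " (",
      paste(unique(paste(conflicts$unit_id, conflicts$indicator, conflicts$year)),
            collapse = "; "), ")"
    ))
  }
  n_before <- nrow(kept)
  out <- dplyr::ungroup(dplyr::slice_head(dup, n = 1))
  n_collapsed <- n_before - nrow(out)

  out <- dplyr::arrange(
    dplyr::select(out, -".row"),
    .data$unit_id, .data$indicator, .data$year
  )
  attr(out, "load_report") <- list(
    n_rows_read = nrow(raw),
    n_missing_dropped = sum(blank),
    n_duplicates_collapsed = n_collapsed,
    n_series = nrow(dplyr::distinct(out, .data$unit_id, .data$indicator))
  )
  out
}

#' Read a unit metadata CSV
#'
#' Expects columns `unit_id`, `conflict_class`, `creation_year`,
#' `imr_endpoint_year`, `mmr_endpoint_year`. Conflict classes are normalised
#' to `high` / `intermittent` / `none` / `national`; endpoint years must be
#' 1999 or 2002.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per unit.
#' @export
read_unit_meta <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  meta <- readr::read_csv(
    path,
    col_types = readr::cols(
      unit_id = readr::col_character(),
      conflict_class = readr::col_character(),
      creation_year = readr::col_integer(),
      imr_endpoint_year = readr::col_integer(),
      mmr_endpoint_year = readr::col_integer()
    ),
    progress = FALSE
  )
  need <- c("unit_id", "conflict_class", "creation_year",
            "imr_endpoint_year", "mmr_endpoint_year")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  meta$unit_id <- canonical_unit_id(meta$unit_id)
  meta$conflict_class <- normalize_conflict_class(meta$conflict_class)
  eps <- c(meta$imr_endpoint_year, meta$mmr_endpoint_year)
  if (!all(eps %in% c(1999L, 2002L) | is.na(eps))) {
    abort("endpoint years must be 1999 or 2002")
  }
  if (anyDuplicated(meta$unit_id)) {
    abort(paste0(
      "duplicate unit_id in metadata: ",
      paste(unique(meta$unit_id[duplicated(meta$unit_id)]), collapse = ", ")
    ))
  }
  dplyr::arrange(meta, .data$unit_id)
}

#' Write result records deterministically
#'
#' Rows are ordered lexicographically by `unit_id` (then by any of
#' `indicator`, `year` present) and columns keep their input order, so repeat
#' runs on the same records produce byte-identical files.
#'
#' @param records A data frame of validated result records.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  keys <- intersect(c("unit_id", "indicator", "year", "shape", "weight"), names(records))
  if (length(keys) > 0) {
    records <- dplyr::arrange(records, dplyr::across(dplyr::all_of(keys)))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    readr::write_csv(records, path, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
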