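#' Run the full conflict-impact analysis on an observation panel
#'
#' Chains the stages: pre-war trend estimation over the configured window,
#' compound counterfactual projection of the baseline observation to each
#' unit's endpoint year, conflict-window trend estimation, rate and endpoint
#' classification, interpretation labels, the 0--4 impact index, and the
#' headline tallies.
#'
#' @param series Long tibble (`unit_id`, `indicator`, `year`, `value`).
#' @param meta Unit metadata (`unit_id`, `conflict_class`, `creation_year`,
#'   endpoint years).
#' @param config A [study_config()].
#' @return A `conflict_impact` object: list with `classification`,
#'   `index`, `tally`, `trends`, `config`, `meta`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @export
#' @examples
#' panel <- generate_panel(synthetic_config(n_units = 6, noise_cv = 0,
#'                                          missing_prob = 0, seed = 3))
#' fit <- analyze_conflict_impact(panel$series, panel$meta)
#' glance(fit)
analyze_conflict_impact <- function(series, meta, config = study_config()) {
  if (!is.data.frame(series) || nrow(series) == 0) {
    abort("no series loaded: the observation panel is empty")
  }
  cf <- build_counterfactual(series, meta, config)

  conflict <- purrr::map(unique(cf$endpoint_year), function(ep) {
    sub_pairs <- cf[cf$endpoint_year == ep, c("unit_id", "indicator")]
    sub <- dplyr::semi_join(series, sub_pairs, by = c("unit_id", "indicator"))
    estimate_window_trend(sub, config$baseline_year, ep, basis = "conflict")
  }) |> dplyr::bind_rows()

  cls <- cf |>
    dplyr::left_join(
      dplyr::select(conflict, "unit_id", "indicator", rate_conflict = "rate"),
      by = c("unit_id", "indicator")
    ) |>
    classify_units(tolerance = config$tie_tolerance)

  index <- impact_index(cls)
  tally <- tally_classifications(cls, meta, index)

  prewar <- estimate_window_trend(
    series, config$baseline_year - config$prewar_window_years,
    config$baseline_year, basis = "prewar"
  )

  structure(
    list(
      classification = cls,
      index = index,
      tally = tally,
      trends = dplyr::bind_rows(prewar, conflict),
      config = config,
      meta = meta
    ),
    class = "conflict_impact"
  )
}

#' @export
print.conflict_impact <- function(x, ...) {
  n_units <- dplyr::n_distinct(x$classification$unit_id)
  n_assess <- sum(x$classification$assessable)
  cat(sprintf(
    "<conflict_impact> %d units; %d of %d unit-indicator series assessable\n",
    n_units, n_assess, nrow(x$classification)
  ))
  counts <- x$tally$counts
  for (ind in unique(counts$indicator)) {
    ci <- counts[counts$indicator == ind, ]
    cat(sprintf(
      "  %s: endpoint worse in %d, rate slowed in %d\n", ind,
      ci$n[ci$metric == "endpoint_worse"], ci$n[ci$metric == "rate_worse"]
    ))
  }
  invisible(x)
}

#' @export
tidy.conflict_impact <- function(x, ...) {
  x$classification |>
    dplyr::left_join(dplyr::select(x$index, "unit_id", "weight", "weight_class"),
                     by = "unit_id") |>
    dplyr::select(
      "unit_id", "indicator", "rate_prewar", "rate_conflict",
      "baseline_value", "actual", "counterfactual",
      "rate_flag", "endpoint_flag", "label", "weight", "weight_class"
    ) |>
    tibble::as_tibble()
}

#' @export
glance.conflict_impact <- function(x, ...) {
  counts <- x$tally$counts
  pull_n <- function(ind, metric) {
    v <- counts$n[counts$indicator == ind & counts$metric == metric]
    if (length(v) == 0) NA_integer_ else v
  }
  tibble::tibble(
    n_units = dplyr::n_distinct(x$classification$unit_id),
    n_assessable = sum(x$classification$assessable),
    imr_endpoint_worse = pull_n("IMR", "endpoint_worse"),
    imr_rate_worse = pull_n("IMR", "rate_worse"),
    mmr_endpoint_worse = pull_n("MMR", "endpoint_worse"),
    mmr_rate_worse = pull_n("MMR", "rate_worse"),
    median_weight = stats::median(x$index$weight, na.rm = TRUE)
  )
}

collect_warnings <- function(expr) {
  msgs <- character(0)
  value <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = msgs)
}

run_manifest <- function(out_dir, config, inputs, warnings, extra = list()) {
  manifest <- c(
    list(
      package = "momentumcf",
      version = as.character(utils::packageVersion("momentumcf")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      warnings = as.list(warnings)
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the analysis from input files to an output directory
#'
#' Reads a series CSV and a metadata CSV, runs
#' [analyze_conflict_impact()], and writes `classification.csv`,
#' `index.csv`, `tally.json`, `reconciliation.csv` (printed-vs-recomputed
#' counterfactual reconciliation over the classified table) and
#' `manifest.json` (config snapshot, input digests, package version,
#' warnings) into `out_dir`. Result files are deterministic for identical
#' inputs and configuration; only the manifest timestamp differs between
#' reruns.
#'
#' @param series_csv,meta_csv Input paths.
#' @param out_dir Output directory (created if needed).
#' @param config A [study_config()]; ignored when `config_file` is given.
#' @param config_file Optional YAML/JSON config file (see
#'   [read_study_config()]).
#' @return The `conflict_impact` object, invisibly.
#' @export
run_analysis <- function(series_csv, meta_csv, out_dir,
                         config = study_config(), config_file = NULL) {
  if (!is.null(config_file)) config <- read_study_config(config_file)
  series <- read_indicator_series(series_csv)
  meta <- read_unit_meta(meta_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- collect_warnings(analyze_conflict_impact(series, meta, config))
  fit <- res$value

  write_results(fit$classification, file.path(out_dir, "classification.csv"))
  write_results(fit$index, file.path(out_dir, "index.csv"))
  jsonlite::write_json(
    list(counts = fit$tally$counts, weights = fit$tally$weights),
    file.path(out_dir, "tally.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  recon <- reconcile_counterfactuals(
    dplyr::rename(fit$classification, baseline = "baseline_value"), config
  )
  write_results(recon, file.path(out_dir, "reconciliation.csv"))
  run_manifest(
    out_dir, config, c(series_csv, meta_csv), res$warnings,
    extra = list(load_report = attr(series, "load_report"))
  )
  invisible(fit)
}

#' Run the projection-shape sensitivity analysis from input files
#'
#' @param series_csv,meta_csv Input paths.
#' @param out_dir Output directory.
#' @param shapes At least two of [projection_shapes()].
#' @param config A [study_config()].
#' @return The sensitivity tibble (see [sensitivity_analysis()]), invisibly.
#' @export
run_sensitivity <- function(series_csv, meta_csv, out_dir,
                            shapes = c("compound", "linear", "exponential", "logarithmic"),
                            config = study_config()) {
  series <- read_indicator_series(series_csv)
  meta <- read_unit_meta(meta_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cf <- build_counterfactual(series, meta, config)
  sens <- sensitivity_analysis(cf, shapes = shapes, config = config)
  write_results(sens, file.path(out_dir, "sensitivity.csv"))
  jsonlite::write_json(attr(sens, "summary"),
                       file.path(out_dir, "sensitivity_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_manifest(out_dir, config, c(series_csv, meta_csv), character(0),
               extra = list(shapes = shapes))
  invisible(sens)
}

#' Join impact weights onto district boundaries (choropleth export)
#'
#' Reads a GeoJSON `FeatureCollection`, matches each feature's name property
#' against the impact-index units (applying the district alias table for
#' variant spellings), and writes a copy in which matched features gain
#' `weight` and `weight_class` properties. Geometry is untouched. Districts
#' present in the index but absent from the boundary file are returned as
#' `unmatched` (and recorded in the output's `unmatched_units` top-level
#' member).
#'
#' @param index An [impact_index()] tibble (or path to a CSV with `unit_id`
#'   and `weight` columns).
#' @param boundaries_path Input GeoJSON path.
#' @param out_path Output GeoJSON path.
#' @param join_key Feature property holding the district name (default
#'   `"name"`).
#' @return Invisibly, a list with `path`, `n_matched`, `unmatched`.
#' @export
export_map <- function(index, boundaries_path, out_path, join_key = "name") {
  if (is.character(index)) {
    index <- readr::read_csv(index, show_col_types = FALSE, progress = FALSE)
  }
  if (!all(c("unit_id", "weight") %in% names(index))) {
    abort("index must have unit_id and weight columns")
  }
  if (nrow(index) == 0) abort("empty impact index: nothing to join")
  if (!"weight_class" %in% names(index)) {
    index$weight_class <- weight_class(index$weight)
  }
  gj <- jsonlite::read_json(boundaries_path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection" || is.null(gj$features)) {
    abort("boundaries file is not a GeoJSON FeatureCollection")
  }
  index$unit_id <- canonical_unit_id(index$unit_id)
  matched_units <- character(0)
  gj$features <- purrr::map(gj$features, function(f) {
    nm <- f$properties[[join_key]]
    if (is.null(nm)) return(f)
    cid <- canonical_unit_id(nm)
    i <- match(cid, index$unit_id)
    if (!is.na(i)) {
      matched_units <<- c(matched_units, cid)
      f$properties$weight <- if (is.na(index$weight[i])) "not_assessable" else index$weight[i]
      f$properties$weight_class <- index$weight_class[i]
    }
    f
  })
  if (length(matched_units) == 0) {
    abort("zero joins: no boundary feature name matched the impact index")
  }
  unmatched <- setdiff(index$unit_id, matched_units)
  gj$unmatched_units <- as.list(unmatched)
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(gj, out_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(path = out_path, n_matched = length(matched_units),
                 unmatched = unmatched))
}
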