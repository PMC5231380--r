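#' Projection shapes
#'
#' Functional forms available for counterfactual projection. `"compound"` is
#' the default throughout: back-solving the published national counterfactuals
#' (34 -> 15.04 over 20 years implies a rate of about -0.04; 0.60 -> 0.11
#' implies about -0.08) shows that the published figures compound the average
#' annual rate, whereas an arithmetic-linear projection (34 * (1 - 0.04 * 20)
#' = 6.8) contradicts every published counterfactual value.
#'
#' @return Character vector of supported shape names.
#' @export
#' @examples
#' projection_shapes()
projection_shapes <- function() c("compound", "linear", "exponential", "logarithmic")

#' Study configuration
#'
#' Bundles the analysis constants: the baseline (last pre-war) year, the
#' conflict endpoint year, the pre-war window length, the report rounding,
#' the tie tolerance used when comparing rates or levels, and the projection
#' shape.
#'
#' Defaults reproduce the primary Sri Lanka analysis: baseline 1982, endpoint
#' 2002 (1999 fallback carried in the unit metadata), a 1975--1982 pre-war
#' window (7 years), two-decimal reporting, strict comparisons (tolerance 0),
#' and compound projection.
#'
#' @param baseline_year Last pre-conflict year; projections start here.
#' @param endpoint_year Default conflict endpoint; unit metadata may override
#'   it per indicator (e.g. 1999 where later data are unavailable).
#' @param prewar_window_years Length of the pre-war estimation window, ending
#'   at `baseline_year`. 7 spans 1975--1982 (the district tables); 5 and 10
#'   give the national variants.
#' @param rounding_decimals Decimals used when printing rates and levels.
#' @param tie_tolerance Non-negative slack: differences within the tolerance
#'   classify as `"same"`.
#' @param projection_shape One of [projection_shapes()].
#' @return A `study_config` object (a named list).
#' @export
#' @examples
#' study_config()
#' study_config(prewar_window_years = 10)
study_config <- function(baseline_year = 1982,
                         endpoint_year = 2002,
                         prewar_window_years = 7,
                         rounding_decimals = 2,
                         tie_tolerance = 0,
                         projection_shape = "compound") {
  projection_shape <- match.arg(projection_shape, projection_shapes())
  stopifnot(
    is_count(baseline_year), is_count(endpoint_year),
    is_count(prewar_window_years), is_count(rounding_decimals + 1L)
  )
  if (baseline_year >= endpoint_year) {
    abort("baseline_year must precede endpoint_year")
  }
  if (!is_number(tie_tolerance) || tie_tolerance < 0) {
    abort("tie_tolerance must be a non-negative number")
  }
  structure(
    list(
      baseline_year = as.integer(baseline_year),
      endpoint_year = as.integer(endpoint_year),
      prewar_window_years = as.integer(prewar_window_years),
      rounding_decimals = as.integer(rounding_decimals),
      tie_tolerance = tie_tolerance,
      projection_shape = projection_shape
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf(
    "  baseline %d -> endpoint %d (pre-war window %d yr)\n",
    x$baseline_year, x$endpoint_year, x$prewar_window_years
  ))
  cat(sprintf(
    "  shape: %s, tie tolerance: %g, printed decimals: %d\n",
    x$projection_shape, x$tie_tolerance, x$rounding_decimals
  ))
  invisible(x)
}

#' Read a study configuration from a YAML or JSON file
#'
#' The file holds any subset of the [study_config()] fields; unnamed fields
#' keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  keep <- intersect(names(vals), names(formals(study_config)))
  do.call(study_config, vals[keep])
}
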