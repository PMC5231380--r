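#' Synthetic panel configuration
#'
#' Describes an indicator panel with the statistical structure the analysis
#' assumes: per-unit pre-war improvement, a conflict-period change of a
#' different magnitude, multiplicative observation noise, missing years,
#' late-created units without pre-war data, and mixed 1999/2002 endpoints.
#'
#' Conventions (documented in the methods vignette): the noise-free pre-war
#' segment is anchored so that the two-point average-annual-change estimator
#' recovers `prewar_rate` exactly over the pre-war window, with geometric
#' interpolation in between; from the baseline on, values compound at
#' `prewar_rate * conflict_rate_multiplier` per year, so a multiplier of 1
#' reproduces the compound counterfactual exactly at the endpoint. A
#' multiplier below 1 on an improving (negative) rate is a wartime slowdown.
#' Observation noise is multiplicative lognormal with coefficient of
#' variation `noise_cv` (mortality rates are positive and right-skewed).
#'
#' Late-created units are the first `ceiling(late_creation_fraction *
#' n_units)` units and 1999-endpoint units the next `floor(
#' endpoint_1999_fraction * n_units)`: deterministic assignment keeps
#' [expected_flags()] computable from the configuration alone.
#'
#' @param n_units Number of district-like units.
#' @param years Observation years (default 1975--2002).
#' @param baseline_year Last pre-war year (default 1982).
#' @param prewar_rate Pre-war annual proportional change; scalar or one per
#'   unit. Default -0.05, a typical district-level pre-war IMR decline.
#' @param conflict_rate_multiplier Multiplier on the rate during conflict
#'   (1 = no war effect, < 1 = slowdown); scalar or per unit. Default 0.5.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   observation noise (default 0.05).
#' @param missing_prob Probability each observation year is missing
#'   (default 0.05).
#' @param late_creation_fraction Fraction of units created after the pre-war
#'   window opens (no pre-baseline observations). Default 0.08 (2 of 25).
#' @param endpoint_1999_fraction Fraction of units whose series end in 1999
#'   instead of 2002. Default 0.32 (8 of 25).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return A `synthetic_config` object.
#' @export
#' @examples
#' synthetic_config(n_units = 10, noise_cv = 0, seed = 7)
synthetic_config <- function(n_units = 25,
                             years = 1975:2002,
                             baseline_year = 1982,
                             prewar_rate = -0.05,
                             conflict_rate_multiplier = 0.5,
                             noise_cv = 0.05,
                             missing_prob = 0.05,
                             late_creation_fraction = 0.08,
                             endpoint_1999_fraction = 0.32,
                             seed = 1L) {
  if (!is_count(n_units)) abort("n_units must be a positive integer")
  years <- as.integer(years)
  if (!baseline_year %in% years || baseline_year == min(years) ||
      baseline_year == max(years)) {
    abort("baseline_year must lie strictly inside the span of years")
  }
  if (!all(is.finite(prewar_rate)) || any(prewar_rate <= -1)) {
    abort("prewar_rate must be finite and > -1")
  }
  if (!all(is.finite(conflict_rate_multiplier))) {
    abort("conflict_rate_multiplier must be finite")
  }
  if (!length(prewar_rate) %in% c(1L, n_units) ||
      !length(conflict_rate_multiplier) %in% c(1L, n_units)) {
    abort("rates and multipliers must have length 1 or n_units")
  }
  if (!is_number(noise_cv) || noise_cv < 0) abort("noise_cv must be >= 0")
  if (!is_number(missing_prob) || missing_prob < 0 || missing_prob >= 1) {
    abort("missing_prob must be in [0, 1)")
  }
  for (f in c(late_creation_fraction, endpoint_1999_fraction)) {
    if (!is_number(f) || f < 0 || f >= 1) {
      abort("fractions must be in [0, 1)")
    }
  }
  if (!is_count(seed + 1)) abort("seed must be an integer")
  structure(
    list(
      n_units = as.integer(n_units),
      years = years,
      baseline_year = as.integer(baseline_year),
      prewar_rate = rep_len(prewar_rate, n_units),
      conflict_rate_multiplier = rep_len(conflict_rate_multiplier, n_units),
      noise_cv = noise_cv,
      missing_prob = missing_prob,
      late_creation_fraction = late_creation_fraction,
      endpoint_1999_fraction = endpoint_1999_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

synthetic_unit_ids <- function(n) sprintf("unit_%03d", seq_len(n))

# Deterministic role assignment so the closed-form oracle needs only the config.
synthetic_roles <- function(config) {
  n <- config$n_units
  n_late <- ceiling(config$late_creation_fraction * n)
  n_1999 <- floor(config$endpoint_1999_fraction * n)
  late <- seq_len(n) <= n_late
  ep1999 <- seq_len(n) > n_late & seq_len(n) <= n_late + n_1999
  tibble::tibble(
    unit_id = synthetic_unit_ids(n),
    late_created = late,
    creation_year = ifelse(late, config$baseline_year + 2L, NA_integer_),
    endpoint_year = ifelse(ep1999, 1999L, max(config$years))
  )
}

# Noise-free value of one unit-indicator trajectory at given years.
# Pre-war: anchored so the two-point estimator over [start, baseline]
# returns exactly `rate`; geometric interpolation between the anchors.
# Conflict: compound at rate * multiplier from the baseline value.
synthetic_true_values <- function(v_start, rate, multiplier, years,
                                  year_start, baseline_year) {
  w <- baseline_year - year_start
  v_base <- v_start * (1 + rate * w)
  if (v_base <= 0) abort("prewar_rate too negative: trajectory hits zero before baseline")
  pre <- years <= baseline_year
  out <- numeric(length(years))
  # geometric interpolation between the two pre-war anchors
  out[pre] <- v_start * (v_base / v_start)^((years[pre] - year_start) / w)
  out[!pre] <- v_base * (1 + rate * multiplier)^(years[!pre] - baseline_year)
  out
}

#' Generate a synthetic indicator panel
#'
#' Produces a long observation panel (both IMR- and MMR-scaled indicators
#' per unit), matching unit metadata, and a ground-truth table carrying the
#' true rates and the analytically implied flags. The same seed always
#' reproduces the identical panel; noise-free values are strictly positive
#' before missingness is applied.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_panel`: `series` (long tibble in the
#'   same format [read_indicator_series()] ingests), `meta` (unit metadata),
#'   `truth` (per unit x indicator ground truth, with `assessable` reflecting
#'   the realised missingness).
#' @export
#' @examples
#' panel <- generate_panel(synthetic_config(n_units = 5, noise_cv = 0, seed = 1))
#' panel$series
#' panel$truth
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  roles <- synthetic_roles(config)
  oracle <- expected_flags(config)
  scales <- c(IMR = 40, MMR = 0.8)
  sigma <- sqrt(log(1 + config$noise_cv^2))

  withr::with_seed(config$seed, {
    rows <- purrr::map(seq_len(config$n_units), function(i) {
      uid <- roles$unit_id[i]
      rate <- config$prewar_rate[i]
      mult <- config$conflict_rate_multiplier[i]
      first_year <- if (roles$late_created[i]) roles$creation_year[i] else min(config$years)
      last_year <- roles$endpoint_year[i]
      yrs <- config$years[config$years >= first_year & config$years <= last_year]
      purrr::map(names(scales), function(ind) {
        v_start <- stats::rlnorm(1, meanlog = log(scales[[ind]]), sdlog = 0.25)
        truth_vals <- if (roles$late_created[i]) {
          # no pre-war anchoring possible; flat-ish decline from creation
          v_start * (1 + rate * mult)^(yrs - first_year)
        } else {
          synthetic_true_values(v_start, rate, mult, yrs,
                                min(config$years), config$baseline_year)
        }
        noise <- if (config$noise_cv > 0) {
          exp(stats::rnorm(length(yrs), mean = -sigma^2 / 2, sd = sigma))
        } else {
          rep(1, length(yrs))
        }
        keep <- stats::runif(length(yrs)) >= config$missing_prob
        tibble::tibble(
          unit_id = uid, indicator = ind, year = yrs,
          value = truth_vals * noise
        )[keep, ]
      }) |> dplyr::bind_rows()
    })
    series <- dplyr::bind_rows(rows)
  })

  meta <- tibble::tibble(
    unit_id = roles$unit_id,
    conflict_class = "none",
    creation_year = roles$creation_year,
    imr_endpoint_year = roles$endpoint_year,
    mmr_endpoint_year = roles$endpoint_year
  )

  avail <- series |>
    dplyr::left_join(dplyr::select(roles, "unit_id", ep = "endpoint_year"),
                     by = "unit_id") |>
    dplyr::group_by(.data$unit_id, .data$indicator) |>
    dplyr::summarise(
      has_baseline = any(.data$year == config$baseline_year),
      has_prestart = any(.data$year < config$baseline_year),
      has_endpoint = any(.data$year == .data$ep),
      .groups = "drop"
    )
  truth <- dplyr::left_join(oracle, avail, by = c("unit_id", "indicator"))
  truth$has_baseline[is.na(truth$has_baseline)] <- FALSE
  truth$has_prestart[is.na(truth$has_prestart)] <- FALSE
  truth$has_endpoint[is.na(truth$has_endpoint)] <- FALSE
  truth$assessable <- !truth$late_created & truth$has_baseline &
    truth$has_prestart & truth$has_endpoint
  truth$rate_flag[!truth$assessable] <- "not_assessable"
  truth$endpoint_flag[!truth$assessable] <- "not_assessable"

  structure(
    list(series = series, meta = meta,
         truth = dplyr::select(truth, -"has_baseline", -"has_prestart", -"has_endpoint"),
         config = config),
    class = "synthetic_panel"
  )
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "<synthetic_panel> %d units x %d indicators, years %d-%d, %d observations\n",
    x$config$n_units, length(unique(x$series$indicator)),
    min(x$config$years), max(x$config$years), nrow(x$series)
  ))
  invisible(x)
}

#' Analytic ground-truth flags for a synthetic configuration
#'
#' Closed-form oracle for end-to-end recovery tests: the flags the pipeline
#' must produce on a noise-free, fully observed panel drawn from `config`.
#' With the generator's conventions the estimated pre-war rate equals `r =
#' prewar_rate`, the compound counterfactual endpoint factor is `(1 + r)^t`,
#' the actual endpoint factor is `(1 + r m)^t` (`m` the multiplier), and the
#' measured conflict-window rate is `((1 + r m)^t - 1) / t`. Late-created
#' units are always `not_assessable`. Missingness is ignored (the oracle is
#' exact for `missing_prob = 0`; [generate_panel()]'s truth table overlays
#' realised assessability).
#'
#' @param config A [synthetic_config()].
#' @param tolerance Tie tolerance used for the analytic comparisons
#'   (default 0).
#' @return A tibble per unit x indicator: true rates, `rate_flag`,
#'   `endpoint_flag`.
#' @export
#' @examples
#' expected_flags(synthetic_config(n_units = 4, conflict_rate_multiplier = 1,
#'                                 noise_cv = 0, missing_prob = 0))
expected_flags <- function(config, tolerance = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  roles <- synthetic_roles(config)
  per_unit <- tibble::tibble(
    unit_id = roles$unit_id,
    prewar_rate = config$prewar_rate,
    conflict_rate_multiplier = config$conflict_rate_multiplier,
    late_created = roles$late_created,
    endpoint_year = roles$endpoint_year
  )
  horizon <- per_unit$endpoint_year - config$baseline_year
  r <- per_unit$prewar_rate
  m <- per_unit$conflict_rate_multiplier
  cf_factor <- (1 + r)^horizon
  actual_factor <- (1 + r * m)^horizon
  rate_conflict <- (actual_factor - 1) / horizon

  endpoint_flag <- classify_endpoint(actual_factor, cf_factor, TRUE, tolerance)
  rate_flag <- classify_rate_change(r, rate_conflict, tolerance)
  endpoint_flag[per_unit$late_created] <- "not_assessable"
  rate_flag[per_unit$late_created] <- "not_assessable"

  per_unit$rate_conflict_measured <- rate_conflict
  per_unit$rate_flag <- rate_flag
  per_unit$endpoint_flag <- endpoint_flag
  tidyr::crossing(per_unit, indicator = c("IMR", "MMR")) |>
    dplyr::relocate("unit_id", "indicator") |>
    dplyr::arrange(.data$unit_id, .data$indicator)
}
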