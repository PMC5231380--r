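# Canonical district register for the Sri Lanka study: 25 districts plus the
# NATIONAL pseudo-unit, the three-way conflict taxonomy, district creation
# years (late-created Vanni districts lack pre-war data), and the endpoint
# year available per indicator (1999 where 2002 data were unavailable).
# Spellings follow the published district tables; known variant spellings are
# carried as aliases so joins against boundary files and the source text work.

sri_lanka_register <- function() {
  tibble::tribble(
    ~unit_id,       ~conflict_class, ~creation_year, ~imr_endpoint_year, ~mmr_endpoint_year,
    "Batticaloa",   "high",          NA_integer_,    2002L,              1999L,
    "Jaffna",       "high",          NA_integer_,    2002L,              2002L,
    "Kilinochchi",  "high",          1984L,          2002L,              1999L,
    "Mannar",       "high",          NA_integer_,    2002L,              1999L,
    "Mullaitivu",   "high",          1978L,          2002L,              1999L,
    "Trincomalee",  "high",          NA_integer_,    2002L,              1999L,
    "Vavuniya",     "high",          NA_integer_,    2002L,              1999L,
    "Ampara",       "intermittent",  NA_integer_,    2002L,              2002L,
    "Anuradhapura", "intermittent",  NA_integer_,    2002L,              2002L,
    "Polonnaruwa",  "intermittent",  NA_integer_,    2002L,              2002L,
    "Puttalam",     "intermittent",  NA_integer_,    2002L,              2002L,
    "Badulla",      "none",          NA_integer_,    2002L,              2002L,
    "Colombo",      "none",          NA_integer_,    2002L,              2002L,
    "Galle",        "none",          NA_integer_,    2002L,              2002L,
    "Gampaha",      "none",          NA_integer_,    2002L,              2002L,
    "Hambantota",   "none",          NA_integer_,    2002L,              2002L,
    "Kaluthara",    "none",          NA_integer_,    2002L,              2002L,
    "Kandy",        "none",          NA_integer_,    2002L,              2002L,
    "Kegalle",      "none",          NA_integer_,    2002L,              1999L,
    "Kurunegala",   "none",          NA_integer_,    2002L,              2002L,
    "Matale",       "none",          NA_integer_,    2002L,              1999L,
    "Matara",       "none",          NA_integer_,    2002L,              2002L,
    "Moneragala",   "none",          NA_integer_,    2002L,              2002L,
    "Nuwara Eliya", "none",          NA_integer_,    2002L,              2002L,
    "Ratnapura",    "none",          NA_integer_,    2002L,              2002L,
    "NATIONAL",     "national",      NA_integer_,    2002L,              2002L
  )
}

#' District name aliases
#'
#' Variant spellings that occur in the source tables, prose, and common
#' boundary files, mapped to the canonical spelling used throughout the
#' package.
#'
#' @return A tibble with columns `alias` and `unit_id`.
#' @export
#' @examples
#' district_aliases()
district_aliases <- function() {
  tibble::tribble(
    ~alias,          ~unit_id,
    "Kilinochi",     "Kilinochchi",
    "Killinochchi",  "Kilinochchi",
    "Baticalloa",    "Batticaloa",
    "Batticoloa",    "Batticaloa",
    "Trincomallee",  "Trincomalee",
    "Kalutara",      "Kaluthara",
    "Monaragala",    "Moneragala",
    "Nuwara-Eliya",  "Nuwara Eliya",
    "NuwaraEliya",   "Nuwara Eliya",
    "Vavuniy",       "Vavuniya",
    "Mullativu",     "Mullaitivu",
    "Sri Lanka",     "NATIONAL"
  )
}

#' Canonicalise unit identifiers
#'
#' Trims whitespace and resolves known variant spellings (see
#' [district_aliases()]) to the canonical district name. Unknown names pass
#' through unchanged so user-supplied units outside the packaged register are
#' not mangled.
#'
#' @param x Character vector of unit names.
#' @return Character vector of the same length.
#' @export
#' @examples
#' canonical_unit_id(c("Kilinochi", "Jaffna", "Somewhere"))
canonical_unit_id <- function(x) {
  x <- trimws(as.character(x))
  al <- district_aliases()
  reg <- sri_lanka_register()$unit_id
  # case-insensitive resolution against register + aliases
  low <- tolower(x)
  hit_reg <- match(low, tolower(reg))
  hit_al <- match(low, tolower(al$alias))
  out <- x
  out[!is.na(hit_reg)] <- reg[hit_reg[!is.na(hit_reg)]]
  out[!is.na(hit_al)] <- al$unit_id[hit_al[!is.na(hit_al)]]
  out
}

#' Unit metadata for the Sri Lanka study
#'
#' One row per district (plus the `NATIONAL` pseudo-unit, which lets every
#' pipeline stage treat national and district analyses identically): conflict
#' class, creation year where the district was carved out after the start of
#' the data series (such districts cannot support a pre-war trend and are
#' excluded from counterfactual modelling), and the endpoint year available
#' per indicator.
#'
#' @param include_national Keep the `NATIONAL` pseudo-unit row (default TRUE).
#' @return A tibble with columns `unit_id`, `conflict_class`, `creation_year`,
#'   `imr_endpoint_year`, `mmr_endpoint_year`.
#' @export
#' @examples
#' sri_lanka_meta()
sri_lanka_meta <- function(include_national = TRUE) {
  reg <- sri_lanka_register()
  if (!include_national) reg <- dplyr::filter(reg, .data$unit_id != "NATIONAL")
  reg
}
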