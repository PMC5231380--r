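# Shared vocabulary for outcome flags. "worse" always means worse for health
# (a slower decline, or a higher mortality level, than the counterfactual).
flag_levels <- function() c("worse", "better", "same", "not_assessable")

indicator_levels <- function() c("IMR", "MMR")

conflict_class_levels <- function() c("high", "intermittent", "none", "national")

as_flag <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x)] <- "not_assessable"
  bad <- setdiff(unique(x), flag_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown outcome flag(s): ", paste(bad, collapse = ", ")))
  }
  x
}

check_indicator <- function(indicator) {
  indicator <- toupper(as.character(indicator))
  bad <- setdiff(unique(indicator), indicator_levels())
  if (length(bad) > 0) {
    abort(paste0(
      "indicator must be one of ", paste(indicator_levels(), collapse = ", "),
      "; got: ", paste(bad, collapse = ", ")
    ))
  }
  indicator
}

# Normalise the printed conflict-class wording ("High Conflict Level",
# "Intermitent Conflict", "No Conflict", ...) to the canonical levels.
normalize_conflict_class <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    grepl("^high", x0) ~ "high",
    grepl("^intermit", x0) ~ "intermittent",
    grepl("^no[ _-]?conflict$|^none$", x0) ~ "none",
    x0 == "no" ~ "none",
    x0 == "national" ~ "national",
    TRUE ~ NA_character_
  )
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[!is.na(x) & is.na(out)])
    abort(paste0("unrecognised conflict class: ", paste(bad, collapse = ", ")))
  }
  out
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= 1
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
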