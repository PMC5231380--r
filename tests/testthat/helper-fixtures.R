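# Builders and independent brute-force oracles shared across the suite.

make_series <- function(unit_id, indicator, years, values) {
  tibble::tibble(unit_id = unit_id, indicator = indicator,
                 year = as.integer(years), value = values)
}

write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

write_meta_csv <- function(meta, path = tempfile(fileext = ".csv")) {
  readr::write_csv(meta, path, na = "")
  path
}

simple_meta <- function(unit_ids, conflict_class = "none",
                        creation_year = NA_integer_, endpoint = 2002L) {
  tibble::tibble(
    unit_id = unit_ids,
    conflict_class = conflict_class,
    creation_year = as.integer(creation_year),
    imr_endpoint_year = endpoint,
    mmr_endpoint_year = endpoint
  )
}

# brute-force re-count of every tally metric by explicit looping
brute_tally <- function(classification, meta) {
  cls <- merge(classification, meta[, c("unit_id", "conflict_class")],
               by = "unit_id", all.x = TRUE)
  cls <- cls[cls$unit_id != "NATIONAL" &
               (is.na(cls$conflict_class) | cls$conflict_class != "national"), ]
  out <- list()
  for (ind in unique(cls$indicator)) {
    sub <- cls[cls$indicator == ind, ]
    ew <- 0; ewo <- 0; rw <- 0; rwnw <- 0
    for (i in seq_len(nrow(sub))) {
      if (sub$endpoint_flag[i] == "worse") {
        ew <- ew + 1
        if (sub$conflict_class[i] != "high") ewo <- ewo + 1
      }
      if (sub$rate_flag[i] == "worse") {
        rw <- rw + 1
        if (sub$endpoint_flag[i] != "worse") rwnw <- rwnw + 1
      }
    }
    out[[ind]] <- c(endpoint_worse = ew, endpoint_worse_outside_zone = ewo,
                    rate_worse = rw, rate_worse_endpoint_not_worse = rwnw)
  }
  out
}

# brute-force impact weight for one district: count WORSE among 4 components
brute_weight <- function(flags) {
  if (all(flags == "not_assessable")) return(NA_integer_)
  sum(flags == "worse")
}

# minimal square polygon feature
square_feature <- function(name, x0) {
  list(
    type = "Feature",
    properties = list(name = name),
    geometry = list(
      type = "Polygon",
      coordinates = list(list(
        list(x0, 0), list(x0 + 1, 0), list(x0 + 1, 1), list(x0, 1), list(x0, 0)
      ))
    )
  )
}

write_boundaries_geojson <- function(names, path = tempfile(fileext = ".geojson")) {
  fc <- list(
    type = "FeatureCollection",
    features = purrr::imap(names, ~ square_feature(.x, .y - 1))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  path
}

random_flags <- function(n) {
  sample(c("worse", "better", "same", "not_assessable"), n, replace = TRUE)
}
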