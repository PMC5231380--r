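test_that("series CSV round-trips through write and read without loss", {
  s <- make_series("Jaffna", "IMR", c(1975, 1982, 2002), c(21.5, 17, 6))
  p <- tempfile(fileext = ".csv")
  write_results(s, p, "csv")
  back <- read_indicator_series(p)
  expect_equal(back$value, s$value)
  expect_equal(back$year, s$year)
  expect_equal(attr(back, "load_report")$n_series, 1L)

  # decimals with up to 6 places survive bit-exactly
  s2 <- make_series("Galle", "MMR", 1975:1980, c(0.123456, 0.9, 1.25, 0.5, 0.000001, 2))
  p2 <- tempfile(fileext = ".csv")
  write_results(s2, p2, "csv")
  expect_identical(read_indicator_series(p2)$value, s2$value)
})

test_that("blank values drop with a count; non-numeric and conflicting rows are hard errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "unit_id,indicator,year,value",
    "Jaffna,IMR,1982,17", "Jaffna,IMR,1999,", "Jaffna,IMR,2002,6"
  ), f)
  s <- read_indicator_series(f)
  expect_equal(nrow(s), 2)
  expect_equal(attr(s, "load_report")$n_missing_dropped, 1L)

  f2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "unit_id,indicator,year,value",
    "Jaffna,IMR,1982,17", "Jaffna,IMR,1999,n/a"
  ), f2)
  expect_error(read_indicator_series(f2), "non-numeric.*row\\(s\\) 3")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c(
    "unit_id,indicator,year,value",
    "Jaffna,IMR,1982,17", "Jaffna,IMR,1982,18"
  ), f3)
  expect_error(read_indicator_series(f3), "conflicting duplicate")

  # identical duplicates collapse silently
  f4 <- tempfile(fileext = ".csv")
  writeLines(c(
    "unit_id,indicator,year,value",
    "Jaffna,IMR,1982,17", "Jaffna,IMR,1982,17", "Jaffna,IMR,2002,6"
  ), f4)
  s4 <- read_indicator_series(f4)
  expect_equal(nrow(s4), 2)
  expect_equal(attr(s4, "load_report")$n_duplicates_collapsed, 1L)
})

test_that("empty series CSV is rejected with a clear message", {
  f <- tempfile(fileext = ".csv")
  writeLines("unit_id,indicator,year,value", f)
  expect_error(read_indicator_series(f), "no series loaded")
})

test_that("packaged district IMR fixture matches the printed table", {
  t3 <- load_fixture("table3")
  expect_equal(nrow(t3), 25)
  batti <- t3[t3$unit_id == "Batticaloa", ]
  expect_equal(batti$imr_1982, 27)
  expect_equal(batti$imr_2002, 15.2)
  expect_equal(batti$counterfactual_2002, 6.2)
  expect_equal(batti$rate_prewar, -0.066)
  expect_equal(batti$rate_conflict, -0.019)
  # late-created Vanni districts carry only the 2002 value
  vanni <- t3[t3$unit_id %in% c("Kilinochchi", "Mullaitivu"), ]
  expect_true(all(is.na(vanni$imr_1982)))
  expect_true(all(is.na(vanni$counterfactual_2002)))
  expect_equal(sort(vanni$imr_2002), c(3.9, 8.9))
})

test_that("national and label fixtures return printed records without recomputation", {
  t2 <- load_fixture("table2")
  expect_equal(t2$actual[t2$indicator == "IMR" & t2$year == 1982], 34.00)
  expect_equal(t2$counterfactual_5yr[t2$indicator == "IMR" & t2$year == 2002], 15.04)
  expect_equal(t2$trend_prewar_5yr[t2$indicator == "MMR" & t2$year == 1982], -0.08)

  t6 <- load_fixture("table6")
  expect_equal(t6$label[t6$unit_id == "Kurunegala"], "Rate is worse; MMR is better")
  # printed variant spelling resolves to the canonical district
  expect_true("Kilinochchi" %in% t6$unit_id)
  expect_equal(t6$district[t6$unit_id == "Kilinochchi"], "Kilinochi")

  expect_error(load_fixture("table7"), "unknown fixture")
})

test_that("fixture files are pinned against accidental edits", {
  files <- c(
    table2_national.csv = "2d23e0f0778ecdf88d7fd9bc81c73e00",
    table3_imr_districts.csv = "5c35e3f709089313bb56f8d482a45490",
    table4_imr_labels.csv = "c0994e196dadbc6a361304cf2f4d153c",
    table5_mmr_districts.csv = "0c255d9bdacaebaae30675156a9e7ef7",
    table6_mmr_labels.csv = "7f3befc16b8db6038a0feb56e6659dc9",
    table9_impact_histogram.csv = "b6ad0ca7d1ad3c9dc09b9730628a7519",
    national_series.csv = "aecf68feea0be9083a87a3856835bd84"
  )
  for (f in names(files)) {
    path <- system.file("extdata", f, package = "momentumcf")
    expect_equal(unname(tools::md5sum(path)), unname(files[[f]]), label = f)
  }
})

test_that("every numeric Table 3 cell appears exactly once in the fixture", {
  t3 <- load_fixture("table3")
  vals <- c(t3$imr_1982, t3$imr_2002, t3$counterfactual_2002,
            t3$rate_prewar, t3$rate_conflict)
  # 25 districts x 5 numeric columns, minus the printed n/a and blank cells:
  # Kilinochchi/Mullaitivu contribute only imr_2002 (2 x 4 missing),
  # Colombo lacks cf + prewar + conflict rate (3), Gampaha lacks cf + prewar (2)
  expect_equal(sum(!is.na(vals)), 25 * 5 - 8 - 3 - 2)
  expect_equal(sum(t3$imr_1982, na.rm = TRUE), 27 + 17 + 27 + 18 + 16 + 20 + 26 +
                 14 + 24 + 34 + 50 + 34 + 22 + 18 + 20 + 39 + 29 + 29 + 29 + 33 +
                 13 + 49 + 43)
})

test_that("write_results is deterministic and order-normalising", {
  t3 <- load_fixture("table3")
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_results(t3, p1)
  write_results(t3[sample(nrow(t3)), ], p2)
  expect_identical(readLines(p1), readLines(p2))
  # empty record set still yields a header-only file
  p3 <- tempfile(fileext = ".csv")
  write_results(t3[0, ], p3)
  expect_equal(length(readLines(p3)), 1)
})

test_that("alias table canonicalises the spelling variants of the source", {
  expect_equal(
    canonical_unit_id(c("Kilinochi", "Trincomallee", "kalutara", "Elsewhere")),
    c("Kilinochchi", "Trincomalee", "Kaluthara", "Elsewhere")
  )
  meta <- sri_lanka_meta()
  expect_equal(nrow(meta), 26) # 25 districts + NATIONAL pseudo-unit
  expect_equal(meta$creation_year[meta$unit_id == "Mullaitivu"], 1978L)
  expect_equal(meta$creation_year[meta$unit_id == "Kilinochchi"], 1984L)
  expect_equal(sum(meta$mmr_endpoint_year == 1999), 8)
})

test_that("unit metadata CSV reader validates classes and endpoint years", {
  m <- simple_meta(c("A", "B"), conflict_class = c("High Conflict", "No Conflict"))
  p <- write_meta_csv(m)
  got <- read_unit_meta(p)
  expect_equal(sort(got$conflict_class), c("high", "none"))

  bad <- simple_meta("A", endpoint = 2005L)
  expect_error(read_unit_meta(write_meta_csv(bad)), "1999 or 2002")
})
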