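test_that("rate and endpoint flags reproduce the published district calls", {
  # Batticaloa: improvement slowed (-0.066 -> -0.019)
  expect_equal(classify_rate_change(-0.066, -0.019), "worse")
  # Jaffna: improvement accelerated
  expect_equal(classify_rate_change(-0.027, -0.038), "better")
  expect_equal(classify_rate_change(-0.05, -0.05), "same")
  # Anuradhapura endpoint above counterfactual; Jaffna below; Hambantota tied
  expect_equal(classify_endpoint(17.6, 11.6), "worse")
  expect_equal(classify_endpoint(6.0, 12.7), "better")
  expect_equal(classify_endpoint(4.7, 4.7), "same")
  # missing inputs propagate
  expect_equal(classify_endpoint(NA, 4), "not_assessable")
  expect_equal(classify_rate_change(NA, -0.02), "not_assessable")
})

test_that("classification is invariant to a common positive rescaling", {
  set.seed(21)
  for (i in 1:40) {
    a <- runif(1, 0.1, 40); cf <- runif(1, 0.1, 40); k <- runif(1, 0.05, 20)
    expect_equal(classify_endpoint(a, cf), classify_endpoint(k * a, k * cf))
  }
})

test_that("tolerance turns near-ties into 'same'", {
  expect_equal(classify_endpoint(4.74, 4.7, tolerance = 0.05), "same")
  expect_equal(classify_endpoint(4.76, 4.7, tolerance = 0.05), "worse")
  expect_equal(classify_rate_change(-0.05, -0.0495, tolerance = 0.001), "same")
})

test_that("label mapping matches the published vocabulary and inverts cleanly", {
  expect_equal(interpret_flags("worse", "better", "IMR"),
               "Rate is worse; IMR is better")   # Trincomalee IMR
  expect_equal(interpret_flags("not_assessable", "worse", "IMR"),
               "Unable to determine")            # Kilinochchi
  expect_equal(interpret_flags("better", "worse", "MMR"),
               "Rate is better; MMR is worse")   # Mannar MMR
  expect_equal(interpret_flags("worse", "same", "MMR"),
               "Rate is worse; MMR is same")     # Vavuniya MMR
  expect_equal(interpret_flags("worse", "not_assessable", "MMR"),
               "Rate is worse")                  # Trincomalee MMR
  expect_equal(interpret_flags("worse", "worse", "IMR"), "Rate and IMR are worse")

  # bijection over defined flag pairs: interpret then parse returns the pair
  defined <- c("worse", "better", "same")
  for (rf in defined) for (ef in c(defined, "not_assessable")) {
    lab <- interpret_flags(rf, ef, "MMR")
    back <- label_to_flags(lab)
    expect_equal(back$rate_flag, rf, label = lab)
    expect_equal(back$endpoint_flag, ef, label = lab)
  }
  # 'outcome' wording of the MMR value table parses too
  expect_equal(label_to_flags("Rate and outcome are worse")$endpoint_flag, "worse")
})

test_that("impact weight equals brute-force counting over the full flag space", {
  flags <- c("worse", "better", "same", "not_assessable")
  grid <- expand.grid(f1 = flags, f2 = flags, f3 = flags, f4 = flags,
                      stringsAsFactors = FALSE)
  cls <- dplyr::bind_rows(purrr::map(seq_len(nrow(grid)), function(i) {
    tibble::tibble(
      unit_id = sprintf("u%03d", i),
      indicator = c("IMR", "MMR"),
      rate_flag = c(grid$f1[i], grid$f3[i]),
      endpoint_flag = c(grid$f2[i], grid$f4[i])
    )
  }))
  idx <- impact_index(cls)
  expect_equal(nrow(idx), 256)
  for (i in seq_len(nrow(grid))) {
    expected <- brute_weight(unlist(grid[i, ]))
    got <- idx$weight[idx$unit_id == sprintf("u%03d", i)]
    expect_equal(got, expected, label = paste(unlist(grid[i, ]), collapse = "/"))
  }
  # spot checks from the index definition
  all_worse <- idx[idx$rate_flag_imr == "worse" & idx$endpoint_flag_imr == "worse" &
                     idx$rate_flag_mmr == "worse" & idx$endpoint_flag_mmr == "worse", ]
  expect_equal(all_worse$weight, 4L)
  expect_equal(weight_class(c(NA, 0L, 1L, 2L, 3L, 4L)),
               c("not_assessable", "none", "minimal", "minimal", "noticeable", "high"))
})

test_that("tallies equal an independent brute-force scan on random inputs", {
  set.seed(31)
  meta <- simple_meta(sprintf("d%02d", 1:30),
                      conflict_class = sample(c("high", "intermittent", "none"),
                                              30, replace = TRUE))
  for (rep in 1:5) {
    cls <- tidyr::crossing(unit_id = meta$unit_id, indicator = c("IMR", "MMR"))
    cls$rate_flag <- random_flags(nrow(cls))
    cls$endpoint_flag <- random_flags(nrow(cls))
    got <- tally_classifications(cls, meta)$counts
    want <- brute_tally(cls, meta)
    for (ind in names(want)) {
      for (metric in names(want[[ind]])) {
        expect_equal(
          got$n[got$indicator == ind & got$metric == metric],
          unname(want[[ind]][metric]),
          label = paste(ind, metric)
        )
      }
    }
  }
  # empty input gives zero counts
  empty <- tally_classifications(
    tibble::tibble(unit_id = character(), indicator = character(),
                   rate_flag = character(), endpoint_flag = character()),
    meta
  )
  expect_equal(nrow(empty$counts), 0)
})

test_that("NATIONAL pseudo-unit is excluded from district tallies", {
  meta <- dplyr::bind_rows(
    simple_meta("d1", conflict_class = "none"),
    simple_meta("NATIONAL", conflict_class = "national")
  )
  cls <- tibble::tibble(
    unit_id = c("d1", "NATIONAL"), indicator = "IMR",
    rate_flag = "worse", endpoint_flag = "worse"
  )
  t <- tally_classifications(cls, meta)$counts
  expect_equal(t$n[t$metric == "endpoint_worse"], 1L)
})

test_that("label reconciliation surfaces the printed inconsistencies", {
  mmr <- classify_units(district_table("MMR"))
  rec <- reconcile_labels(mmr, printed_labels("MMR"))
  # Vavuniya printed "same" despite 0.60 against a counterfactual of 0.06
  vav <- rec[rec$unit_id == "Vavuniya", ]
  expect_equal(nrow(vav), 1)
  expect_equal(vav$computed_label, "Rate and MMR are worse")
  expect_equal(vav$printed_label, "Rate is worse; MMR is same")

  imr <- classify_units(district_table("IMR"))
  rec_imr <- reconcile_labels(imr, printed_labels("IMR"))
  expect_false("Jaffna" %in% rec_imr$unit_id) # computed == printed
  # identical sets give an empty report
  self <- reconcile_labels(mmr, dplyr::select(mmr, "unit_id", "indicator", "label"))
  expect_equal(nrow(self), 0)
})

test_that("classify_units on the IMR fixture matches the printed labels except ties", {
  imr <- classify_units(district_table("IMR"))
  # Batticaloa both worse; Jaffna both better
  expect_equal(imr$label[imr$unit_id == "Batticaloa"], "Rate and IMR are worse")
  expect_equal(imr$label[imr$unit_id == "Jaffna"], "Rate and IMR are better")
  # Hambantota ties at 4.7 = 4.7 under strict comparison
  expect_equal(imr$endpoint_flag[imr$unit_id == "Hambantota"], "same")
  # Vanni districts cannot be assessed
  expect_equal(imr$label[imr$unit_id == "Kilinochchi"], "Unable to determine")
})
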