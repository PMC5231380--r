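test_that("generator is seed-deterministic and validates its configuration", {
  cfg <- synthetic_config(n_units = 8, seed = 5)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$series, p2$series)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_panel(synthetic_config(n_units = 8, seed = 6))
  expect_false(identical(p1$series$value, p3$series$value))

  expect_error(synthetic_config(missing_prob = 1), "\\[0, 1\\)")
  expect_error(synthetic_config(prewar_rate = -1.2), "> -1")
  expect_error(synthetic_config(n_units = 0), "positive integer")
  expect_error(synthetic_config(baseline_year = 1975), "strictly inside")
})

test_that("values are positive before missingness and missing years thin the panel", {
  p <- generate_panel(synthetic_config(n_units = 10, noise_cv = 0.2,
                                       missing_prob = 0, seed = 2))
  expect_true(all(p$series$value > 0))
  full_n <- nrow(p$series)
  pm <- generate_panel(synthetic_config(n_units = 10, noise_cv = 0.2,
                                        missing_prob = 0.3, seed = 2))
  expect_lt(nrow(pm$series), full_n)
})

test_that("null effect: actual endpoint equals the compound counterfactual exactly", {
  cfg <- synthetic_config(n_units = 6, conflict_rate_multiplier = 1,
                          noise_cv = 0, missing_prob = 0,
                          late_creation_fraction = 0, endpoint_1999_fraction = 0,
                          seed = 4)
  p <- generate_panel(cfg)
  fit <- analyze_conflict_impact(p$series, p$meta, study_config(tie_tolerance = 1e-9))
  expect_equal(fit$classification$actual, fit$classification$counterfactual,
               tolerance = 1e-12)
  expect_true(all(fit$classification$endpoint_flag == "same"))
})

test_that("zero-noise parameter recovery is exact to 1e-9", {
  set.seed(101)
  cfg <- synthetic_config(n_units = 12, prewar_rate = runif(12, -0.08, -0.01),
                          noise_cv = 0, missing_prob = 0,
                          late_creation_fraction = 0, endpoint_1999_fraction = 0.25,
                          seed = 9)
  p <- generate_panel(cfg)
  tr <- estimate_window_trend(p$series, 1975, 1982)
  truth <- p$truth[match(paste(tr$unit_id, tr$indicator),
                         paste(p$truth$unit_id, p$truth$indicator)), ]
  expect_true(all(abs(tr$rate - truth$prewar_rate) /
                    abs(truth$prewar_rate) <= 1e-9))
})

test_that("analytic oracle: multiplier direction maps to flags as expected", {
  base <- function(m) synthetic_config(
    n_units = 5, prewar_rate = -0.05, conflict_rate_multiplier = m,
    noise_cv = 0, missing_prob = 0, late_creation_fraction = 0,
    endpoint_1999_fraction = 0, seed = 1
  )
  # slowdown on an improving rate: both flags worse
  ef <- expected_flags(base(0.4))
  expect_true(all(ef$rate_flag == "worse"))
  expect_true(all(ef$endpoint_flag == "worse"))
  # faster improvement: endpoint better
  ef2 <- expected_flags(base(1.6))
  expect_true(all(ef2$endpoint_flag == "better"))
  # no effect: endpoint same (at a small tolerance for the analytic tie)
  ef3 <- expected_flags(base(1), tolerance = 1e-12)
  expect_true(all(ef3$endpoint_flag == "same"))
  # oracle counts match a brute-force enumeration on a mixed panel
  cfgmix <- synthetic_config(
    n_units = 100, prewar_rate = -0.05,
    conflict_rate_multiplier = rep(c(0.4, 1.6), 50),
    noise_cv = 0, missing_prob = 0, late_creation_fraction = 0,
    endpoint_1999_fraction = 0, seed = 8
  )
  efm <- expected_flags(cfgmix)
  brute_worse <- 0
  for (i in seq_len(nrow(efm))) {
    if (efm$conflict_rate_multiplier[i] < 1) brute_worse <- brute_worse + 1
  }
  expect_equal(sum(efm$endpoint_flag == "worse"), brute_worse)
  expect_equal(sum(efm$endpoint_flag == "better"), nrow(efm) - brute_worse)
})

test_that("end-to-end zero-noise recovery: pipeline flags equal the oracle for all units", {
  set.seed(102)
  cfg <- synthetic_config(
    n_units = 40, prewar_rate = runif(40, -0.08, -0.02),
    conflict_rate_multiplier = sample(c(0.3, 0.5, 1.5), 40, replace = TRUE),
    noise_cv = 0, missing_prob = 0,
    late_creation_fraction = 0.1, endpoint_1999_fraction = 0.2, seed = 13
  )
  p <- generate_panel(cfg)
  fit <- analyze_conflict_impact(p$series, p$meta)
  cmp <- dplyr::inner_join(
    dplyr::select(fit$classification, "unit_id", "indicator",
                  got_rate = "rate_flag", got_end = "endpoint_flag"),
    dplyr::select(p$truth, "unit_id", "indicator",
                  exp_rate = "rate_flag", exp_end = "endpoint_flag"),
    by = c("unit_id", "indicator")
  )
  expect_equal(mean(cmp$got_rate == cmp$exp_rate), 1)
  expect_equal(mean(cmp$got_end == cmp$exp_end), 1)
})

test_that("noisy recovery: at least 95% flag agreement at cv 0.05 with a 50% slowdown", {
  cfg <- synthetic_config(
    n_units = 500, prewar_rate = -0.05, conflict_rate_multiplier = 0.5,
    noise_cv = 0.05, missing_prob = 0,
    late_creation_fraction = 0, endpoint_1999_fraction = 0, seed = 2026
  )
  p <- generate_panel(cfg)
  fit <- analyze_conflict_impact(p$series, p$meta)
  cmp <- dplyr::inner_join(
    dplyr::select(fit$classification, "unit_id", "indicator",
                  got_rate = "rate_flag", got_end = "endpoint_flag"),
    dplyr::select(p$truth, "unit_id", "indicator",
                  exp_rate = "rate_flag", exp_end = "endpoint_flag"),
    by = c("unit_id", "indicator")
  )
  agreement <- mean(cmp$got_rate == cmp$exp_rate & cmp$got_end == cmp$exp_end)
  expect_gte(agreement, 0.95)
})

test_that("late-created units always classify as unable to determine", {
  cfg <- synthetic_config(n_units = 10, late_creation_fraction = 0.3,
                          noise_cv = 0, missing_prob = 0, seed = 17)
  p <- generate_panel(cfg)
  fit <- analyze_conflict_impact(p$series, p$meta)
  late_units <- p$meta$unit_id[!is.na(p$meta$creation_year)]
  expect_equal(length(late_units), 3)
  late_cls <- fit$classification[fit$classification$unit_id %in% late_units, ]
  expect_true(all(!late_cls$assessable))
  expect_true(all(late_cls$label == "Unable to determine"))
  expect_true(all(
    p$truth$rate_flag[p$truth$unit_id %in% late_units] == "not_assessable"
  ))
})
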