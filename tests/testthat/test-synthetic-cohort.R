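test_that("cohort spec validation rejects degenerate parameters", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_participants = 1), "n_participants")
  expect_error(cohort_spec(hand_prevalence = 0), "hand_prevalence")
  expect_error(cohort_spec(hand_prevalence = 1), "hand_prevalence")
  expect_error(cohort_spec(effect_size = -1), "effect_size")
  expect_error(cohort_spec(sample_rate_hz = 0), "sample_rate_hz")
  expect_error(cohort_spec(n_channels = 2, n_zones = 2,
                           n_informative_variables = 5), "planting cells")
  expect_error(cohort_spec(error_rate_hand = c(1, 2)), "error_rate_hand")
})

test_that("study-scale cohort has 62 participants and 35 HAND-positive", {
  spec <- cohort_spec(n_participants = 62, hand_prevalence = 0.57,
                      n_channels = 1, n_zones = 2,
                      session_duration_sec = 5, seed = 0)
  co <- generate_cohort(spec)
  expect_length(co$sessions, 62)
  expect_equal(sum(co$truth$hand_labels), 35)
  expect_equal(nrow(co$cnpa), 62)
})

test_that("null spec plants nothing and identical specs reproduce cohorts", {
  spec <- cohort_spec(n_participants = 8, hand_prevalence = 0.5,
                      n_channels = 2, n_zones = 2,
                      session_duration_sec = 8,
                      effect_size = 0, n_informative_variables = 0, seed = 3)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_length(co1$truth$informative_variable_ids, 0)
  expect_identical(co1$truth$hand_labels, co2$truth$hand_labels)
  expect_identical(co1$cnpa, co2$cnpa)
  expect_identical(co1$sessions[[5]]$channels, co2$sessions[[5]]$channels)
  expect_identical(co1$sessions[[5]]$events, co2$sessions[[5]]$events)
})

test_that("replay sessions have rate x duration samples and the declared
           zone inventory", {
  spec <- cohort_spec(n_zones = 22, n_channels = 1,
                      session_duration_sec = 600, sample_rate_hz = 10,
                      seed = 2)
  s <- generate_replay(spec, "P001", seed = 10)
  expect_equal(nrow(s$channels), 6000)
  zones <- unique(s$zone_track)
  expect_length(setdiff(zones, "none"), 22)
  expect_true("none" %in% zones)
  expect_true(all(s$events$t_sec >= 0 & s$events$t_sec <= 600))
})

test_that("a fixed seed serializes byte-identically", {
  spec <- cohort_spec(n_channels = 2, n_zones = 3,
                      session_duration_sec = 10, seed = 6)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_replay(generate_replay(spec, "P9", hand = TRUE, seed = 77), f1)
  write_replay(generate_replay(spec, "P9", hand = TRUE, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted shifts move informative group medians by the stated
           effect", {
  spec <- cohort_spec(n_participants = 40, hand_prevalence = 0.5,
                      n_channels = 4, n_zones = 4,
                      session_duration_sec = 40,
                      n_informative_variables = 10, effect_size = 2.0,
                      seed = 7)
  co <- generate_cohort(spec)
  fm <- summarize_variables(co$sessions)
  lab <- unname(co$truth$hand_labels)
  ids <- co$truth$informative_variable_ids
  expect_length(ids, 10)
  expect_true(all(ids %in% colnames(fm$values)))
  diffs <- vapply(ids, function(id) {
    v <- fm$values[, id]
    median(v[lab]) - median(v[!lab])
  }, numeric(1))
  planted <- unname(co$truth$planted_shift[ids])
  # per-variable sampling error of a group median difference is ~0.3 here
  # (participant effect sd 0.5, 20 per group); 0.9 is a 3-sigma band
  expect_true(all(abs(diffs - planted) < 0.9))
  expect_lt(mean(abs(diffs - planted)), 0.4)
  expect_true(any(planted > 0) && any(planted < 0))
})

test_that("without planted effects downstream KW p-values are uniform", {
  spec <- cohort_spec(n_participants = 62, hand_prevalence = 0.57,
                      n_channels = 10, n_zones = 5,
                      session_duration_sec = 60, effect_size = 0, seed = 11)
  co <- generate_cohort(spec)
  fm <- summarize_variables(co$sessions)
  cont <- fm$meta$variable_id[
    fm$meta$stat %in% c("min", "max", "mean", "median", "sd")
  ]
  expect_gte(length(cont), 500)
  rl <- kw_rank(fm, co$truth$hand_labels)
  p <- rl$p[match(cont, rl$variable_id)]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ground truth serializes to JSON", {
  spec <- cohort_spec(n_participants = 6, hand_prevalence = 0.5,
                      n_channels = 2, n_zones = 2,
                      session_duration_sec = 5,
                      n_informative_variables = 2, effect_size = 1, seed = 1)
  co <- generate_cohort(spec)
  f <- tempfile(fileext = ".json")
  write_ground_truth(co$truth, f)
  back <- jsonlite::fromJSON(f)
  expect_identical(unlist(back$hand_labels),
                   stats::setNames(unname(co$truth$hand_labels),
                                   names(co$truth$hand_labels)))
  expect_identical(back$informative_variable_ids,
                   co$truth$informative_variable_ids)
})
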