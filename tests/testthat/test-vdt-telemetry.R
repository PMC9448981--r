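two_zone <- function() rep(c("zone_a", "zone_b"), each = 5)

test_that("replay parsing validates the dialect and round-trips losslessly", {
  spec <- cohort_spec(n_channels = 2, n_zones = 3,
                      session_duration_sec = 10, seed = 5)
  s <- generate_replay(spec, "P1", seed = 8)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_replay(s, f1)
  s2 <- parse_replay(f1)
  write_replay(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(s2$channels), nrow(s$channels))

  # missing required channel named in the error
  obj <- jsonlite::fromJSON(f1)
  obj$samples$speed_mph <- NULL
  f3 <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE), f3)
  expect_error(parse_replay(f3), "speed_mph")

  # non-uniform timestamps rejected, naming the field
  obj2 <- jsonlite::fromJSON(f1)
  obj2$samples$t_sec[3] <- obj2$samples$t_sec[3] + 0.05
  writeLines(jsonlite::toJSON(obj2, dataframe = "rows", auto_unbox = TRUE), f3)
  expect_error(parse_replay(f3), "t_sec")

  writeLines("{not json", f3)
  expect_error(parse_replay(f3), "malformed")
})

test_that("derived channels follow the finite-difference and wrap rules", {
  s <- make_manual_session("P1", speed = rep(30, 10), zones = two_zone())
  d <- derive_channels(s)
  expect_true(all(d$forward_accel_mphps$values == 0))
  expect_true(all(d$forward_jerk_mphps2$values == 0))

  s2 <- make_manual_session("P2", speed = c(10, 12, 12), zones = rep("z", 3))
  d2 <- derive_channels(s2)
  expect_equal(d2$forward_accel_mphps$values, c(20, 0))
  expect_equal(d2$forward_jerk_mphps2$values, -200)

  # heading wrap-around: 359 vs 1 degrees -> 2 degrees misalignment
  s3 <- make_manual_session("P3", speed = rep(20, 4), zones = rep("z", 4))
  s3$channels$heading_deg <- rep(359, 4)
  s3$channels$road_heading_deg <- rep(1, 4)
  expect_equal(derive_channels(s3)$heading_misalignment_deg$values,
               rep(2, 4))

  expect_error(derive_channels(make_manual_session("P4", speed = c(1, 2),
                                                   zones = c("z", "z"))),
               "3 samples")
})

test_that("below-limit indicator measures time at least X mph under the
           posted limit", {
  # always 20 mph under a 45 limit, entirely in-zone -> both % time = 1
  s <- make_manual_session("P1", speed = rep(25, 10),
                           posted = rep(45, 10), zones = rep("z", 10))
  d <- derive_channels(s)
  expect_equal(mean(d$below_limit_15mph$values), 1)
  expect_equal(mean(d$below_limit_10mph$values), 1)
  # 5 mph under the limit trips neither threshold
  s2 <- make_manual_session("P2", speed = rep(40, 10),
                            posted = rep(45, 10), zones = rep("z", 10))
  expect_equal(mean(derive_channels(s2)$below_limit_15mph$values), 0)
})

test_that("zonal statistics of a constant-in-zone channel equal the
           constant and globals summarize the concatenation", {
  speed_a <- rep(20, 5)
  speed_b <- rep(40, 5)
  s1 <- make_manual_session("P1", speed = c(speed_a, speed_b),
                            zones = two_zone())
  s2 <- make_manual_session("P2", speed = c(speed_a + 1, speed_b + 3),
                            zones = two_zone())
  fm <- summarize_variables(list(s1, s2), drop_zero_variance = FALSE)
  v <- fm$values
  expect_equal(unname(v["P1", "speed_mph|mean|zone:zone_a"]), 20)
  expect_equal(unname(v["P1", "speed_mph|median|zone:zone_a"]), 20)
  expect_equal(unname(v["P1", "speed_mph|min|zone:zone_a"]), 20)
  expect_equal(unname(v["P1", "speed_mph|max|zone:zone_a"]), 20)
  expect_equal(unname(v["P1", "speed_mph|sd|zone:zone_a"]), 0)
  # global stats are the statistics of all samples pooled, not a mean of
  # zonal statistics
  expect_equal(unname(v["P1", "speed_mph|sd|global"]),
               sd(c(speed_a, speed_b)))
  expect_equal(unname(v["P1", "speed_mph|median|global"]),
               median(c(speed_a, speed_b)))
})

test_that("zero-variance columns are removed and logged; ordering is
           stable across runs", {
  spec <- cohort_spec(n_participants = 6, hand_prevalence = 0.5,
                      n_channels = 2, n_zones = 2,
                      session_duration_sec = 8, seed = 12)
  co <- generate_cohort(spec)
  fm1 <- summarize_variables(co$sessions)
  fm2 <- summarize_variables(co$sessions)
  expect_identical(fm1$meta, fm2$meta)
  # the posted limit and road heading are route constants -> dropped
  expect_true(any(grepl("posted_speed_mph", fm1$dropped$variable_id)))
  expect_false(any(grepl("^posted_speed_mph", fm1$meta$variable_id)))
  expect_gt(nrow(fm1$dropped), 0)
  # column_index records pre-filter positions, strictly increasing
  expect_true(all(diff(fm1$meta$column_index) > 0))
  # no retained column is constant
  rng <- apply(fm1$values, 2, function(x) max(x) - min(x))
  expect_true(all(rng > 0))
})

test_that("sessions missing a zone follow the configured policy", {
  s1 <- make_manual_session("P1", speed = rnorm(10, 30), zones = two_zone())
  s2 <- make_manual_session("P2", speed = rnorm(10, 30),
                            zones = rep("zone_a", 10))
  expect_error(summarize_variables(list(s1, s2)), "zone_b")
  fm <- summarize_variables(list(s1, s2), missing_zone = "drop")
  expect_false(any(grepl("zone:zone_b", fm$meta$variable_id)))
})

test_that("the composite error score is a dot product and linear in counts", {
  expect_equal(vdt_error_score(rep(0, 8)), 0)
  expect_equal(vdt_error_score(c(2, 0, 1, 0, 0, 0, 0, 0), rep(1, 8)), 3)
  expect_equal(
    vdt_error_score(c(1, 0, 2, 0, 1, 0, 0, 0), c(5, 5, 3, 10, 2, 2, 1, 4)),
    13
  )
  set.seed(2)
  for (i in 1:10) {
    c1 <- rpois(8, 2)
    c2 <- rpois(8, 1)
    w <- runif(8, 0, 5)
    expect_equal(vdt_error_score(c1 + c2, w),
                 vdt_error_score(c1, w) + vdt_error_score(c2, w))
  }
  expect_error(vdt_error_score(c(-1, rep(0, 7))), "non-negative")
  expect_error(vdt_error_score(rep(0, 7)), "length 8")
})

test_that("feature matrices round-trip through CSV plus metadata sidecar", {
  spec <- cohort_spec(n_participants = 5, hand_prevalence = 0.4,
                      n_channels = 1, n_zones = 2,
                      session_duration_sec = 6, seed = 13)
  co <- generate_cohort(spec)
  fm <- summarize_variables(co$sessions)
  f <- tempfile(fileext = ".csv")
  write_feature_csv(fm, f)
  back <- read_feature_csv(f)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$meta, fm$meta, ignore_attr = TRUE)
})
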