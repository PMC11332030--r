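test_that("accelerating schedules realize the plateau/rate structure", {
  # canonical fast sequence: 5 plateaus x 48 tokens
  s <- make_accelerating_schedule(4.3, 4.7, 0.1, 48)
  expect_equal(s$n_events, 240)
  expect_equal(unique(s$rates), c(4.3, 4.4, 4.5, 4.6, 4.7))

  # single plateau: pure isochrony
  s2 <- make_accelerating_schedule(2, 2, 0.04, 48)
  expect_equal(s2$n_events, 48)
  expect_equal(diff(s2$onsets), rep(0.5, 47))

  # slow sequence duration = direct sum of inter-onset intervals
  s3 <- make_accelerating_schedule(1.92, 2.08, 0.04, 48)
  expect_equal(s3$n_events, 240)
  expected <- 48 * sum(1 / c(1.92, 1.96, 2.00, 2.04, 2.08))
  expect_equal(sum(1 / s3$rates), expected, tolerance = 1e-12)
  # span + final IOI equals the same total
  expect_equal(total_duration(s3) + 1 / 2.08, expected, tolerance = 1e-9)
})

test_that("schedule parameter validation rejects bad grids", {
  expect_error(make_accelerating_schedule(-1, 2, 0.1, 48),
               class = "plvsync_invalid")
  expect_error(make_accelerating_schedule(2, 1.9, 0.1, 48),
               class = "plvsync_invalid")
  # grid that does not close on rate_end
  expect_error(make_accelerating_schedule(1.92, 2.09, 0.04, 48),
               class = "plvsync_invalid")
})

test_that("duration conservation and monotonicity hold over random specs", {
  set.seed(7)
  for (i in 1:25) {
    r0 <- runif(1, 0.5, 5)
    n_plat <- sample(1:6, 1)
    step <- runif(1, 0.01, 0.2)
    tps <- sample(2:60, 1)
    s <- make_accelerating_schedule(r0, r0 + step * (n_plat - 1),
                                    if (n_plat > 1) step else 0.1, tps)
    expect_true(all(diff(s$onsets) > 0))
    n <- s$n_events
    expect_equal(total_duration(s), sum(1 / s$rates[-n]), tolerance = 1e-9)
  }
})

test_that("perception trials place the deviant final onset correctly", {
  dev <- make_perception_trial(
    perception_trial_spec(2, 10, TRUE, 0.30, "syllable"))
  expect_equal(dev$onsets[10], 4.35)       # 4.5 - 0.30 * 0.5
  std <- make_perception_trial(
    perception_trial_spec(4.5, 10, FALSE, 0, "tone"))
  expect_equal(std$onsets[10], 2.0)        # 9 / 4.5
  expect_false(any(std$deviant_shifted))
  expect_true(dev$deviant_shifted[10])
  # shift >= 1 would cross the previous event
  expect_error(perception_trial_spec(2, 10, TRUE, 1.0),
               class = "plvsync_invalid")
  # shift must be > 0 exactly when deviant
  expect_error(perception_trial_spec(2, 10, TRUE, 0),
               class = "plvsync_invalid")
  expect_error(perception_trial_spec(2, 10, FALSE, 0.1),
               class = "plvsync_invalid")
})

test_that("perception blocks are balanced, on-grid, and reproducible", {
  b <- make_perception_block("syllable", 80, 2.0, 0.02, 5, c(0.28, 0.34),
                             seed = 1)
  expect_equal(sum(b$trials$is_deviant), 40)
  expect_true(all(b$trials$base_rate %in%
                    c(1.92, 1.96, 2.00, 2.04, 2.08)))
  expect_true(all(b$trials$shift_fraction[b$trials$is_deviant] >= 0.28 &
                    b$trials$shift_fraction[b$trials$is_deviant] <= 0.34))
  expect_true(all(b$trials$shift_fraction[!b$trials$is_deviant] == 0))

  # same seed twice -> identical block
  b2 <- make_perception_block("syllable", 80, 2.0, 0.02, 5,
                              c(0.28, 0.34), seed = 1)
  expect_identical(b, b2)

  # minimal balanced block at a single rate
  b3 <- make_perception_block("tone", 2, 2.0, 0, 1, c(0.15, 0.15),
                              seed = 7)
  expect_equal(sum(b3$trials$is_deviant), 1)
  expect_equal(unique(b3$trials$base_rate), 2.0)

  # balance holds regardless of seed
  for (s in 1:10) {
    bb <- make_perception_block("tone", 40, 4.5, 0.02, 5, c(0.12, 0.18),
                                seed = s)
    expect_equal(sum(bb$trials$is_deviant), 20)
  }
  expect_error(make_perception_block("tone", 7), class = "plvsync_invalid")
})

test_that("schedules and blocks round-trip through CSV/JSON", {
  s <- fast_sched()
  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, f)
  s2 <- read_schedule_csv(f)
  expect_equal(s2$onsets, s$onsets, tolerance = 1e-12)
  expect_equal(s2$rates, s$rates)

  b <- make_perception_block("tone", 10, 4.5, 0.02, 5, c(0.12, 0.18),
                             seed = 3)
  fj <- withr::local_tempfile(fileext = ".json")
  write_block_json(b, fj)
  b2 <- read_block_json(fj)
  expect_equal(b2$trials$base_rate, b$trials$base_rate)
  expect_equal(b2$trials$is_deviant, b$trials$is_deviant)
  expect_equal(b2$seed, b$seed)
})

test_that("click-train renderer covers the schedule at unit peaks", {
  s <- make_accelerating_schedule(2, 2, 0.1, 8)
  aud <- render_click_train(s, fs = 8000)
  expect_gte(length(aud$samples) / aud$fs, total_duration(s))
  expect_lte(max(abs(aud$samples)), 1)
  # a click sits at each onset
  for (t0 in s$onsets) {
    idx <- round(t0 * aud$fs) + 1:80
    expect_gt(max(aud$samples[idx]), 0.5)
  }
})
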