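test_that("plv matches its closed-form special cases", {
  set.seed(1)
  th <- runif(500, -pi, pi)
  expect_equal(plv(th, th), 1)
  expect_equal(plv(th + pi / 3, th), 1)                 # constant offset
  expect_equal(plv(c(0, 2 * pi / 3, 4 * pi / 3), c(0, 0, 0)), 0,
               tolerance = 1e-15)                       # cancelling phasors
  expect_error(plv(th, th[-1]), class = "plvsync_invalid")
})

test_that("plv equals the brute-force complex-mean oracle", {
  set.seed(42)
  for (T in c(3, 100, 1e5)) {
    t1 <- runif(T, -pi, pi)
    t2 <- runif(T, -pi, pi)
    # oracle: explicit real/imaginary accumulation
    oracle <- sqrt(sum(cos(t1 - t2))^2 + sum(sin(t1 - t2))^2) / T
    expect_equal(plv(t1, t2), oracle, tolerance = 1e-12)
  }
})

test_that("mean PLV of random phases matches the Rayleigh prediction", {
  # for i.i.d. uniform phase differences, E[PLV] ~ sqrt(pi)/(2 sqrt(T))
  set.seed(99)
  T <- 1000
  reps <- 2000
  vals <- vapply(seq_len(reps), function(i) {
    plv(runif(T, -pi, pi), numeric(T))
  }, numeric(1))
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(T)), tolerance = 0.05)
})

test_that("windowing follows the start/hop arithmetic and drops partials", {
  fs <- 100
  th <- numeric(50 * fs)
  w <- windowed_plv(th, th, band_preset("fast"), fs = fs)
  expect_equal(w$n_windows, 16)                 # floor((50-5)/3) + 1
  expect_equal(w$window_starts_s, seq(0, 45, by = 3))
  expect_equal(w$raw_plv, 1)
  expect_true(all(w$window_plvs == 1))

  th11 <- numeric(11 * fs)
  w2 <- windowed_plv(th11, th11, band_preset("slow"), fs = fs)
  expect_equal(w2$n_windows, 1)
  expect_error(windowed_plv(numeric(400), numeric(400),
                            band_preset("fast"), fs = fs),
               class = "plvsync_invalid")
})

test_that("permutation baseline is sound for identical and null inputs", {
  # identical non-periodic envelopes: raw PLV exactly 1, baseline well
  # below it
  env <- noise_envelope(120, seed = 11)
  env_m <- envelope_signal(env$samples, env$fs, "motor")
  est <- permutation_baseline(env, env_m, band_preset("slow"),
                              n_permutations = 20, seed = 2)
  expect_equal(est$raw_plv, 1, tolerance = 1e-9)
  expect_gt(est$normalized_plv, 0.5)
  expect_true(all(est$window_plvs >= 0 & est$window_plvs <= 1))
  expect_lte(est$normalized_plv, est$raw_plv)

  # reproducibility from seed
  est2 <- permutation_baseline(env, env_m, band_preset("slow"),
                               n_permutations = 20, seed = 2)
  expect_equal(est$baseline_plv, est2$baseline_plv)

  # under independent inputs raw - baseline is centred at 0
  vals <- vapply(1:30, function(s) {
    a <- noise_envelope(60, seed = 100 + s)
    m <- noise_envelope(60, seed = 900 + s, label = "motor")
    permutation_baseline(a, m, band_preset("slow"), n_permutations = 10,
                         seed = s)$normalized_plv
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 0.01)
})

test_that("single-segment inputs fall back to an identity baseline", {
  a <- noise_envelope(12, seed = 1)
  m <- noise_envelope(12, seed = 2, label = "motor")
  expect_warning(est <- permutation_baseline(a, m, band_preset("slow"),
                                             n_permutations = 10,
                                             seed = 1),
                 "fewer than 2")
  expect_equal(est$baseline_plv, est$raw_plv)
  expect_equal(est$normalized_plv, 0)
  expect_equal(est$n_permutations, 0L)
})

test_that("condition scores average trial normalized PLVs", {
  mk <- function(v) structure(list(normalized_plv = v),
                              class = "plv_estimate")
  sc <- score_condition(list(mk(0.30), mk(0.40)), "P001", "tap",
                        "syllable", "slow")
  expect_equal(sc$plv, 0.35)
  expect_equal(score_condition(list(mk(0.2)), "P1", "tap", "tone",
                               "fast")$plv, 0.2)
  expect_equal(score_condition(list(mk(0), mk(0), mk(0)), "P1", "whisper",
                               "tone", "slow")$plv, 0)
  expect_error(score_condition(list(), "P1", "tap", "tone", "fast"),
               class = "plvsync_invalid")
})
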