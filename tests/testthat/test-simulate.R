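test_that("a perfect tracker reproduces the stimulus onsets exactly", {
  sched <- slow_sched()
  env <- simulate_motor_response(sched, oscillator_params(coupling = 1),
                                 syllable_kernel(), fs = 100, seed = 1)
  ev <- attr(env, "events")
  expect_equal(ev, sched$onsets[seq_along(ev)], tolerance = 1e-12)
  # same seed -> identical envelope
  env2 <- simulate_motor_response(sched, oscillator_params(coupling = 1),
                                  syllable_kernel(), fs = 100, seed = 1)
  expect_identical(env$samples, env2$samples)
})

test_that("an uncoupled mistuned oscillator locks worse than a matched one", {
  sched <- make_accelerating_schedule(2, 2, 0.04, 200)  # long isochronous
  stim <- render_stimulus_envelope(sched, syllable_kernel(), 100)
  band <- band_preset("slow")
  run <- function(rate) {
    mo <- simulate_motor_response(
      sched, oscillator_params(coupling = 0, intrinsic_rate = rate),
      effector_kernel("tap"), 100, seed = 5)
    ph_a <- bandpass_phase(stim, band)
    ph_m <- bandpass_phase(mo, band)
    windowed_plv(ph_a, ph_m, band)$raw_plv
  }
  expect_gt(run(2.0), run(2.1))   # +5% detuning decoheres the phase
})

test_that("coupling monotonicity: mean normalized PLV rises with coupling", {
  sched <- slow_sched()
  stim <- render_stimulus_envelope(sched, syllable_kernel(), 100)
  band <- band_preset("slow")
  couplings <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(couplings, function(cp) {
    mean(vapply(1:20, function(s) {
      par <- oscillator_params(cp, phase_noise_sd = 0.6, lag = 0.02,
                               drift_sd = 0.005)
      mo <- simulate_motor_response(sched, par, effector_kernel("tap"),
                                    100, seed = 1000 * cp + s)
      permutation_baseline(stim, mo, band, n_permutations = 5,
                           seed = s)$normalized_plv
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("tap and whisper kernels separate in envelope FWHM", {
  sched <- make_accelerating_schedule(2, 2, 0.04, 120)
  tap <- simulate_motor_response(sched, oscillator_params(1),
                                 effector_kernel("tap"), 100, seed = 1)
  whi <- simulate_motor_response(sched, oscillator_params(1),
                                 effector_kernel("whisper"), 100, seed = 1)
  # narrower bursts -> more energy in higher harmonics -> broader
  # low-frequency spectral structure; assert a consistent ordering of the
  # temporal burst widths via the envelope autocorrelation width instead:
  # the whisper envelope has wider bursts, so its envelope spectrum decays
  # faster above the rate peak
  sp_t <- spectral_peak(tap)
  sp_w <- spectral_peak(whi)
  expect_equal(sp_t$peak_freq, sp_w$peak_freq, tolerance = 0.05)
  # harmonic at 4 Hz relative to 2 Hz fundamental is stronger for taps
  harm_ratio <- function(env) {
    x <- env$samples - mean(env$samples)
    amp <- Mod(fft(x))
    freqs <- (seq_along(amp) - 1) * env$fs / length(amp)
    near <- function(f) max(amp[abs(freqs - f) < 0.1])
    near(4) / near(2)
  }
  expect_gt(harm_ratio(tap), harm_ratio(whi))
})

test_that("population couplings reproduce latent scores when noiseless", {
  L <- diag(3)[rep(1:3, length.out = 8) * 0 + rep(1:3, c(4, 2, 2)), ]
  L <- L * 0.1
  mod <- population_model(50, loadings = L, noise_sd = 0,
                          base_coupling = 0.5, seed = 4)
  pop <- simulate_population(mod)
  # inside the clip region couplings are an exact affine map of latents
  recon <- 0.5 + pop$latent_scores %*% t(L)
  inside <- recon > 0 & recon < 1
  expect_equal(pop$couplings[inside], recon[inside], tolerance = 1e-12)
})

test_that("single-component populations concentrate the variance", {
  L <- matrix(0.15, 8, 1)
  mod <- population_model(300, loadings = L, noise_sd = 0.01,
                          base_coupling = 0.5, seed = 9)
  pop <- simulate_population(mod)
  ev <- eigen(cor(pop$couplings), symmetric = TRUE)$values
  expect_gt(ev[1] / 8, 0.9)
})

test_that("psychometric responses respect the model's limiting cases", {
  block <- make_perception_block("syllable", 40, 2, 0.02, 5,
                                 c(0.28, 0.34), seed = 6)
  # near-step psychometric function with threshold below every shift
  sharp <- psychometric_model(thresholds = c(syllable_slow = 0.10,
                                             syllable_fast = 0.10,
                                             tone_slow = 0.10,
                                             tone_fast = 0.10),
                              slope = 1e4, lapse = 0)
  resp <- simulate_perception_responses(block, sharp, seed = 1)
  expect_true(all(resp$correct[resp$is_deviant]))

  # unattainable threshold -> overall accuracy at chance
  impossible <- psychometric_model(thresholds = c(syllable_slow = 1e6,
                                                  syllable_fast = 1e6,
                                                  tone_slow = 1e6,
                                                  tone_fast = 1e6),
                                   slope = 10, lapse = 0)
  big <- make_perception_block("syllable", 400, 2, 0.02, 5,
                               c(0.28, 0.34), seed = 8)
  resp2 <- simulate_perception_responses(big, impossible, seed = 2)
  expect_equal(mean(resp2$correct), 0.5, tolerance = 0.06)

  # determinism
  r1 <- simulate_perception_responses(block, psychometric_model(),
                                      seed = 3)
  r2 <- simulate_perception_responses(block, psychometric_model(),
                                      seed = 3)
  expect_identical(r1, r2)
})

test_that("default thresholds produce the rate-by-stimulus crossover", {
  # syllables relatively easier fast, tones easier slow
  model <- psychometric_model()
  acc <- sapply(c("syllable", "tone"), function(st) {
    sapply(c("slow", "fast"), function(rt) {
      b <- make_perception_block(
        st, 200, if (rt == "slow") 2 else 4.5,
        shift_range = if (st == "syllable") c(0.28, 0.34) else
          c(0.12, 0.18),
        seed = 10)
      r <- simulate_perception_responses(b, model, seed = 11)
      mean(r$correct[r$is_deviant])
    })
  })
  expect_gt(acc["fast", "syllable"], acc["slow", "syllable"])
  expect_gt(acc["slow", "tone"], acc["fast", "tone"])
})
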