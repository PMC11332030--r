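#' Error-correcting oscillator parameters
#'
#' Parameters of the synthetic synchronizer. On each cycle the simulated
#' producer predicts its next event one intrinsic period after the last,
#' then corrects a fraction `coupling` of the gap between that prediction
#' and the nearest stimulus onset (plus `lag`), with Gaussian timing noise
#' of `phase_noise_sd` radians per event. The intrinsic rate follows a
#' random walk with step SD `drift_sd` Hz.
#'
#' @param coupling fraction of each cycle's phase error corrected, in
#'   \[0, 1\].
#' @param phase_noise_sd per-event phase noise SD in radians.
#' @param lag constant production lag in seconds (motor events aim at
#'   `onset + lag`).
#' @param drift_sd random-walk step SD of the intrinsic rate, in Hz.
#' @param intrinsic_rate intrinsic production rate in Hz; `NULL` adopts the
#'   stimulus sequence's starting rate.
#' @return An `oscillator_params` object.
#' @export
oscillator_params <- function(coupling, phase_noise_sd = 0, lag = 0,
                              drift_sd = 0, intrinsic_rate = NULL) {
  if (coupling < 0 || coupling > 1) stop_invalid("coupling must be in [0,1]")
  if (phase_noise_sd < 0 || drift_sd < 0) {
    stop_invalid("noise SDs must be >= 0")
  }
  structure(list(coupling = coupling, phase_noise_sd = phase_noise_sd,
                 lag = lag, drift_sd = drift_sd,
                 intrinsic_rate = intrinsic_rate),
            class = "oscillator_params")
}

#' Effector-specific burst kernels
#'
#' Motor events are rendered into the envelope as Gaussian bursts whose
#' width reflects the effector: finger taps are brief transients (default
#' FWHM 30 ms) while whispered syllables are broader bursts (default FWHM
#' 120 ms). These defaults are chosen for clear separability of the two
#' effectors' envelope spectra, not calibrated to any recording corpus.
#'
#' @param label `"tap"`, `"whisper"`, or a free label for stimulus kernels.
#' @param burst_fwhm burst full width at half maximum in seconds; defaults
#'   to 0.03 for `"tap"` and 0.12 for `"whisper"`.
#' @param amplitude_jitter multiplicative per-event amplitude jitter
#'   (uniform on `1 +/- amplitude_jitter`).
#' @return An `effector_kernel` object.
#' @export
effector_kernel <- function(label = c("tap", "whisper"), burst_fwhm = NULL,
                            amplitude_jitter = 0) {
  if (length(label) > 1) label <- label[1]
  if (is.null(burst_fwhm)) {
    burst_fwhm <- switch(label, tap = 0.03, whisper = 0.12,
                         stop_invalid("burst_fwhm required for label '",
                                      label, "'"))
  }
  if (burst_fwhm <= 0) stop_invalid("burst_fwhm must be positive")
  if (amplitude_jitter < 0 || amplitude_jitter >= 1) {
    stop_invalid("amplitude_jitter must be in [0, 1)")
  }
  structure(list(label = label, burst_fwhm = burst_fwhm,
                 amplitude_jitter = amplitude_jitter),
            class = "effector_kernel")
}

# Render event times as Gaussian bursts into an envelope.
render_bursts <- function(times, amplitudes, fwhm, fs, duration) {
  n <- max(1L, round(duration * fs))
  env <- numeric(n)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half_n <- max(1L, ceiling(4 * sigma * fs))
  kernel_t <- (-half_n:half_n) / fs
  kernel <- exp(-kernel_t^2 / (2 * sigma^2))
  for (j in seq_along(times)) {
    c0 <- round(times[j] * fs) + 1L
    idx <- (c0 - half_n):(c0 + half_n)
    ok <- idx >= 1L & idx <= n
    env[idx[ok]] <- env[idx[ok]] + amplitudes[j] * kernel[ok]
  }
  env
}

#' Render a stimulus schedule as an acoustic envelope
#'
#' Places one burst per scheduled onset, standing in for the envelope of
#' the synthesized syllable or tone stream.
#'
#' @param schedule an [onset_schedule()].
#' @param kernel an [effector_kernel()] describing the burst shape.
#' @param fs envelope sampling rate in Hz.
#' @param duration envelope duration in seconds; defaults to the schedule
#'   span plus one final inter-onset interval.
#' @param seed RNG seed (used only when the kernel has amplitude jitter).
#' @return An [envelope_signal()] with `channel_label = "acoustic"`.
#' @export
render_stimulus_envelope <- function(schedule, kernel, fs = 100,
                                     duration = NULL, seed = NULL) {
  stopifnot(inherits(schedule, "onset_schedule"),
            inherits(kernel, "effector_kernel"))
  if (is.null(duration)) {
    duration <- total_duration(schedule) +
      1 / schedule$rates[schedule$n_events]
  }
  amps <- if (kernel$amplitude_jitter > 0) {
    with_rng_seed(seed, 1 + runif(schedule$n_events,
                                  -kernel$amplitude_jitter,
                                  kernel$amplitude_jitter))
  } else rep(1, schedule$n_events)
  env <- render_bursts(schedule$onsets, amps, kernel$burst_fwhm, fs,
                       duration)
  envelope_signal(env, fs, "acoustic")
}

#' Simulate a motor response to a stimulus sequence
#'
#' Generates motor event times from the error-correcting phase model and
#' renders them as an envelope. The first motor event coincides with the
#' first stimulus onset (plus `lag`); each subsequent event is predicted
#' one intrinsic period ahead and pulled toward the nearest stimulus onset
#' by the coupling fraction. With `coupling = 1` and no noise, lag or
#' drift, the motor events reproduce the stimulus onsets exactly; with
#' `coupling = 0` the producer free-runs at its intrinsic rate.
#'
#' @param stimulus an [onset_schedule()].
#' @param params an [oscillator_params()].
#' @param kernel an [effector_kernel()].
#' @param fs envelope sampling rate in Hz (>= 100 recommended).
#' @param seed RNG seed; the response is a pure function of
#'   (stimulus, params, kernel, fs, seed).
#' @param duration envelope duration in seconds (default: schedule span
#'   plus one final IOI).
#' @return An [envelope_signal()] with `channel_label = "motor"` and an
#'   attribute `"events"` holding the motor event times.
#' @export
simulate_motor_response <- function(stimulus, params, kernel, fs = 100,
                                    seed = 1, duration = NULL) {
  stopifnot(inherits(stimulus, "onset_schedule"),
            inherits(params, "oscillator_params"),
            inherits(kernel, "effector_kernel"))
  onsets <- stimulus$onsets
  if (is.null(duration)) {
    duration <- total_duration(stimulus) +
      1 / stimulus$rates[stimulus$n_events]
  }
  rate <- if (is.null(params$intrinsic_rate)) stimulus$rates[1] else
    params$intrinsic_rate
  events <- with_rng_seed(seed, {
    ev <- numeric(0)
    t_cur <- onsets[1] + params$lag
    repeat {
      ev <- c(ev, t_cur)
      if (params$drift_sd > 0) {
        rate <- max(rate + rnorm(1, 0, params$drift_sd), 0.1)
      }
      predicted <- t_cur + 1 / rate
      if (predicted > duration) break
      # re-anchor on the nearest stimulus onset (robust to missed events)
      nearest <- onsets[which.min(abs(onsets - predicted))]
      t_next <- predicted +
        params$coupling * (nearest + params$lag - predicted)
      if (params$phase_noise_sd > 0) {
        t_next <- t_next + rnorm(1, 0, params$phase_noise_sd) /
          (2 * pi * rate)
      }
      if (t_next <= t_cur) t_next <- t_cur + 0.25 / rate
      if (t_next > duration) break
      t_cur <- t_next
    }
    ev
  })
  amps <- if (kernel$amplitude_jitter > 0) {
    with_rng_seed(seed + 1, 1 + runif(length(events),
                                      -kernel$amplitude_jitter,
                                      kernel$amplitude_jitter))
  } else rep(1, length(events))
  env <- render_bursts(events, amps, kernel$burst_fwhm, fs, duration)
  out <- envelope_signal(env, fs, "motor")
  attr(out, "events") <- events
  out
}

# The eight canonical synchronization conditions.
#' @rdname population_model
#' @export
condition_grid <- function() {
  g <- expand.grid(rate = c("fast", "slow"),
                   effector = c("tap", "whisper"),
                   stimulus = c("syllable", "tone"),
                   stringsAsFactors = FALSE)
  g <- g[order(g$rate, g$effector, g$stimulus), c("effector", "stimulus",
                                                  "rate")]
  g$condition <- paste(g$effector, g$stimulus, g$rate, sep = "_")
  rownames(g) <- NULL
  g
}

#' Latent-component participant population
#'
#' Defines a population whose 8-condition coupling strengths arise from
#' three latent components: one general fast-synchronization component
#' loading on all four fast conditions, and two slow effector-specific
#' components (slow-whisper and slow-tap). A participant's coupling in
#' condition j is `base + (L z)_j * + noise`, clipped into \[0, 1\], with
#' `z` standard-normal latent scores. Clipping (rather than a logistic
#' squash) keeps the latent-to-coupling map affine where valid, which makes
#' recovery tests interpretable.
#'
#' @param n_participants population size.
#' @param loadings 8 x 3 loading matrix (rows ordered as
#'   [condition_grid()]); `NULL` uses the default well-separated structure
#'   with loading 0.18 on each component's conditions.
#' @param component_sds SDs of the three latent components.
#' @param noise_sd SD of condition-specific coupling noise.
#' @param base_coupling population-mean coupling; the default 0.35 places
#'   the population in the responsive part of the coupling-to-PLV map
#'   (above ~0.6 the normalized PLV saturates and between-participant
#'   differences compress).
#' @param seed RNG seed.
#' @return A `population_model` object.
#' @export
population_model <- function(n_participants, loadings = NULL,
                             component_sds = c(1, 1, 1), noise_sd = 0.05,
                             base_coupling = 0.35, seed = 1) {
  grid <- condition_grid()
  if (is.null(loadings)) {
    loadings <- matrix(0, 8, 3,
                       dimnames = list(grid$condition,
                                       c("fast_general", "slow_whisper",
                                         "slow_tap")))
    loadings[grid$rate == "fast", "fast_general"] <- 0.18
    loadings[grid$rate == "slow" & grid$effector == "whisper",
             "slow_whisper"] <- 0.18
    loadings[grid$rate == "slow" & grid$effector == "tap",
             "slow_tap"] <- 0.18
  }
  if (!all(dim(loadings) == c(8, ncol(loadings)))) {
    stop_invalid("loadings must have 8 rows (one per condition)")
  }
  if (any(!is.finite(loadings)) || any(component_sds < 0) || noise_sd < 0) {
    stop_invalid("loadings must be finite and SDs >= 0")
  }
  component_sds <- rep_len(component_sds, ncol(loadings))
  structure(list(n_participants = as.integer(n_participants),
                 loadings = loadings, component_sds = component_sds,
                 noise_sd = noise_sd, base_coupling = base_coupling,
                 seed = seed, conditions = grid),
            class = "population_model")
}

#' Draw a participant population's condition couplings
#'
#' Samples latent component scores and condition-specific noise, returning
#' each participant's coupling strength in the eight conditions together
#' with the generating latent scores (the ground truth for recovery tests).
#'
#' @param model a [population_model()].
#' @return list with `couplings` (participant x 8 matrix in \[0, 1\]),
#'   `latent_scores` (participant x k matrix), and `conditions`.
#' @export
simulate_population <- function(model) {
  stopifnot(inherits(model, "population_model"))
  k <- ncol(model$loadings)
  with_rng_seed(model$seed, {
    z <- matrix(rnorm(model$n_participants * k), ncol = k)
    z <- sweep(z, 2, model$component_sds, `*`)
    eps <- matrix(rnorm(model$n_participants * 8, 0, model$noise_sd),
                  ncol = 8)
    raw <- model$base_coupling + z %*% t(model$loadings) + eps
    couplings <- pmin(pmax(raw, 0), 1)
    colnames(couplings) <- model$conditions$condition
    colnames(z) <- colnames(model$loadings)
    list(couplings = couplings, latent_scores = z,
         conditions = model$conditions)
  })
}

#' Psychometric model for deviant detection
#'
#' Response generator for the temporal deviant-detection task. The
#' probability of reporting "deviant" given a final-onset advance of `s`
#' (as a fraction of the IOI) is
#' `guess + (1 - guess - lapse) * logistic(slope * (s - threshold))`;
#' standards are answered "deviant" at the false-alarm rate implied by
#' `s = 0`. Thresholds are per stimulus x rate condition.
#'
#' @param thresholds named numeric vector of shift-fraction thresholds with
#'   names `"syllable_slow"`, `"syllable_fast"`, `"tone_slow"`,
#'   `"tone_fast"`. The defaults make syllables relatively easier at fast
#'   rates and tones easier at slow rates.
#' @param slope logistic steepness (per unit shift fraction).
#' @param lapse lapse rate.
#' @param guess guessing baseline (0.5 for the two-alternative task).
#' @return A `psychometric_model` object.
#' @export
psychometric_model <- function(thresholds = c(syllable_slow = 0.31,
                                              syllable_fast = 0.27,
                                              tone_slow = 0.13,
                                              tone_fast = 0.16),
                               slope = 25, lapse = 0.02, guess = 0.5) {
  if (slope <= 0) stop_invalid("slope must be positive")
  if (lapse < 0 || lapse > 0.5 || guess < 0 || guess > 1) {
    stop_invalid("lapse/guess out of range")
  }
  structure(list(thresholds = thresholds, slope = slope, lapse = lapse,
                 guess = guess),
            class = "psychometric_model")
}

#' Simulate deviant-detection responses for a block
#'
#' @param block a `perception_block` from [make_perception_block()].
#' @param model a [psychometric_model()].
#' @param seed RNG seed.
#' @return The block's trials data frame with added columns
#'   `p_report_deviant`, `response` (TRUE = "deviant"), and `correct`.
#' @export
simulate_perception_responses <- function(block, model, seed = 1) {
  stopifnot(inherits(block, "perception_block"),
            inherits(model, "psychometric_model"))
  key <- paste(block$stimulus_class, block$rate_label, sep = "_")
  thr <- model$thresholds[[key]]
  if (is.null(thr)) stop_invalid("no threshold for condition ", key)
  tr <- block$trials
  p <- model$guess + (1 - model$guess - model$lapse) *
    plogis(model$slope * (tr$shift_fraction - thr))
  resp <- with_rng_seed(seed, rbinom(nrow(tr), 1, p) == 1)
  tr$p_report_deviant <- p
  tr$response <- resp
  tr$correct <- resp == tr$is_deviant
  tr$stimulus <- block$stimulus_class
  tr$rate <- block$rate_label
  tr
}
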