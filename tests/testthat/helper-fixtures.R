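# Shared fixtures, built in code at test time.

# Envelope carrying a pure sinusoidal modulation at f_hz (offset to stay
# nonnegative).
sine_envelope <- function(f_hz, duration_s, fs = 100, amp = 1,
                          label = "acoustic") {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  envelope_signal(1 + amp * sin(2 * pi * f_hz * t), fs, label)
}

# Non-periodic envelope: low-passed white noise, shifted nonnegative.
noise_envelope <- function(duration_s, fs = 100, seed = 1,
                           label = "acoustic", lp_hz = 10) {
  set.seed(seed)
  x <- rnorm(round(duration_s * fs))
  b <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  e <- signal::filtfilt(b, x)
  envelope_signal(e - min(e), fs, label)
}

# Amplitude-modulated audio carrier for envelope-extraction tests.
am_tone <- function(carrier_hz, mod_hz, duration_s, fs = 16000,
                    depth = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  (1 + depth * sin(2 * pi * mod_hz * t)) / 2 * sin(2 * pi * carrier_hz * t)
}

slow_sched <- function() make_accelerating_schedule(1.92, 2.08, 0.04, 48)
fast_sched <- function() make_accelerating_schedule(4.3, 4.7, 0.1, 48)

syllable_kernel <- function() effector_kernel("syllable", burst_fwhm = 0.10)
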