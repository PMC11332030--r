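#' Amplitude-envelope signals
#'
#' An `envelope_signal` is a uniformly sampled, nonnegative amplitude
#' envelope -- the common currency between recorded audio and the simulator.
#' The canonical sampling rate for synchronization analysis is 100 Hz.
#'
#' @param samples nonnegative numeric vector.
#' @param fs sampling rate in Hz.
#' @param channel_label `"acoustic"` or `"motor"`.
#' @return An object of class `envelope_signal`.
#' @export
envelope_signal <- function(samples, fs,
                            channel_label = c("acoustic", "motor")) {
  channel_label <- match.arg(channel_label)
  if (fs <= 0) stop_invalid("fs must be positive")
  if (any(!is.finite(samples))) stop_invalid("samples must be finite")
  if (any(samples < -1e-12)) stop_invalid("envelope samples must be >= 0")
  structure(list(samples = as.double(pmax(samples, 0)), fs = fs,
                 duration = length(samples) / fs,
                 channel_label = channel_label),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("Envelope [%s]: %.2f s at %g Hz (%d samples)\n",
              x$channel_label, x$duration, x$fs, length(x$samples)))
  invisible(x)
}

#' @export
plot.envelope_signal <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  plot(t, x$samples, type = "l", xlab = "time (s)",
       ylab = "amplitude (a.u.)",
       main = paste(x$channel_label, "envelope"), ...)
  invisible(x)
}

#' Analysis rate bands
#'
#' A `rate_band` bundles the band-pass corner frequencies used before phase
#' extraction with the PLV windowing parameters for that rate. The two
#' canonical presets are `fast` (3.5-5.5 Hz band, 5 s windows with 2 s
#' overlap) and `slow` (1.56-2.44 Hz band, 11 s windows with 4.5 s overlap);
#' the slow band equals the fast band scaled by the rate ratio 2.0/4.5.
#'
#' @param label band name.
#' @param lo,hi band corner frequencies in Hz.
#' @param window_s PLV window length in seconds.
#' @param overlap_s overlap between consecutive windows in seconds.
#' @return An object of class `rate_band`.
#' @export
rate_band <- function(label, lo, hi, window_s, overlap_s) {
  if (!(lo > 0 && lo < hi)) stop_invalid("need 0 < lo < hi")
  if (!(overlap_s > 0 && overlap_s < window_s)) {
    stop_invalid("need 0 < overlap_s < window_s")
  }
  structure(list(label = label, lo = lo, hi = hi,
                 window_s = window_s, overlap_s = overlap_s),
            class = "rate_band")
}

#' @rdname rate_band
#' @param name `"fast"` or `"slow"`.
#' @export
band_preset <- function(name = c("fast", "slow")) {
  name <- match.arg(name)
  switch(name,
         fast = rate_band("fast", 3.5, 5.5, window_s = 5, overlap_s = 2),
         slow = rate_band("slow", 1.56, 2.44, window_s = 11,
                          overlap_s = 4.5))
}

#' Extract a 100 Hz amplitude envelope from audio
#'
#' Cochlear-style envelope extraction: a bank of `n_channels` log-spaced
#' band-pass filters spanning `band_lo`-`band_hi` Hz (default 180-7246 Hz),
#' per-channel half-wave rectification and optional power-law compression,
#' cross-channel summation, low-pass smoothing and anti-aliased resampling
#' to `target_fs`.
#'
#' @param audio numeric waveform (mono; a matrix's first column is used).
#' @param fs audio sample rate in Hz; must exceed `2 * band_hi`.
#' @param band_lo,band_hi filterbank span in Hz.
#' @param target_fs output envelope rate in Hz.
#' @param n_channels number of filterbank channels.
#' @param compression power-law exponent applied per channel after
#'   rectification (e.g. 0.3); `NULL` disables compression, making the
#'   extraction homogeneous of degree 1 in the input amplitude.
#' @param smooth_hz low-pass corner for envelope smoothing before
#'   resampling; must be below `target_fs / 2`.
#' @param channel_label forwarded to [envelope_signal()].
#' @return An [envelope_signal()] at `target_fs`.
#' @export
extract_envelope <- function(audio, fs, band_lo = 180, band_hi = 7246,
                             target_fs = 100, n_channels = 32,
                             compression = 0.3, smooth_hz = 10,
                             channel_label = "acoustic") {
  if (is.matrix(audio)) audio <- audio[, 1]
  if (any(!is.finite(audio))) stop_invalid("audio must be finite")
  if (fs <= 2 * band_hi) {
    stop_invalid("audio sample rate (", fs, " Hz) must exceed 2 * band_hi (",
                 2 * band_hi, " Hz)")
  }
  if (smooth_hz >= target_fs / 2) {
    stop_invalid("smooth_hz must be below target_fs / 2")
  }
  edges <- exp(seq(log(band_lo), log(band_hi), length.out = n_channels + 1))
  nyq <- fs / 2
  env <- numeric(length(audio))
  for (ch in seq_len(n_channels)) {
    b <- signal::butter(2, c(edges[ch], edges[ch + 1]) / nyq, type = "pass")
    y <- signal::filtfilt(b, audio)
    y <- pmax(y, 0)                      # half-wave rectification
    if (!is.null(compression)) y <- y^compression
    env <- env + y
  }
  lp <- signal::butter(4, smooth_hz / nyq, type = "low")
  env <- signal::filtfilt(lp, env)
  t_out <- seq(0, (length(audio) - 1) / fs, by = 1 / target_fs)
  t_in <- (seq_along(env) - 1) / fs
  out <- stats::approx(t_in, env, xout = t_out, rule = 2)$y
  envelope_signal(pmax(out, 0), target_fs, channel_label)
}

# Mirror extension of length m off the end of x (triangular reflection,
# so m may exceed length(x)).
reflect_tail <- function(x, m) {
  n <- length(x)
  idx <- n + seq_len(m)
  period <- 2 * n
  r <- (idx - 1) %% period
  mirrored <- ifelse(r < n, r + 1, period - r)
  x[mirrored]
}

reflect_head <- function(x, m) rev(reflect_tail(rev(x), m))

# Squared magnitude response of a digital filter at the n FFT bin
# frequencies, memoized: permutation loops reapply the same band to
# same-length signals many times.
.response_cache <- new.env(parent = emptyenv())

butter_mag2_response <- function(b, n, band, fs, order) {
  key <- paste(n, fs, band$lo, band$hi, order, sep = "|")
  cached <- .response_cache[[key]]
  if (!is.null(cached)) return(cached)
  z <- exp(-1i * 2 * pi * (seq_len(n) - 1) / n)
  horner <- function(coefs) {
    acc <- rep(coefs[length(coefs)] + 0i, n)
    for (j in rev(seq_len(length(coefs) - 1))) acc <- acc * z + coefs[j]
    acc
  }
  H <- Mod(horner(b$b) / horner(b$a))^2
  if (length(.response_cache) > 64) {
    rm(list = ls(.response_cache), envir = .response_cache)
  }
  .response_cache[[key]] <- H
  H
}

# Analytic signal via FFT: positive frequencies doubled, negative zeroed.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Band-pass filter an envelope and extract instantaneous phase
#'
#' Zero-phase Butterworth band-pass around the stimulus rate, followed by
#' the Hilbert transform. The signal is reflect-padded by `3 / band$lo`
#' seconds to suppress edge transients and filtered spectrally with the
#' squared magnitude response of the digital Butterworth design (the
#' transfer function a forward-backward pass applies), which is exactly
#' zero-phase and exactly symmetric under time reversal. Instantaneous
#' phase is the argument of the analytic signal, in (-pi, pi].
#'
#' @param env an [envelope_signal()].
#' @param band a [rate_band()] (see [band_preset()]).
#' @param order Butterworth order before the forward-backward doubling.
#' @return An object of class `phase_series`: `phases` (radians), `fs`,
#'   `band`, and the analytic `amplitude` (envelope of the band-limited
#'   signal).
#' @export
bandpass_phase <- function(env, band, order = 2) {
  stopifnot(inherits(env, "envelope_signal"), inherits(band, "rate_band"))
  if (env$fs <= 2 * band$hi) {
    stop_invalid("envelope fs must exceed 2 * band hi")
  }
  pad_n <- ceiling(3 / band$lo * env$fs)
  x <- env$samples
  if (length(x) <= pad_n) {
    stop_invalid("envelope too short for band filtering: need > ",
                 sprintf("%.1f", pad_n / env$fs), " s, got ",
                 sprintf("%.1f", env$duration), " s")
  }
  # total padded length rounded up to a 2-3-5-smooth FFT size, keeping the
  # two reflection pads equal so filtering stays exactly time-reversal
  # symmetric
  n <- stats::nextn(length(x) + 2 * pad_n, c(2, 3, 5))
  if ((n - length(x)) %% 2 == 1) n <- stats::nextn(n + 1, c(2, 3, 5))
  p <- (n - length(x)) / 2
  xp <- c(reflect_head(x, p), x, reflect_tail(x, p))
  b <- signal::butter(order, c(band$lo, band$hi) / (env$fs / 2),
                      type = "pass")
  H <- butter_mag2_response(b, n, band, env$fs, order)
  yf <- Re(fft(fft(xp) * H, inverse = TRUE) / n)[p + seq_along(x)]
  a <- analytic_signal(yf)
  structure(list(phases = Arg(a), fs = env$fs, band = band,
                 amplitude = Mod(a), filtered = yf),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Phase series: %d samples at %g Hz, band %s [%g, %g] Hz\n",
              length(x$phases), x$fs, x$band$label, x$band$lo, x$band$hi))
  invisible(x)
}

#' Write/read an envelope as CSV with a JSON sidecar
#'
#' The CSV has columns `time_s` and `amplitude`; the sidecar
#' (`<path>.json`) records `fs`, `channel_label`, and provenance fields.
#'
#' @param env an [envelope_signal()].
#' @param path CSV file path.
#' @param provenance optional named list stored in the sidecar.
#' @return `read_envelope_csv` returns an [envelope_signal()].
#' @export
write_envelope_csv <- function(env, path, provenance = list()) {
  stopifnot(inherits(env, "envelope_signal"))
  df <- data.frame(time_s = (seq_along(env$samples) - 1) / env$fs,
                   amplitude = env$samples)
  write.csv(df, path, row.names = FALSE)
  meta <- c(list(fs = env$fs, channel_label = env$channel_label,
                 n_samples = length(env$samples),
                 package_version = as.character(packageVersion("plvsync"))),
            provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  df <- read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- meta$fs
    label <- meta$channel_label
  } else {
    fs <- 1 / stats::median(diff(df$time_s))
    label <- "acoustic"
  }
  envelope_signal(df$amplitude, fs, label)
}
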