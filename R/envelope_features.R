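#' Spectral peak features of an amplitude envelope
#'
#' Computes the covariates used alongside the synchronization scores: the
#' amplitude and full-width-half-maximum (FWHM) width of the strongest
#' sub-`f_max` peak of the envelope's amplitude spectrum. The envelope is
#' mean-subtracted before the FFT so the DC term cannot win; the strongest
#' local maximum with `0 < f < f_max` is selected, and the FWHM is measured
#' by linear interpolation to the half-height crossings around that peak.
#' A sharply rhythmic envelope yields a tall, narrow peak at the production
#' rate; irregular production broadens it.
#'
#' @param env an [envelope_signal()] of at least 2 s.
#' @param f_max upper frequency bound for the peak search, in Hz.
#' @return A `spectral_peak_features` object: `peak_freq` (Hz), `peak_amp`,
#'   `peak_width` (Hz, FWHM, floored at one frequency bin), `n_fft`,
#'   `freq_resolution` (Hz), and `width_truncated` (TRUE when a half-height
#'   crossing fell outside `[0, f_max]` and the width was truncated there).
#' @examples
#' t <- seq(0, 60, by = 0.01)
#' env <- envelope_signal(1 + sin(2 * pi * 2 * t), 100)
#' spectral_peak(env)$peak_freq  # 2 Hz
#' @export
spectral_peak <- function(env, f_max = 10) {
  stopifnot(inherits(env, "envelope_signal"))
  if (env$duration < 2) stop_invalid("envelope must be at least 2 s long")
  x <- env$samples - mean(env$samples)
  n <- length(x)
  amp <- Mod(fft(x))
  df <- env$fs / n
  freqs <- (seq_len(n) - 1) * df
  half <- freqs <= env$fs / 2
  amp <- amp[half]; freqs <- freqs[half]

  in_band <- which(freqs > 0 & freqs < f_max)
  # local maxima: strictly above the left neighbor, at least the right
  is_peak <- vapply(in_band, function(i) {
    left <- if (i > 1) amp[i - 1] else -Inf
    right <- if (i < length(amp)) amp[i + 1] else -Inf
    amp[i] > left && amp[i] >= right
  }, logical(1))
  cand <- in_band[is_peak]
  if (!length(cand) || all(amp[cand] <= 0)) {
    stop(errorCondition(
      paste0("no spectral peak below ", f_max, " Hz"),
      class = c("plvsync_no_peak", "plvsync_invalid", "error")))
  }
  # strongest peak; ties broken toward lower frequency
  pk <- cand[which.max(amp[cand])]
  peak_amp <- amp[pk]
  half_h <- peak_amp / 2

  cross <- function(dir) {
    i <- pk
    repeat {
      j <- i + dir
      if (j < 1 || j > length(amp)) return(list(f = NA_real_, trunc = TRUE))
      if (amp[j] < half_h) {
        f <- freqs[i] + dir * df * (amp[i] - half_h) / (amp[i] - amp[j])
        return(list(f = f, trunc = FALSE))
      }
      i <- j
    }
  }
  left <- cross(-1L)
  right <- cross(+1L)
  truncated <- FALSE
  f_lo <- if (left$trunc || left$f < 0) { truncated <- TRUE; 0 } else left$f
  f_hi <- if (right$trunc || right$f > f_max) {
    truncated <- TRUE; f_max
  } else right$f
  width <- max(f_hi - f_lo, df)

  structure(list(peak_freq = freqs[pk], peak_amp = peak_amp,
                 peak_width = width, n_fft = n, freq_resolution = df,
                 width_truncated = truncated),
            class = "spectral_peak_features")
}

#' @export
print.spectral_peak_features <- function(x, ...) {
  cat(sprintf(
    "Spectral peak: %.3f Hz, amplitude %.3g, FWHM %.3f Hz (res %.4f Hz)%s\n",
    x$peak_freq, x$peak_amp, x$peak_width, x$freq_resolution,
    if (x$width_truncated) " [width truncated]" else ""))
  invisible(x)
}
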