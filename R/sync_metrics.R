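#' Phase-locking value
#'
#' The PLV between two phase series is the magnitude of the time-averaged
#' unit phasor of their phase difference,
#' `PLV = |sum(exp(i * (theta1 - theta2)))| / T`. It is 1 when the phase
#' difference is constant (perfect locking, at any fixed offset) and near 0
#' when the phase relation is inconsistent.
#'
#' @param theta1,theta2 numeric phase vectors in radians, or `phase_series`
#'   objects of equal length and sampling rate.
#' @return A scalar in \[0, 1\].
#' @examples
#' th <- runif(100, -pi, pi)
#' plv(th, th)            # 1
#' plv(th + pi / 3, th)   # 1: constant offsets do not matter
#' @export
plv <- function(theta1, theta2) {
  t1 <- if (inherits(theta1, "phase_series")) theta1$phases else theta1
  t2 <- if (inherits(theta2, "phase_series")) theta2$phases else theta2
  if (inherits(theta1, "phase_series") && inherits(theta2, "phase_series") &&
      theta1$fs != theta2$fs) {
    stop_invalid("phase series sampling rates differ")
  }
  if (length(t1) != length(t2)) stop_invalid("phase series lengths differ")
  if (length(t1) < 1) stop_invalid("phase series must be non-empty")
  Mod(mean(exp(1i * (t1 - t2))))
}

#' Windowed phase-locking value
#'
#' Computes the PLV in sliding windows of `band$window_s` seconds advancing
#' by `window_s - overlap_s` seconds (fast preset: 5 s windows, 2 s overlap;
#' slow preset: 11 s windows, 4.5 s overlap). Windows are aligned to the
#' trial start; a trailing partial window is dropped. The trial-level raw
#' PLV is the unweighted mean over windows.
#'
#' @param theta1,theta2 `phase_series` objects (or numeric phase vectors
#'   with sampling rate taken from `fs`).
#' @param band a [rate_band()] supplying the windowing parameters.
#' @param fs sampling rate, required only when phases are plain vectors.
#' @return list with `raw_plv`, `window_plvs`, `window_starts_s`,
#'   `n_windows`.
#' @export
windowed_plv <- function(theta1, theta2, band, fs = NULL) {
  stopifnot(inherits(band, "rate_band"))
  t1 <- if (inherits(theta1, "phase_series")) theta1$phases else theta1
  t2 <- if (inherits(theta2, "phase_series")) theta2$phases else theta2
  if (is.null(fs)) {
    if (!inherits(theta1, "phase_series")) {
      stop_invalid("fs required for plain phase vectors")
    }
    fs <- theta1$fs
  }
  if (length(t1) != length(t2)) stop_invalid("phase series lengths differ")
  win_n <- round(band$window_s * fs)
  hop_n <- round((band$window_s - band$overlap_s) * fs)
  if (length(t1) < win_n) {
    stop_invalid("series shorter than one analysis window (",
                 band$window_s, " s)")
  }
  starts <- seq.int(1L, length(t1) - win_n + 1L, by = hop_n)
  wp <- vapply(starts, function(s) {
    idx <- s:(s + win_n - 1L)
    Mod(mean(exp(1i * (t1[idx] - t2[idx]))))
  }, numeric(1))
  list(raw_plv = mean(wp), window_plvs = wp,
       window_starts_s = (starts - 1) / fs, n_windows = length(wp))
}

#' Permutation-baselined phase-locking value
#'
#' Estimates chance-level phase locking by cutting the acoustic envelope
#' into contiguous segments of `band$window_s` seconds, shuffling the
#' segment order, re-running band filtering and phase extraction on the
#' shuffled envelope, and recomputing the windowed PLV against the
#' unshuffled motor phase. The baseline is the mean over `n_permutations`
#' shuffles (identity permutations are rejected and redrawn); the
#' normalized PLV is `raw - baseline`. Trailing samples beyond a whole
#' number of segments are dropped from both channels so raw and baseline
#' are computed on identical supports.
#'
#' @param env_acoustic,env_motor [envelope_signal()] objects at the same
#'   sampling rate (trimmed to the shorter).
#' @param band a [rate_band()].
#' @param n_permutations number of segment shuffles (>= 1).
#' @param seed RNG seed for the shuffles.
#' @param order filter order passed to [bandpass_phase()].
#' @return A `plv_estimate`: `raw_plv`, `baseline_plv`, `normalized_plv`,
#'   `window_plvs`, `band`, `n_windows`, `n_segments`, `n_permutations`,
#'   `seed`.
#' @export
permutation_baseline <- function(env_acoustic, env_motor, band,
                                 n_permutations = 100, seed = 1,
                                 order = 2) {
  stopifnot(inherits(env_acoustic, "envelope_signal"),
            inherits(env_motor, "envelope_signal"),
            inherits(band, "rate_band"))
  if (env_acoustic$fs != env_motor$fs) {
    stop_invalid("envelope sampling rates differ")
  }
  if (n_permutations < 1) stop_invalid("n_permutations must be >= 1")
  fs <- env_acoustic$fs
  seg_n <- round(band$window_s * fs)
  len <- min(length(env_acoustic$samples), length(env_motor$samples))
  n_seg <- len %/% seg_n
  if (n_seg < 1) {
    stop_invalid("envelopes shorter than one segment (", band$window_s,
                 " s)")
  }
  keep <- seq_len(n_seg * seg_n)
  ac <- envelope_signal(env_acoustic$samples[keep], fs, "acoustic")
  mo <- envelope_signal(env_motor$samples[keep], fs, "motor")

  ph_mo <- bandpass_phase(mo, band, order = order)
  ph_ac <- bandpass_phase(ac, band, order = order)
  raw <- windowed_plv(ph_ac, ph_mo, band)

  if (n_seg < 2) {
    warning("fewer than 2 permutation segments; baseline set to raw PLV ",
            "(normalized PLV is 0)")
    baseline <- raw$raw_plv
    n_permutations <- 0L
  } else {
    seg_idx <- split(keep, rep(seq_len(n_seg), each = seg_n))
    perm_plvs <- with_rng_seed(seed, {
      vapply(seq_len(n_permutations), function(p) {
        repeat {
          ord <- sample.int(n_seg)
          if (!all(ord == seq_len(n_seg))) break
        }
        shuf <- envelope_signal(ac$samples[unlist(seg_idx[ord],
                                                  use.names = FALSE)],
                                fs, "acoustic")
        ph_shuf <- bandpass_phase(shuf, band, order = order)
        windowed_plv(ph_shuf, ph_mo, band)$raw_plv
      }, numeric(1))
    })
    baseline <- mean(perm_plvs)
  }
  structure(list(raw_plv = raw$raw_plv, baseline_plv = baseline,
                 normalized_plv = raw$raw_plv - baseline,
                 window_plvs = raw$window_plvs, band = band,
                 n_windows = raw$n_windows, n_segments = n_seg,
                 n_permutations = n_permutations, seed = seed),
            class = "plv_estimate")
}

#' @export
print.plv_estimate <- function(x, ...) {
  cat(sprintf(
    "PLV estimate [%s band]: raw %.3f, baseline %.3f, normalized %.3f\n",
    x$band$label, x$raw_plv, x$baseline_plv, x$normalized_plv))
  cat(sprintf("  %d windows, %d segments, %d permutations (seed %s)\n",
              x$n_windows, x$n_segments, x$n_permutations,
              format(x$seed)))
  invisible(x)
}

#' Average trial PLVs into one condition score
#'
#' One synchronization score per participant and condition: the arithmetic
#' mean of the trials' normalized PLVs (canonically two trials per
#' condition).
#'
#' @param trials list of `plv_estimate` objects.
#' @param participant_id,effector,stimulus,rate condition metadata.
#' @return A `condition_score`: metadata plus `plv` and `n_trials`.
#' @export
score_condition <- function(trials, participant_id, effector, stimulus,
                            rate) {
  if (length(trials) < 1) stop_invalid("need at least one trial")
  ok <- vapply(trials, inherits, logical(1), what = "plv_estimate")
  if (!all(ok)) stop_invalid("all trials must be plv_estimate objects")
  structure(list(participant_id = participant_id, effector = effector,
                 stimulus = stimulus, rate = rate,
                 plv = mean(vapply(trials, `[[`, numeric(1),
                                   "normalized_plv")),
                 n_trials = length(trials)),
            class = "condition_score")
}

#' Per-trial PLV results as a data frame row
#'
#' @param est a `plv_estimate`.
#' @param participant_id,effector,stimulus,rate,trial metadata columns.
#' @return One-row data frame matching the long-format per-trial table.
#' @export
plv_estimate_row <- function(est, participant_id, effector, stimulus, rate,
                             trial) {
  stopifnot(inherits(est, "plv_estimate"))
  data.frame(participant = participant_id, effector = effector,
             stimulus = stimulus, rate = rate, trial = trial,
             raw_plv = est$raw_plv, baseline_plv = est$baseline_plv,
             normalized_plv = est$normalized_plv,
             n_windows = est$n_windows,
             n_permutations = est$n_permutations, seed = est$seed)
}
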