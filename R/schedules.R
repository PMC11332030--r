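#' Onset schedules
#'
#' An `onset_schedule` is the timing skeleton of a stimulus sequence: ordered
#' event onsets in seconds (first at 0) with the nominal presentation rate
#' attached to each event. An event's rate governs the interval *following*
#' it, so within an isochronous plateau every inter-onset interval (IOI)
#' equals `1/rate`.
#'
#' @param onsets numeric, strictly increasing onset times in seconds,
#'   starting at 0.
#' @param rates numeric, nominal rate (Hz) attached to each event.
#' @param deviant_shifted logical, whether each onset was displaced by a
#'   deviant manipulation (breaks the IOI/rate identity at that event).
#' @return An object of class `onset_schedule`.
#' @export
onset_schedule <- function(onsets, rates,
                           deviant_shifted = rep(FALSE, length(onsets))) {
  if (length(onsets) != length(rates)) {
    stop_invalid("onsets and rates must have equal length")
  }
  if (any(!is.finite(onsets)) || any(!is.finite(rates))) {
    stop_invalid("onsets and rates must be finite")
  }
  if (any(rates <= 0)) stop_invalid("rates must be positive")
  if (length(onsets) && abs(onsets[1]) > 1e-12) {
    stop_invalid("first onset must be at t = 0")
  }
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    stop_invalid("onsets must be strictly increasing")
  }
  structure(
    list(onsets = as.double(onsets), rates = as.double(rates),
         n_events = length(onsets),
         deviant_shifted = as.logical(deviant_shifted)),
    class = "onset_schedule"
  )
}

#' @export
print.onset_schedule <- function(x, ...) {
  cat("Onset schedule:", x$n_events, "events,",
      sprintf("%.3f", total_duration(x)), "s span,",
      sprintf("rates %.3g-%.3g Hz\n", min(x$rates), max(x$rates)))
  invisible(x)
}

#' @export
as.data.frame.onset_schedule <- function(x, ...) {
  data.frame(event_index = seq_len(x$n_events) - 1L,
             onset_s = x$onsets, rate_hz = x$rates,
             is_deviant_shifted = x$deviant_shifted)
}

#' Total span of a schedule in seconds
#' @param schedule an [onset_schedule()].
#' @return Time of the last onset minus the first, in seconds.
#' @export
total_duration <- function(schedule) {
  stopifnot(inherits(schedule, "onset_schedule"))
  if (schedule$n_events < 2) return(0)
  schedule$onsets[schedule$n_events] - schedule$onsets[1]
}

#' Build an accelerating stimulus schedule
#'
#' Generates the onset times of a sequence whose presentation rate steps
#' upward by `rate_step` Hz every `tokens_per_step` tokens, covering the
#' inclusive rate grid from `rate_start` to `rate_end`. These slightly
#' accelerating sequences probe spontaneous auditory-motor synchronization:
#' the canonical fast sequence runs 4.3 to 4.7 Hz in 0.1 Hz steps and the
#' slow sequence 1.92 to 2.08 Hz in 0.04 Hz steps, each with 48 tokens per
#' plateau (240 tokens total).
#'
#' @param rate_start,rate_end first and last plateau rates in Hz.
#' @param rate_step plateau increment in Hz (ignored when
#'   `rate_start == rate_end`).
#' @param tokens_per_step number of tokens per rate plateau.
#' @return An [onset_schedule()] with
#'   `n_plateaus * tokens_per_step` events.
#' @examples
#' sched <- make_accelerating_schedule(1.92, 2.08, 0.04, 48)
#' sched$n_events           # 240
#' round(total_duration(sched) + 1 / 2.08)  # ~120 s including final IOI
#' @export
make_accelerating_schedule <- function(rate_start, rate_end, rate_step,
                                       tokens_per_step) {
  if (rate_start <= 0 || rate_end <= 0) stop_invalid("rates must be positive")
  if (rate_start > rate_end) stop_invalid("rate_start must not exceed rate_end")
  if (tokens_per_step < 1) stop_invalid("tokens_per_step must be >= 1")
  if (rate_start == rate_end) {
    grid <- rate_start
  } else {
    if (rate_step <= 0) stop_invalid("rate_step must be positive")
    n_steps <- (rate_end - rate_start) / rate_step
    if (abs(n_steps - round(n_steps)) > 1e-9) {
      stop_invalid("rate grid does not close on rate_end: ",
                   "(rate_end - rate_start) must be a multiple of rate_step")
    }
    grid <- rate_start + rate_step * (0:round(n_steps))
  }
  rates <- rep(grid, each = tokens_per_step)
  n <- length(rates)
  onsets <- c(0, cumsum(1 / rates[-n]))
  onset_schedule(onsets, rates)
}

#' Specify a single deviant-detection trial
#'
#' A perception trial is a short isochronous sequence of tokens at
#' `base_rate`; in deviant trials the final onset is advanced by
#' `shift_fraction` of the inter-onset interval, and the listener's task is
#' to detect that advance.
#'
#' @param base_rate presentation rate in Hz.
#' @param n_tokens number of tokens (>= 2; canonical 10).
#' @param is_deviant whether the final onset is advanced.
#' @param shift_fraction fraction of the IOI by which the final onset is
#'   advanced; must be 0 for standards and in (0, 1) for deviants.
#' @param stimulus_class `"syllable"` or `"tone"`.
#' @return A `perception_trial_spec` list.
#' @export
perception_trial_spec <- function(base_rate, n_tokens = 10,
                                  is_deviant = FALSE, shift_fraction = 0,
                                  stimulus_class = c("syllable", "tone")) {
  stimulus_class <- match.arg(stimulus_class)
  if (base_rate <= 0) stop_invalid("base_rate must be positive")
  if (n_tokens < 2) stop_invalid("n_tokens must be >= 2")
  if (shift_fraction < 0 || shift_fraction >= 1) {
    stop_invalid("shift_fraction must be in [0, 1)")
  }
  if (is_deviant != (shift_fraction > 0)) {
    stop_invalid("shift_fraction must be > 0 exactly when is_deviant")
  }
  structure(list(base_rate = base_rate, n_tokens = as.integer(n_tokens),
                 is_deviant = isTRUE(is_deviant),
                 shift_fraction = shift_fraction,
                 stimulus_class = stimulus_class),
            class = "perception_trial_spec")
}

#' Realize a perception trial as an onset schedule
#'
#' Onsets sit at `k / base_rate` for `k = 0 .. n_tokens - 1`; in deviant
#' trials the final onset is advanced by `shift_fraction / base_rate`.
#'
#' @param spec a [perception_trial_spec()].
#' @return An [onset_schedule()].
#' @export
make_perception_trial <- function(spec) {
  stopifnot(inherits(spec, "perception_trial_spec"))
  ioi <- 1 / spec$base_rate
  onsets <- (seq_len(spec$n_tokens) - 1) * ioi
  shifted <- rep(FALSE, spec$n_tokens)
  if (spec$is_deviant && spec$shift_fraction > 0) {
    onsets[spec$n_tokens] <- onsets[spec$n_tokens] - spec$shift_fraction * ioi
    shifted[spec$n_tokens] <- TRUE
  }
  onset_schedule(onsets, rep(spec$base_rate, spec$n_tokens), shifted)
}

#' Generate a balanced deviant-detection block
#'
#' Builds `n_trials` perception trials with exactly half deviant. Per-trial
#' base rates are drawn uniformly (with replacement) from the multiplicative
#' grid `rate_center * (1 + rate_grid_fraction * k)` for
#' `k = -(n_grid-1)/2 .. +(n_grid-1)/2`; deviant shift fractions are drawn
#' uniformly from `shift_range`. The canonical design presents 80 sequences
#' per stimulus class, rates varying by +/-2% steps around the center
#' (1.92-2.08 Hz around 2 Hz; 4.32-4.68 Hz around 4.5 Hz), with shifts of
#' 28-34% of the IOI for syllables and 12-18% for tones.
#'
#' @param stimulus_class `"syllable"` or `"tone"`.
#' @param n_trials even number of trials.
#' @param rate_center central rate in Hz.
#' @param rate_grid_fraction multiplicative step between adjacent grid rates.
#' @param n_grid odd number of grid rates.
#' @param shift_range length-2 numeric, `c(lo, hi)` shift fractions.
#' @param seed RNG seed; the block is fully reproducible from it.
#' @param n_tokens tokens per sequence.
#' @return A `perception_block`: list with a `trials` data frame
#'   (trial, stimulus_class, base_rate, n_tokens, is_deviant,
#'   shift_fraction), a `rate_label` (`"slow"` if `rate_center < 3` Hz,
#'   else `"fast"`), and the generating parameters.
#' @export
make_perception_block <- function(stimulus_class = c("syllable", "tone"),
                                  n_trials = 80, rate_center = 2,
                                  rate_grid_fraction = 0.02, n_grid = 5,
                                  shift_range = c(0.28, 0.34), seed = 1,
                                  n_tokens = 10) {
  stimulus_class <- match.arg(stimulus_class)
  if (n_trials %% 2 != 0) stop_invalid("n_trials must be even")
  if (n_grid < 1 || n_grid %% 2 == 0) stop_invalid("n_grid must be odd")
  lo <- shift_range[1]; hi <- shift_range[2]
  if (!(lo > 0 && lo <= hi && hi < 1)) {
    stop_invalid("shift_range must satisfy 0 < lo <= hi < 1")
  }
  k <- seq.int(-(n_grid - 1) / 2, (n_grid - 1) / 2)
  grid <- rate_center * (1 + rate_grid_fraction * k)
  trials <- with_rng_seed(seed, {
    is_dev <- sample(rep(c(TRUE, FALSE), n_trials / 2))
    rates <- grid[sample.int(length(grid), n_trials, replace = TRUE)]
    shifts <- ifelse(is_dev, runif(n_trials, lo, hi), 0)
    data.frame(trial = seq_len(n_trials), stimulus_class = stimulus_class,
               base_rate = rates, n_tokens = as.integer(n_tokens),
               is_deviant = is_dev, shift_fraction = shifts)
  })
  structure(list(trials = trials,
                 rate_label = if (rate_center < 3) "slow" else "fast",
                 stimulus_class = stimulus_class, rate_center = rate_center,
                 rate_grid_fraction = rate_grid_fraction, n_grid = n_grid,
                 shift_range = c(lo, hi), seed = seed),
            class = "perception_block")
}

#' @export
print.perception_block <- function(x, ...) {
  cat("Perception block:", nrow(x$trials), x$stimulus_class, "trials (",
      sum(x$trials$is_deviant), "deviant ) around",
      x$rate_center, "Hz [", x$rate_label, "], seed", x$seed, "\n")
  invisible(x)
}

#' Write/read a schedule as CSV
#'
#' Columns: `event_index`, `onset_s`, `rate_hz`, `is_deviant_shifted`.
#' @param schedule an [onset_schedule()].
#' @param path file path.
#' @return `read_schedule_csv` returns an [onset_schedule()].
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- read.csv(path)
  onset_schedule(df$onset_s, df$rate_hz, df$is_deviant_shifted)
}

#' Write/read a perception block as JSON (parameters + seed + trials)
#' @param block a `perception_block`.
#' @param path file path.
#' @return `read_block_json` returns a `perception_block`.
#' @export
write_block_json <- function(block, path) {
  jsonlite::write_json(unclass(block), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_block_json
#' @export
read_block_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$trials <- as.data.frame(x$trials)
  structure(x, class = "perception_block")
}

#' Render a schedule as an audible click train
#'
#' A listening-check utility: each onset becomes a short raised-cosine click
#' (or an amplitude-modulated tone burst). Not a substitute for the real
#' syllable/tone stimuli.
#'
#' @param schedule an [onset_schedule()].
#' @param fs output sample rate in Hz.
#' @param click_dur click duration in seconds.
#' @param tone_hz if non-`NULL`, fill each click with a sinusoidal carrier at
#'   this frequency instead of a wideband click.
#' @return list with `samples` (numeric in \[-1, 1\]) and `fs`.
#' @export
render_click_train <- function(schedule, fs = 44100, click_dur = 0.01,
                               tone_hz = NULL) {
  stopifnot(inherits(schedule, "onset_schedule"))
  dur <- total_duration(schedule) + 1 / schedule$rates[schedule$n_events]
  n <- ceiling(dur * fs)
  y <- numeric(n)
  k <- round(click_dur * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  carrier <- if (is.null(tone_hz)) rep(1, k) else
    sin(2 * pi * tone_hz * (seq_len(k) - 1) / fs)
  for (t0 in schedule$onsets) {
    i <- round(t0 * fs) + 1L
    idx <- i:min(i + k - 1L, n)
    y[idx] <- y[idx] + (win * carrier)[seq_along(idx)]
  }
  list(samples = pmax(pmin(y, 1), -1), fs = fs)
}
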