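#' Analysis run configuration
#'
#' Bundles every knob of the synchronization pipeline so a run is fully
#' described by (config, seed). The configuration is serializable to JSON
#' and hashed; every output table carries the hash that produced it.
#'
#' @param seed root RNG seed; all stage seeds are derived from it.
#' @param fs envelope sampling rate in Hz.
#' @param n_permutations permutation-baseline shuffles per trial.
#' @param n_trials_per_condition synchronization trials per condition.
#' @param bands list of [rate_band()] presets, named `fast` and `slow`.
#' @param osc_defaults list of [oscillator_params()] fields (other than
#'   `coupling`) used when rendering simulated participants.
#' @param stimulus_kernels list of [effector_kernel()] objects for the
#'   acoustic channel, named `syllable` and `tone`.
#' @param motor_kernels list of [effector_kernel()] objects for the motor
#'   channel, named `tap` and `whisper`.
#' @param fast_schedule,slow_schedule parameters
#'   `(rate_start, rate_end, rate_step, tokens_per_step)` of the two
#'   accelerating sequences.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1, fs = 100, n_permutations = 20,
                       n_trials_per_condition = 2,
                       bands = list(fast = band_preset("fast"),
                                    slow = band_preset("slow")),
                       osc_defaults = list(phase_noise_sd = 0.6,
                                           lag = 0.02, drift_sd = 0.005),
                       stimulus_kernels =
                         list(syllable = effector_kernel("syllable",
                                                         burst_fwhm = 0.10),
                              tone = effector_kernel("tone",
                                                     burst_fwhm = 0.04)),
                       motor_kernels =
                         list(tap = effector_kernel("tap"),
                              whisper = effector_kernel("whisper")),
                       fast_schedule = c(4.3, 4.7, 0.1, 48),
                       slow_schedule = c(1.92, 2.08, 0.04, 48)) {
  cfg <- structure(list(seed = seed, fs = fs,
                        n_permutations = n_permutations,
                        n_trials_per_condition = n_trials_per_condition,
                        bands = bands, osc_defaults = osc_defaults,
                        stimulus_kernels = stimulus_kernels,
                        motor_kernels = motor_kernels,
                        fast_schedule = fast_schedule,
                        slow_schedule = slow_schedule),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Hash a configuration
#'
#' MD5 of the canonical JSON serialization (hash field excluded), so that
#' any change to an analysis parameter changes the recorded provenance.
#'
#' @param config a `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

provenance <- function(config) {
  list(package_version = as.character(packageVersion("plvsync")),
       config_hash = config$hash, seed = config$seed)
}

# Schedule for one rate condition under a config.
condition_schedule <- function(config, rate) {
  p <- if (rate == "fast") config$fast_schedule else config$slow_schedule
  make_accelerating_schedule(p[1], p[2], p[3], p[4])
}

#' Analyze one synchronization trial
#'
#' The per-trial pipeline: band-pass filter and phase-extract both
#' envelopes, compute the windowed PLV, and baseline it against the
#' segment-shuffling permutation distribution.
#'
#' @param env_acoustic,env_motor [envelope_signal()] objects.
#' @param band a [rate_band()].
#' @param n_permutations shuffles for the baseline.
#' @param seed RNG seed for the shuffles.
#' @return A `plv_estimate` (see [permutation_baseline()]) with spectral
#'   peak features of both envelopes attached as `acoustic_features` /
#'   `motor_features` attributes (NULL when no peak is found).
#' @export
analyze_trial <- function(env_acoustic, env_motor, band,
                          n_permutations = 20, seed = 1) {
  est <- permutation_baseline(env_acoustic, env_motor, band,
                              n_permutations = n_permutations, seed = seed)
  attr(est, "acoustic_features") <- tryCatch(spectral_peak(env_acoustic),
                                             error = function(e) NULL)
  attr(est, "motor_features") <- tryCatch(spectral_peak(env_motor),
                                          error = function(e) NULL)
  est
}

feature_cols <- function(feat, prefix) {
  if (is.null(feat)) {
    out <- data.frame(NA_real_, NA_real_, NA_real_)
  } else {
    out <- data.frame(feat$peak_freq, feat$peak_amp, feat$peak_width)
  }
  names(out) <- paste0(prefix, c("_peak_freq_hz", "_peak_amp",
                                 "_peak_width_hz"))
  out
}

#' Run the full synchronization analysis on a synthetic study
#'
#' Simulates a latent-component participant population, renders every
#' synchronization trial (stimulus envelope + coupled motor response),
#' runs the per-trial PLV pipeline, averages trials into per-condition
#' scores, and performs the component analysis. All randomness derives
#' from `config$seed` via a documented per-stage splitting scheme.
#'
#' @param config a [run_config()].
#' @param model a [population_model()]; its own seed is overridden by the
#'   config's population-stage seed so one root seed regenerates the study.
#' @param pca whether to run [pca_varimax()] on the condition table.
#' @return list with `trials` (long per-trial data frame incl. envelope
#'   features), `conditions` (participant x condition normalized PLVs,
#'   long), `condition_matrix` (wide, participants x 8), `pca`
#'   (`component_solution` or NULL), `couplings` (ground truth), and
#'   `provenance`.
#' @export
run_synchronization_analysis <- function(config = run_config(),
                                         model = population_model(20),
                                         pca = TRUE) {
  stopifnot(inherits(config, "run_config"),
            inherits(model, "population_model"))
  model$seed <- derive_seed(config$seed, 1)
  pop <- simulate_population(model)
  grid <- model$conditions
  schedules <- list(fast = condition_schedule(config, "fast"),
                    slow = condition_schedule(config, "slow"))
  trial_rows <- vector("list", model$n_participants * nrow(grid) *
                         config$n_trials_per_condition)
  k <- 0L
  for (i in seq_len(model$n_participants)) {
    for (j in seq_len(nrow(grid))) {
      cond <- grid[j, ]
      sched <- schedules[[cond$rate]]
      stim_kernel <- config$stimulus_kernels[[cond$stimulus]]
      motor_kernel <- config$motor_kernels[[cond$effector]]
      band <- config$bands[[cond$rate]]
      params <- oscillator_params(
        coupling = pop$couplings[i, cond$condition],
        phase_noise_sd = config$osc_defaults$phase_noise_sd,
        lag = config$osc_defaults$lag,
        drift_sd = config$osc_defaults$drift_sd)
      env_ac <- render_stimulus_envelope(sched, stim_kernel, config$fs)
      for (trial in seq_len(config$n_trials_per_condition)) {
        trial_seed <- derive_seed(config$seed,
                                  100 + ((i - 1) * nrow(grid) + j) * 10 +
                                    trial)
        env_mo <- simulate_motor_response(sched, params, motor_kernel,
                                          config$fs, seed = trial_seed)
        est <- analyze_trial(env_ac, env_mo, band,
                             n_permutations = config$n_permutations,
                             seed = trial_seed + 1)
        k <- k + 1L
        trial_rows[[k]] <- cbind(
          plv_estimate_row(est, paste0("P", sprintf("%03d", i)),
                           cond$effector, cond$stimulus, cond$rate, trial),
          feature_cols(attr(est, "acoustic_features"), "acoustic"),
          feature_cols(attr(est, "motor_features"), "motor"))
      }
    }
  }
  trials <- do.call(rbind, trial_rows[seq_len(k)])
  conditions <- aggregate(normalized_plv ~ participant + effector +
                            stimulus + rate, trials, FUN = mean)
  names(conditions)[names(conditions) == "normalized_plv"] <- "plv"
  conditions$condition <- paste(conditions$effector, conditions$stimulus,
                                conditions$rate, sep = "_")
  wide <- matrix(NA_real_, model$n_participants, nrow(grid),
                 dimnames = list(sort(unique(conditions$participant)),
                                 grid$condition))
  for (r in seq_len(nrow(conditions))) {
    wide[conditions$participant[r], conditions$condition[r]] <-
      conditions$plv[r]
  }
  sol <- if (pca) pca_varimax(wide) else NULL
  list(trials = trials, conditions = conditions, condition_matrix = wide,
       pca = sol, couplings = pop$couplings,
       latent_scores = pop$latent_scores, provenance = provenance(config))
}

#' Run the synchronization analysis on recorded envelope files
#'
#' File-driven variant of [run_synchronization_analysis()]: each row of
#' `input_table` names one trial's acoustic and motor inputs, either
#' envelope CSVs (see [write_envelope_csv()]) or WAV files (which are run
#' through [extract_envelope()]).
#'
#' @param input_table data frame with columns `participant`, `effector`,
#'   `stimulus`, `rate` (`"fast"`/`"slow"`), `trial`, `acoustic_path`,
#'   `motor_path`.
#' @param config a [run_config()].
#' @return list with `trials`, `conditions`, `errors` (per-file failures,
#'   isolated so the run continues), and `provenance`.
#' @export
analyze_sync_files <- function(input_table, config = run_config()) {
  need <- c("participant", "effector", "stimulus", "rate", "trial",
            "acoustic_path", "motor_path")
  if (!all(need %in% names(input_table))) {
    stop_invalid("input_table must have columns ",
                 paste(need, collapse = ", "))
  }
  load_env <- function(path, label) {
    if (grepl("\\.wav$", path, ignore.case = TRUE)) {
      w <- read_wav(path)
      extract_envelope(w$samples, w$fs, target_fs = config$fs,
                       channel_label = label)
    } else {
      env <- read_envelope_csv(path)
      env$channel_label <- label
      env
    }
  }
  rows <- list(); errors <- list()
  for (r in seq_len(nrow(input_table))) {
    row <- input_table[r, ]
    res <- tryCatch({
      env_ac <- load_env(row$acoustic_path, "acoustic")
      env_mo <- load_env(row$motor_path, "motor")
      band <- config$bands[[row$rate]]
      est <- analyze_trial(env_ac, env_mo, band,
                           n_permutations = config$n_permutations,
                           seed = derive_seed(config$seed, 500 + r))
      cbind(plv_estimate_row(est, row$participant, row$effector,
                             row$stimulus, row$rate, row$trial),
            feature_cols(attr(est, "acoustic_features"), "acoustic"),
            feature_cols(attr(est, "motor_features"), "motor"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = r, participant = row$participant,
                   message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  trials <- if (length(rows)) do.call(rbind, rows) else NULL
  conditions <- if (!is.null(trials)) {
    ag <- aggregate(normalized_plv ~ participant + effector + stimulus +
                      rate, trials, FUN = mean)
    names(ag)[names(ag) == "normalized_plv"] <- "plv"
    ag
  } else NULL
  list(trials = trials, conditions = conditions,
       errors = if (length(errors)) do.call(rbind, errors) else NULL,
       provenance = provenance(config))
}

#' Run the perception-task analysis on a synthetic cohort
#'
#' Generates balanced deviant-detection blocks (two stimulus classes at
#' two rates) for each participant, simulates responses from the
#' psychometric model, tabulates accuracy per participant x stimulus x
#' rate, and applies the chance-level exclusion screen.
#'
#' @param n_participants cohort size.
#' @param model a [psychometric_model()]; may also be a named list of one
#'   model per participant for heterogeneous cohorts.
#' @param n_trials_per_block trials per stimulus x rate block (the
#'   canonical design presents 80 sequences per stimulus class, i.e. 40
#'   per rate).
#' @param seed root seed.
#' @return list with `responses` (per-trial long table), `accuracy`
#'   (participant x stimulus x rate), `chance_report`, `provenance`.
#' @export
run_perception_analysis <- function(n_participants = 20,
                                    model = psychometric_model(),
                                    n_trials_per_block = 40, seed = 1) {
  cells <- expand.grid(stimulus = c("syllable", "tone"),
                       rate = c("slow", "fast"), stringsAsFactors = FALSE)
  all_resp <- list()
  for (i in seq_len(n_participants)) {
    pmod <- if (inherits(model, "psychometric_model")) model else
      model[[i]]
    for (cl in seq_len(nrow(cells))) {
      st <- cells$stimulus[cl]; rt <- cells$rate[cl]
      block <- make_perception_block(
        stimulus_class = st, n_trials = n_trials_per_block,
        rate_center = if (rt == "slow") 2 else 4.5,
        shift_range = if (st == "syllable") c(0.28, 0.34) else
          c(0.12, 0.18),
        seed = derive_seed(seed, 2000 + i * 10 + cl))
      resp <- simulate_perception_responses(
        block, pmod, seed = derive_seed(seed, 3000 + i * 10 + cl))
      resp$participant <- paste0("P", sprintf("%03d", i))
      all_resp[[length(all_resp) + 1L]] <- resp
    }
  }
  responses <- do.call(rbind, all_resp)
  report <- chance_screen(responses)
  list(responses = responses, accuracy = report$accuracy,
       chance_report = report,
       provenance = list(package_version =
                           as.character(packageVersion("plvsync")),
                         seed = seed))
}

#' Write a result table with provenance sidecar
#'
#' Writes `table` to `path` as CSV and a `<path>.json` sidecar carrying
#' the package version, config hash and seed, so every artifact records
#' what produced it.
#'
#' @param table data frame.
#' @param path CSV path.
#' @param prov provenance list (e.g. the `provenance` element of a run).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(table, path, prov) {
  write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
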