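#' Trial-consistency participant screen
#'
#' For each condition, fits an ordinary least-squares regression predicting
#' each participant's second-trial score from their first-trial score, and
#' flags participants whose second-trial score falls outside the
#' `level`-probability interval at their first-trial value. The default
#' interval is the prediction interval for a new observation (a
#' mean-response confidence band narrows with sample size and would flag
#' nearly everyone at large n); the mean-response band is available via
#' `interval = "confidence"`.
#'
#' @param data data frame with columns `participant`, `condition`,
#'   `trial1`, `trial2` (one row per participant x condition).
#' @param level interval probability (default 0.99).
#' @param interval `"prediction"` (default) or `"confidence"`.
#' @return A `consistency_report`: `fits` (per-condition slope/intercept/
#'   residual SD), `flagged` (data frame of participant, condition,
#'   trial1, trial2, lower, upper), `flagged_participants`,
#'   `interval_level`, `interval_type`.
#' @export
consistency_screen <- function(data, level = 0.99,
                               interval = c("prediction", "confidence")) {
  interval <- match.arg(interval)
  need <- c("participant", "condition", "trial1", "trial2")
  if (!all(need %in% names(data))) {
    stop_invalid("data must have columns ", paste(need, collapse = ", "))
  }
  fits <- list()
  flagged <- data.frame()
  for (cond in unique(data$condition)) {
    d <- data[data$condition == cond, , drop = FALSE]
    if (nrow(d) < 3) stop_invalid("need >= 3 participants per condition")
    if (sd(d$trial1) < .Machine$double.eps^0.5) {
      warning("condition '", cond,
              "' skipped: no variance in first-trial scores")
      next
    }
    fit <- lm(trial2 ~ trial1, data = d)
    pr <- predict(fit, newdata = d, interval = interval, level = level)
    out <- d$trial2 < pr[, "lwr"] | d$trial2 > pr[, "upr"]
    fits[[as.character(cond)]] <- list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      sigma = summary(fit)$sigma, n = nrow(d))
    if (any(out)) {
      flagged <- rbind(flagged, data.frame(
        participant = d$participant[out], condition = cond,
        trial1 = d$trial1[out], trial2 = d$trial2[out],
        lower = pr[out, "lwr"], upper = pr[out, "upr"]))
    }
  }
  structure(list(fits = fits, flagged = flagged,
                 flagged_participants = unique(flagged$participant),
                 interval_level = level, interval_type = interval),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency screen (%g%% %s interval): %d flagged\n",
              100 * x$interval_level, x$interval_type,
              length(x$flagged_participants)))
  if (length(x$flagged_participants)) {
    print(x$flagged, row.names = FALSE)
  }
  invisible(x)
}

#' Chance-level performance screen
#'
#' Computes per-participant accuracy in every stimulus x rate cell of the
#' deviant-detection task and excludes participants whose accuracy is at or
#' below chance (0.5 for the two-alternative task) in at least one cell.
#' Participants missing any cell are reported separately as incomplete, not
#' excluded.
#'
#' @param responses data frame with columns `participant`, `stimulus`,
#'   `rate`, `correct` (logical or 0/1), one row per trial.
#' @param chance chance accuracy (default 0.5).
#' @return A `chance_report`: `accuracy` (participant x stimulus x rate
#'   table as a long data frame with `n_trials`), `excluded`, `incomplete`,
#'   `chance_level`.
#' @export
chance_screen <- function(responses, chance = 0.5) {
  need <- c("participant", "stimulus", "rate", "correct")
  if (!all(need %in% names(responses))) {
    stop_invalid("responses must have columns ", paste(need, collapse = ", "))
  }
  acc <- aggregate(correct ~ participant + stimulus + rate, responses,
                   FUN = mean)
  names(acc)[names(acc) == "correct"] <- "accuracy"
  ntr <- aggregate(correct ~ participant + stimulus + rate, responses,
                   FUN = length)
  acc$n_trials <- ntr$correct
  cells <- unique(responses[, c("stimulus", "rate")])
  participants <- unique(responses$participant)
  incomplete <- participants[vapply(participants, function(p) {
    sum(acc$participant == p) < nrow(cells)
  }, logical(1))]
  at_or_below <- acc$participant[acc$accuracy <= chance]
  excluded <- setdiff(unique(at_or_below), incomplete)
  structure(list(accuracy = acc, excluded = excluded,
                 incomplete = incomplete, chance_level = chance),
            class = "chance_report")
}

#' @export
print.chance_report <- function(x, ...) {
  cat(sprintf("Chance screen (chance = %g): %d excluded, %d incomplete\n",
              x$chance_level, length(x$excluded), length(x$incomplete)))
  if (length(x$excluded)) cat("  excluded:", toString(x$excluded), "\n")
  if (length(x$incomplete)) cat("  incomplete:", toString(x$incomplete), "\n")
  invisible(x)
}

#' Serialize QC reports to JSON
#' @param report a `consistency_report` or `chance_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
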