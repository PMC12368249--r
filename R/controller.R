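#' Closed-loop trigger rule
#'
#' Decision parameters of the organoid-to-robot interface: an avoidance
#' command is issued when the mean firing rate over the active electrodes
#' (at least `min_active_electrodes` of them) rises by at least
#' `min_fold_increase` over its baseline. Rates are re-evaluated every
#' `evaluation_window` seconds and the condition must hold on
#' `confirm_windows` consecutive evaluations before a command is emitted
#' (debouncing: with 16 electrodes and 1-s windows a single-window rate
#' estimate has ~25% coefficient of variation).
#'
#' @param spike_threshold_sd spike-detection threshold for the control path,
#'   in noise SDs (default 3; the offline analysis path uses 5.5).
#' @param min_active_electrodes minimum active electrodes (default 8,
#'   i.e. >= 50% of a 16-electrode well).
#' @param min_fold_increase minimum rate fold increase over baseline
#'   (default 2).
#' @param baseline_window trailing pre-stimulation window for baseline
#'   estimation, seconds (default 60).
#' @param evaluation_window trigger evaluation cadence and rate window,
#'   seconds (default 1, matching 1-Hz stimulation).
#' @param confirm_windows consecutive supra-threshold evaluations required
#'   (default 2).
#' @param active_min_rate spikes/min defining an active electrode in the
#'   baseline epoch (default 5).
#' @return an object of class `trigger_rule`.
#' @export
trigger_rule <- function(spike_threshold_sd = 3, min_active_electrodes = 8,
                         min_fold_increase = 2, baseline_window = 60,
                         evaluation_window = 1, confirm_windows = 2,
                         active_min_rate = 5) {
  vals <- c(spike_threshold_sd, min_active_electrodes, min_fold_increase,
            baseline_window, evaluation_window, confirm_windows)
  if (any(vals <= 0)) stop_param("all trigger-rule parameters must be positive")
  structure(
    list(spike_threshold_sd = spike_threshold_sd,
         min_active_electrodes = min_active_electrodes,
         min_fold_increase = min_fold_increase,
         baseline_window = baseline_window,
         evaluation_window = evaluation_window,
         confirm_windows = confirm_windows,
         active_min_rate = active_min_rate),
    class = "trigger_rule")
}

#' Baseline firing rates from the pre-stimulation epoch
#'
#' Per-electrode mean firing rate over the trailing `window` seconds before
#' `t_ref` (typically the first stimulation pulse); the well baseline is the
#' mean over electrodes classified active in that epoch (>= 5 spikes/min by
#' default).
#'
#' @param trains a [spike_train_set()].
#' @param window baseline window in seconds (>= 5 s of pre-stimulation data
#'   must be available).
#' @param t_ref end of the baseline epoch, seconds (defaults to the
#'   recording end).
#' @param active_min_rate spikes/min rule for the active set.
#' @return list with `rates` (named per-electrode Hz), `active` (electrode
#'   ids), `well_rate` (mean over active electrodes, 0 if none),
#'   `window` (the `c(start, end)` used).
#' @export
estimate_baseline <- function(trains, window = 60, t_ref = NULL,
                              active_min_rate = 5) {
  if (is.null(t_ref)) t_ref <- trains$duration
  t0 <- max(0, t_ref - window)
  if (t_ref - t0 < 5) stop_param("need >= 5 s of pre-stimulation data")
  w <- t_ref - t0
  rates <- vapply(trains$trains, function(t) sum(t >= t0 & t < t_ref) / w,
                  numeric(1))
  active <- names(rates)[rates >= active_min_rate / 60]
  list(rates = rates, active = active,
       well_rate = if (length(active)) mean(rates[active]) else 0,
       window = c(t0, t_ref))
}

#' Evaluate the avoidance trigger
#'
#' True iff at least `min_active_electrodes` electrodes are active (by their
#' baseline rate) and the mean current rate over that active set is at least
#' `min_fold_increase` times its mean baseline rate. A zero baseline
#' disables the trigger (returns `FALSE` with a warning).
#'
#' @param current_rates named per-electrode rates in the current window (Hz).
#' @param baseline named per-electrode baseline rates (Hz); electrode sets
#'   must match.
#' @param rule a [trigger_rule()].
#' @param warn warn on a zero baseline (default TRUE).
#' @return logical; attributes `n_active`, `mean_current`, `mean_baseline`,
#'   `fold`.
#' @export
evaluate_trigger <- function(current_rates, baseline, rule, warn = TRUE) {
  if (!setequal(names(current_rates), names(baseline)))
    stop_param("electrode sets of current and baseline rates must match")
  baseline <- baseline[names(current_rates)]
  active <- names(baseline)[baseline >= rule$active_min_rate / 60]
  n_active <- length(active)
  mb <- if (n_active) mean(baseline[active]) else 0
  mc <- if (n_active) mean(current_rates[active]) else 0
  if (mb <= 0) {
    if (warn) warning("zero baseline rate: trigger disabled")
    out <- FALSE
    fold <- NA_real_
  } else {
    fold <- mc / mb
    out <- n_active >= rule$min_active_electrodes &&
      fold >= rule$min_fold_increase
  }
  structure(out, n_active = n_active, mean_current = mc,
            mean_baseline = mb, fold = fold)
}

#' Run the closed-loop controller over a recording
#'
#' Streams the spike trains through the trigger state machine. Baseline
#' rates are estimated from the trailing pre-stimulation window; the trigger
#' is then evaluated on every `evaluation_window` boundary. The state starts
#' FORWARD; after `confirm_windows` consecutive positive evaluations it
#' switches to AVOID and emits one avoidance command for the episode; after
#' the stimulation ends and a full evaluation window passes with the trigger
#' false, it returns to FORWARD and emits a resume command.
#'
#' @param trains a [spike_train_set()] (e.g. from [detect_spikes_all()] at
#'   the rule's 3-SD threshold).
#' @param stim a [stim_schedule()].
#' @param rule a [trigger_rule()].
#' @return an object of class `controller_log`: data frame `log` (time,
#'   state, mfr_baseline, mfr_current, n_active, trigger, command), plus
#'   `baseline`, `commands` (data frame time/command), `rule`.
#' @export
run_controller <- function(trains, stim, rule = trigger_rule()) {
  if (!inherits(rule, "trigger_rule")) stop_param("`rule` must be a trigger_rule")
  if (!length(stim$pulse_times)) stop_param("stimulation schedule is empty")
  stim_start <- stim$pulse_times[1L]
  stim_end <- stim$pulse_times[length(stim$pulse_times)] + stim$pulse_width
  bl <- estimate_baseline(trains, rule$baseline_window, t_ref = stim_start,
                          active_min_rate = rule$active_min_rate)
  W <- rule$evaluation_window
  n_eval <- floor(trains$duration / W)
  zero_baseline <- bl$well_rate <= 0
  if (zero_baseline)
    warning("silent well: zero baseline rate, trigger permanently disabled")

  state <- "FORWARD"
  streak <- 0L
  avoided_this_episode <- FALSE
  log <- vector("list", n_eval)
  commands <- list()
  for (k in seq_len(n_eval)) {
    t1 <- k * W; t0 <- t1 - W
    cur <- vapply(trains$trains, function(t) sum(t >= t0 & t < t1) / W,
                  numeric(1))
    trig <- evaluate_trigger(cur, bl$rates, rule, warn = FALSE)
    cmd <- NA_character_
    if (isTRUE(as.logical(trig))) streak <- streak + 1L else streak <- 0L
    if (state == "FORWARD" && streak >= rule$confirm_windows &&
        !avoided_this_episode) {
      state <- "AVOID"
      avoided_this_episode <- TRUE
      cmd <- "AVOID"
      commands[[length(commands) + 1L]] <- data.frame(time = t1, command = cmd)
    } else if (state == "AVOID" && t0 >= stim_end &&
               !isTRUE(as.logical(trig))) {
      state <- "FORWARD"
      cmd <- "RESUME"
      commands[[length(commands) + 1L]] <- data.frame(time = t1, command = cmd)
    }
    log[[k]] <- data.frame(
      time = t1, state = state,
      mfr_baseline = bl$well_rate,
      mfr_current = attr(trig, "mean_current"),
      n_active = attr(trig, "n_active"),
      trigger = as.logical(trig),
      command = cmd)
  }
  structure(
    list(log = do.call(rbind, log), baseline = bl,
         commands = if (length(commands)) do.call(rbind, commands)
                    else data.frame(time = numeric(0), command = character(0)),
         rule = rule),
    class = "controller_log")
}

#' @export
print.controller_log <- function(x, ...) {
  n_avoid <- sum(x$commands$command == "AVOID")
  cat(sprintf("<controller_log> %d evaluations, %d avoidance command(s), baseline %.2f Hz\n",
              nrow(x$log), n_avoid, x$baseline$well_rate))
  invisible(x)
}
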