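#' Spike-train set container
#'
#' @param trains named list mapping electrode id to an ascending numeric
#'   vector of spike times (seconds).
#' @param duration recording duration in seconds; all times must lie in
#'   `[0, duration)`.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration) {
  check_scalar_pos(duration, "duration")
  if (is.null(names(trains)) && length(trains) > 0L)
    names(trains) <- paste0("E", seq_along(trains))
  trains <- lapply(trains, function(t) sort(as.numeric(t)))
  bad <- vapply(trains, function(t) length(t) && (min(t) < 0 || max(t) >= duration),
                logical(1))
  if (any(bad)) stop_param("spike times must lie in [0, duration)")
  structure(list(trains = trains, duration = duration), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d electrodes over %.3g s, %d spikes total\n",
              length(x$trains), x$duration, sum(lengths(x$trains))))
  invisible(x)
}

#' Multichannel extracellular recording container
#'
#' @param raw channels x samples numeric matrix in microvolts, or `NULL` when
#'   only ground-truth spike times are carried.
#' @param fs sampling rate in Hz.
#' @param stim_times stimulation pulse onsets in seconds.
#' @param layout data frame with columns `electrode`, `row`, `col`.
#' @param duration duration in seconds (required when `raw` is `NULL`).
#' @return an object of class `mea_recording`.
#' @export
mea_recording <- function(raw, fs, stim_times = numeric(0), layout = NULL,
                          duration = NULL) {
  check_scalar_pos(fs, "fs")
  if (is.null(raw)) {
    if (is.null(duration)) stop_param("`duration` required when `raw` is NULL")
  } else {
    if (!is.matrix(raw)) stop_param("`raw` must be a channels x samples matrix")
    duration <- ncol(raw) / fs
  }
  stim_times <- as.numeric(stim_times)
  if (length(stim_times) > 1L && any(diff(stim_times) <= 0))
    stop_param("`stim_times` must be ascending")
  if (length(stim_times) && (min(stim_times) < 0 || max(stim_times) >= duration))
    stop_param("`stim_times` must lie within the recording")
  if (is.null(layout) && !is.null(raw))
    layout <- default_layout(nrow(raw))
  structure(
    list(raw = raw, fs = fs, stim_times = stim_times, layout = layout,
         duration = duration),
    class = "mea_recording")
}

default_layout <- function(n) {
  side <- ceiling(sqrt(n))
  data.frame(electrode = paste0("E", seq_len(n)),
             row = (seq_len(n) - 1L) %/% side + 1L,
             col = (seq_len(n) - 1L) %% side + 1L)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %s channels @ %.4g kHz, %.3g s, %d stim pulses\n",
              if (is.null(x$raw)) "?" else nrow(x$raw), x$fs / 1000, x$duration,
              length(x$stim_times)))
  invisible(x)
}

#' Biphasic extracellular spike template
#'
#' Negative-then-positive waveform, `-A * sin(2 * pi * t / width)` with the
#' positive lobe scaled to 40% of the negative one (typical extracellular
#' asymmetry); peak (negative) amplitude `A`.
#'
#' @param fs sampling rate (Hz).
#' @param amplitude_uv peak negative amplitude in microvolts.
#' @param width_ms total template width in milliseconds.
#' @return numeric vector of template samples.
#' @export
spike_template <- function(fs, amplitude_uv = 50, width_ms = 1) {
  width <- width_ms / 1000
  t <- seq(0, width, by = 1 / fs)
  s <- sin(2 * pi * t / width)
  s[s < 0] <- 0.4 * s[s < 0]
  -amplitude_uv * s
}

#' Simulate a multichannel MEA recording with light-evoked rate elevation
#'
#' Ground-truth spikes are drawn from an inhomogeneous Poisson process: the
#' rate is `baseline_rate` except inside evoked windows on responding
#' electrodes, where it is `evoked_multiplier * baseline_rate`. The evoked
#' window for each pulse starts a jittered latency after pulse onset and spans
#' the pulse plus `response_span` seconds of after-discharge. An absolute
#' refractory period is enforced per electrode. Traces are i.i.d. Gaussian
#' noise plus a biphasic template summed at the spike times.
#'
#' @param n_electrodes number of electrodes.
#' @param fs sampling rate in Hz (>= 10 kHz when traces are rendered).
#' @param duration recording duration in seconds.
#' @param baseline_rate spontaneous firing rate per electrode (Hz).
#' @param evoked_multiplier rate multiplier inside evoked windows (>= 0).
#' @param evoked_latency numeric `c(mean, jitter)` in seconds: response onset
#'   latency is uniform on `mean +/- jitter`, drawn per electrode and pulse.
#' @param stim a [stim_schedule()] (or `NULL` for spontaneous activity only).
#' @param waveform numeric `c(amplitude_uv, width_ms)` for [spike_template()].
#' @param noise_sd trace noise SD in microvolts.
#' @param responding_electrodes indices of electrodes whose rate is modulated.
#' @param seed integer seed.
#' @param response_span after-discharge span in seconds appended to each
#'   evoked window (default 0.9 s: post-pulse network reverberation keeps the
#'   population rate elevated between 1-Hz pulses, as organoid responses do,
#'   so a 3-fold rate multiplier realises a ~2.8-fold elevation per cycle).
#' @param refractory absolute refractory period between ground-truth spikes on
#'   one electrode (seconds).
#' @param render if `FALSE`, skip rendering raw traces (ground truth only);
#'   useful for long-duration rate statistics.
#' @return list with `recording` (an [mea_recording()]) and `ground_truth`:
#'   `spike_times` (per-electrode list), `unit_labels`, `burst_intervals`,
#'   `evoked_windows` (per-electrode merged start/end matrices).
#' @export
simulate_mea_recording <- function(n_electrodes = 16L, fs = 20000, duration = 60,
                                   baseline_rate = 1,
                                   evoked_multiplier = 3,
                                   evoked_latency = c(mean = 0.0125, jitter = 0.0075),
                                   stim = NULL,
                                   waveform = c(amplitude_uv = 50, width_ms = 1),
                                   noise_sd = 5,
                                   responding_electrodes = seq_len(n_electrodes),
                                   seed = 1L,
                                   response_span = 0.9,
                                   refractory = 0.0025,
                                   render = TRUE) {
  if (evoked_multiplier < 0) stop_param("`evoked_multiplier` must be >= 0")
  if (baseline_rate < 0) stop_param("`baseline_rate` must be >= 0")
  if (render && fs < 10000) stop_param("`fs` must be >= 10 kHz to resolve spike waveforms")
  if (render && noise_sd > 0 && waveform[[1L]] / noise_sd <= 6)
    stop_param("waveform amplitude / noise_sd must exceed 6 for reliable detection")
  lat_mean <- evoked_latency[[1L]]; lat_jit <- evoked_latency[[2L]]
  pulse_times <- if (is.null(stim)) numeric(0) else stim$pulse_times
  pulse_width <- if (is.null(stim)) 0 else stim$pulse_width

  set.seed(derive_seed(seed, "mea-spikes"))
  rmax <- baseline_rate * max(1, evoked_multiplier)
  spikes <- vector("list", n_electrodes)
  windows <- vector("list", n_electrodes)
  for (e in seq_len(n_electrodes)) {
    responds <- e %in% responding_electrodes && length(pulse_times) > 0 &&
      evoked_multiplier != 1
    if (responds) {
      lat <- stats::runif(length(pulse_times),
                          max(0, lat_mean - lat_jit), lat_mean + lat_jit)
      iv <- cbind(pulse_times + lat,
                  pulse_times + lat + pulse_width + response_span)
      windows[[e]] <- merge_intervals(iv)
    } else {
      windows[[e]] <- matrix(numeric(0), ncol = 2L)
    }
    if (rmax == 0) { spikes[[e]] <- numeric(0); next }
    n_cand <- stats::rpois(1L, rmax * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    rate <- rep(baseline_rate, length(cand))
    if (nrow(windows[[e]]) > 0 && length(cand)) {
      inwin <- findInterval(cand, as.vector(t(windows[[e]]))) %% 2L == 1L
      rate[inwin] <- baseline_rate * evoked_multiplier
    }
    keep <- stats::runif(length(cand)) < rate / rmax
    st <- cand[keep]
    # absolute refractory period
    if (length(st) > 1L) {
      ok <- logical(length(st)); ok[1L] <- TRUE; last <- st[1L]
      for (i in 2:length(st)) {
        if (st[i] - last >= refractory) { ok[i] <- TRUE; last <- st[i] }
      }
      st <- st[ok]
    }
    spikes[[e]] <- st
  }
  names(spikes) <- paste0("E", seq_len(n_electrodes))

  raw <- NULL
  if (render) {
    n_samp <- round(duration * fs)
    tmpl <- spike_template(fs, waveform[[1L]], waveform[[2L]])
    L <- length(tmpl)
    raw <- matrix(stats::rnorm(n_electrodes * n_samp, sd = noise_sd),
                  nrow = n_electrodes)
    for (e in seq_len(n_electrodes)) {
      for (s in spikes[[e]]) {
        i0 <- round(s * fs) + 1L
        i1 <- min(n_samp, i0 + L - 1L)
        if (i0 <= n_samp)
          raw[e, i0:i1] <- raw[e, i0:i1] + tmpl[seq_len(i1 - i0 + 1L)]
      }
    }
  }

  list(
    recording = mea_recording(raw, fs, pulse_times,
                              layout = default_layout(n_electrodes),
                              duration = duration),
    ground_truth = list(
      spike_times = spikes,
      unit_labels = lapply(spikes, function(s) rep(1L, length(s))),
      burst_intervals = rep(list(matrix(numeric(0), ncol = 2L)), n_electrodes),
      evoked_windows = windows))
}
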