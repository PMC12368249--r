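#' Lag times between stimulation pulses and the first following peak
#'
#' For every stimulation time, the lag is the time from the pulse to the
#' first peak (spike or supra-threshold signal peak) strictly after it and
#' before the next pulse; `NA` when no peak occurs in that interval. Peaks
#' preceding the first stimulation are never assigned.
#'
#' @param signal_peaks ascending peak times, seconds.
#' @param stim_times ascending stimulation times, seconds.
#' @return data frame with columns `stim_time`, `lag` (seconds or `NA`).
#' @export
lag_times <- function(signal_peaks, stim_times) {
  signal_peaks <- sort(as.numeric(signal_peaks))
  stim_times <- sort(as.numeric(stim_times))
  nxt <- c(stim_times[-1L], Inf)
  lag <- vapply(seq_along(stim_times), function(i) {
    p <- signal_peaks[signal_peaks > stim_times[i] & signal_peaks < nxt[i]]
    if (length(p)) p[1L] - stim_times[i] else NA_real_
  }, numeric(1))
  data.frame(stim_time = stim_times, lag = lag)
}

#' Mean-firing-rate metrics around a stimulation epoch
#'
#' Per-electrode mean firing rates in named before / during / after windows,
#' the during/before fold change, and rates normalised to the before-window
#' rate. Fold changes are `NA` where the before-window rate is zero.
#'
#' @param trains a [spike_train_set()].
#' @param windows named list with elements `before`, `during`, `after`, each
#'   a half-open interval `c(start, end)` in seconds; windows must be
#'   disjoint and at least 1 s wide.
#' @return an object of class `mfr_report`: data frame `rates` (electrode,
#'   rate_before, rate_during, rate_after, fold_change, norm_before,
#'   norm_during, norm_after) and the `windows` used.
#' @export
mfr_metrics <- function(trains, windows) {
  need <- c("before", "during", "after")
  if (!all(need %in% names(windows))) stop_param("windows must be named before/during/after")
  for (w in need) {
    iv <- windows[[w]]
    if (length(iv) != 2L || diff(iv) < 1) stop_param("window `%s` must span >= 1 s", w)
  }
  ivs <- do.call(rbind, windows[need])
  ord <- order(ivs[, 1L])
  if (any(ivs[ord, 1L][-1L] < ivs[ord, 2L][-3L]))
    stop_param("windows must be disjoint")

  count_in <- function(t, iv) sum(t >= iv[1L] & t < iv[2L])
  rows <- lapply(names(trains$trains), function(e) {
    t <- trains$trains[[e]]
    r <- vapply(need, function(w)
      count_in(t, windows[[w]]) / diff(windows[[w]]), numeric(1))
    fold <- if (r[["before"]] > 0) r[["during"]] / r[["before"]] else NA_real_
    norm <- if (r[["before"]] > 0) r / r[["before"]] else rep(NA_real_, 3L)
    data.frame(electrode = e,
               rate_before = r[["before"]], rate_during = r[["during"]],
               rate_after = r[["after"]], fold_change = fold,
               norm_before = norm[1L], norm_during = norm[2L],
               norm_after = norm[3L])
  })
  structure(list(rates = do.call(rbind, rows), windows = windows[need]),
            class = "mfr_report")
}

#' @export
print.mfr_report <- function(x, ...) {
  cat(sprintf("<mfr_report> %d electrodes; median fold change %.2f\n",
              nrow(x$rates), stats::median(x$rates$fold_change, na.rm = TRUE)))
  invisible(x)
}
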