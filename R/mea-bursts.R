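#' Active-electrode classification
#'
#' An electrode is active when it fires at least `min_rate` spikes per
#' minute over the recording.
#'
#' @param trains a [spike_train_set()].
#' @param min_rate minimum rate in spikes per minute (default 5).
#' @return character vector of active electrode ids.
#' @export
active_electrodes <- function(trains, min_rate = 5) {
  if (trains$duration <= 0) stop_param("duration must be positive")
  mins <- trains$duration / 60
  rates <- lengths(trains$trains) / mins
  names(trains$trains)[rates >= min_rate]
}

#' Single-electrode burst detection
#'
#' A burst is a maximal run of consecutive spikes in which every inter-spike
#' interval is at most `max_isi`, containing at least `min_spikes` spikes.
#'
#' @param train ascending spike times (seconds).
#' @param max_isi maximum in-burst inter-spike interval, seconds (default 0.1).
#' @param min_spikes minimum spikes per burst (default 5).
#' @return data frame with columns `start`, `end`, `n_spikes` (one row per
#'   burst; zero rows when none).
#' @export
detect_bursts <- function(train, max_isi = 0.100, min_spikes = 5) {
  train <- sort(as.numeric(train))
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (length(train) < min_spikes) return(empty)
  gap <- which(diff(train) > max_isi)
  starts <- c(1L, gap + 1L)
  ends <- c(gap, length(train))
  n <- ends - starts + 1L
  ok <- n >= min_spikes
  if (!any(ok)) return(empty)
  data.frame(start = train[starts[ok]], end = train[ends[ok]],
             n_spikes = n[ok])
}

#' Network-burst detection on pooled spike trains
#'
#' Spikes of all electrodes are pooled and sorted; maximal runs with every
#' consecutive pooled inter-spike interval at most `max_isi` qualify as
#' network bursts when they contain at least `min_spikes` spikes and at
#' least `min_frac_active` of the active electrodes contribute at least one
#' spike each.
#'
#' @param trains a [spike_train_set()].
#' @param max_isi maximum pooled inter-spike interval, seconds (default 0.1).
#' @param min_spikes minimum pooled spikes per network burst (default 10).
#' @param min_frac_active minimum participating fraction of active
#'   electrodes (default 0.25).
#' @param active_min_rate spikes-per-minute threshold defining active
#'   electrodes (default 5).
#' @return data frame with columns `start`, `end`, `n_spikes`,
#'   `n_electrodes`.
#' @export
detect_network_bursts <- function(trains, max_isi = 0.100, min_spikes = 10,
                                  min_frac_active = 0.25,
                                  active_min_rate = 5) {
  act <- active_electrodes(trains, active_min_rate)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0))
  if (length(act) < 1L) return(empty)
  pooled_t <- unlist(trains$trains[act], use.names = FALSE)
  pooled_e <- rep(act, lengths(trains$trains[act]))
  if (length(pooled_t) == 0L) return(empty)
  ord <- order(pooled_t)
  pooled_t <- pooled_t[ord]; pooled_e <- pooled_e[ord]
  gap <- which(diff(pooled_t) > max_isi)
  starts <- c(1L, gap + 1L)
  ends <- c(gap, length(pooled_t))
  n <- ends - starts + 1L
  n_elec <- vapply(seq_along(starts), function(i)
    length(unique(pooled_e[starts[i]:ends[i]])), integer(1))
  ok <- n >= min_spikes & n_elec >= min_frac_active * length(act)
  if (!any(ok)) return(empty)
  data.frame(start = pooled_t[starts[ok]], end = pooled_t[ends[ok]],
             n_spikes = n[ok], n_electrodes = n_elec[ok])
}
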