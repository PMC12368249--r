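#' Stimulus-evoked activation-time map
#'
#' Assigns each active pixel an activation time `T(x, y)`: the time of its
#' stimulus-evoked event (deepest phase minimum, see [evoked_spike_time()])
#' minus the stimulation time. Pixels outside the mask, pixels without a
#' clear event (prominence gate), and pixels whose evoked event precedes the
#' stimulus are `NA`; pre-stimulus rejections are counted in the
#' `n_pre_stimulus` attribute.
#'
#' @param movie a [calcium_movie()].
#' @param mask a [active_pixel_mask()] result (or logical matrix).
#' @param stim_time stimulation pulse time in seconds; defaults to the
#'   movie's first stimulation pulse.
#' @inheritParams phase_spike_detect
#' @return an object of class `activation_map`: `T` (height x width matrix of
#'   seconds since the stimulus, `NA` where undefined), `reference`
#'   (description of the time origin); attribute `n_pre_stimulus`.
#' @export
activation_map <- function(movie, mask, stim_time = NULL, smooth_window = 5,
                           min_prominence = 0.4, pedestal_k = 20) {
  if (inherits(mask, "pixel_mask")) mask <- mask$mask
  d <- dim(movie$data)
  if (!identical(dim(mask), d[2:3])) stop_param("mask shape must match the movie")
  if (is.null(stim_time)) {
    if (!length(movie$stim_times)) stop_param("no `stim_time` available")
    stim_time <- movie$stim_times[1L]
  }
  if (stim_time < 0 || stim_time >= movie_duration(movie))
    stop_param("`stim_time` must fall inside the movie")

  X <- movie_matrix(movie)
  sel <- which(mask)
  Tmap <- matrix(NA_real_, d[2L], d[3L])
  n_pre <- 0L
  if (length(sel)) {
    evs <- phase_events_matrix(X[, sel, drop = FALSE], movie$frame_rate,
                               smooth_window, min_prominence, pedestal_k)
    tv <- vapply(evs, function(e)
      if (is.na(e$evoked_index)) NA_real_ else e$times[e$evoked_index],
      numeric(1))
    rel <- tv - stim_time
    # events more than half a frame before the pulse are rejected; smaller
    # negatives are timing quantisation and clamp to 0
    tol <- 0.5 / movie$frame_rate
    n_pre <- sum(!is.na(rel) & rel < -tol)
    rel[!is.na(rel) & rel < -tol] <- NA_real_
    rel[!is.na(rel) & rel < 0] <- 0
    Tmap[sel] <- rel
  }
  structure(
    list(T = Tmap,
         reference = sprintf("seconds after stimulation pulse at %.3f s", stim_time)),
    n_pre_stimulus = n_pre, class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  fin <- sum(!is.na(x$T))
  cat(sprintf("<activation_map> %d / %d pixels with activation times (%s)\n",
              fin, length(x$T), x$reference))
  invisible(x)
}

#' Per-pixel spike-count map
#'
#' Counts phase-detected events per masked pixel and flags the regions where
#' more than one spike timing occurs — repeated activations mark
#' well-connected network sites.
#'
#' @inheritParams activation_map
#' @return an object of class `spike_count_map`: `counts` (integer matrix,
#'   0 for unmasked pixels) and `multi_mask` (logical matrix, counts > 1).
#' @export
spike_count_map <- function(movie, mask, smooth_window = 5,
                            min_prominence = 0.4, pedestal_k = 20) {
  if (inherits(mask, "pixel_mask")) mask <- mask$mask
  d <- dim(movie$data)
  if (!identical(dim(mask), d[2:3])) stop_param("mask shape must match the movie")
  counts <- matrix(0L, d[2L], d[3L])
  sel <- which(mask)
  if (length(sel)) {
    X <- movie_matrix(movie)
    evs <- phase_events_matrix(X[, sel, drop = FALSE], movie$frame_rate,
                               smooth_window, min_prominence, pedestal_k)
    counts[sel] <- vapply(evs, function(e) length(e$times), integer(1))
  }
  structure(list(counts = counts, multi_mask = counts > 1L),
            class = "spike_count_map")
}

#' @export
print.spike_count_map <- function(x, ...) {
  cat(sprintf("<spike_count_map> %d pixels with events, %d with > 1\n",
              sum(x$counts > 0), sum(x$multi_mask)))
  invisible(x)
}
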