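#' Calcium-imaging movie container
#'
#' @param data 3D numeric array, frames x height x width (fluorescence, a.u.).
#' @param frame_rate acquisition rate in frames per second.
#' @param stim_times optical stimulation onset times in seconds (may be empty).
#' @return an object of class `calcium_movie`.
#' @export
calcium_movie <- function(data, frame_rate, stim_times = numeric(0)) {
  if (length(dim(data)) != 3L) stop_param("`data` must be frames x height x width")
  if (dim(data)[1L] < 2L) stop_param("movie needs at least 2 frames")
  if (any(!is.finite(data))) stop_param("movie data must be finite")
  check_scalar_pos(frame_rate, "frame_rate")
  structure(
    list(data = data, frame_rate = frame_rate,
         stim_times = as.numeric(stim_times)),
    class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<calcium_movie> %d frames of %dx%d px @ %.3g fps (%.2f s), %d stim pulses\n",
              d[1L], d[2L], d[3L], x$frame_rate, d[1L] / x$frame_rate,
              length(x$stim_times)))
  invisible(x)
}

#' @export
dim.calcium_movie <- function(x) dim(x$data)

movie_duration <- function(movie) dim(movie$data)[1L] / movie$frame_rate

## Movie as a frames x pixels matrix (column-major spatial order).
movie_matrix <- function(movie) {
  d <- dim(movie$data)
  dim(movie$data) <- c(d[1L], d[2L] * d[3L])
  movie$data
}

#' Double-exponential calcium transient kernel
#'
#' `k(t) = (exp(-t / decay) - exp(-t / rise))`, normalised to unit peak, for
#' `t >= 0`; 0 for `t < 0`. Defaults follow the slow transients of
#' hiPSC-derived neurons (rise 0.1 s, decay 1.5 s).
#'
#' @param t time in seconds relative to event onset (vectorised).
#' @param rise,decay kernel time constants in seconds, `decay > rise > 0`.
#' @return kernel values, peak 1.
#' @export
calcium_kernel <- function(t, rise = 0.1, decay = 1.5) {
  if (!(decay > rise && rise > 0)) stop_param("need decay > rise > 0")
  # peak location/height of the difference of exponentials
  tp <- (log(decay) - log(rise)) * rise * decay / (decay - rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / peak
  out
}

#' Simulate a calcium movie of an optically triggered activation wave
#'
#' A single light pulse activates the network's stimulated cell; activation
#' propagates along shortest-delay paths, so cell `j` fires at
#' `pulse_time + shortest_path_delay(stimulated_cell, j)`. Each activated cell
#' emits a calcium transient (double-exponential kernel) on its pixel mask on
#' top of a constant baseline; i.i.d. Gaussian noise is added to every pixel.
#'
#' @param network a [generate_network()] model.
#' @param stim a [stim_schedule()]; the first pulse launches the wave.
#' @param frame_rate frames per second (30-100 fps typical for wide-field /
#'   confocal acquisition).
#' @param duration movie duration in seconds.
#' @param kernel numeric `c(rise, decay, amplitude)`: transient time constants
#'   (s) and peak amplitude (fluorescence units above baseline).
#' @param noise_sd additive Gaussian noise SD (fluorescence units).
#' @param seed integer seed.
#' @param baseline constant baseline fluorescence.
#' @param extra_spikes optional list mapping cell index (as character or by
#'   position) to additional spike times in seconds, e.g. spontaneous events.
#' @return list with elements `movie` (a [calcium_movie()]) and
#'   `ground_truth`: `spike_times` (per-cell list), `activation_time`
#'   (per-cell scalar, `NA` when unreachable or truncated), `cell_pixel_masks`
#'   (per-cell linear pixel indices), `truncated` (logical flag, `TRUE` when
#'   the wave outruns the movie).
#' @export
simulate_calcium_movie <- function(network, stim, frame_rate = 30,
                                   duration = 20,
                                   kernel = c(rise = 0.1, decay = 1.5, amplitude = 10),
                                   noise_sd = 0, seed = 1L,
                                   baseline = 100, extra_spikes = NULL) {
  if (!inherits(network, "network_model")) stop_param("`network` must be a network_model")
  if (!inherits(stim, "stim_schedule")) stop_param("`stim` must be a stim_schedule")
  if (frame_rate < 1) stop_param("`frame_rate` must be positive")
  if (length(stim$pulse_times) < 1L) stop_param("need at least one stimulation pulse")
  rise <- kernel[[1L]]; decay <- kernel[[2L]]; amplitude <- kernel[[3L]]
  if (!(decay > rise && rise > 0)) stop_param("kernel needs decay > rise > 0")

  n_cells <- nrow(network$cell_positions)
  h <- network$field_shape[1L]; w <- network$field_shape[2L]
  n_frames <- round(duration * frame_rate)
  pulse <- stim$pulse_times[1L]
  if (pulse >= duration) stop_param("first pulse falls outside the movie")

  delays <- network_delays(network)
  act <- pulse + delays
  truncated <- any(is.finite(act) & act >= duration)
  if (truncated)
    warning("movie shorter than the longest propagation path; ground truth truncated")
  act[!is.finite(act) | act >= duration] <- NA_real_

  spikes <- lapply(seq_len(n_cells), function(i) {
    s <- if (is.na(act[i])) numeric(0) else act[i]
    if (!is.null(extra_spikes)) {
      key <- as.character(i)
      if (!is.null(extra_spikes[[key]]))
        s <- sort(c(s, extra_spikes[[key]][extra_spikes[[key]] < duration]))
    }
    s
  })
  masks <- lapply(seq_len(n_cells), function(i)
    cell_mask_indices(network$cell_positions[i, ], network$cell_radius,
                      network$field_shape))

  tt <- (seq_len(n_frames) - 1L) / frame_rate
  mov <- matrix(baseline, n_frames, h * w)
  for (i in seq_len(n_cells)) {
    if (length(spikes[[i]]) == 0L) next
    trace <- rowSums(vapply(spikes[[i]], function(s)
      calcium_kernel(tt - s, rise, decay), numeric(n_frames))) * amplitude
    mov[, masks[[i]]] <- mov[, masks[[i]]] + trace
  }
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "calcium-noise"))
    mov <- mov + stats::rnorm(length(mov), sd = noise_sd)
  }
  dim(mov) <- c(n_frames, h, w)

  list(
    movie = calcium_movie(mov, frame_rate, stim$pulse_times),
    ground_truth = list(
      spike_times = spikes,
      activation_time = act,
      cell_pixel_masks = masks,
      truncated = truncated))
}
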