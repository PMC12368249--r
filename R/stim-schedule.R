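#' Stimulation schedule
#'
#' A train of light pulses: ascending onset times, a common pulse width and a
#' free-text intensity label (intensity is carried as metadata only, it is not
#' modelled physically).
#'
#' @param pulse_times pulse onset times in seconds, strictly ascending.
#' @param pulse_width pulse width in seconds (> 0).
#' @param intensity_label free-text description, e.g. `"475 nm, 3.9 mW/mm2"`.
#' @return an object of class `stim_schedule`.
#' @export
stim_schedule <- function(pulse_times, pulse_width, intensity_label = "") {
  pulse_times <- as.numeric(pulse_times)
  check_scalar_pos(pulse_width, "pulse_width")
  if (length(pulse_times) > 1L && any(diff(pulse_times) <= 0))
    stop_param("`pulse_times` must be strictly ascending")
  if (any(pulse_times < 0)) stop_param("`pulse_times` must be non-negative")
  structure(
    list(pulse_times = pulse_times, pulse_width = pulse_width,
         intensity_label = as.character(intensity_label)[1L]),
    class = "stim_schedule")
}

#' Build a periodic stimulation schedule
#'
#' Pulses at `t_start, t_start + 1/frequency, ...` strictly below `t_end`.
#'
#' @param frequency pulse rate in Hz.
#' @param pulse_width pulse width in seconds; the duty cycle
#'   `frequency * pulse_width` must be < 1.
#' @param t_start,t_end half-open interval `[t_start, t_end)` in seconds.
#' @param intensity_label free-text metadata.
#' @return a [stim_schedule()].
#' @export
#' @examples
#' make_stim_schedule(1, 0.010, 0, 5)$pulse_times  # 0 1 2 3 4
make_stim_schedule <- function(frequency, pulse_width, t_start, t_end,
                               intensity_label = "") {
  check_scalar_pos(frequency, "frequency")
  check_scalar_pos(pulse_width, "pulse_width")
  if (t_end <= t_start) stop_param("`t_end` must exceed `t_start`")
  if (frequency * pulse_width >= 1)
    stop_param("duty cycle frequency * pulse_width must be < 1")
  times <- seq(t_start, t_end, by = 1 / frequency)
  times <- times[times < t_end]
  stim_schedule(times, pulse_width, intensity_label)
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d pulses, width %.4g s", length(x$pulse_times),
              x$pulse_width))
  if (length(x$pulse_times))
    cat(sprintf(", t in [%.3g, %.3g] s", min(x$pulse_times), max(x$pulse_times)))
  if (nzchar(x$intensity_label)) cat(" [", x$intensity_label, "]", sep = "")
  cat("\n")
  invisible(x)
}
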