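#' @keywords internal
"_PACKAGE"

# cache for band-pass frequency-response curves (keyed by length and band)
.filter_cache <- new.env(parent = emptyenv())

## Internal numeric helpers shared across the pipelines.

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param("`%s` must be a single positive finite number", name)
  invisible(x)
}

#' Centered moving average with shrinking edge windows
#'
#' Smooths a trace with a centered window of `width` samples; near the edges
#' the window shrinks so every output sample averages only observed data.
#'
#' @param x numeric vector.
#' @param width window width in samples (>= 1); even widths are extended
#'   symmetrically by `floor(width / 2)` on each side.
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, width) {
  if (width < 1) stop_param("`width` must be >= 1")
  n <- length(x)
  if (width <= 1 || n == 0L) return(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i * H(x)` computed by zeroing the
#' negative frequencies of the FFT (the standard one-sided spectrum method).
#'
#' @param x real-valued numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  if (any(!is.finite(x))) stop_param("trace must be finite")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a trace
#'
#' Phase (argument) of the analytic signal of the mean-subtracted trace, in
#' `(-pi, pi]`; no unwrapping is applied.
#'
#' @inheritParams analytic_signal
#' @return numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(x) {
  Arg(analytic_signal(x - mean(x)))
}

## Local maxima (strict rise, plateau-tolerant fall) as integer indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # collapse plateaus: a maximum is a point where the last nonzero diff before
  # it is positive and the next nonzero diff is negative
  rise <- c(FALSE, d > 0)
  fall <- c(d < 0, FALSE)
  # propagate rise through zero-diff plateaus
  for (i in 2:n) if (d[i - 1L] == 0 && rise[i - 1L]) rise[i] <- TRUE
  which(rise & fall)
}

## Topographic prominence of peaks (maxima) of x at the given indices.
## For each peak: extend left/right until a sample higher than the peak (or the
## boundary); the prominence is peak height minus the higher of the two lowest
## points found on the excursions.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

## Merge possibly-overlapping intervals given as a 2-column matrix [start, end];
## returns a 2-column matrix of disjoint intervals sorted by start.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2L))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(iv), 2L)
  k <- 1L
  out[1L, ] <- iv[1L, ]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1L] <= out[k, 2L]) {
        if (iv[i, 2L] > out[k, 2L]) out[k, 2L] <- iv[i, 2L]
      } else {
        k <- k + 1L
        out[k, ] <- iv[i, ]
      }
    }
  }
  out[seq_len(k), , drop = FALSE]
}

## Total time in [0, T] covered by merged +/- dt windows around spike times.
tiled_fraction <- function(times, dt, T) {
  if (length(times) == 0L) return(0)
  iv <- cbind(pmax(0, times - dt), pmin(T, times + dt))
  m <- merge_intervals(iv)
  sum(m[, 2L] - m[, 1L]) / T
}

## Fraction of spikes in `a` lying within +/- dt of any spike in `b`.
## Both inputs ascending.
prop_tiled <- function(a, b, dt) {
  if (length(a) == 0L) return(NA_real_)
  if (length(b) == 0L) return(0)
  # nearest b at or before each a, and the one after
  idx <- findInterval(a, b)
  near <- rep(FALSE, length(a))
  has_prev <- idx >= 1L
  near[has_prev] <- (a[has_prev] - b[idx[has_prev]]) <= dt
  has_next <- idx < length(b)
  near[has_next] <- near[has_next] | (b[idx[has_next] + 1L] - a[has_next]) <= dt
  mean(near)
}

## Derive a reproducible child seed from a top-level seed and a stream label.
## Double arithmetic keeps intermediate products exact (< 2^53) and the
## result within the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, stream) {
  base <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + base * 7919) %% 2147483640) + 1L
}
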