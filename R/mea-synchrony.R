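#' Spike-time tiling coefficient (STTC)
#'
#' Firing-rate-independent pairwise synchrony:
#' `STTC = 1/2 * ((P_A - T_B) / (1 - P_A * T_B) + (P_B - T_A) / (1 - P_B * T_A))`
#' where `P_A` is the fraction of spikes of train `a` falling within
#' `+/- dt` of any spike of `b`, and `T_B` the fraction of the total
#' recording tiled by the merged `+/- dt` windows around `b`'s spikes
#' (clipped to `[0, T]`); `P_B`, `T_A` symmetrically. Returns `NA` when a
#' train is empty or a denominator vanishes.
#'
#' @param a,b ascending spike times in seconds.
#' @param dt synchrony half-window in seconds (default 0.020, matching the
#'   cross-correlogram synchrony window).
#' @param T total recording duration in seconds (`2 * dt < T`).
#' @return the coefficient in `[-1, 1]`, or `NA`.
#' @export
sttc <- function(a, b, dt = 0.020, T) {
  if (dt <= 0) stop_param("`dt` must be positive")
  if (2 * dt >= T) stop_param("`T` must exceed 2 * dt")
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  PA <- prop_tiled(a, b, dt)
  PB <- prop_tiled(b, a, dt)
  TA <- tiled_fraction(a, dt, T)
  TB <- tiled_fraction(b, dt, T)
  d1 <- 1 - PA * TB
  d2 <- 1 - PB * TA
  # a denominator vanishes only when the spike fraction and the tiled
  # fraction both equal 1; the term is then taken at its continuous limit, 1
  t1 <- if (d1 == 0) 1 else (PA - TB) / d1
  t2 <- if (d2 == 0) 1 else (PB - TA) / d2
  0.5 * (t1 + t2)
}

#' Pairwise STTC matrix over active electrodes
#'
#' @param trains a [spike_train_set()].
#' @param dt synchrony half-window (seconds).
#' @param active_min_rate spikes/min rule for including an electrode.
#' @return an object of class `synchrony_matrix`: `sttc` (symmetric matrix,
#'   unit diagonal for non-empty trains), `dt`, `electrodes`.
#' @export
sttc_matrix <- function(trains, dt = 0.020, active_min_rate = 5) {
  act <- active_electrodes(trains, active_min_rate)
  k <- length(act)
  M <- matrix(NA_real_, k, k, dimnames = list(act, act))
  for (i in seq_len(k)) {
    M[i, i] <- if (length(trains$trains[[act[i]]])) 1 else NA_real_
    if (i < k) for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- sttc(trains$trains[[act[i]]],
                                 trains$trains[[act[j]]],
                                 dt, trains$duration)
    }
  }
  structure(list(sttc = M, dt = dt, electrodes = act),
            class = "synchrony_matrix")
}

#' @export
print.synchrony_matrix <- function(x, ...) {
  off <- x$sttc[upper.tri(x$sttc)]
  cat(sprintf("<synchrony_matrix> %d active electrodes, mean STTC %.3f (dt %.3g s)\n",
              nrow(x$sttc), mean(off, na.rm = TRUE), x$dt))
  invisible(x)
}

#' Cross-correlogram synchrony index
#'
#' For each electrode pair, the fraction of spike-time differences (within a
#' `+/- support` correlogram) that fall inside the `+/- window` synchrony
#' band. Under independent stationary firing the expected raw index is
#' `window / support`; the rescaled index divides by that expectation, so 1
#' means chance-level synchrony. The well aggregate is the mean over active
#' pairs.
#'
#' @param trains a [spike_train_set()].
#' @param window synchrony half-window, seconds (default 0.020).
#' @param support correlogram half-support, seconds (default 1).
#' @param active_min_rate spikes/min rule for including an electrode.
#' @return list with `pairs` (data frame: electrodes, `raw` index,
#'   `rescaled`), `well_raw`, `well_rescaled`, `expected_raw`.
#' @export
synchrony_index <- function(trains, window = 0.020, support = 1,
                            active_min_rate = 5) {
  act <- active_electrodes(trains, active_min_rate)
  if (length(act) < 2L) stop_param("need >= 2 active electrodes")
  expected <- window / support
  combs <- utils::combn(act, 2L)
  res <- apply(combs, 2L, function(pr) {
    a <- trains$trains[[pr[1L]]]
    b <- trains$trains[[pr[2L]]]
    # count time differences |a_i - b_j| within window / within support
    n_win <- count_diffs_within(a, b, window)
    n_sup <- count_diffs_within(a, b, support)
    if (n_sup == 0) return(NA_real_)
    n_win / n_sup
  })
  pairs <- data.frame(a = combs[1L, ], b = combs[2L, ], raw = res,
                      rescaled = res / expected)
  list(pairs = pairs,
       well_raw = mean(res, na.rm = TRUE),
       well_rescaled = mean(res, na.rm = TRUE) / expected,
       expected_raw = expected)
}

## Number of pairs (i, j) with |a_i - b_j| <= w; a, b ascending.
count_diffs_within <- function(a, b, w) {
  if (!length(a) || !length(b)) return(0)
  hi <- findInterval(a + w, b)
  lo <- findInterval(a - w, b, left.open = TRUE)
  sum(hi - lo)
}
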