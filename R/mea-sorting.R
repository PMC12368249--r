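#' PCA + k-means spike sorting with gap-statistic model selection
#'
#' Projects spike waveforms onto their first `n_pcs` principal components and
#' clusters the scores with k-means for k = 1..`max_k`; the number of units
#' is chosen by the gap statistic (reference: uniform draws over the score
#' bounding box, `B` replicates, Tibshirani's one-standard-error rule).
#'
#' @param waveforms spikes x samples numeric matrix.
#' @param n_pcs number of principal components used (default 5).
#' @param max_k maximum number of clusters (default 10); reduced with a
#'   warning when there are fewer than `2 * max_k` spikes.
#' @param seed integer seed for k-means restarts and the reference draws.
#' @param B number of gap-statistic reference draws (default 20).
#' @return an object of class `sort_result`: `labels` (per-spike unit, 1-based),
#'   `n_units`, `mean_waveforms` (units x samples), `pc_scores`
#'   (spikes x n_pcs), `gap` (the gap-statistic table).
#' @export
sort_spikes <- function(waveforms, n_pcs = 5, max_k = 10, seed = 1L, B = 20) {
  if (!is.matrix(waveforms)) waveforms <- as.matrix(waveforms)
  n <- nrow(waveforms)
  if (ncol(waveforms) < n_pcs) stop_param("need at least `n_pcs` samples per waveform")
  if (n < 2L * max_k) {
    max_k <- max(1L, floor(n / 2))
    warning(sprintf("few spikes: max_k reduced to %d", max_k))
  }
  pc <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  k_avail <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k_avail), drop = FALSE]

  # degenerate case: (near-)identical waveforms form a single unit
  spread <- max(apply(scores, 2L, function(s) diff(range(s))))
  total_scale <- max(abs(waveforms)) + 1e-12
  if (spread <= 1e-8 * total_scale || max_k == 1L) {
    labels <- rep(1L, n)
    return(structure(
      list(labels = labels, n_units = 1L,
           mean_waveforms = matrix(colMeans(waveforms), nrow = 1L),
           pc_scores = scores, gap = NULL),
      class = "sort_result"))
  }

  set.seed(as.integer(seed))
  km <- function(x, k) {
    if (k == 1L) return(list(cluster = rep(1L, nrow(x))))
    stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
  }
  gap <- cluster::clusGap(scores, FUNcluster = km, K.max = max_k, B = B,
                          spaceH0 = "original", verbose = FALSE)
  k_best <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                           method = "Tibs2001SEmax")
  set.seed(as.integer(seed) + 1L)
  labels <- km(scores, k_best)$cluster
  mw <- do.call(rbind, lapply(seq_len(k_best), function(u)
    colMeans(waveforms[labels == u, , drop = FALSE])))
  structure(
    list(labels = as.integer(labels), n_units = as.integer(k_best),
         mean_waveforms = mw, pc_scores = scores, gap = gap$Tab),
    class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> %d spikes in %d units (gap statistic)\n",
              length(x$labels), x$n_units))
  invisible(x)
}

#' Extract spike waveforms around detected spike times
#'
#' Cuts a window from `pre` before to `post` after each spike peak; spikes
#' too close to the trace edges are dropped.
#'
#' @param trace filtered trace.
#' @param fs sampling rate, Hz.
#' @param spike_times spike (peak) times in seconds.
#' @param pre,post window extent in seconds (defaults 0.6 ms / 1.4 ms).
#' @return list with `waveforms` (spikes x samples) and `times` (kept spikes).
#' @export
extract_waveforms <- function(trace, fs, spike_times,
                              pre = 0.0006, post = 0.0014) {
  np <- round(pre * fs); na <- round(post * fs)
  idx <- round(spike_times * fs) + 1L
  ok <- idx - np >= 1L & idx + na <= length(trace)
  idx <- idx[ok]
  wf <- t(vapply(idx, function(i) trace[(i - np):(i + na)],
                 numeric(np + na + 1L)))
  list(waveforms = wf, times = spike_times[ok])
}
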