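#' Truncated-SVD denoising of a calcium movie
#'
#' Factorises the frames x pixels matrix and keeps the `rank` most dominant
#' modes; the low-rank reconstruction suppresses pixel noise while retaining
#' the coherent spatiotemporal signal. With `rank = "auto"` every mode above
#' the optimal hard threshold for singular values under i.i.d. noise
#' (Gavish-Donoho: `omega(beta) * median` of the spectrum, `beta` the aspect
#' ratio) is kept, a cut users should confirm against the spectrum returned
#' in the `singular_values` attribute.
#'
#' @param movie a [calcium_movie()].
#' @param rank number of modes to keep (1 <= rank <= min(frames, pixels)), or
#'   `"auto"`.
#' @return a denoised [calcium_movie()] with attributes `singular_values`
#'   (the full spectrum) and `rank` (the rank used).
#' @export
svd_denoise <- function(movie, rank = "auto") {
  X <- movie_matrix(movie)
  m <- min(dim(X))
  sv <- svd(X)
  if (identical(rank, "auto")) {
    rank <- pick_rank_auto(sv$d, dim(X))
  } else {
    if (!is.numeric(rank) || rank < 1 || rank != round(rank))
      stop_param("`rank` must be a positive integer or \"auto\"")
    if (rank > m) stop_param("`rank` exceeds min(frames, pixels) = %d", m)
  }
  k <- seq_len(rank)
  Y <- sv$u[, k, drop = FALSE] %*% (sv$d[k] * t(sv$v[, k, drop = FALSE]))
  dim(Y) <- dim(movie$data)
  out <- calcium_movie(Y, movie$frame_rate, movie$stim_times)
  attr(out, "singular_values") <- sv$d
  attr(out, "rank") <- as.integer(rank)
  out
}

## Automatic rank from the eigenspectrum: the optimal hard threshold for
## singular values under i.i.d. noise (Gavish-Donoho), tau = omega(beta) *
## median(d) with beta the matrix aspect ratio. Keeps every mode above the
## Marchenko-Pastur noise bulk. A pure ratio-elbow rule fails on
## fluorescence movies, where the static-baseline mode dwarfs the many
## comparable dynamic modes and the "largest drop" lands at rank 1-2.
pick_rank_auto <- function(d, dims) {
  m <- length(d)
  if (m <= 2L) return(1L)
  beta <- min(dims) / max(dims)
  omega <- 0.56 * beta^3 - 0.95 * beta^2 + 1.82 * beta + 1.43
  k <- sum(d > omega * stats::median(d))
  max(1L, min(m - 1L, k))
}

#' Mask of pixels with significant calcium fluctuation
#'
#' Classifies a pixel as active when its fluorescence range over time
#' (max - min) reaches `range_threshold`; pixels below it are excluded from
#' further analysis. With `"auto"` the threshold is chosen by Otsu's method on
#' the range image.
#'
#' @param movie a [calcium_movie()].
#' @param range_threshold fluorescence-range cutoff, or `"auto"`.
#' @return list of class `pixel_mask`: `mask` (logical height x width),
#'   `range_threshold` (the cutoff used), `range_image`.
#' @export
active_pixel_mask <- function(movie, range_threshold = "auto") {
  X <- movie_matrix(movie)
  rng <- apply(X, 2L, function(p) max(p) - min(p))
  d <- dim(movie$data)
  rimg <- matrix(rng, d[2L], d[3L])
  if (identical(range_threshold, "auto")) {
    lo <- min(rng); hi <- max(rng)
    if (hi - lo < .Machine$double.eps) {
      range_threshold <- hi + 1  # constant movie: nothing is active
    } else {
      norm <- (rimg - lo) / (hi - lo)
      range_threshold <- EBImage::otsu(norm, range = c(0, 1)) * (hi - lo) + lo
    }
  }
  structure(
    list(mask = rimg >= range_threshold, range_threshold = range_threshold,
         range_image = rimg),
    class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d / %d pixels active (range threshold %.4g)\n",
              sum(x$mask), length(x$mask), x$range_threshold))
  invisible(x)
}
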