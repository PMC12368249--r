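#' Binarize a spike train into presence/absence symbols
#'
#' Symbol `i` is 1 when at least one spike falls in the half-open bin
#' `[i * bin, (i + 1) * bin)`; the sequence has `ceiling(duration / bin)`
#' symbols. The default 1-ms bin preserves the temporal detail of
#' 20-kHz-derived spike trains while keeping sequences tractable.
#'
#' @param train spike times in seconds.
#' @param duration recording duration in seconds.
#' @param bin bin width in seconds (default 0.001).
#' @return integer vector of 0/1 symbols.
#' @export
binarize_train <- function(train, duration, bin = 0.001) {
  if (bin <= 0) stop_param("`bin` must be positive")
  n <- ceiling(duration / bin)
  seq_out <- integer(n)
  idx <- floor(train / bin) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  seq_out[unique(idx)] <- 1L
  seq_out
}

#' Lempel-Ziv complexity of a binary sequence
#'
#' Raw complexity `c(n)` is the number of phrases in the exhaustive-history
#' (LZ76) parsing: scanning left to right, each new phrase is the shortest
#' substring that cannot be copied from the previous history (copies may
#' extend into the phrase itself). The normalised complexity is
#' `LZC = c(n) / n * log2(n)`. Random sequences parse into many short
#' phrases (high LZC); regular sequences into few long ones.
#'
#' @param seq_bin vector of 0/1 symbols (length >= 1).
#' @param binarization free-text description stored in the result (e.g. the
#'   bin width used).
#' @return an object of class `lzc_result`: `n`, `c_n`, `lzc`,
#'   `binarization`.
#' @export
lempel_ziv_complexity <- function(seq_bin, binarization = "1 if >=1 spike per bin") {
  seq_bin <- as.integer(seq_bin)
  n <- length(seq_bin)
  if (n < 1L) stop_param("sequence must have length >= 1")
  if (any(is.na(seq_bin)) || any(!seq_bin %in% c(0L, 1L)))
    stop_param("sequence symbols must be 0 or 1")
  # Kaspar-Schuster implementation of the LZ76 exhaustive parsing
  c_n <- 1L
  i <- 0L   # history length already parsed
  k <- 1L   # current match extension length
  l <- 1L   # start offset of the candidate copy source
  k_max <- 1L
  if (n > 1L) {
    repeat {
      if (seq_bin[i + k] == seq_bin[l + k]) {
        k <- k + 1L
        if (l + k > n) {
          c_n <- c_n + 1L
          break
        }
      } else {
        if (k > k_max) k_max <- k
        i <- i + 1L
        if (i == l) {
          c_n <- c_n + 1L
          l <- l + k_max
          if (l + 1L > n) break
          i <- 0L
          k <- 1L
          k_max <- 1L
        } else {
          k <- 1L
        }
      }
    }
  }
  structure(
    list(n = n, c_n = c_n, lzc = c_n / n * log2(n),
         binarization = binarization),
    class = "lzc_result")
}

#' @export
print.lzc_result <- function(x, ...) {
  cat(sprintf("<lzc_result> n = %d, c(n) = %d, LZC = %.4f [%s]\n",
              x$n, x$c_n, x$lzc, x$binarization))
  invisible(x)
}

#' Lempel-Ziv complexity of every electrode in a spike-train set
#'
#' @param trains a [spike_train_set()].
#' @param bin binarization bin width, seconds.
#' @return data frame with `electrode`, `n`, `c_n`, `lzc`.
#' @export
lzc_per_electrode <- function(trains, bin = 0.001) {
  res <- lapply(names(trains$trains), function(e) {
    r <- lempel_ziv_complexity(
      binarize_train(trains$trains[[e]], trains$duration, bin),
      binarization = sprintf("%g-s bins, presence/absence", bin))
    data.frame(electrode = e, n = r$n, c_n = r$c_n, lzc = r$lzc)
  })
  do.call(rbind, res)
}
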