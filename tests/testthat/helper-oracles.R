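# Independent brute-force oracles used to cross-check the implementations.
# Written deliberately in the most literal style possible; no code shared
# with the package internals.

# exhaustive single-train burst scanner: every maximal run of consecutive
# spikes whose ISIs all stay within max_isi, kept if long enough
brute_bursts <- function(times, max_isi = 0.1, min_spikes = 5) {
  times <- sort(times)
  n <- length(times)
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1L] - times[j] <= max_isi) j <- j + 1L
    if (j - i + 1L >= min_spikes)
      out <- rbind(out, c(times[i], times[j], j - i + 1L))
    i <- j + 1L
  }
  if (is.null(out)) {
    data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  } else {
    data.frame(start = out[, 1L], end = out[, 2L],
               n_spikes = as.integer(out[, 3L]))
  }
}

# exhaustive pooled-train network-burst scanner
brute_network_bursts <- function(trains, duration, max_isi = 0.1,
                                 min_spikes = 10, min_frac = 0.25,
                                 active_min_rate = 5) {
  rates <- sapply(trains, length) / (duration / 60)
  act <- names(trains)[rates >= active_min_rate]
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0))
  if (!length(act)) return(empty)
  ts <- NULL; es <- NULL
  for (e in act) { ts <- c(ts, trains[[e]]); es <- c(es, rep(e, length(trains[[e]]))) }
  if (!length(ts)) return(empty)
  o <- order(ts); ts <- ts[o]; es <- es[o]
  out <- NULL
  i <- 1L; n <- length(ts)
  while (i <= n) {
    j <- i
    while (j < n && ts[j + 1L] - ts[j] <= max_isi) j <- j + 1L
    ne <- length(unique(es[i:j]))
    if (j - i + 1L >= min_spikes && ne >= min_frac * length(act))
      out <- rbind(out, c(ts[i], ts[j], j - i + 1L, ne))
    i <- j + 1L
  }
  if (is.null(out)) empty else
    data.frame(start = out[, 1L], end = out[, 2L],
               n_spikes = as.integer(out[, 3L]),
               n_electrodes = as.integer(out[, 4L]))
}

# literal transcription of the tiling-coefficient formula; coverage computed
# by sweeping over window boundaries and accumulating covered length
brute_sttc <- function(a, b, dt, T) {
  if (!length(a) || !length(b)) return(NA_real_)
  prop_near <- function(x, y) {
    hit <- 0L
    for (t in x) if (any(abs(y - t) <= dt)) hit <- hit + 1L
    hit / length(x)
  }
  covered <- function(x) {
    lo <- pmax(0, x - dt); hi <- pmin(T, x + dt)
    bounds <- sort(unique(c(lo, hi)))
    tot <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      mid <- (bounds[k] + bounds[k + 1L]) / 2
      if (any(lo <= mid & mid <= hi)) tot <- tot + bounds[k + 1L] - bounds[k]
    }
    tot / T
  }
  PA <- prop_near(a, b); PB <- prop_near(b, a)
  TA <- covered(a); TB <- covered(b)
  term <- function(P, Tv) if (1 - P * Tv == 0) 1 else (P - Tv) / (1 - P * Tv)
  0.5 * (term(PA, TB) + term(PB, TA))
}

# naive LZ76 exhaustive-history parser: the next phrase is one symbol longer
# than the longest prefix of the remainder that can be copied from any
# earlier starting position (copies may run into the phrase itself)
brute_lz76 <- function(s) {
  n <- length(s)
  pos <- 1L
  cnt <- 0L
  while (pos <= n) {
    Lmax <- 0L
    if (pos > 1L) {
      L <- 1L
      while (pos + L - 1L <= n) {
        found <- FALSE
        for (k in 1:(pos - 1L)) {
          if (all(s[k:(k + L - 1L)] == s[pos:(pos + L - 1L)])) { found <- TRUE; break }
        }
        if (!found) break
        Lmax <- L
        L <- L + 1L
      }
    }
    cnt <- cnt + 1L
    pos <- pos + min(Lmax + 1L, n - pos + 1L)
  }
  cnt
}

# deterministic hand-built chain network: 3 cells in a row, 0.5-s delays
chain_network <- function(delay = 0.5) {
  structure(list(
    cell_positions = cbind(row = c(10, 20, 30), col = c(10, 20, 30)),
    adjacency = matrix(c(FALSE, TRUE, FALSE,
                         TRUE, FALSE, TRUE,
                         FALSE, TRUE, FALSE), 3, 3),
    conduction_delay = matrix(c(NA, delay, NA,
                                delay, NA, delay,
                                NA, delay, NA), 3, 3),
    stimulated_cell = 1L, field_shape = c(40L, 40L), cell_radius = 2.5),
    class = "network_model")
}

random_train <- function(n, T) sort(stats::runif(n, 0, T))
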