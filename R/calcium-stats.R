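#' Spearman rank-correlation matrix of ROI activity traces
#'
#' Pairwise Spearman correlations between fluorescence traces; ties are
#' handled by average ranks (the default of [stats::cor()]). Correlations
#' involving a constant trace are reported as `NA`, not 0.
#'
#' @param traces numeric matrix, ROIs x time points.
#' @param labels optional ROI identifiers (defaults to row names).
#' @return an object of class `correlation_matrix`: `rho` (symmetric matrix
#'   with unit diagonal for non-constant traces) and `labels`.
#' @export
spearman_matrix <- function(traces, labels = rownames(traces)) {
  if (!is.matrix(traces)) traces <- as.matrix(traces)
  if (nrow(traces) < 2L) stop_param("need at least 2 ROIs")
  if (ncol(traces) < 3L) stop_param("need at least 3 time points")
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(traces)))
  constant <- apply(traces, 1L, function(x) max(x) - min(x) == 0)
  rho <- suppressWarnings(stats::cor(t(traces), method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  dimnames(rho) <- list(labels, labels)
  structure(list(rho = rho, labels = labels), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d Spearman rho, mean off-diagonal %.3f\n",
              nrow(x$rho), ncol(x$rho),
              mean(x$rho[upper.tri(x$rho)], na.rm = TRUE)))
  invisible(x)
}

#' Gaussian-mixture decomposition of activation-time histograms
#'
#' Fits univariate Gaussian mixtures to activation times by
#' expectation-maximisation for each candidate component count and selects
#' the best count by BIC ([mclust::Mclust] with equal- and unequal-variance
#' models). Activation-time histograms of propagating waves decompose into a
#' few components whose means mark the successive activation stages of the
#' network. Input times are sorted before fitting, so the result does not
#' depend on input order.
#'
#' @param times finite activation times in seconds (>= 10 values).
#' @param k_candidates candidate component counts (default 1:6).
#' @param seed integer seed (EM initialisation is deterministic; the seed is
#'   fixed for reproducibility of any stochastic model-selection internals).
#' @return an object of class `mixture_fit`: `k`, `means` (ascending, s),
#'   `sds` (s), `weights` (sums to 1), `selection_scores` (named BIC per
#'   candidate k; larger is better), `loglik`, `n`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_activation_mixture <- function(times, k_candidates = 1:6, seed = 1L) {
  times <- times[is.finite(times)]
  if (length(times) < 10L) stop_param("need >= 10 finite activation times")
  if (!length(k_candidates)) stop_param("`k_candidates` must be non-empty")
  if (length(times) < 2L * max(k_candidates))
    stop_param("need at least 2 * max(k_candidates) observations")
  times <- sort(times)
  set.seed(as.integer(seed))
  fit <- mclust::Mclust(times, G = sort(unique(k_candidates)),
                        modelNames = c("E", "V"), verbose = FALSE)
  if (is.null(fit)) stop_param("mixture fit failed for every candidate k")
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(rep_len(as.numeric(fit$parameters$variance$sigmasq), fit$G))
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  bic <- fit$BIC
  scores <- apply(matrix(bic, nrow = nrow(bic),
                         dimnames = dimnames(bic)), 1L, max, na.rm = TRUE)
  structure(
    list(k = fit$G, means = mu[ord], sds = sig[ord], weights = w[ord],
         selection_scores = scores, loglik = fit$loglik, n = fit$n),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d components (BIC-selected), n = %d\n", x$k, x$n))
  for (i in seq_len(x$k))
    cat(sprintf("  t%d = %.3f s (sd %.3f, weight %.3f)\n",
                i, x$means[i], x$sds[i], x$weights[i]))
  invisible(x)
}

#' Fraction of cells responding to stimulation
#'
#' Proportion of activated cells with an exact (Clopper-Pearson) binomial
#' confidence interval.
#'
#' @param n_active number of activated cells (0 <= n_active <= n_total).
#' @param n_total total cells in the field of view (> 0).
#' @param conf_level confidence level for the interval.
#' @return list with `fraction`, `conf_int` (length 2), `n_active`, `n_total`.
#' @export
responsive_fraction <- function(n_active, n_total, conf_level = 0.95) {
  if (n_total <= 0) stop_param("`n_total` must be > 0")
  if (n_active < 0 || n_active > n_total)
    stop_param("`n_active` must lie in [0, n_total]")
  bt <- stats::binom.test(n_active, n_total, conf.level = conf_level)
  list(fraction = n_active / n_total,
       conf_int = as.numeric(bt$conf.int),
       n_active = n_active, n_total = n_total)
}
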