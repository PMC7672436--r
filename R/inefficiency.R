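# Statistical inefficiency of correlated force time series.

#' Statistical inefficiency of a time series
#'
#' Primary estimator: g = 1 + 2 * sum of normalized autocorrelations, with
#' the sum truncated at the first negative autocorrelation (integrated
#' autocorrelation time).  The blocking (Flyvbjerg-Petersen) estimator is
#' available as a cross-check.  The effective number of independent samples
#' is length(series)/g.
#'
#' @param series Ordered numeric samples (length >= 4).
#' @param method "iact" (default) or "blocking".
#' @param max_lag Autocorrelation cutoff for "iact" (default min(n-1, 5000)).
#' @return Estimated g (a constant series returns 1 by convention).  The
#'   estimator is noisy: for iid data values slightly below 1 can occur.
#' @export
statistical_inefficiency <- function(series, method = c("iact", "blocking"),
                                     max_lag = NULL) {
  method <- match.arg(method)
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4) stop("series too short (need >= 4 samples)")
  if (stats::var(x) == 0) return(1)
  if (method == "iact") .g_iact(x, max_lag) else .g_blocking(x)
}

# FFT autocovariance for all lags at O(n log n).
.autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(xc, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  ac[seq_len(n)] / n
}

.g_iact <- function(x, max_lag = NULL) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 5000L)
  ac <- .autocov_fft(x)
  rho <- ac[-1] / ac[1]
  upto <- min(max_lag, length(rho))
  rho <- rho[seq_len(upto)]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1L)]
  1 + 2 * sum(rho)
}

.g_blocking <- function(x, min_blocks = 20L) {
  n <- length(x)
  v0 <- stats::var(x)
  g <- 1
  b <- 1L
  while (n %/% (2L * b) >= min_blocks) {
    b <- 2L * b
    nb <- n %/% b
    means <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    est <- b * stats::var(means) / v0
    g <- max(g, est)
  }
  g
}
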