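#' Low-pass Fourier smoothing of a time series
#'
#' Discrete Fourier transform of the series, retention of the DC
#' component and the `m` lowest frequency modes (with their conjugates),
#' inverse transform.  The output is real, has the same length, and
#' preserves the series mean exactly; truncating modes can only reduce
#' the variance (Parseval).
#'
#' @param x real series (length >= 2m).
#' @param m number of retained low-frequency modes,
#'   `1 <= m <= length(x)/2`.
#' @return smoothed numeric series.
#' @export
fourier_filter <- function(x, m) {
  n <- length(x)
  if (m < 1 || m > n / 2) stop("m must satisfy 1 <= m <= length(x)/2")
  X <- stats::fft(x)
  keep <- c(seq_len(m + 1), if (m >= 1) seq(n - m + 1, n))
  X[setdiff(seq_len(n), keep)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}
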