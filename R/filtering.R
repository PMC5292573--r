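#' Design a linear-phase windowed-sinc FIR filter
#'
#' Returns the numerator coefficients of a symmetric (linear-phase) FIR
#' filter designed by the windowed-sinc method, for use with
#' [filtfilt_fft()].  A band whose lower edge is 0 gives a low-pass
#' design, otherwise a band-pass design.
#'
#' @param order filter order (number of taps minus one), at least 2.
#' @param band numeric vector `c(low_hz, high_hz)`; `low_hz = 0` is
#'   allowed for a low-pass filter.  Both edges must lie below the
#'   Nyquist frequency `fs / 2`.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of `order + 1` filter coefficients.
#' @examples
#' b <- design_windowed_sinc(64, c(0, 30), fs = 500)
#' sum(b)  # ~1: unit DC gain of the low-pass design
#' @seealso [filtfilt_fft()]
#' @export
design_windowed_sinc <- function(order, band, fs) {
  if (!is.numeric(order) || length(order) != 1 || order < 2 ||
      order != round(order))
    fcnet_stop("order must be an integer >= 2", "fcnet_invalid_order")
  if (!is.numeric(band) || length(band) != 2)
    fcnet_stop("band must be c(low_hz, high_hz)", "fcnet_invalid_band")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    fcnet_stop("fs must be a positive sampling rate in Hz", "fcnet_param")
  low <- band[1]; high <- band[2]
  if (low < 0 || high <= low || high >= fs / 2)
    fcnet_stop("band edges must satisfy 0 <= low < high < fs/2",
               "fcnet_invalid_band")
  nyq <- fs / 2
  b <- if (low <= 0) {
    signal::fir1(order, high / nyq, type = "low")
  } else {
    signal::fir1(order, c(low, high) / nyq, type = "pass")
  }
  as.numeric(b)
}

#' Zero-phase FIR filtering in the frequency domain
#'
#' Applies an FIR filter twice, once forwards and once backwards, so the
#' net transfer function is `|H(f)|^2` with exactly zero phase response.
#' Each channel is mirror-padded by the kernel length at both ends to
#' suppress border transients, the kernel is zero-padded to the working
#' FFT length (next power of two), and each pass is a frequency-domain
#' multiplication realizing plain causal convolution.  The result is
#' numerically identical (to round-off) to a direct two-pass time-domain
#' convolution on the padded data.
#'
#' If the kernel is asymmetric the two-pass scheme still cancels the
#' phase, i.e. the magnitude response is squared and the output has zero
#' phase distortion; linear-phase symmetry is only enforced by
#' [design_windowed_sinc()].
#'
#' @param x `signal_matrix` or channels-by-samples numeric matrix.
#' @param kernel numeric vector of FIR numerator coefficients, shorter
#'   than the signal.
#' @return A `signal_matrix` with the same dimensions, sampling rate and
#'   labels as the input.
#' @examples
#' x <- signal_matrix(matrix(rnorm(512), nrow = 1), fs = 100)
#' b <- design_windowed_sinc(40, c(5, 15), fs = 100)
#' y <- filtfilt_fft(x, b)
#' dim(y)
#' @export
filtfilt_fft <- function(x, kernel) {
  sm <- as_signal_matrix(x)
  if (!is.numeric(kernel) || length(kernel) < 1 || any(!is.finite(kernel)))
    fcnet_stop("kernel must be a finite numeric vector", "fcnet_param")
  d <- sm$data
  L <- length(kernel)
  N <- ncol(d)
  if (L >= N)
    fcnet_stop("kernel must be shorter than the signal",
               "fcnet_kernel_too_long")
  # mirror (reflection) padding, L samples at each end
  xp <- cbind(d[, seq(L + 1, 2), drop = FALSE],
              d,
              d[, seq(N - 1, N - L), drop = FALSE])
  Np <- ncol(xp)
  nfft <- next_pow2(Np + L)  # >= padded length + kernel: no circular wrap
  B <- fft(c(kernel, numeric(nfft - L)))

  causal_pass <- function(M) {
    X <- mvfft(rbind(t(M), matrix(0, nfft - Np, nrow(M))))
    Y <- Re(mvfft(X * B, inverse = TRUE)) / nfft
    t(Y[seq_len(Np), , drop = FALSE])
  }
  y <- causal_pass(xp)
  y <- causal_pass(y[, Np:1, drop = FALSE])[, Np:1, drop = FALSE]
  out <- y[, (L + 1):(Np - L), drop = FALSE]
  signal_matrix(out, fs = sm$fs, labels = sm$labels)
}
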