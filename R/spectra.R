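#' Welch segment-averaged auto- and cross-spectra
#'
#' Splits each channel into `n_segments` tapered, 50%-overlapping
#' segments (segment length `floor(2 * N / (n_segments + 1))`, hop
#' `floor(s * (1 - overlap))`), takes the FFT of each tapered segment and
#' retains the one-sided spectra.  Auto-spectra are averaged over
#' segments; per-segment complex cross-spectra are kept because the
#' weighted phase lag index averages their imaginary parts over
#' segments.
#'
#' @param x `signal_matrix` with a sampling rate, or a plain matrix plus
#'   `fs`.
#' @param n_segments target number of segments (default 5).
#' @param overlap fractional overlap between consecutive segments
#'   (default 0.5).
#' @param window taper name; currently `"hann"`.
#' @param fs sampling rate in Hz, required when `x` carries none.
#' @return Object of class `cross_spectra` with fields `freqs` (Hz),
#'   `auto` (channels x bins, segment-averaged power), `cross`
#'   (channels x channels x bins x segments complex array with
#'   `cross[i, j, , ] = Z_i * Conj(Z_j)`), `n_segments`,
#'   `segment_length`, `window`, `fs`, `labels`.
#' @seealso [imc()], [wpli()]
#' @export
welch_cross_spectra <- function(x, n_segments = 5, overlap = 0.5,
                                window = "hann", fs = NULL) {
  sm <- as_signal_matrix(x, fs = fs)
  if (is.null(sm$fs)) {
    if (is.null(fs))
      fcnet_stop("a sampling rate is required (fs)", "fcnet_param")
    sm$fs <- fs
  }
  if (n_segments < 1 || n_segments != round(n_segments))
    fcnet_stop("n_segments must be a positive integer", "fcnet_param")
  if (overlap < 0 || overlap >= 1)
    fcnet_stop("overlap must lie in [0, 1)", "fcnet_param")
  window <- match.arg(window, "hann")
  d <- sm$data
  N <- ncol(d)
  s <- floor(2 * N / (n_segments + 1))
  if (s < 8)
    fcnet_stop("signal too short for the requested segmentation",
               "fcnet_too_short")
  hop <- max(1L, floor(s * (1 - overlap)))
  starts <- seq(1L, N - s + 1L, by = hop)
  nseg <- length(starts)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(s - 1)) / (s - 1)))
  nf <- floor(s / 2) + 1
  nch <- nrow(d)

  Z <- array(complex(real = 0), dim = c(nch, nf, nseg))
  for (g in seq_len(nseg)) {
    seg <- d[, starts[g]:(starts[g] + s - 1), drop = FALSE]
    Fg <- mvfft(t(seg) * taper)          # s x nch
    Z[, , g] <- t(Fg[seq_len(nf), , drop = FALSE])
  }
  auto <- apply(Mod(Z)^2, c(1, 2), mean)
  cross <- array(complex(real = 0), dim = c(nch, nch, nf, nseg))
  for (g in seq_len(nseg)) {
    for (f in seq_len(nf)) {
      zf <- Z[, f, g]
      cross[, , f, g] <- zf %o% Conj(zf)
    }
  }
  structure(list(freqs = (0:(nf - 1)) * sm$fs / s, auto = auto,
                 cross = cross, n_segments = nseg, segment_length = s,
                 window = window, fs = sm$fs, labels = sm$labels),
            class = "cross_spectra")
}

band_bins <- function(cs, band) {
  if (!is.numeric(band) || length(band) != 2 || band[2] < band[1])
    fcnet_stop("band must be c(low_hz, high_hz)", "fcnet_empty_band")
  bins <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  if (length(bins) == 0)
    fcnet_stop("band does not intersect the available frequency bins",
               "fcnet_empty_band")
  bins
}

#' Imaginary part of the coherency
#'
#' Per frequency bin, the coherency is the segment-averaged cross-
#' spectrum normalized by the segment-averaged auto-spectra,
#' `C = <X> / sqrt(<|Z1|^2> <|Z2|^2>)`; its imaginary part is insensitive
#' to instantaneous (zero-lag) volume-conduction coupling.  Bins inside
#' `band` are averaged arithmetically.  The result is antisymmetric with
#' a zero diagonal and values in `[-1, 1]`.
#'
#' @param cs `cross_spectra` from [welch_cross_spectra()].
#' @param band numeric `c(low_hz, high_hz)` intersecting the frequency
#'   bins.
#' @return Antisymmetric channels-by-channels `connectivity_matrix`.
#' @export
imc <- function(cs, band) {
  stopifnot(inherits(cs, "cross_spectra"))
  bins <- band_bins(cs, band)
  nch <- nrow(cs$auto)
  acc <- matrix(0, nch, nch)
  for (b in bins) {
    Xm <- apply(cs$cross[, , b, , drop = FALSE], c(1, 2), mean)
    denom <- sqrt(outer(cs$auto[, b], cs$auto[, b]))
    acc <- acc + Im(Xm / denom)
  }
  v <- acc / length(bins)
  diag(v) <- 0
  connectivity_matrix(clamp(v, -1, 1), "imc", cs$labels)
}

#' Weighted phase lag index
#'
#' Per frequency bin, `|<Im X>| / <|Im X|>` with averages taken over
#' Welch segments; relative phases near zero lag carry small imaginary
#' cross-spectra and are therefore down-weighted.  A `0/0` bin is defined
#' as 0.  Bins inside `band` are averaged.  Requires at least two
#' segments (a single-segment wPLI is identically 1).
#'
#' @inheritParams imc
#' @return Symmetric channels-by-channels `connectivity_matrix` in
#'   `[0, 1]` with a zero diagonal.
#' @export
wpli <- function(cs, band) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (cs$n_segments < 2)
    fcnet_stop("wPLI needs at least 2 segments to average",
               "fcnet_insufficient_averages")
  bins <- band_bins(cs, band)
  nch <- nrow(cs$auto)
  acc <- matrix(0, nch, nch)
  for (b in bins) {
    ImX <- Im(cs$cross[, , b, ])
    num <- abs(apply(ImX, c(1, 2), mean))
    den <- apply(abs(ImX), c(1, 2), mean)
    r <- ifelse(den > 0, num / den, 0)
    acc <- acc + r
  }
  v <- acc / length(bins)
  diag(v) <- 0
  connectivity_matrix(clamp(v, 0, 1), "wpli", cs$labels)
}
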