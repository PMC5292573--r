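#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Builds, per channel, the complex analytic representation whose real
#' part is the input signal and whose imaginary part is its Hilbert
#' transform.  Intended for narrow-band (pre-filtered) input; this is not
#' enforced.  The spectrum of each resulting row vanishes at negative
#' frequencies (to round-off), and the real part equals the input
#' exactly.
#'
#' @param x `signal_matrix` or channels-by-samples numeric matrix with at
#'   least 4 samples.
#' @return Object of class `analytic_matrix` with fields `values`
#'   (complex channels-by-samples matrix), `fs`, `labels`.
#' @examples
#' t <- seq(0, 2, by = 1 / 500)
#' a <- analytic_signal(signal_matrix(cos(2 * pi * 10 * t), fs = 500))
#' # imaginary part approximates sin(2*pi*10*t) away from the borders
#' @export
analytic_signal <- function(x) {
  sm <- as_signal_matrix(x)
  d <- sm$data
  N <- ncol(d)
  if (N < 4)
    fcnet_stop("need at least 4 samples for the analytic signal",
               "fcnet_too_short")
  h <- numeric(N)
  if (N %% 2 == 0) {
    h[c(1, N / 2 + 1)] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((N + 1) / 2)] <- 2
  }
  A <- mvfft(t(d)) * h
  a <- t(mvfft(A, inverse = TRUE)) / N
  values <- matrix(complex(real = as.vector(d), imaginary = as.vector(Im(a))),
                   nrow = nrow(d), dimnames = dimnames(d))
  structure(list(values = values, fs = sm$fs, labels = sm$labels),
            class = "analytic_matrix")
}

#' Instantaneous phase of an analytic signal
#'
#' Four-quadrant angle of each complex sample, in radians within
#' `(-pi, pi]`.  `discard` records how many border samples at each end
#' are excluded from downstream averages (Hilbert border effect); the
#' phases themselves are kept so the matrix keeps the input shape.
#'
#' @param a `analytic_matrix` from [analytic_signal()].
#' @param discard nonnegative integer; number of samples ignored at each
#'   border by [plv()] and [pli()].  Must satisfy `2 * discard < samples`.
#' @return Object of class `phase_matrix` with fields `phases`,
#'   `discard`, `fs`, `labels`.
#' @export
instantaneous_phase <- function(a, discard = 0) {
  if (!inherits(a, "analytic_matrix"))
    fcnet_stop("a must come from analytic_signal()", "fcnet_param")
  N <- ncol(a$values)
  if (!is.numeric(discard) || length(discard) != 1 || discard < 0 ||
      discard != round(discard) || 2 * discard >= N)
    fcnet_stop("discard must be a nonnegative integer with 2*discard < samples",
               "fcnet_invalid_discard")
  structure(list(phases = Arg(a$values), discard = as.integer(discard),
                 fs = a$fs, labels = a$labels),
            class = "phase_matrix")
}

used_columns <- function(ph) {
  N <- ncol(ph$phases)
  (ph$discard + 1):(N - ph$discard)
}

connectivity_matrix <- function(values, kind, labels = NULL) {
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  structure(values, index_kind = kind, class = c("connectivity_matrix",
                                                 class(values)))
}

#' Phase locking value (mean phase coherence)
#'
#' For every channel pair, the modulus of the time-averaged unit phasor
#' of the relative phase, `|< exp(i (phi_k - phi_l)) >|`, computed over
#' the non-discarded samples.  Ranges from 0 (no phase synchronization)
#' to 1 (perfect phase synchronization); the diagonal is 1.
#'
#' @param ph `phase_matrix` from [instantaneous_phase()], at least 2
#'   channels.
#' @return Symmetric channels-by-channels `connectivity_matrix`.
#' @seealso [pli()], [plv_significance()]
#' @export
plv <- function(ph) {
  stopifnot(inherits(ph, "phase_matrix"))
  if (nrow(ph$phases) < 2)
    fcnet_stop("need at least 2 channels", "fcnet_param")
  P <- ph$phases[, used_columns(ph), drop = FALSE]
  Z <- exp(1i * P)
  M <- Mod(Z %*% Conj(t(Z))) / ncol(P)
  M <- clamp(M, 0, 1)
  diag(M) <- 1
  connectivity_matrix(M, "plv", ph$labels)
}

#' Phase lag index
#'
#' The modulus of the time-averaged sign of the wrapped relative phase.
#' Insensitive to zero-lag (volume-conduction) coupling: relative phases
#' symmetric around zero cancel.  An exactly zero relative phase
#' contributes 0 to the average.  The diagonal is 0.
#'
#' @inheritParams plv
#' @return Symmetric channels-by-channels `connectivity_matrix` in
#'   `[0, 1]`.
#' @export
pli <- function(ph) {
  stopifnot(inherits(ph, "phase_matrix"))
  nch <- nrow(ph$phases)
  if (nch < 2) fcnet_stop("need at least 2 channels", "fcnet_param")
  P <- ph$phases[, used_columns(ph), drop = FALSE]
  M <- matrix(0, nch, nch)
  for (k in seq_len(nch - 1)) {
    for (l in (k + 1):nch) {
      rel <- wrap_phase(P[k, ] - P[l, ])
      M[k, l] <- M[l, k] <- abs(mean(sign(rel)))
    }
  }
  connectivity_matrix(clamp(M, 0, 1), "pli", ph$labels)
}

#' Rayleigh-test significance of PLV values (Wilkie approximation)
#'
#' The PLV equals the mean resultant length of the circular distribution
#' of the relative phase, so its significance under the null of a
#' uniform phase distribution follows the Rayleigh test.  This uses
#' Wilkie's closed-form approximation
#' `p = exp(sqrt(1 + 4N + 4(N^2 - N*K)) - (1 + 2N))` with
#' `K = N * PLV^2`, clamped to `[0, 1]`.  It assumes approximately
#' independent consecutive phase samples.
#'
#' @param c symmetric PLV `connectivity_matrix` (or plain matrix of PLV
#'   values in `[0, 1]`).
#' @param n_samples effective number of samples averaged (samples minus
#'   twice the border discard); at least 2.
#' @return Object of class `pvalue_matrix` with fields `p` (symmetric,
#'   in `[0, 1]`) and `n_samples`.
#' @examples
#' plv_significance(matrix(c(1, 0.3, 0.3, 1), 2), n_samples = 100)$p
#' @export
plv_significance <- function(c, n_samples) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 2)
    fcnet_stop("n_samples must be an integer >= 2", "fcnet_invalid_n")
  v <- unclass(c)
  if (any(v < 0 | v > 1))
    fcnet_stop("PLV values must lie in [0, 1]", "fcnet_param")
  N <- n_samples
  K <- N * v^2
  p <- exp(sqrt(pmax(1 + 4 * N + 4 * (N^2 - N * K), 0)) - (1 + 2 * N))
  p <- clamp(p, 0, 1)
  dimnames(p) <- dimnames(v)
  structure(list(p = p, n_samples = N, fdr_mask = NULL),
            class = "pvalue_matrix")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up correction over the `m = n_ch * (n_ch - 1) / 2` upper-triangle
#' p-values of a `pvalue_matrix` (each channel pair tested once); the
#' resulting discovery mask is symmetrized.  A plain numeric vector of
#' p-values is also accepted, in which case the logical discovery vector
#' is returned directly.
#'
#' @param p `pvalue_matrix` from [plv_significance()], or numeric vector.
#' @param q FDR level in (0, 1).
#' @return The `pvalue_matrix` with an added logical `fdr_mask` (and the
#'   level `q`), or a logical vector for vector input.
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.03, 0.8), q = 0.05)
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    fcnet_stop("q must lie strictly between 0 and 1", "fcnet_invalid_level")
  if (is.numeric(p) && is.null(dim(p))) {
    if (any(p < 0 | p > 1)) fcnet_stop("p-values must lie in [0, 1]",
                                       "fcnet_param")
    return(p.adjust(p, method = "BH") <= q)
  }
  if (!inherits(p, "pvalue_matrix"))
    fcnet_stop("p must be a pvalue_matrix or numeric vector", "fcnet_param")
  pm <- p$p
  ut <- upper.tri(pm)
  mask <- matrix(FALSE, nrow(pm), ncol(pm), dimnames = dimnames(pm))
  mask[ut] <- p.adjust(pm[ut], method = "BH") <= q
  mask <- mask | t(mask)
  p$fdr_mask <- mask
  p$q <- q
  p
}
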