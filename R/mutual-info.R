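# Kraskov k-nearest-neighbour mutual information and marginal entropies.
#
# Ties between repeated values (common in quantized EEG) make neighbor
# counts ill-defined, so a deterministic, seeded jitter far below the
# data scale is added before any neighbor search.  The same jitter draw
# is shared by both arguments so that mi(x, y) == mi(y, x) exactly.

jitter_vector <- function(x, u, amplitude) {
  scale <- stats::sd(x)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  x + amplitude * scale * u
}

check_mi_input <- function(x, y = NULL, k) {
  if (!is.numeric(x) || any(!is.finite(x)))
    fcnet_stop("x must be a finite numeric vector", "fcnet_param")
  if (!is.null(y)) {
    if (!is.numeric(y) || any(!is.finite(y)))
      fcnet_stop("y must be a finite numeric vector", "fcnet_param")
    if (length(x) != length(y))
      fcnet_stop("x and y must have the same length", "fcnet_shape")
  }
  if (length(x) < 20)
    fcnet_stop("need at least 20 samples", "fcnet_too_short")
  if (k < 1 || k >= length(x) || k != round(k))
    fcnet_stop("k must satisfy 1 <= k < length(x)", "fcnet_invalid_k")
}

#' Kraskov k-nearest-neighbour mutual information (nats)
#'
#' Estimator of the mutual information between two continuous samples
#' using joint-space k-nearest-neighbour statistics (Kraskov algorithm
#' 1): for every point, `eps_i` is the max-norm distance to its k-th
#' neighbour in the joint space and `n_x`, `n_y` count the marginal
#' points strictly within `eps_i`; then
#' `MI = psi(k) - < psi(n_x + 1) + psi(n_y + 1) > + psi(N)`.
#'
#' Before the neighbour search each marginal is jittered (deterministic
#' seed, amplitude `jitter` times the sample standard deviation, to
#' break ties) and mapped to its empirical copula `(rank - 0.5) / N`, so
#' the estimate is exactly invariant under strictly monotone rescaling
#' of either marginal, as the mutual information itself is.  Small
#' negative estimates are possible under independence and are reported
#' as-is.
#'
#' @param x,y numeric sample vectors of equal length (at least 20).
#' @param k neighbour count, `1 <= k < length(x)` (default 4).
#' @param jitter tie-breaking jitter amplitude relative to the data
#'   scale (default `1e-10`).
#' @param seed integer seed for the jitter draw.
#' @return Mutual information estimate in nats.
#' @references Kraskov, Stoegbauer & Grassberger (2004) Phys Rev E 69,
#'   066138.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500)
#' kraskov_mi(x, y)
#' @export
kraskov_mi <- function(x, y, k = 4, jitter = 1e-10, seed = 1) {
  check_mi_input(x, y, k)
  n <- length(x)
  u <- with_seed(seed, runif(n, -0.5, 0.5))
  xr <- (rank(jitter_vector(x, u, jitter)) - 0.5) / n
  yr <- (rank(jitter_vector(y, u, jitter)) - 0.5) / n
  kraskov_mi_cpp(xr, yr, as.integer(k))
}

#' Kozachenko-Leonenko nearest-neighbour differential entropy (nats)
#'
#' `H = psi(N) - psi(k) + mean(log(2 r_i))` where `r_i` is the distance
#' from sample `i` to its k-th nearest neighbour.  Unlike
#' [kraskov_mi()], no copula transform is applied: differential entropy
#' is not invariant under rescaling.  The same deterministic tie-breaking
#' jitter is used.
#'
#' @param x numeric sample vector (at least 20 values).
#' @inheritParams kraskov_mi
#' @return Differential entropy estimate in nats.
#' @examples
#' kl_entropy(rnorm(1000))  # ~ 0.5 * log(2 * pi * exp(1)) = 1.4189
#' @export
kl_entropy <- function(x, k = 4, jitter = 1e-10, seed = 1) {
  check_mi_input(x, k = k)
  u <- with_seed(seed, runif(length(x), -0.5, 0.5))
  kl_entropy_cpp(jitter_vector(x, u, jitter), as.integer(k))
}

#' Symmetric uncertainty normalization of mutual information
#'
#' `U(X, Y) = 2 MI / (H(X) + H(Y))`, clamped to `[0, 1]`.
#'
#' @param mi mutual information in nats.
#' @param hx,hy marginal entropies in nats; their sum must be positive.
#' @return Value in `[0, 1]`.
#' @export
symmetric_uncertainty <- function(mi, hx, hy) {
  if (!is.finite(hx + hy) || hx + hy <= 0)
    fcnet_stop("entropy sum must be positive", "fcnet_invalid_normalizer")
  clamp(2 * mi / (hx + hy), 0, 1)
}

#' Total-correlation normalization of mutual information
#'
#' `MI / min(H(X), H(Y))`, clamped to `[0, 1]`.
#'
#' @inheritParams symmetric_uncertainty
#' @return Value in `[0, 1]`.
#' @export
total_correlation_norm <- function(mi, hx, hy) {
  if (!is.finite(min(hx, hy)) || min(hx, hy) <= 0)
    fcnet_stop("minimum marginal entropy must be positive",
               "fcnet_invalid_normalizer")
  clamp(mi / min(hx, hy), 0, 1)
}

#' Pairwise mutual information matrix
#'
#' Applies [kraskov_mi()] to every channel pair and [kl_entropy()] to
#' every channel.  The diagonal is reported as `NA`: the self-MI of
#' continuous data diverges.  When a normalization is requested, raw MI
#' values are floored at 0 first so the output respects `[0, 1]`.
#'
#' @param x `signal_matrix` or channels-by-samples matrix with at least
#'   2 channels.
#' @param normalization one of `"none"`, `"symmetric_uncertainty"`,
#'   `"total_correlation"`.
#' @param bits if `TRUE`, report unnormalized MI and entropies in bits
#'   instead of nats (values divided by `log(2)` at output only).
#' @inheritParams kraskov_mi
#' @return Object of class `mi_result` with fields `mi` (symmetric,
#'   `NA` diagonal), `entropies`, `k`, `normalization`, `bits`, `seed`.
#' @export
mi_matrix <- function(x, k = 4, normalization = c("none",
                                                  "symmetric_uncertainty",
                                                  "total_correlation"),
                      bits = FALSE, jitter = 1e-10, seed = 1) {
  normalization <- match.arg(normalization)
  sm <- as_signal_matrix(x)
  d <- sm$data
  nch <- nrow(d)
  if (nch < 2) fcnet_stop("need at least 2 channels", "fcnet_param")
  H <- vapply(seq_len(nch),
              function(i) kl_entropy(d[i, ], k = k, jitter = jitter,
                                     seed = seed),
              numeric(1))
  M <- matrix(NA_real_, nch, nch, dimnames = list(sm$labels, sm$labels))
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      v <- kraskov_mi(d[i, ], d[j, ], k = k, jitter = jitter, seed = seed)
      if (normalization == "symmetric_uncertainty") {
        v <- symmetric_uncertainty(max(v, 0), H[i], H[j])
      } else if (normalization == "total_correlation") {
        v <- total_correlation_norm(max(v, 0), H[i], H[j])
      }
      M[i, j] <- M[j, i] <- v
    }
  }
  Hout <- H
  if (bits) {
    Hout <- H / log(2)
    if (normalization == "none") M <- M / log(2)
  }
  names(Hout) <- sm$labels
  structure(list(mi = M, entropies = Hout, k = k,
                 normalization = normalization, bits = bits, seed = seed),
            class = "mi_result")
}
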