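# Generalized synchronization: Takens delay embedding and the four
# conditioned-neighbour indices S, H, M, L.

#' Takens delay embedding
#'
#' Builds the delayed state vectors
#' `X_i = (x(t_i), x(t_i + tau), ..., x(t_i + (m - 1) tau))` with origin
#' times `t_i = 1 + (i - 1) * stride`; the state count is
#' `floor((N - (m - 1) * tau - 1) / stride) + 1`.
#'
#' @param x numeric sample vector.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @param stride subsampling step over embedded states (default 1);
#'   useful when the reconstructed space is densely populated.
#' @return Object of class `state_space` with fields `states`
#'   (`N_v x m` matrix), `origins` (time index of each state's first
#'   component), `m`, `tau`, `stride`.
#' @examples
#' embed_delay(1:10, m = 3, tau = 2)$states
#' @export
embed_delay <- function(x, m, tau, stride = 1) {
  if (!is.numeric(x) || any(!is.finite(x)))
    fcnet_stop("x must be a finite numeric vector", "fcnet_param")
  if (m < 1 || tau < 1 || stride < 1 ||
      any(c(m, tau, stride) != round(c(m, tau, stride))))
    fcnet_stop("m, tau and stride must be positive integers", "fcnet_param")
  N <- length(x)
  span <- (m - 1) * tau
  if (N <= span + 1)
    fcnet_stop("series too short for this embedding", "fcnet_too_short")
  nv <- floor((N - span - 1) / stride) + 1
  origins <- 1 + (seq_len(nv) - 1) * stride
  states <- vapply(0:(m - 1), function(d) x[origins + d * tau],
                   numeric(nv))
  states <- matrix(states, nrow = nv)
  structure(list(states = states, origins = as.integer(origins),
                 m = as.integer(m), tau = as.integer(tau),
                 stride = as.integer(stride)),
            class = "state_space")
}

#' Neighbour-distance statistics for generalized synchronization
#'
#' For each state `X_i`, computes the Euclidean-distance statistics
#' underlying the S, H, M and L indices: the mean distance to its own
#' `k` nearest neighbours (`R_knn`), the mean distance to all admissible
#' states (`R_all`), the mean distance to the `k` Y-conditioned partners
#' (`R_cond`, the states of X at the time indices of Y's nearest
#' neighbours), and the mean rank of those partners among all admissible
#' distances from `X_i` (`G_cond`, nearest = rank 1).  Admissible states
#' exclude the state itself and anything within `theiler` samples of its
#' origin time (temporal Theiler exclusion, so autocorrelated neighbours
#' do not masquerade as state-space neighbours; `theiler = 0` reproduces
#' the plain index definitions).  Distance ties are broken stably by
#' time index.
#'
#' @param sx,sy aligned `state_space` objects (identical origin times).
#' @param k neighbour count.
#' @param theiler temporal exclusion half-window in samples.
#' @return Object of class `gs_distance_summary` with fields `R_knn`,
#'   `R_all`, `R_cond`, `G_cond`, `G_knn` (own-neighbour mean rank,
#'   `(k + 1) / 2` by construction), `G_all` (per-state admissible
#'   count / 2), `neighbor_idx` (own and conditioned state indices),
#'   `N_v`, `k`, `theiler`.
#' @seealso [gs_indices()], [gs_matrix()]
#' @export
neighbor_statistics <- function(sx, sy, k, theiler = 0) {
  if (!inherits(sx, "state_space") || !inherits(sy, "state_space"))
    fcnet_stop("sx and sy must be state_space objects", "fcnet_param")
  if (!identical(sx$origins, sy$origins))
    fcnet_stop("state spaces are not aligned (different origin times)",
               "fcnet_alignment")
  nv <- nrow(sx$states)
  if (k < 1 || k != round(k))
    fcnet_stop("k must be a positive integer", "fcnet_invalid_k")
  if (theiler < 0 || theiler != round(theiler))
    fcnet_stop("theiler must be a nonnegative integer", "fcnet_param")
  # worst-case admissible count must still exceed k
  excl <- 2 * floor(theiler / sx$stride) + 1
  if (nv - excl < k + 1)
    fcnet_stop("too few admissible states for k and theiler",
               "fcnet_alignment")
  res <- gs_stats_cpp(sx$states, sy$states, sx$origins,
                      as.integer(k), as.integer(theiler))
  structure(c(res, list(N_v = nv, k = as.integer(k),
                        theiler = as.integer(theiler))),
            class = "gs_distance_summary")
}

#' Generalized-synchronization indices for one directed pair
#'
#' Evaluates, from a [neighbor_statistics()] summary for the directed
#' pair (X conditioned on Y):
#' \itemize{
#'   \item `S = mean(R_knn / R_cond)`, in `(0, 1]`, 1 for identical
#'     signals;
#'   \item `H = mean(log(R_all / R_cond))`, ~0 for independent signals
#'     regardless of attractor size, unbounded above;
#'   \item `M = mean((R_all - R_cond) / (R_all - R_knn))`, ~0 for
#'     independent and 1 for identical signals;
#'   \item `L = mean((G_all - G_cond) / (G_all - G_knn))`, the ranked
#'     analogue of M, more robust to outliers.
#' }
#'
#' @param summary `gs_distance_summary` from [neighbor_statistics()].
#' @return Named list with scalars `S`, `H`, `M`, `L`.
#' @export
gs_indices <- function(summary) {
  if (!inherits(summary, "gs_distance_summary"))
    fcnet_stop("summary must come from neighbor_statistics()", "fcnet_param")
  R_knn <- summary$R_knn; R_all <- summary$R_all
  R_cond <- summary$R_cond; G_cond <- summary$G_cond
  G_all <- summary$G_all
  G_knn <- (summary$k + 1) / 2
  if (any(R_cond <= 0) || any(R_all - R_knn <= 0) || any(G_all - G_knn <= 0))
    fcnet_stop("degenerate input (constant or near-constant series)",
               "fcnet_degenerate_input")
  list(S = mean(R_knn / R_cond),
       H = mean(log(R_all / R_cond)),
       M = mean((R_all - R_cond) / (R_all - R_knn)),
       L = mean((G_all - G_cond) / (G_all - G_knn)))
}

#' Directed generalized-synchronization matrices
#'
#' Computes all four indices jointly for every ordered channel pair.
#' Entry `[i, j]` is `Index(X_i | X_j)`: channel `i`'s state space
#' conditioned on channel `j`'s neighbour time indices, i.e. how well
#' channel `j`'s neighbourhoods project into channel `i`'s space.  The
#' diagonals of S, M and L are fixed at their identical-signal value 1;
#' the diagonal of H holds each channel's maximal attainable value
#' `mean(log(R_all / R_knn))`.
#'
#' Channel pairs are processed one at a time (distances for a pair are
#' never kept beyond its computation), which bounds memory at the cost
#' of re-deriving each channel's own-neighbour statistics per pair.
#'
#' @param x `signal_matrix` or channels-by-samples matrix, >= 2
#'   channels.
#' @param m,tau embedding dimension and delay (required; no automatic
#'   selection heuristics are provided).
#' @param k neighbour count (default 4).
#' @param theiler temporal exclusion window; defaults to `m * tau`.
#'   Use 0 for the plain textbook definitions.
#' @param stride embedded-state subsampling step (default 1).
#' @return Object of class `gs_result` with directed matrices `S`, `H`,
#'   `M`, `L` and the embedding parameters.
#' @export
gs_matrix <- function(x, m, tau, k = 4, theiler = NULL, stride = 1) {
  sm <- as_signal_matrix(x)
  nch <- nrow(sm$data)
  if (nch < 2) fcnet_stop("need at least 2 channels", "fcnet_param")
  if (is.null(theiler)) theiler <- m * tau
  emb <- lapply(seq_len(nch), function(i)
    embed_delay(sm$data[i, ], m = m, tau = tau, stride = stride))
  mk <- function() matrix(0, nch, nch, dimnames = list(sm$labels, sm$labels))
  S <- mk(); H <- mk(); M <- mk(); L <- mk()
  for (i in seq_len(nch)) {
    for (j in seq_len(nch)) {
      if (i == j) {
        own <- gs_indices(neighbor_statistics(emb[[i]], emb[[i]], k = k,
                                              theiler = theiler))
        S[i, i] <- M[i, i] <- L[i, i] <- 1
        H[i, i] <- own$H
      } else {
        idx <- gs_indices(neighbor_statistics(emb[[i]], emb[[j]], k = k,
                                              theiler = theiler))
        S[i, j] <- idx$S; H[i, j] <- idx$H
        M[i, j] <- idx$M; L[i, j] <- idx$L
      }
    }
  }
  structure(list(S = S, H = H, M = M, L = L, m = as.integer(m),
                 tau = as.integer(tau), k = as.integer(k),
                 theiler = as.integer(theiler), stride = as.integer(stride),
                 labels = sm$labels),
            class = "gs_result")
}
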