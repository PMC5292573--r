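# Weighted network measures on functional-connectivity matrices.
# Link lengths are the inverse weights, f(w) = 1/w; absent links (w = 0)
# have infinite length.

#' Node strength
#'
#' Sum of each node's link weights.  For a symmetric (undirected) matrix
#' a named vector of nodal strengths is returned; for a directed matrix,
#' a list with `out` (row sums) and `in` (column sums).  The global
#' strength of a network is the mean of the nodal values.
#'
#' @param W square nonnegative weight matrix (zero self-weights
#'   expected).
#' @return Numeric vector, or list with `out` and `in` components.
#' @export
node_strength <- function(W) {
  check_adjacency(W)
  if (isSymmetric(unname(W))) {
    s <- rowSums(W)
    names(s) <- rownames(W)
    s
  } else {
    list(out = rowSums(W), `in` = colSums(W))
  }
}

#' Rescale weights to the unit interval
#'
#' Divides all weights by the maximum weight, mapping them into
#' `[0, 1]` as required by [weighted_clustering()].  Kept explicit (not
#' applied silently) so results remain reproducible.
#'
#' @param W square nonnegative weight matrix with at least one positive
#'   weight.
#' @return Rescaled matrix with maximum weight 1.
#' @export
rescale_weights <- function(W) {
  check_adjacency(W)
  mx <- max(W)
  if (mx <= 0) fcnet_stop("all weights are zero", "fcnet_param")
  W / mx
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle intensity around each node:
#' `t_i = 0.5 * sum_{j,h} (w_ij w_ih w_jh)^(1/3)` and
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `k_i` the number of nonzero
#' links (`C_i = 0` for `k_i < 2`).  Weights must lie in `[0, 1]` (the
#' geometric mean exceeds 1 otherwise); see [rescale_weights()].
#'
#' @param W square symmetric weight matrix with entries in `[0, 1]` and
#'   zero diagonal.
#' @return List with `nodal` (per-node C_i) and `global` (their mean).
#' @export
weighted_clustering <- function(W) {
  check_adjacency(W, unit_weights = TRUE, zero_diag = TRUE,
                  symmetric = TRUE)
  k <- rowSums(W != 0)
  W3 <- W^(1 / 3)
  t_i <- diag(W3 %*% W3 %*% W3) / 2
  C <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  names(C) <- rownames(W)
  list(nodal = C, global = mean(C))
}

# Dijkstra from one source over a link-length matrix (Inf = no link).
# O(n^2) extract-min; tie tolerance only matters for path counting, not
# for plain distances.
dijkstra_single <- function(len, s) {
  n <- nrow(len)
  dist <- rep(Inf, n)
  dist[s] <- 0
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    relax <- which(!visited & is.finite(len[u, ]))
    if (length(relax)) {
      alt <- dist[u] + len[u, relax]
      upd <- alt < dist[relax]
      dist[relax[upd]] <- alt[upd]
    }
  }
  dist
}

length_matrix <- function(W) {
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- Inf
  len
}

#' All-pairs shortest weighted path lengths
#'
#' Link length is the inverse weight, `f(w) = 1/w` (a zero weight means
#' no link).  Runs Dijkstra's algorithm from every source; unreachable
#' pairs are reported as `Inf`.
#'
#' @param W square nonnegative weight matrix.
#' @return Distance matrix with zero diagonal (symmetric for symmetric
#'   input).
#' @export
shortest_path_lengths <- function(W) {
  check_adjacency(W)
  len <- length_matrix(W)
  n <- nrow(W)
  D <- t(vapply(seq_len(n), function(s) dijkstra_single(len, s),
                numeric(n)))
  diag(D) <- 0
  dimnames(D) <- dimnames(W)
  D
}

#' Characteristic path length
#'
#' `L_i` is the mean finite distance from node `i` to the other nodes
#' (unreachable pairs are excluded from the average and counted
#' explicitly rather than propagated as infinities); the global `L` is
#' the mean over nodes with at least one reachable partner.
#'
#' @param d distance matrix from [shortest_path_lengths()].
#' @return List with `nodal` (`NA` for isolated nodes), `global`, and
#'   `unreachable_pairs` (count of ordered node pairs with no connecting
#'   path).
#' @export
char_path_length <- function(d) {
  if (!is_square(d) || !is.numeric(d))
    fcnet_stop("d must be a square numeric distance matrix", "fcnet_param")
  n <- nrow(d)
  off <- !diag(n)
  nodal <- vapply(seq_len(n), function(i) {
    v <- d[i, -i]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (all(is.na(nodal)))
    fcnet_stop("graph is completely disconnected", "fcnet_disconnected")
  list(nodal = nodal, global = mean(nodal, na.rm = TRUE),
       unreachable_pairs = sum(!is.finite(d[off])))
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Fraction of shortest paths passing through each node, accumulated by
#' Brandes' single-source dependency scheme over Dijkstra orderings.
#' All co-optimal predecessors are kept (distances compared with an
#' absolute tolerance of 1e-12 so float round-off cannot split a tie),
#' path endpoints are excluded, and the sum over ordered source-target
#' pairs is normalized by `(n - 1)(n - 2)`, which maps the centre of a
#' star graph to exactly 1.  The undirected weighted graph must have a
#' zero diagonal.  The distance matrix is returned alongside, as both
#' come out of the same sweep.
#'
#' @param W square symmetric nonnegative weight matrix with zero
#'   diagonal.
#' @return List with `betweenness` (per-node values in `[0, 1]`) and
#'   `distances` (the shortest-path matrix).
#' @export
betweenness_centrality <- function(W) {
  check_adjacency(W, zero_diag = TRUE, symmetric = TRUE)
  n <- nrow(W)
  len <- length_matrix(W)
  tol <- 1e-12
  b <- numeric(n)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    visited <- rep(FALSE, n)
    order_popped <- integer(0)
    repeat {
      cand <- which(!visited & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      visited[u] <- TRUE
      order_popped <- c(order_popped, u)
      for (v in which(!visited & is.finite(len[u, ]))) {
        alt <- dist[u] + len[u, v]
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (alt <= dist[v] + tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_popped)) {
      for (u in preds[[w]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      }
      if (w != s) b[w] <- b[w] + delta[w]
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  if (n > 2) b <- b / ((n - 1) * (n - 2))
  names(b) <- rownames(W)
  dimnames(D) <- dimnames(W)
  list(betweenness = b, distances = D)
}
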