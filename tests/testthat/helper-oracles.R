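# Independent reference implementations used as oracles.  They share no
# code with the package paths they check: direct time-domain
# convolution, explicit distance matrices, Floyd-Warshall, exhaustive
# path enumeration.

# causal FIR convolution, zero initial conditions, O(N * L) loop
conv_causal <- function(x, b) {
  N <- length(x)
  L <- length(b)
  y <- numeric(N)
  for (n in seq_len(N)) {
    kmax <- min(L, n)
    y[n] <- sum(b[seq_len(kmax)] * x[n - seq_len(kmax) + 1])
  }
  y
}

# mirror-pad, filter forward, reverse, filter again, reverse, unpad
oracle_filtfilt <- function(x, b) {
  N <- length(x)
  L <- length(b)
  xp <- c(x[(L + 1):2], x, x[(N - 1):(N - L)])
  y <- conv_causal(xp, b)
  y <- rev(conv_causal(rev(y), b))
  y[(L + 1):(L + N)]
}

# discrete frequency response of an FIR kernel at frequencies f (Hz)
fir_response <- function(b, f, fs) {
  vapply(f, function(fi) {
    Mod(sum(b * exp(-2i * pi * fi * (seq_along(b) - 1) / fs)))
  }, numeric(1))
}

# explicit-distance-matrix evaluation of the GS indices S, H, M, L
gs_oracle <- function(x, y, m, tau, k, theiler = 0, stride = 1) {
  N <- length(x)
  span <- (m - 1) * tau
  nv <- floor((N - span - 1) / stride) + 1
  org <- 1 + (0:(nv - 1)) * stride
  emb <- function(v) {
    matrix(vapply(0:(m - 1), function(d) v[org + d * tau], numeric(nv)),
           nrow = nv)
  }
  DX <- as.matrix(dist(emb(x)))
  DY <- as.matrix(dist(emb(y)))
  R_knn <- R_all <- R_cond <- G_cond <- G_all <- numeric(nv)
  for (i in seq_len(nv)) {
    adm <- setdiff(which(abs(org - org[i]) > theiler), i)
    oX <- adm[order(DX[i, adm], adm)]   # stable ties by time index
    oY <- adm[order(DY[i, adm], adm)]
    aX <- oX[seq_len(k)]
    bY <- oY[seq_len(k)]
    R_knn[i] <- mean(DX[i, aX])
    R_all[i] <- mean(DX[i, adm])
    R_cond[i] <- mean(DX[i, bY])
    G_cond[i] <- mean(match(bY, oX))
    G_all[i] <- length(adm) / 2
  }
  list(S = mean(R_knn / R_cond),
       H = mean(log(R_all / R_cond)),
       M = mean((R_all - R_cond) / (R_all - R_knn)),
       L = mean((G_all - G_cond) / (G_all - (k + 1) / 2)))
}

# package-facing wrapper: indices for one directed pair x | y
gs_pair <- function(x, y, m, tau, k, theiler = 0, stride = 1) {
  sx <- embed_delay(x, m, tau, stride)
  sy <- embed_delay(y, m, tau, stride)
  gs_indices(neighbor_statistics(sx, sy, k = k, theiler = theiler))
}

# all-pairs shortest paths by Floyd-Warshall on a link-length matrix
floyd_warshall <- function(W) {
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- 0
  n <- nrow(len)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (len[i, k] + len[k, j] < len[i, j])
          len[i, j] <- len[i, k] + len[k, j]
      }
    }
  }
  len
}

# betweenness by exhaustive enumeration of all simple paths
enum_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- Inf
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path, used, d) {
      last <- path[length(path)]
      if (last == t) {
        res[[length(res) + 1]] <<- list(path = path, d = d)
        return(invisible())
      }
      for (v in which(is.finite(len[last, ]))) {
        if (!used[v]) {
          used[v] <- TRUE
          rec(c(path, v), used, d + len[last, v])
          used[v] <- FALSE
        }
      }
    }
    used <- rep(FALSE, n)
    used[s] <- TRUE
    rec(s, used, 0)
    res
  }
  b <- numeric(n)
  for (h in seq_len(n)) {
    for (j in seq_len(n)) {
      if (h == j) next
      ps <- all_paths(h, j)
      if (length(ps) == 0) next
      ds <- vapply(ps, `[[`, numeric(1), "d")
      sel <- which(ds <= min(ds) + tol)
      for (i in seq_len(n)) {
        if (i == h || i == j) next
        through <- sum(vapply(sel, function(q) i %in% ps[[q]]$path,
                              logical(1)))
        b[i] <- b[i] + through / length(sel)
      }
    }
  }
  b / ((n - 1) * (n - 2))
}

# convenience: PLV/PLI between the first two channels of a signal matrix
phase_pair <- function(sm, discard = 0) {
  ph <- instantaneous_phase(analytic_signal(sm), discard)
  list(plv = plv(ph)[1, 2], pli = pli(ph)[1, 2])
}
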