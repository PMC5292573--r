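# Seeded generators of coupled signals and random graphs.  Every
# generator is a pure function of its parameters: per-channel draws come
# from independent seeded streams derived from the single integer seed,
# so adding a channel never disturbs the others.

channel_seed <- function(seed, channel, salt = 0L) {
  (abs(seed) + channel * 1000003 + salt * 7919) %% .Machine$integer.max
}

#' Coupled phase-walk oscillators
#'
#' Narrow-band oscillators whose instantaneous phase performs a slow
#' random walk (step s.d. 0.1 rad/sample), so the phase-locking value is
#' below 1 at intermediate coupling and the Rayleigh significance test
#' has a non-degenerate null.  Channel 1 carries its own walk
#' `theta_1`; every further channel `j` mixes an independent walk
#' `theta_j` with channel 1's in proportion `coupling`, plus a constant
#' imposed lag:
#' `x_j(t) = sin(2 pi f0 t + (1 - eps) theta_j + eps theta_1 + lag) + noise`.
#' At `coupling = 1` all channels share one phase walk and differ only
#' by `lag_rad` and independent additive noise.
#'
#' @param n_channels number of channels (>= 1).
#' @param n_samples samples per channel.
#' @param fs sampling rate in Hz.
#' @param f0 oscillation frequency in Hz, below `fs / 2`.
#' @param coupling phase-coupling strength `eps` in `[0, 1]`.
#' @param lag_rad constant phase lag (radians) imposed on channels > 1.
#' @param noise_sd additive white-noise standard deviation.
#' @param seed integer seed.
#' @return A `signal_matrix` (`n_channels x n_samples`, sampling rate
#'   `fs`).
#' @export
gen_coupled_oscillators <- function(n_channels = 2, n_samples = 2000,
                                    fs = 500, f0 = 10, coupling = 0,
                                    lag_rad = 0, noise_sd = 0.1, seed = 1) {
  if (n_channels < 1 || n_samples < 2 || fs <= 0 || f0 <= 0 ||
      f0 >= fs / 2 || coupling < 0 || coupling > 1 || noise_sd < 0)
    fcnet_stop("invalid oscillator specification", "fcnet_param")
  tt <- (seq_len(n_samples) - 1) / fs
  base <- 2 * pi * f0 * tt
  walk <- function(ch) with_seed(channel_seed(seed, ch),
                                 cumsum(rnorm(n_samples, 0, 0.1)))
  noise <- function(ch) with_seed(channel_seed(seed, ch, salt = 1L),
                                  rnorm(n_samples, 0, noise_sd))
  theta1 <- walk(1)
  d <- matrix(0, n_channels, n_samples)
  d[1, ] <- sin(base + theta1) + noise(1)
  if (n_channels > 1) {
    for (j in 2:n_channels) {
      th <- (1 - coupling) * walk(j) + coupling * theta1 + lag_rad
      d[j, ] <- sin(base + th) + noise(j)
    }
  }
  signal_matrix(d, fs = fs)
}

#' Unidirectionally coupled Henon maps
#'
#' The standard driver-response benchmark for generalized
#' synchronization: an autonomous Henon map in the chaotic regime
#' (`a = 1.4`, `b = 0.3`) drives a second, identically parameterized map
#' whose quadratic term mixes driver and response states with weight
#' `coupling`:
#' \preformatted{x[n+1] = 1.4 - x[n]^2 + 0.3 x[n-1]
#' y[n+1] = 1.4 - (C x[n] + (1 - C) y[n]) y[n] + 0.3 y[n-1]}
#' The transient (`burn_in` samples) is discarded.  If a trajectory
#' diverges for a given seed, the generator restarts from a new derived
#' seed (with a message) and raises an error after 10 attempts.
#'
#' @param n_samples retained samples per channel.
#' @param coupling coupling strength `C` in `[0, 1]`.
#' @param burn_in discarded transient samples (>= 100).
#' @param seed integer seed for the random initial conditions.
#' @return A `signal_matrix` with channels `driver` and `response`.
#' @export
gen_unidir_henon <- function(n_samples = 2000, coupling = 0, burn_in = 500,
                             seed = 1) {
  if (n_samples < 2 || coupling < 0 || coupling > 1 || burn_in < 100)
    fcnet_stop("invalid coupled-map specification", "fcnet_param")
  total <- n_samples + burn_in
  for (attempt in 0:9) {
    init <- with_seed(channel_seed(seed, 1, salt = attempt),
                      runif(4, -0.1, 0.1))
    x <- numeric(total); y <- numeric(total)
    x[1:2] <- init[1:2]; y[1:2] <- init[3:4]
    ok <- TRUE
    for (n in 2:(total - 1)) {
      x[n + 1] <- 1.4 - x[n]^2 + 0.3 * x[n - 1]
      y[n + 1] <- 1.4 - (coupling * x[n] + (1 - coupling) * y[n]) * y[n] +
        0.3 * y[n - 1]
      if (!is.finite(x[n + 1]) || !is.finite(y[n + 1]) ||
          abs(x[n + 1]) > 1e6 || abs(y[n + 1]) > 1e6) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      if (attempt > 0)
        message(sprintf("gen_unidir_henon: trajectory diverged; restarted %d time(s)",
                        attempt))
      d <- rbind(x[(burn_in + 1):total], y[(burn_in + 1):total])
      return(signal_matrix(d, labels = c("driver", "response")))
    }
  }
  fcnet_stop("coupled Henon maps diverged after 10 restarts",
             "fcnet_instability")
}

#' Random weighted graph
#'
#' Erdos-Renyi topology: each of the `n (n - 1) / 2` possible undirected
#' edges is present independently with probability `density`; present
#' edges receive uniform `(0, 1]` weights.  The diagonal is zero.
#'
#' @param n node count (>= 2).
#' @param density edge probability in `(0, 1]`.
#' @param seed integer seed.
#' @return Symmetric `n x n` weight matrix with attribute `edge_count`
#'   (number of undirected links).
#' @export
gen_random_weighted_graph <- function(n, density, seed = 1) {
  if (n < 2 || n != round(n) || density <= 0 || density > 1)
    fcnet_stop("need n >= 2 and density in (0, 1]", "fcnet_param")
  m <- n * (n - 1) / 2
  draws <- with_seed(channel_seed(seed, 1),
                     list(present = runif(m) < density,
                          w = 1 - runif(m)))  # weights in (0, 1]
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- ifelse(draws$present, draws$w, 0)
  W <- W + t(W)
  attr(W, "edge_count") <- sum(draws$present)
  W
}
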