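# Internal helpers shared across modules.

fcnet_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fcnet_error")))
}

# Evaluate `code` with the RNG temporarily seeded; global RNG state restored.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2^ceiling(log2(n))
}

# Wrap angles to (-pi, pi]; exact zero stays zero.
wrap_phase <- function(p) Arg(exp(1i * p))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_square <- function(W) is.matrix(W) && nrow(W) == ncol(W)

check_adjacency <- function(W, unit_weights = FALSE, zero_diag = FALSE,
                            symmetric = FALSE) {
  if (!is_square(W) || !is.numeric(W))
    fcnet_stop("adjacency matrix must be a square numeric matrix",
               "fcnet_param")
  if (any(!is.finite(W)))
    fcnet_stop("adjacency matrix must contain finite values only",
               "fcnet_param")
  if (any(W < 0))
    fcnet_stop("adjacency weights must be nonnegative", "fcnet_param")
  if (zero_diag && any(diag(W) != 0))
    fcnet_stop("adjacency matrix must have a zero main diagonal (self-loops are not accepted)",
               "fcnet_self_loop")
  if (unit_weights && any(W > 1))
    fcnet_stop("weights must lie in [0, 1]; rescale first (see rescale_weights())",
               "fcnet_unnormalized_weights")
  if (symmetric && !isSymmetric(unname(W)))
    fcnet_stop("adjacency matrix must be symmetric (undirected graph)",
               "fcnet_param")
  invisible(W)
}
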