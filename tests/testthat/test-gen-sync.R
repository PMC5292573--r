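test_that("delay embedding builds the delayed vectors with the stated state count", {
  e <- embed_delay(1:10, m = 3, tau = 2)
  expect_identical(nrow(e$states), 6L)
  expect_equal(e$states[1, ], c(1, 3, 5))
  expect_equal(e$states[6, ], c(6, 8, 10))

  e1 <- embed_delay(rnorm(50), m = 1, tau = 3)
  expect_identical(nrow(e1$states), 50L)

  e2 <- embed_delay(1:9, m = 2, tau = 1, stride = 2)
  expect_equal(e2$states, rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
  expect_error(embed_delay(1:5, m = 3, tau = 2), class = "fcnet_too_short")
})

test_that("self-conditioning reproduces own-neighbour statistics; ranks are forced to (k+1)/2", {
  set.seed(14)
  s <- embed_delay(rnorm(120), m = 2, tau = 1)
  ns <- neighbor_statistics(s, s, k = 3, theiler = 2)
  expect_identical(ns$R_cond, ns$R_knn)
  expect_true(all(ns$G_cond == 2))            # (k + 1) / 2
  expect_true(all(ns$G_knn == 2))
  expect_error(neighbor_statistics(s, s, k = 3, theiler = nrow(s$states)),
               class = "fcnet_alignment")
  s2 <- embed_delay(rnorm(120), m = 2, tau = 1, stride = 2)
  expect_error(neighbor_statistics(s, s2, k = 3),
               class = "fcnet_alignment")
})

test_that("hand-placed states match the exhaustive distance-matrix computation", {
  x <- c(0, 1, 4, 9, 16, 2)
  y <- c(5, 3, 1, 8, 2, 7)
  sx <- embed_delay(x, m = 2, tau = 1)
  sy <- embed_delay(y, m = 2, tau = 1)
  got <- gs_indices(neighbor_statistics(sx, sy, k = 1, theiler = 0))
  want <- gs_oracle(x, y, m = 2, tau = 1, k = 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("identical signals attain the S = M = L = 1 endpoints", {
  set.seed(4)
  x <- rnorm(200)
  idx <- gs_pair(x, x, m = 3, tau = 1, k = 4)
  expect_equal(idx$S, 1)
  expect_equal(idx$M, 1)
  expect_equal(idx$L, 1)
  expect_gt(idx$H, 0)
})

test_that("all four indices equal the brute-force oracle on randomized instances", {
  set.seed(77)
  for (case in 1:50) {
    N <- sample(30:60, 1)
    m <- sample(1:3, 1)
    tau <- sample(1:2, 1)
    k <- sample(1:4, 1)
    th <- sample(0:2, 1)
    x <- rnorm(N + (m - 1) * tau + 1)
    y <- 0.5 * x + rnorm(length(x))
    got <- gs_pair(x, y, m = m, tau = tau, k = k, theiler = th)
    want <- gs_oracle(x, y, m = m, tau = tau, k = k, theiler = th)
    for (nm in c("S", "H", "M", "L"))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
  }
})

test_that("stride > 1 equals the computation on the explicitly subsampled state list", {
  set.seed(23)
  x <- rnorm(240)
  y <- rnorm(240)
  got <- gs_pair(x, y, m = 2, tau = 2, k = 3, theiler = 0, stride = 3)
  want <- gs_oracle(x, y, m = 2, tau = 2, k = 3, theiler = 0, stride = 3)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("independent noise gives near-zero H, M and L and bounded S", {
  res <- t(vapply(1:10, function(s) {
    set.seed(s)
    idx <- gs_pair(rnorm(1000), rnorm(1000), m = 3, tau = 1, k = 4)
    c(idx$S, idx$H, idx$M, idx$L)
  }, numeric(4)))
  expect_lt(abs(mean(res[, 2])), 0.1)   # H
  expect_lt(abs(mean(res[, 3])), 0.1)   # M
  expect_lt(abs(mean(res[, 4])), 0.1)   # L
  expect_true(all(res[, 1] > 0 & res[, 1] <= 1))
})

test_that("gs_matrix fills ordered pairs with the documented orientation and diagonals", {
  set.seed(6)
  x <- rnorm(300)
  d <- rbind(x, x, rnorm(300))
  g <- gs_matrix(d, m = 2, tau = 1, k = 3, theiler = 0)
  expect_equal(g$S[1, 2], 1)
  expect_equal(g$S[2, 1], 1)
  expect_true(all(diag(g$S) == 1) && all(diag(g$M) == 1) &&
                all(diag(g$L) == 1))
  expect_true(all(diag(g$H) > 0))
  # entry [i, j] = Index(X_i | X_j)
  want <- gs_pair(d[3, ], d[1, ], m = 2, tau = 1, k = 3)
  expect_equal(g$S[3, 1], want$S, tolerance = 1e-12)
})

test_that("unidirectional Henon coupling is detected with the right direction", {
  res <- t(vapply(1:20, function(s) {
    h <- gen_unidir_henon(1500, coupling = 0.6, seed = s)
    g <- gs_matrix(h, m = 2, tau = 1, k = 4, theiler = 0)
    c(g$L["driver", "response"], g$L["response", "driver"])
  }, numeric(2)))
  # the driver is recovered from the response's neighbourhoods
  expect_gte(sum(res[, 1] > res[, 2]), 16)
})
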