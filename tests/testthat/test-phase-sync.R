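test_that("analytic signal is the quadrature pair of a pure tone", {
  fs <- 500
  t <- (0:999) / fs
  x <- cos(2 * pi * 10 * t)
  a <- analytic_signal(signal_matrix(x, fs = fs))
  expect_identical(Re(a$values)[1, ], x)        # real part exact
  dev <- abs(Im(a$values)[1, 51:950] - sin(2 * pi * 10 * t)[51:950])
  expect_lt(max(dev), 0.01)
  # one-sided spectrum
  sp <- fft(a$values[1, ])
  neg <- sp[502:1000]
  expect_lt(max(Mod(neg)), 1e-9 * max(Mod(sp)))
  expect_error(analytic_signal(signal_matrix(matrix(0:1, 1, 2))),
               class = "fcnet_too_short")
})

test_that("instantaneous phase is the four-quadrant angle with the tone's angular velocity", {
  a <- structure(list(values = matrix(c(1 + 0i, 0 + 1i, -1 + 0i, 0 - 1i),
                                      nrow = 1),
                      fs = NULL, labels = "ch1"),
                 class = "analytic_matrix")
  ph <- instantaneous_phase(a)
  expect_equal(ph$phases[1, ], c(0, pi / 2, pi, -pi / 2))
  expect_error(instantaneous_phase(a, discard = 2),
               class = "fcnet_invalid_discard")

  fs <- 500
  t <- (0:1999) / fs
  x <- cos(2 * pi * 10 * t)
  p <- instantaneous_phase(analytic_signal(signal_matrix(x, fs = fs)))
  inc <- diff(p$phases[1, 100:1900])
  inc <- Arg(exp(1i * inc))                     # wrapped increments
  expect_equal(mean(inc), 2 * pi * 10 / fs, tolerance = 0.01)
})

make_phase_matrix <- function(rows, discard = 0) {
  structure(list(phases = rows, discard = as.integer(discard), fs = NULL,
                 labels = paste0("ch", seq_len(nrow(rows)))),
            class = "phase_matrix")
}

test_that("PLV endpoints: identical rows, symmetric cancellation, two-atom distribution", {
  set.seed(5)
  p1 <- runif(400, -pi, pi)
  expect_equal(plv(make_phase_matrix(rbind(p1, p1)))[1, 2], 1)

  N <- 36
  roots <- 2 * pi * (0:(N - 1)) / N             # phasors sum to zero
  expect_equal(plv(make_phase_matrix(rbind(roots, rep(0, N))))[1, 2], 0,
               tolerance = 1e-12)

  two <- rep(c(0, pi / 2), 50)
  expect_equal(plv(make_phase_matrix(rbind(two, rep(0, 100))))[1, 2],
               sqrt(2) / 2, tolerance = 1e-12)
})

test_that("PLV equals the circular mean resultant length of the relative phase", {
  set.seed(8)
  for (rep in 1:5) {
    a <- runif(200, -pi, pi)
    b <- runif(200, -pi, pi)
    rel <- a - b
    R <- sqrt(sum(cos(rel))^2 + sum(sin(rel))^2) / length(rel)
    expect_equal(plv(make_phase_matrix(rbind(a, b)))[1, 2], R,
                 tolerance = 1e-12)
  }
})

test_that("PLI counts sign consistency of the wrapped relative phase", {
  n <- 100
  base <- runif(n, -1, 1)
  expect_equal(pli(make_phase_matrix(rbind(base + 0.3, base)))[1, 2], 1)
  alt <- base + rep(c(0.3, -0.3), n / 2)
  expect_equal(pli(make_phase_matrix(rbind(alt, base)))[1, 2], 0)
  a <- c(0.4, 0.4, -0.4, 0.4)
  expect_equal(pli(make_phase_matrix(rbind(a, rep(0, 4))))[1, 2], 0.5)
})

test_that("PLV and PLI are unchanged by a common phase offset and by swapping the pair", {
  set.seed(13)
  a <- cumsum(rnorm(300, 0, 0.2))
  b <- cumsum(rnorm(300, 0, 0.2))
  m1 <- make_phase_matrix(rbind(a, b))
  m2 <- make_phase_matrix(rbind(a + 1.1, b + 1.1))
  expect_equal(plv(m1)[1, 2], plv(m2)[1, 2], tolerance = 1e-12)
  expect_equal(pli(m1)[1, 2], pli(m2)[1, 2], tolerance = 1e-12)
  expect_equal(plv(m1)[1, 2], plv(m1)[2, 1])
  expect_true(all(plv(m1) >= 0 & plv(m1) <= 1))
  expect_true(all(pli(m1) >= 0 & pli(m1) <= 1))
})

test_that("Wilkie significance hits its endpoints and is monotone in PLV and N", {
  p0 <- plv_significance(matrix(0, 2, 2), 100)$p
  expect_identical(p0[1, 2], 1)                 # algebraic collapse at PLV=0
  p3 <- plv_significance(matrix(0.3, 2, 2), 100)$p[1, 2]
  expect_equal(p3, exp(sqrt(36801) - 201), tolerance = 1e-12)
  expect_equal(p3, 1.0e-4, tolerance = 0.05)
  expect_lt(plv_significance(matrix(1, 2, 2), 100)$p[1, 2], 1e-70)

  plvs <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(plvs, function(v)
    plv_significance(matrix(v, 2, 2), 200)$p[1, 2], numeric(1))
  expect_true(all(diff(ps) < 0))
  ns <- c(50, 100, 200, 400, 800)
  pn <- vapply(ns, function(n)
    plv_significance(matrix(0.2, 2, 2), n)$p[1, 2], numeric(1))
  expect_true(all(diff(pn) < 0))
  expect_error(plv_significance(matrix(0.2, 2, 2), 1),
               class = "fcnet_invalid_n")
})

test_that("Benjamini-Hochberg step-up flags the right discoveries", {
  expect_identical(bh_fdr(c(0.001, 0.02, 0.03, 0.8), q = 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  ones <- plv_significance(matrix(0, 4, 4), 50)       # all p = 1
  expect_false(any(bh_fdr(ones, 0.05)$fdr_mask))
  zero <- plv_significance(matrix(1, 4, 4) - diag(4) * 0, 50)  # PLV=1
  mask <- bh_fdr(zero, 0.05)$fdr_mask
  expect_true(all(mask[upper.tri(mask)]))
  expect_true(isSymmetric(mask))
  expect_error(bh_fdr(ones, 1.5), class = "fcnet_invalid_level")
})
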