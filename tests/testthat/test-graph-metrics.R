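path3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

star5 <- function() {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- 1
  W[2:5, 1] <- 1
  W
}

test_that("strength is the weighted degree, with in/out split for directed input", {
  complete4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(node_strength(complete4), rep(3, 4), ignore_attr = TRUE)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.2
  expect_equal(node_strength(W)[1], 0.7, ignore_attr = TRUE)
  expect_equal(node_strength(matrix(0, 3, 3)), rep(0, 3),
               ignore_attr = TRUE)
  D <- matrix(0, 2, 2)
  D[1, 2] <- 1
  s <- node_strength(D)
  expect_equal(s$out, c(1, 0))
  expect_equal(s$`in`, c(0, 1))
  # exact brute force on random matrices
  set.seed(1)
  for (i in 1:5) {
    W <- gen_random_weighted_graph(10, 0.5, seed = i)
    expect_identical(node_strength(W), rowSums(W))
  }
})

test_that("weighted clustering matches hand-evaluated triangles and degree rules", {
  cl <- weighted_clustering(path3())
  expect_identical(cl$nodal[1], 0)          # degree-1 end node
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(weighted_clustering(tri)$nodal, rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(weighted_clustering(0.8 * tri)$nodal, rep(0.8, 3),
               ignore_attr = TRUE)
  expect_error(weighted_clustering(2 * tri),
               class = "fcnet_unnormalized_weights")
  expect_equal(weighted_clustering(rescale_weights(2 * tri))$nodal,
               rep(1, 3), ignore_attr = TRUE)
})

test_that("binary clustering equals the direct triangle-fraction enumeration", {
  set.seed(40)
  for (case in 1:5) {
    W <- (gen_random_weighted_graph(8, 0.5, seed = case) > 0) * 1
    got <- weighted_clustering(W)$nodal
    n <- nrow(W)
    want <- vapply(seq_len(n), function(i) {
      nb <- which(W[i, ] > 0)
      if (length(nb) < 2) return(0)
      pairs <- utils::combn(nb, 2)
      closed <- sum(W[cbind(pairs[1, ], pairs[2, ])])
      2 * closed / (length(nb) * (length(nb) - 1))
    }, numeric(1))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("inverse-weight Dijkstra distances match examples and the Floyd-Warshall oracle", {
  D <- shortest_path_lengths(path3())
  expect_equal(D[1, 3], 2)
  single <- matrix(0, 2, 2)
  single[1, 2] <- single[2, 1] <- 0.5
  expect_equal(shortest_path_lengths(single)[1, 2], 2)   # f(w) = 1/w
  for (s in 1:20) {
    W <- gen_random_weighted_graph(8, 0.4, seed = 200 + s)
    expect_equal(shortest_path_lengths(W), floyd_warshall(W),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("deleting an edge never shortens any distance, and scaling weights rescales distances", {
  set.seed(55)
  for (case in 1:5) {
    W <- gen_random_weighted_graph(8, 0.6, seed = 300 + case)
    D0 <- shortest_path_lengths(W)
    e <- which(W > 0 & upper.tri(W), arr.ind = TRUE)[1, ]
    W2 <- W
    W2[e[1], e[2]] <- W2[e[2], e[1]] <- 0
    D1 <- shortest_path_lengths(W2)
    fin <- is.finite(D0)               # pairs unreachable before stay so
    expect_true(all(D1[fin] - D0[fin] > -1e-12))
    expect_true(all(!is.finite(D1[!fin])))
    # c * W scales distances by 1/c, strengths by c, betweenness unchanged
    D3 <- shortest_path_lengths(3 * W)
    expect_equal(D3, D0 / 3, tolerance = 1e-12)
    expect_equal(node_strength(3 * W), 3 * node_strength(W))
    expect_equal(betweenness_centrality(3 * W)$betweenness,
                 betweenness_centrality(W)$betweenness, tolerance = 1e-12)
  }
})

test_that("characteristic path length averages finite distances and reports unreachable pairs", {
  expect_equal(char_path_length(shortest_path_lengths(path3()))$global,
               4 / 3)
  complete5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(char_path_length(shortest_path_lengths(complete5))$global, 1)
  two_pairs <- matrix(0, 4, 4)
  two_pairs[1, 2] <- two_pairs[2, 1] <- 1
  two_pairs[3, 4] <- two_pairs[4, 3] <- 1
  cp <- char_path_length(shortest_path_lengths(two_pairs))
  expect_equal(cp$global, 1)
  expect_identical(cp$unreachable_pairs, 8L)
  expect_error(char_path_length(shortest_path_lengths(matrix(0, 3, 3))),
               class = "fcnet_disconnected")
})

test_that("Brandes betweenness maps the star graph to its endpoints", {
  b <- betweenness_centrality(star5())$betweenness
  expect_equal(b[1], 1, ignore_attr = TRUE)      # centre: 12 ordered pairs
  expect_equal(b[2:5], rep(0, 4), ignore_attr = TRUE)
  loops <- star5()
  diag(loops) <- 1
  expect_error(betweenness_centrality(loops), class = "fcnet_self_loop")
})

test_that("Brandes accumulation equals exhaustive shortest-path enumeration", {
  set.seed(60)
  for (case in 1:50) {
    n <- sample(5:7, 1)
    W <- gen_random_weighted_graph(n, 0.5, seed = 400 + case)
    got <- betweenness_centrality(W)$betweenness
    expect_equal(got, enum_betweenness(W), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("distances and betweenness agree with igraph on larger graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:3) {
    W <- gen_random_weighted_graph(25, 0.2, seed = 500 + s)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    Dig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(shortest_path_lengths(W), Dig, tolerance = 1e-10,
                 ignore_attr = TRUE)
    big <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    n <- nrow(W)
    expect_equal(betweenness_centrality(W)$betweenness,
                 2 * big / ((n - 1) * (n - 2)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
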