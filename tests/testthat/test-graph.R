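# Density thresholding, topology metrics against brute-force oracles, and
# degree-preserving null normalization.

test_that("density thresholding keeps the strongest edges", {
  M <- matrix(0, 5, 5)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, -0.5)
  M[upper.tri(M)] <- vals
  M <- M + t(M)
  th <- threshold_density(M, density = 0.2)       # round(0.2 * 10) = 2 edges
  expect_equal(th$n_edges, 2)
  expect_equal(sum(th$adjacency) / 2, 2)
  expect_equal(sort(th$weighted[upper.tri(th$weighted)], decreasing = TRUE)[1:2],
               c(0.9, 0.8))
  # density 1 gives the complete graph
  full <- threshold_density(M, density = 1)
  expect_equal(sum(full$adjacency), 5 * 4)
  # signed ranking keeps a positive edge over a stronger negative one
  N <- matrix(0, 3, 3); N[1, 2] <- 0.1; N[1, 3] <- -0.9
  N <- N + t(N)
  ts <- threshold_density(N, density = 1 / 3, rank_by = "signed")
  expect_equal(ts$adjacency[1, 2], 1L)
  expect_equal(ts$adjacency[1, 3], 0L)
  ta <- threshold_density(N, density = 1 / 3, rank_by = "absolute")
  expect_equal(ta$adjacency[1, 3], 1L)
  # top-k agreement with a sort oracle on a random matrix
  S <- withr::with_seed(8, { A <- matrix(rnorm(100), 10, 10); (A + t(A)) / 2 })
  diag(S) <- 0
  t10 <- threshold_density(S, density = 0.2)       # 9 edges
  expect_equal(sort(t10$weighted[upper.tri(t10$weighted)], decreasing = TRUE)[1:9],
               sort(S[upper.tri(S)], decreasing = TRUE)[1:9])
  expect_error(threshold_density(matrix(rnorm(9), 3, 3), 0.5), "symmetric")
  expect_error(threshold_density(M, density = 0.01), "no edges")
})

test_that("edge sets nest monotonically across densities", {
  S <- withr::with_seed(5, { A <- matrix(rnorm(30^2), 30, 30); (A + t(A)) / 2 })
  diag(S) <- 0
  prev <- NULL
  for (d in seq(0.01, 0.10, by = 0.01)) {
    adj <- threshold_density(S, d)$adjacency
    if (!is.null(prev)) expect_true(all(adj[prev == 1L] == 1L))
    prev <- adj
  }
})

test_that("clustering and path length match brute-force oracles", {
  # closed forms first
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(clustering_coefficient(K4)$mean, 1)
  expect_equal(char_path_length(K4)$mean, 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(star)$mean, 0)
  cyc4 <- matrix(0, 4, 4)
  cyc4[cbind(1:4, c(2, 3, 4, 1))] <- 1; cyc4 <- cyc4 + t(cyc4); cyc4[cyc4 > 1] <- 1
  expect_equal(char_path_length(cyc4)$mean, 4 / 3)
  # random graphs against the triangle-enumeration and BFS oracles
  for (s in 1:50) {
    R <- sample(5:25, 1)
    adj <- rand_adjacency(R, p = runif(1, 0.15, 0.5), seed = 100 + s)
    expect_equal(clustering_coefficient(adj)$mean, oracle_clustering(adj),
                 tolerance = 1e-12)
    if (sum(adj) > 0) {
      pl <- suppressMessages(char_path_length(adj)$mean)
      expect_equal(pl, oracle_path_length(adj), tolerance = 1e-12)
    }
  }
  # disconnected pairs are excluded and reported
  two <- matrix(0, 4, 4); two[1, 2] <- two[3, 4] <- 1; two <- two + t(two)
  expect_message(res <- char_path_length(two), "unreachable")
  expect_equal(res$mean, 1)
  expect_equal(res$excluded_fraction, 8 / 12)
})

test_that("randomization preserves every degree and fixes rigid graphs", {
  adj <- rand_adjacency(20, p = 0.25, seed = 7)
  rg <- degree_preserving_randomize(adj, seed = 3)
  expect_equal(rowSums(rg), rowSums(adj))
  expect_equal(sum(rg), sum(adj))
  expect_identical(degree_preserving_randomize(adj, seed = 3), rg)
  # a triangle admits no degree-preserving rewiring
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(degree_preserving_randomize(tri, seed = 1), tri,
               ignore_attr = TRUE)
  expect_equal(normalize_metric(3, c(1, 2, 3)), 1.5)
  expect_error(normalize_metric(1, numeric(0)), "empty")
})

test_that("null normalization separates small-world from random topology", {
  # Watts-Strogatz small world: high normalized clustering, short paths
  ws <- withr::with_seed(10, igraph::sample_smallworld(1, 60, 4, 0.1))
  ws_adj <- as.matrix(igraph::as_adjacency_matrix(ws, sparse = FALSE))
  gm_ws <- suppressMessages(
    graph_metrics(ws_adj + 0, density = sum(ws_adj) / (60 * 59),
                  n_null = 100, seed = 2))
  expect_gt(gm_ws$clustering_normalized, 1.5)
  expect_lt(gm_ws$path_length_normalized, 1.3)
  # Erdos-Renyi: both ratios near 1
  er_adj <- rand_adjacency(60, p = 8 / 59, seed = 12)
  gm_er <- suppressMessages(
    graph_metrics(er_adj + 0, density = sum(er_adj) / (60 * 59),
                  n_null = 100, seed = 2))
  expect_lt(abs(gm_er$clustering_normalized - 1), 0.15)
  expect_lt(abs(gm_er$path_length_normalized - 1), 0.15)
})

test_that("regional weighted degree averages within the partition", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.5; W[3, 4] <- 0.2; W <- W + t(W)
  out <- regional_weighted_degree(W, c("a", "a", "b", "b"))
  expect_equal(as.numeric(out[c("a", "b")]), c(0.5, 0.2))
  expect_error(regional_weighted_degree(W, c("a", "b")), "every node")
})
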