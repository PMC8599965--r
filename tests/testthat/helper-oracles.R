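# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's computational paths: densities are evaluated with plain
# solve()/determinant(), paths are enumerated, template pairs are counted
# with double loops, and graph metrics are computed from the adjacency matrix
# directly.

# Multivariate normal log-density, written independently of emission_loglik().
oracle_dmvnorm_log <- function(x, mu, Sigma) {
  d <- length(mu)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  q <- drop(t(x - mu) %*% solve(Sigma) %*% (x - mu))
  -0.5 * (d * log(2 * pi) + ld + q)
}

# All K^T state paths as rows.
oracle_all_paths <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# Total likelihood by explicit path enumeration.
oracle_loglik <- function(model, x) {
  K <- nrow(model$means); T <- nrow(x)
  paths <- oracle_all_paths(K, T)
  lp <- apply(paths, 1, function(p) {
    v <- log(model$initial[p[1]])
    if (T > 1) for (t in 2:T) v <- v + log(model$transition[p[t - 1], p[t]])
    for (t in 1:T)
      v <- v + oracle_dmvnorm_log(x[t, ], model$means[p[t], ], model$covariance)
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Most probable path by enumeration.
oracle_viterbi <- function(model, x) {
  K <- nrow(model$means); T <- nrow(x)
  paths <- oracle_all_paths(K, T)
  lp <- apply(paths, 1, function(p) {
    v <- log(model$initial[p[1]])
    if (T > 1) for (t in 2:T) v <- v + log(model$transition[p[t - 1], p[t]])
    for (t in 1:T)
      v <- v + oracle_dmvnorm_log(x[t, ], model$means[p[t], ], model$covariance)
    v
  })
  as.integer(paths[which.max(lp), ])
}

# Sample entropy by explicit O(T^2) pair counting.
oracle_sample_entropy <- function(x, m, r) {
  T <- length(x); N <- T - m
  A <- 0; B <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
    if (db <= r) B <- B + 1
    da <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
    if (da <= r) A <- A + 1
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Mean local clustering by triangle enumeration.
oracle_clustering <- function(adj) {
  R <- nrow(adj)
  cc <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

# Mean shortest path over reachable pairs by BFS from every node.
oracle_path_length <- function(adj) {
  R <- nrow(adj)
  total <- 0; count <- 0
  for (s in seq_len(R)) {
    dist <- rep(Inf, R); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    reach <- is.finite(dist) & seq_len(R) != s
    total <- total + sum(dist[reach]); count <- count + sum(reach)
  }
  total / count
}

# A small random model for the enumeration checks.
tiny_model <- function(K, C = 2, seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(runif(K * K) + 0.2, K, K)
    P <- P / rowSums(P)
    A <- matrix(rnorm(C * C), C, C)
    list(means = matrix(rnorm(K * C, sd = 1.5), K, C),
         covariance = crossprod(A) / C + diag(0.5, C),
         transition = P,
         initial = rep(1 / K, K))
  })
}

rand_adjacency <- function(R, p = 0.25, seed = 1) {
  g <- withr::with_seed(seed, igraph::sample_gnp(R, p))
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}
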