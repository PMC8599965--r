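# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic functions route through this.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Stationary distribution of a row-stochastic matrix: the left fixed vector
# pi' = pi' P, obtained by solving (I - P') pi = 0 with the normalization
# sum(pi) = 1 replacing the last (redundant) equation.
stationary_distribution <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  check_row_stochastic(P)
  K <- nrow(P)
  if (K == 1) return(1)
  M <- diag(K) - t(P)
  M[K, ] <- 1
  v <- tryCatch(solve(M, c(rep(0, K - 1), 1)),
                error = function(e) stop("chain is reducible; stationary distribution not unique"))
  if (any(v < -1e-10)) stop("stationary distribution has negative entries; chain may be reducible")
  pmax(v, 0) / sum(pmax(v, 0))
}

check_row_stochastic <- function(P, tol = 1e-8) {
  if (any(P < -tol) || any(abs(rowSums(P) - 1) > tol))
    stop("matrix is not row-stochastic")
  invisible(TRUE)
}

# Sample one multivariate normal draw per row of `mu` offsets using a
# pre-computed upper Cholesky factor of the covariance.
rmvnorm_chol <- function(n, C, chol_upper) {
  matrix(rnorm(n * C), n, C) %*% chol_upper
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 0

`%||%` <- function(a, b) if (is.null(a)) b else a
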