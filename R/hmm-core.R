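# Forward-backward and Viterbi for the shared-covariance Gaussian HMM.
# The recursions themselves are compiled (src/hmm.cpp); this file computes
# emission log-densities and exposes the user-facing wrappers.

# Per-volume Gaussian log-densities under each state, exploiting the shared
# covariance: log N(x; mu_k, Sigma) = const - 0.5 x'S x + x'S mu_k
# - 0.5 mu_k'S mu_k with S = Sigma^{-1}; the quadratic term in x is computed
# once for all states.
emission_loglik <- function(x, means, covariance) {
  x <- as.matrix(x)
  C <- ncol(x)
  ch <- chol(covariance)
  Sinv <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  xs <- x %*% Sinv
  quad_x <- rowSums(xs * x)                      # x' Sinv x, length T
  cross <- xs %*% t(means)                       # T x K, x' Sinv mu_k
  quad_mu <- rowSums((means %*% Sinv) * means)   # length K
  const <- -0.5 * (C * log(2 * pi) + logdet)
  sweep(cross, 2, 0.5 * quad_mu, "-") - 0.5 * quad_x + const
}

validate_hmm_inputs <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop("series has ", ncol(x), " channels but the model expects ", ncol(model$means))
  x
}

#' Forward-backward posterior state inference
#'
#' Runs the scaled forward-backward algorithm for a shared-covariance Gaussian
#' hidden Markov model on one multichannel series, returning per-volume
#' posterior state probabilities (`gamma`), pairwise transition posteriors
#' (`xi`), and the exact log-likelihood of the series under the model.
#'
#' @param model A fitted [fit_hmm()] object, or any list with elements
#'   `means` (K x C), `covariance` (C x C), `transition` (K x K
#'   row-stochastic) and `initial` (length K).
#' @param x Numeric matrix, timepoints x channels.
#' @param return_xi Logical; if `TRUE` the full `(T-1) x K x K` array of
#'   pairwise posteriors is returned (memory grows with T), otherwise only
#'   their sum over time.
#' @return A list with `gamma` (T x K, rows sum to 1), `xi` (array, or `NULL`),
#'   `xi_sum` (K x K), and `loglik`.
#' @examples
#' m <- list(means = matrix(c(-1, 1), 2, 1), covariance = diag(1) * 0.25,
#'           transition = matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE),
#'           initial = c(.5, .5))
#' fb <- forward_backward(m, matrix(c(-1.1, -0.9, 1.2, 0.8), ncol = 1))
#' rowSums(fb$gamma)
#' @export
forward_backward <- function(model, x, return_xi = TRUE) {
  x <- validate_hmm_inputs(model, x)
  logB <- emission_loglik(x, model$means, model$covariance)
  res <- .forward_backward_cpp(logB, model$transition, model$initial,
                               return_xi = isTRUE(return_xi))
  if (!is.finite(res$loglik)) stop("non-finite log-likelihood on finite input")
  list(gamma = res$gamma, xi = if (isTRUE(return_xi)) res$xi else NULL,
       xi_sum = res$xi_sum, loglik = res$loglik)
}

#' Viterbi decoding of the most probable state path
#'
#' @inheritParams forward_backward
#' @return Integer vector of length `nrow(x)` with 1-based state indices; the
#'   jointly most probable path under the model.
#' @export
viterbi <- function(model, x) {
  x <- validate_hmm_inputs(model, x)
  logB <- emission_loglik(x, model$means, model$covariance)
  as.integer(.viterbi_cpp(logB, model$transition, model$initial))
}
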