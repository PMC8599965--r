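# Group-level shared-covariance Gaussian HMM, fit by EM over the
# temporally concatenated, per-subject standardized component timecourses.

#' Standardize and concatenate subject timecourses
#'
#' Each subject's each channel is z-scored (mean 0, SD 1) within subject, then
#' subjects are stacked row-wise in the order given. The HMM is fit to this
#' concatenated matrix; subject boundaries let the chain restart at each
#' subject with the model's initial distribution.
#'
#' @param series A list of numeric matrices (timepoints x channels), all with
#'   the same number of channels, or a single matrix (treated as one subject).
#' @return A list with `x` (concatenated standardized matrix), `starts` and
#'   `ends` (row indices delimiting each subject), and `subject_ids`.
#' @export
standardize_and_concatenate <- function(series) {
  if (is.matrix(series) || is.data.frame(series)) series <- list(as.matrix(series))
  series <- lapply(series, as.matrix)
  C <- unique(vapply(series, ncol, 1L))
  if (length(C) != 1) stop("all subjects must have the same number of channels")
  std <- lapply(seq_along(series), function(i) {
    m <- series[[i]]
    sds <- apply(m, 2, sd)
    if (any(sds == 0))
      stop("zero-variance channel(s) ", paste(which(sds == 0), collapse = ", "),
           " in subject ", i)
    scale(m)[, , drop = FALSE]
  })
  Ts <- vapply(std, nrow, 1L)
  ends <- cumsum(Ts)
  ids <- names(series) %||% paste0("sub", seq_along(series))
  list(x = do.call(rbind, std), starts = c(1L, head(ends, -1L) + 1L),
       ends = ends, subject_ids = ids)
}

#' Fit a shared-covariance Gaussian hidden Markov model
#'
#' Fits a K-state multivariate Gaussian HMM by maximum-likelihood EM
#' (Baum-Welch) to concatenated standardized subject timecourses. All states
#' share one covariance matrix, so states are distinguished by their mean
#' activation patterns and the dynamics are driven by activation changes
#' rather than by connectivity differences. All subjects share the emission
#' model and transition matrix (a group-level model); the chain restarts with
#' the initial distribution at each subject boundary.
#'
#' State means are initialized by k-means on the pooled volumes; the
#' transition matrix starts with configurable diagonal mass (`stay_prob`) to
#' encourage temporally coherent states. The best of `n_restarts` EM runs (by
#' final log-likelihood) is returned. A ridge of `1e-6 * trace/C` is added to
#' the covariance diagonal each M-step. A state whose total responsibility
#' falls below `empty_floor` is re-initialized at a random volume (recorded in
#' `$notes`).
#'
#' @param series List of subject matrices (timepoints x channels), or a single
#'   matrix.
#' @param K Number of latent states.
#' @param n_restarts EM restarts with different k-means initializations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed controlling initialization (the fit is
#'   deterministic given `seed`).
#' @param stay_prob Initial diagonal mass of the transition matrix.
#' @param empty_floor Minimum total responsibility per state before
#'   re-initialization.
#' @return An object of class `ghmm`: `K`, `means` (K x C), `covariance`
#'   (C x C), `transition`, `initial`, `loglik` and `loglik_trace`,
#'   per-subject posteriors `gamma`, subject bookkeeping, and `notes`.
#' @seealso [forward_backward()], [viterbi()], [state_metrics()],
#'   [match_states()]
#' @export
fit_hmm <- function(series, K = 8, n_restarts = 3, tol = 1e-6, max_iter = 200,
                    seed = 1, stay_prob = 0.9, empty_floor = 1e-3) {
  cc <- standardize_and_concatenate(series)
  x <- cc$x
  Ttot <- nrow(x); C <- ncol(x)
  if (Ttot < 10 * K) stop("need at least 10*K volumes to fit ", K, " states")
  Sxx <- crossprod(x)

  best <- NULL
  notes <- character()
  for (r in seq_len(n_restarts)) {
    fitr <- with_seed(seed + r - 1L, {
      em_run(x, cc, K, Sxx, tol, max_iter, stay_prob, empty_floor)
    })
    notes <- c(notes, fitr$notes)
    if (is.null(best) || fitr$loglik > best$loglik) best <- fitr
  }

  out <- list(K = K, C = C, means = best$means, covariance = best$covariance,
              transition = best$transition, initial = best$initial,
              loglik = best$loglik, loglik_trace = best$trace,
              gamma = best$gamma, subject_ids = cc$subject_ids,
              starts = cc$starts, ends = cc$ends, x = x,
              n_iter = length(best$trace), converged = best$converged,
              notes = notes,
              call = match.call())
  class(out) <- "ghmm"
  out
}

# One EM run from a k-means initialization. RNG state is managed by caller.
em_run <- function(x, cc, K, Sxx, tol, max_iter, stay_prob, empty_floor) {
  Ttot <- nrow(x); C <- ncol(x)
  # init only: EM refines the centers, so exhausting iter.max is acceptable
  km <- suppressWarnings(kmeans(x, centers = K, nstart = 1, iter.max = 30,
                                algorithm = "Lloyd"))
  means <- km$centers
  covariance <- cov_ridge(Sxx / Ttot - crossprod(sqrt(km$size / Ttot) * means), C)
  transition <- matrix((1 - stay_prob) / (K - 1), K, K)
  diag(transition) <- stay_prob
  if (K == 1) transition <- matrix(1, 1, 1)
  initial <- rep(1 / K, K)

  trace <- numeric(0)
  notes <- character()
  converged <- FALSE
  gamma_list <- NULL
  n_sub <- length(cc$starts)

  for (iter in seq_len(max_iter)) {
    logB <- emission_loglik(x, means, covariance)
    Nk <- numeric(K); GX <- matrix(0, K, C); xi_sum <- matrix(0, K, K)
    init_acc <- numeric(K); ll <- 0
    gamma_list <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      idx <- cc$starts[s]:cc$ends[s]
      fb <- .forward_backward_cpp(logB[idx, , drop = FALSE], transition,
                                  initial, return_xi = FALSE)
      g <- fb$gamma
      gamma_list[[s]] <- g
      Nk <- Nk + colSums(g)
      GX <- GX + crossprod(g, x[idx, , drop = FALSE])
      xi_sum <- xi_sum + fb$xi_sum
      init_acc <- init_acc + g[1, ]
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)

    empty <- which(Nk < empty_floor)
    if (length(empty)) {
      for (k in empty) {
        means[k, ] <- x[sample.int(Ttot, 1), ] + rnorm(C, sd = 0.1)
        notes <- c(notes, sprintf("iteration %d: state %d empty, re-initialized", iter, k))
      }
      next
    }

    means <- GX / Nk
    covariance <- cov_ridge(Sxx / Ttot - crossprod(sqrt(Nk / Ttot) * means), C)
    rs <- rowSums(xi_sum)
    transition <- (xi_sum + 1e-12) / (rs + K * 1e-12)
    if (K == 1) transition <- matrix(1, 1, 1)
    initial <- init_acc / n_sub
    initial <- initial / sum(initial)

    n <- length(trace)
    if (n >= 2) {
      if (trace[n] < trace[n - 1] - 1e-8 * abs(trace[n - 1]))
        notes <- c(notes, sprintf("iteration %d: log-likelihood decreased by %g",
                                  iter, trace[n - 1] - trace[n]))
      if (abs(trace[n] - trace[n - 1]) < tol * abs(trace[n - 1])) {
        converged <- TRUE
        break
      }
    }
  }
  list(means = means, covariance = covariance, transition = transition,
       initial = initial, loglik = trace[length(trace)], trace = trace,
       gamma = gamma_list, converged = converged, notes = notes)
}

cov_ridge <- function(S, C) {
  S <- (S + t(S)) / 2
  S + diag(1e-6 * sum(diag(S)) / C, C)
}

#' @export
print.ghmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM (shared covariance): %d states, %d channels\n", x$K, x$C))
  cat(sprintf("  %d subjects, %d concatenated volumes\n",
              length(x$subject_ids), nrow(x$x)))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "iteration limit"))
  invisible(x)
}

#' @export
summary.ghmm <- function(object, ...) {
  sm <- state_metrics(object)
  out <- list(model = object, fo = sm$fo, switching_rate = sm$switching_rate)
  class(out) <- "summary.ghmm"
  out
}

#' @export
print.summary.ghmm <- function(x, ...) {
  print(x$model)
  cat("\nGroup mean fractional occupancy per state:\n")
  print(round(colMeans(x$fo), 3))
  cat(sprintf("\nSwitching rate: mean %.3f (range %.3f-%.3f)\n",
              mean(x$switching_rate), min(x$switching_rate), max(x$switching_rate)))
  invisible(x)
}

#' @export
coef.ghmm <- function(object, ...) {
  list(means = object$means, covariance = object$covariance,
       transition = object$transition, initial = object$initial)
}

#' @export
logLik.ghmm <- function(object, ...) {
  K <- object$K; C <- object$C
  df <- K * C + C * (C + 1) / 2 + K * (K - 1) + (K - 1)
  structure(object$loglik, df = df, nobs = nrow(object$x), class = "logLik")
}

#' Posterior decoding for new series
#'
#' @param object A fitted `ghmm`.
#' @param newdata Matrix (timepoints x channels) or list of matrices; defaults
#'   to the training subjects.
#' @param type `"gamma"` for posterior state probabilities, `"viterbi"` for
#'   the most probable hard path.
#' @param ... Unused.
#' @return For one matrix: a T x K matrix or integer path; for a list, a list
#'   of those.
#' @export
predict.ghmm <- function(object, newdata = NULL, type = c("gamma", "viterbi"), ...) {
  type <- match.arg(type)
  one <- function(m) {
    if (type == "gamma") forward_backward(object, m, return_xi = FALSE)$gamma
    else viterbi(object, m)
  }
  if (is.null(newdata)) {
    if (type == "gamma") return(object$gamma)
    return(lapply(seq_along(object$starts), function(s)
      viterbi(object, object$x[object$starts[s]:object$ends[s], , drop = FALSE])))
  }
  if (is.matrix(newdata) || is.data.frame(newdata)) return(one(as.matrix(newdata)))
  lapply(newdata, function(m) one(as.matrix(m)))
}

#' Simulate series from a fitted or hand-built model
#'
#' @param object A `ghmm` (or compatible list of parameters).
#' @param nsim Number of independent series.
#' @param seed Integer seed.
#' @param n_timepoints Length of each simulated series.
#' @param ... Unused.
#' @return A list of `nsim` lists with `x` (T x C matrix) and `path`.
#' @export
simulate.ghmm <- function(object, nsim = 1, seed = NULL, n_timepoints = 200, ...) {
  run <- function() lapply(seq_len(nsim), function(i)
    simulate_hmm_series(object$transition, object$means, object$covariance,
                        n_timepoints, initial = object$initial))
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Core HMM sampler; RNG state managed by caller.
simulate_hmm_series <- function(transition, means, covariance, n_timepoints,
                                initial = NULL, noise_model = c("iid", "ar1"),
                                ar_phi = 0.4, state_cov_scale = NULL) {
  noise_model <- match.arg(noise_model)
  K <- nrow(transition); C <- ncol(means)
  check_row_stochastic(transition)
  ch <- tryCatch(chol(covariance),
                 error = function(e) stop("covariance must be positive definite"))
  if (is.null(initial)) initial <- stationary_distribution(transition)
  path <- integer(n_timepoints)
  path[1] <- sample.int(K, 1, prob = initial)
  if (n_timepoints > 1)
    for (t in 2:n_timepoints) path[t] <- sample.int(K, 1, prob = transition[path[t - 1], ])
  eps <- rmvnorm_chol(n_timepoints, C, ch)
  if (!is.null(state_cov_scale)) eps <- eps * sqrt(state_cov_scale[path])
  if (noise_model == "ar1") {
    # temporally smoothed noise at matched marginal variance
    for (t in 2:n_timepoints)
      eps[t, ] <- ar_phi * eps[t - 1, ] + sqrt(1 - ar_phi^2) * eps[t, ]
  }
  list(x = means[path, , drop = FALSE] + eps, path = path)
}

#' Plot state mean activation patterns
#'
#' @param x A `ghmm`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ghmm <- function(x, ...) {
  graphics::image(seq_len(x$C), seq_len(x$K), t(x$means), xlab = "channel",
                  ylab = "state", main = "State mean activation", ...)
  invisible(x)
}
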