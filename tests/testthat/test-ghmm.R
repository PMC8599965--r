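# EM fitting: monotone likelihood, closed forms, determinism, recovery.

make_two_state_series <- function(T, seed = 1) {
  P <- matrix(c(0.92, 0.08, 0.10, 0.90), 2, 2, byrow = TRUE)
  means <- make_state_basis(2, 6, seed = 2) * 2
  simulate_subject(P, means, diag(0.3, 6), T, seed = seed)
}

test_that("EM log-likelihood is monotone non-decreasing", {
  sim <- make_two_state_series(600, seed = 3)
  fit <- fit_hmm(list(sim$x), K = 2, n_restarts = 2, seed = 1)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) > -1e-8 * abs(tr[-length(tr)])))
})

test_that("K = 1 reduces to the sample mean and covariance", {
  x <- withr::with_seed(7, matrix(rnorm(400 * 3), 400, 3))
  fit <- fit_hmm(list(x), K = 1, n_restarts = 1, seed = 1)
  z <- scale(x)
  expect_equal(drop(fit$means), colMeans(z), tolerance = 1e-8)
  smp <- crossprod(sweep(z, 2, colMeans(z))) / nrow(z)
  # up to the ridge term added for conditioning
  expect_equal(fit$covariance, smp + diag(1e-6 * sum(diag(smp)) / 3, 3),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fits are deterministic given the seed", {
  sim <- make_two_state_series(300, seed = 5)
  f1 <- fit_hmm(list(sim$x), K = 2, n_restarts = 2, seed = 11)
  f2 <- fit_hmm(list(sim$x), K = 2, n_restarts = 2, seed = 11)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("well-separated two-state model is recovered from a long series", {
  P <- matrix(c(0.92, 0.08, 0.10, 0.90), 2, 2, byrow = TRUE)
  means <- make_state_basis(2, 6, seed = 2) * 2
  sim <- simulate_subject(P, means, diag(0.3, 6), 3000, seed = 21)
  fit <- fit_hmm(list(sim$x), K = 2, n_restarts = 2, seed = 4)
  perm <- match_states(fit, list(means = means))$permutation
  inv <- order(perm)
  expect_lt(max(abs(fit$transition[inv, inv] - P)), 0.05)
  # Viterbi decoding recovers the generating hidden path almost everywhere
  path <- predict(fit, type = "viterbi")[[1]]
  expect_gt(mean(perm[path] == sim$path), 0.95)
})

test_that("model methods are coherent", {
  sim <- make_two_state_series(300, seed = 9)
  fit <- fit_hmm(list(sim$x), K = 2, n_restarts = 1, seed = 2)
  expect_output(print(fit), "Gaussian HMM")
  expect_named(coef(fit), c("means", "covariance", "transition", "initial"))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), 2 * 6 + 6 * 7 / 2 + 2 * 1 + 1)
  g <- predict(fit, sim$x)
  expect_equal(dim(g), c(300L, 2L))
  s <- simulate(fit, nsim = 2, seed = 1, n_timepoints = 50)
  expect_length(s, 2)
  expect_equal(dim(s[[1]]$x), c(50L, 6L))
  expect_identical(simulate(fit, seed = 3, n_timepoints = 20)[[1]]$x,
                   simulate(fit, seed = 3, n_timepoints = 20)[[1]]$x)
})

test_that("dual regression stage 1 recovers timecourses", {
  # orthonormal maps: exact recovery
  maps <- make_state_basis(4, 40, seed = 3)   # orthonormal rows
  tc <- withr::with_seed(1, matrix(rnorm(60 * 4), 60, 4))
  data <- tc %*% maps
  expect_equal(dual_regression_stage1(maps, data), tc, tolerance = 1e-10)
  # linearity: doubling the maps halves the coefficients
  expect_equal(dual_regression_stage1(2 * maps, data), tc / 2, tolerance = 1e-10)
  # correlated maps plus noise: error bounded by the noise scale
  mix <- maps + 0.3 * maps[c(2, 3, 4, 1), ]
  datn <- tc %*% mix + withr::with_seed(2, matrix(rnorm(60 * 40, sd = 0.05), 60, 40))
  est <- dual_regression_stage1(mix, datn)
  expect_lt(max(abs(est - tc)), 0.15)
  expect_error(dual_regression_stage1(rbind(maps, maps[1, ]), data), "rank")
})
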