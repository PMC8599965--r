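# Synthetic cohort generator: planted occupancy shifts, covariate
# correlations, QC outliers, determinism, convergence of empirical occupancy.

test_that("state basis rows are unit norm with low pairwise correlation", {
  B <- make_state_basis(8, 30, seed = 1)
  expect_equal(dim(B), c(8L, 30L))
  expect_equal(sqrt(rowSums(B^2)), rep(1, 8), tolerance = 1e-10)
  cors <- cor(t(B))
  expect_lte(max(abs(cors[upper.tri(cors)])), 0.3)
  # K = C: normalization forced, correlations unconstrained
  B2 <- make_state_basis(2, 2, seed = 3)
  expect_equal(sqrt(rowSums(B2^2)), c(1, 1), tolerance = 1e-12)
  expect_identical(make_state_basis(5, 20, seed = 9),
                   make_state_basis(5, 20, seed = 9))
  expect_error(make_state_basis(4, 3), "channels")
})

test_that("transition tilting shifts stationary mass by delta", {
  base <- dynconn:::base_transition(4, 0.8)
  # delta = 0 leaves the base untouched
  expect_identical(sample_transition_matrix(base, "case", 0, 1, 2), base)
  expect_identical(sample_transition_matrix(base, "control", 0.2, 1, 2), base)
  # symmetric 2-state chain has stationary (0.5, 0.5)
  P2 <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  expect_equal(dynconn:::stationary_distribution(P2), c(0.5, 0.5))
  # planted shift: executive set gains delta, subcortical loses delta
  tilted <- sample_transition_matrix(base, "case", 0.1,
                                     executive_states = 1,
                                     subcortical_states = 2)
  expect_equal(rowSums(tilted), rep(1, 4), tolerance = 1e-12)
  pi0 <- dynconn:::stationary_distribution(base)
  pi1 <- dynconn:::stationary_distribution(tilted)
  expect_equal(pi1[1] - pi0[1], 0.1, tolerance = 1e-8)
  expect_equal(pi0[2] - pi1[2], 0.1, tolerance = 1e-8)
  # brute-force power iteration agrees on the stationary distribution
  p <- rep(0.25, 4)
  for (i in 1:5000) p <- drop(p %*% tilted)
  expect_equal(p, pi1, tolerance = 1e-10)
  # infeasible shift errors
  expect_error(sample_transition_matrix(base, "case", 0.9, 1, 2), "outside")
})

test_that("hidden-path occupancy converges to the stationary distribution", {
  P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  means <- matrix(c(1, -1), 2, 1)
  sim <- simulate_subject(P2, means, diag(1), 10000, seed = 6)
  occ <- tabulate(sim$path, 2) / 10000
  # occupancy SE under this chain is ~0.015 (autocorrelated), so 0.05 ~ 3.3 SE
  expect_lt(max(abs(occ - 0.5)), 0.05)
  # K = 1: constant path
  s1 <- simulate_subject(matrix(1, 1, 1), matrix(0, 1, 2), diag(2), 50, seed = 1)
  expect_identical(unique(s1$path), 1L)
  # near-zero noise: nearest-mean classification equals the hidden path
  basis <- make_state_basis(3, 8, seed = 4)
  sim2 <- simulate_subject(dynconn:::base_transition(3, 0.8), basis,
                           diag(1e-8, 8), 300, seed = 2)
  cls <- apply(sim2$x, 1, function(v)
    which.min(colSums((t(basis) - v)^2)))
  expect_identical(as.integer(cls), sim2$path)
  expect_error(simulate_subject(P2, means, matrix(c(1, 2, 2, 1), 2, 2), 10),
               "positive definite")
})

test_that("severity and structural covariates carry the planted correlations", {
  # large-n case group with the full loading
  occ <- withr::with_seed(8, {
    d <- rnorm(400, 0.05, 0.05)
    t(vapply(d, function(dd) {
      base <- dynconn:::base_transition(4, 0.8)
      P <- if (dd >= 0) dynconn:::tilt_transition(base, dd, 1, 2)
           else dynconn:::tilt_transition(base, -dd, 2, 1)
      dynconn:::stationary_distribution(P)
    }, numeric(4)))
  })
  cov1 <- simulate_covariates(occ, rep("case", 400), severity_loading = 0.6,
                              structural_loading = 0.5,
                              executive_states = 1, subcortical_states = 2,
                              seed = 3)
  contrast <- occ[, 1] - occ[, 2]
  oriented <- -scale(contrast)   # case-directed component score
  r <- cor(cov1$severity, oriented)
  expect_lt(abs(r - (-0.6)), 0.1)
  expect_gt(cor(cov1$subcortical_vol, occ[, 2]), 0.3)
  expect_gt(cor(cov1$frontal_thickness, occ[, 2]), 0.05)
  # zero loading: correlation near zero on average over replicates
  rs <- vapply(1:50, function(s) {
    cv <- simulate_covariates(occ[1:40, ], rep("case", 40),
                              severity_loading = 0, structural_loading = 0,
                              executive_states = 1, subcortical_states = 2,
                              seed = s)
    cor(cv$severity, contrast[1:40])
  }, 1)
  expect_lt(abs(mean(rs)), 0.1)
  expect_lt(quantile(abs(rs), 0.9), 0.35)
  # determinism
  expect_identical(cov1, simulate_covariates(occ, rep("case", 400), 0.6, 0.5,
                                             1, 2, seed = 3))
})

test_that("QC simulation plants detectable motion outliers", {
  q <- simulate_qc_metrics(20, n_timepoints = 200, outlier_fraction = 0.15,
                           seed = 4)
  expect_length(q$outliers, 3)
  excl <- exclusion_rule(q$metrics[, -1])
  expect_true(all(q$outliers %in% which(excl$excluded)))
  # an external permissive reference overrides the within-sample rule
  nm <- colnames(q$metrics)[-1]
  ref <- list(mean = setNames(rep(1e6, 4), nm), sd = setNames(rep(1, 4), nm))
  expect_false(any(exclusion_rule(q$metrics[, -1], reference = ref)$excluded))
  expect_identical(q$metrics,
                   simulate_qc_metrics(20, 200, 0.15, seed = 4)$metrics)
})

test_that("cohort generation is reproducible and respects its invariants", {
  sp <- cohort_spec(n_control = 4, n_case = 4, n_channels = 8,
                    n_timepoints = 80, K = 4, seed = 12)
  co <- simulate_cohort(sp)
  expect_length(co$timeseries, 8)
  expect_true(all(vapply(co$ground_truth$per_subject_transition,
                         function(P) max(abs(rowSums(P) - 1)), 1) < 1e-12))
  expect_equal(rowSums(co$ground_truth$true_occupancy), rep(1, 8),
               tolerance = 1e-10)
  expect_true(all(is.na(co$covariates$severity[co$covariates$group == "control"])))
  expect_true(all(!is.na(co$covariates$severity[co$covariates$group == "case"])))
  co2 <- simulate_cohort(sp)
  expect_identical(co$timeseries, co2$timeseries)
  expect_identical(co$covariates, co2$covariates)
})
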