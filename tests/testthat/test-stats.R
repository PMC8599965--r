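# Inference statistics: summary tests against published cohort tables and
# base-R references, Steiger's Z calibration, PCA identities, partial
# correlation, moderation, and the Freedman-Lane permutation GLM.

test_that("summary t and chi-squared reproduce the cohort demographic table", {
  # age: 64.9 (9.9) n=22 vs 70.1 (6.5) n=24, pooled t
  tt <- two_sample_t(64.9, 9.9, 22, 70.1, 6.5, 24)
  expect_equal(round(abs(tt$t), 1), 2.1)
  expect_equal(tt$df, 44)
  # gender 14/8 vs 11/13 and 26/10 vs 15/27, Pearson chi-squared, df 1
  expect_equal(round(chi_squared_2x2(14, 8, 11, 13)$chi2, 1), 1.5)
  expect_equal(round(chi_squared_2x2(26, 10, 15, 27)$chi2, 1), 10.4)
})

test_that("summary tests agree with stats::t.test and stats::chisq.test", {
  x <- withr::with_seed(1, rnorm(15, 1, 2)); y <- withr::with_seed(2, rnorm(20))
  ref <- t.test(x, y, var.equal = TRUE)
  out <- two_sample_t(mean(x), sd(x), 15, mean(y), sd(y), 20)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(out$p, ref$p.value, tolerance = 1e-10)
  refw <- t.test(x, y)
  outw <- two_sample_t(mean(x), sd(x), 15, mean(y), sd(y), 20, welch = TRUE)
  expect_equal(outw$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(outw$df, unname(refw$parameter), tolerance = 1e-10)
  refc <- chisq.test(matrix(c(14, 11, 8, 13), 2, 2), correct = FALSE)
  outc <- chi_squared_2x2(14, 8, 11, 13)
  expect_equal(outc$chi2, unname(refc$statistic), tolerance = 1e-10)
  expect_equal(outc$p, refc$p.value, tolerance = 1e-10)
  expect_error(chi_squared_2x2(0, 0, 3, 4), "margin")
})

test_that("Steiger's Z has the expected trivial and calibration behaviour", {
  expect_equal(steiger_z(0.4, 0.4, 0.2, 50)$Z, 0)
  expect_gt(steiger_z(0.5, 0.1, 0.3, 60)$Z, 0)
  expect_lt(steiger_z(0.1, 0.5, 0.3, 60)$Z, 0)
  # |Z| grows with n at fixed correlations
  expect_gt(abs(steiger_z(0.5, 0.2, 0.3, 200)$Z),
            abs(steiger_z(0.5, 0.2, 0.3, 50)$Z))
  expect_error(steiger_z(0.9, -0.9, 0.9, 50), "positive semi-definite")
  # null calibration: equal population correlations give Z ~ N(0,1)
  Sig <- matrix(c(1, 0.4, 0.4, 0.4, 1, 0.3, 0.4, 0.3, 1), 3, 3)
  L <- chol(Sig)
  zs <- withr::with_seed(42, vapply(1:400, function(i) {
    X <- matrix(rnorm(80 * 3), 80, 3) %*% L
    R <- cor(X)
    steiger_z(R[1, 2], R[1, 3], R[2, 3], 80)$Z
  }, 1))
  expect_lt(abs(mean(zs)), 0.15)
  expect_lt(abs(sd(zs) - 1), 0.15)
  expect_lt(abs(mean(abs(zs) > qnorm(0.975)) - 0.05), 0.035)
})

test_that("Kaiser PCA satisfies its algebraic identities", {
  X <- withr::with_seed(6, matrix(rnorm(100 * 4), 100, 4))
  p <- pca_kaiser(X)
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-10)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unclass(p$scores), unclass(scale(X) %*% p$loadings),
               ignore_attr = TRUE)
  # score covariance reproduces the eigenvalues
  expect_equal(diag(cov(p$scores)), p$eigenvalues,
               tolerance = 1e-10, ignore_attr = TRUE)
  # two perfectly correlated columns: eigenvalues (2, 0), one retained
  a <- withr::with_seed(7, rnorm(50))
  p2 <- pca_kaiser(cbind(a, 2 * a + 3))
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_identical(p2$retained, 1L)
  expect_output(print(p2), "retained")
  expect_error(pca_kaiser(cbind(a, 1)), "constant")
})

test_that("partial correlation removes a planted confounder", {
  z <- withr::with_seed(11, rnorm(500))
  e <- withr::with_seed(12, matrix(rnorm(1000), 500, 2))
  x <- z + 0.5 * e[, 1]; y <- z + 0.5 * e[, 2]
  expect_gt(partial_correlation(x, y)$r, 0.6)
  pc <- partial_correlation(x, y, covariates = z)
  expect_lt(abs(pc$r), 0.1)
  expect_gt(pc$p, 1e-4)
  # no covariates reduces to cor.test
  ref <- cor.test(x, y)
  p0 <- partial_correlation(x, y)
  expect_equal(p0$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(p0$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(p0$p, ref$p.value, tolerance = 1e-10)
})

test_that("moderation test detects a planted slope difference and not its absence", {
  x <- withr::with_seed(21, rnorm(120))
  g <- rep(c("a", "b"), 60)
  # identical slopes in both groups: negligible increment
  y0 <- 2 * x + 1 + (g == "b") + withr::with_seed(24, rnorm(120, sd = 1e-3))
  m0 <- moderation_test(y0, x, g)
  expect_lt(m0$delta_r2, 1e-4)
  expect_gt(m0$p, 0.001)
  # opposite slopes
  y1 <- ifelse(g == "a", 1.5 * x, -0.5 * x) + withr::with_seed(22, rnorm(120, sd = 0.5))
  m1 <- moderation_test(y1, x, g)
  expect_gt(m1$delta_r2, 0.2)
  expect_lt(m1$p, 1e-6)
  # covariates are carried through both models
  m2 <- moderation_test(y1, x, g, covariates = withr::with_seed(23, rnorm(120)))
  expect_lt(m2$p, 1e-6)
  expect_gte(m2$delta_r2, 0)
})

test_that("permutation GLM t equals the lm t and p-values behave", {
  n <- 40
  X <- cbind(1, withr::with_seed(31, rnorm(n)), withr::with_seed(32, rnorm(n)))
  colnames(X) <- c("intercept", "group", "age")
  Y <- cbind(strong = X[, "group"] * 2 + withr::with_seed(33, rnorm(n, sd = 0.5)),
             null = withr::with_seed(34, rnorm(n)))
  res <- permutation_glm(Y, X, contrasts = "group", n_perm = 999, seed = 5)
  # observed t matches lm
  for (j in 1:2) {
    ref <- summary(lm(Y[, j] ~ X[, "group"] + X[, "age"]))$coefficients[2, "t value"]
    expect_equal(res$t[j], ref, tolerance = 1e-10)
  }
  # strong effect reaches the permutation floor 1/(n_perm + 1)
  expect_equal(res$p_unc[1], 1 / 1000)
  expect_gte(res$p_fwe[1], res$p_unc[1])
  expect_gt(res$p_unc[2], 0.05)
  # determinism
  res2 <- permutation_glm(Y, X, contrasts = "group", n_perm = 999, seed = 5)
  expect_identical(res, res2)
  # constant outcome excluded with a warning, others unaffected
  Yc <- cbind(Y, flat = 1)
  expect_warning(resc <- permutation_glm(Yc, X, contrasts = "group",
                                         n_perm = 99, seed = 1), "constant")
  expect_true(is.na(resc$t[3]))
  expect_false(anyNA(resc$t[1:2]))
  expect_error(permutation_glm(Y, X[, c(1, 2, 2)], "group", 99), "rank deficient")
})

test_that("occupancy group analysis finds a planted component difference", {
  n <- 60; K <- 4
  group <- rep(c("control", "case"), each = 30)
  base <- withr::with_seed(41, matrix(rnorm(n * K, sd = 0.02), n, K) + 0.25)
  shift <- 0.03 * (group == "case")
  fo <- base; fo[, 1] <- fo[, 1] + shift; fo[, 2] <- fo[, 2] - shift
  fo <- fo / rowSums(fo)
  sev_noise <- withr::with_seed(42, rnorm(30, sd = 0.01))
  covs <- data.frame(group = group,
                     age = withr::with_seed(43, rnorm(n, 68, 8)),
                     sex = rep(0:1, 30),
                     severity = c(rep(NA, 30),
                                  35 + 13 * scale((fo[31:60, 1] - fo[31:60, 2]) +
                                                    sev_noise)))
  out <- fo_group_analysis(fo, covs, n_perm = 999, seed = 3)
  expect_lt(out$p_fwe, 0.05)
  # oriented so cases score lower
  expect_lt(mean(out$scores_oriented[31:60]), mean(out$scores_oriented[1:30]))
  # severity rises with the case-direction contrast, so the oriented
  # component correlates negatively with it
  expect_lt(out$severity_r, -0.5)
  expect_lt(out$severity_p, 0.01)
})
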