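# Group statistics: Freedman-Lane permutation GLM with max-statistic
# family-wise error correction, Kaiser-criterion PCA of fractional occupancy,
# partial correlations, moderation (interaction) tests, Steiger's Z for
# dependent correlations, and the summary-statistic demographic tests.

#' Permutation GLM with max-statistic FWE correction
#'
#' Tests single-column contrasts of a linear model on each column of `Y` by
#' Freedman-Lane permutation: residuals of the reduced (nuisance-only) model
#' are permuted, the reduced fit is added back, and the full-model t statistic
#' is recomputed. Family-wise error corrected p-values come from the
#' permutation distribution of the maximum |t| across all outcomes and
#' contrasts in the call (the family is what the call contains). The observed
#' statistic is included in the permutation distribution, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param Y n x q outcome matrix (or vector).
#' @param X n x p design matrix including the intercept.
#' @param contrasts Column indices (or names) of `X` to test, one at a time;
#'   for each, the remaining columns act as nuisance.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed.
#' @return Data frame with one row per outcome x contrast: `outcome`,
#'   `contrast`, `t`, `p_unc`, `p_fwe`, `n_perm`, `seed`. Zero-variance
#'   outcomes are flagged with `NA` statistics and excluded from the family.
#' @export
permutation_glm <- function(Y, X, contrasts, n_perm = 10000, seed = 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  if (nrow(X) != n) stop("X and Y must have the same number of rows")
  if (n <= p) stop("need more observations than design columns")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (is.character(contrasts)) contrasts <- match(contrasts, colnames(X))
  if (anyNA(contrasts)) stop("unknown contrast column")
  onames <- colnames(Y) %||% paste0("y", seq_len(q))
  cnames <- (colnames(X) %||% paste0("x", seq_len(p)))[contrasts]

  ok <- apply(Y, 2, sd) > 0
  if (!all(ok)) warning("constant outcome(s) excluded: ",
                        paste(onames[!ok], collapse = ", "))
  nc <- length(contrasts)
  tobs <- matrix(NA_real_, q, nc)
  # permutation t statistics: [perm, outcome, contrast], included outcomes only
  tperm <- array(NA_real_, c(n_perm, q, nc))
  perms <- with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))

  for (ci in seq_len(nc)) {
    cc <- contrasts[ci]
    Z <- X[, -cc, drop = FALSE]
    qz <- qr(Z)
    gt <- qr.resid(qz, X[, cc])            # contrast column partialled for nuisance
    gg <- sum(gt^2)
    if (gg < 1e-12) stop("contrast column collinear with nuisance")
    E <- qr.resid(qz, Y[, ok, drop = FALSE])
    ssE <- colSums(E^2)
    df <- n - p
    tstat <- function(Ep) {
      b <- drop(crossprod(gt, Ep)) / gg
      ss <- colSums(Ep^2) - colSums(qr.fitted(qz, Ep)^2)   # ||(I-Hz)Ep||^2
      rss <- pmax(ss - b^2 * gg, 0)
      b * sqrt(gg) / sqrt(rss / df)
    }
    tobs[ok, ci] <- tstat(E)
    for (b in seq_len(n_perm)) tperm[b, ok, ci] <- tstat(E[perms[[b]], , drop = FALSE])
  }

  maxt <- apply(abs(tperm), 1, max, na.rm = TRUE)
  out <- expand.grid(outcome = onames, contrast = cnames,
                     stringsAsFactors = FALSE)
  out$t <- as.vector(tobs)
  out$p_unc <- NA_real_; out$p_fwe <- NA_real_
  for (ci in seq_len(nc)) for (j in seq_len(q)) {
    if (!ok[j]) next
    to <- abs(tobs[j, ci])
    row <- (ci - 1) * q + j
    out$p_unc[row] <- (1 + sum(abs(tperm[, j, ci]) >= to - 1e-12)) / (n_perm + 1)
    out$p_fwe[row] <- (1 + sum(maxt >= to - 1e-12)) / (n_perm + 1)
  }
  out$n_perm <- n_perm
  out$seed <- seed
  out
}

#' PCA of fractional occupancy with Kaiser retention
#'
#' Principal component analysis of the column correlation matrix (columns are
#' standardized before projection, so scores are centered); components with
#' eigenvalue strictly greater than 1 are retained.
#'
#' @param x n x K matrix (e.g. per-subject fractional occupancy).
#' @return List of class `pca_kaiser`: `loadings` (K x K orthonormal columns),
#'   `scores` (n x K), `eigenvalues`, `variance_explained` (fractions),
#'   `retained` (indices with eigenvalue > 1).
#' @export
pca_kaiser <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); K <- ncol(x)
  if (n <= K) stop("need more rows than columns")
  if (any(apply(x, 2, sd) == 0)) stop("constant column(s)")
  R <- cor(x)
  e <- eigen(R, symmetric = TRUE)
  scores <- scale(x) %*% e$vectors
  colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(loadings = e$vectors, scores = scores,
                 eigenvalues = e$values,
                 variance_explained = e$values / K,
                 retained = which(e$values > 1)),
            class = "pca_kaiser")
}

#' @export
print.pca_kaiser <- function(x, ...) {
  cat("PCA (correlation matrix), Kaiser retention:\n")
  cat("  eigenvalues:", paste(round(x$eigenvalues, 2), collapse = ", "), "\n")
  cat(sprintf("  %d component(s) retained, explaining %.0f%% of variance\n",
              length(x$retained),
              100 * sum(x$variance_explained[x$retained])))
  invisible(x)
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariates (with intercept); reduces to the plain Pearson
#' correlation when no covariates are given.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional matrix/data frame of covariates.
#' @return List with `r`, `t` (on `n - k - 2` df, k = number of covariates),
#'   and two-sided `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    k <- ncol(Z) - 1
    if (n <= k + 2) stop("too few observations for the covariate count")
    qz <- qr(Z)
    x <- qr.resid(qz, x); y <- qr.resid(qz, y)
  }
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate residuals")
  r <- cor(x, y)
  tt <- r * sqrt((n - k - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, t = tt, p = 2 * pt(-abs(tt), df = n - k - 2))
}

#' Moderation (interaction) test
#'
#' Compares a model of `y` on `x`, group and covariates against one that adds
#' the `x:group` interaction: reports the R-squared increment and the F-test
#' on the interaction term. Tests whether the x-y slope differs between
#' groups.
#'
#' @param y,x Numeric vectors.
#' @param group Two-level factor (or coercible).
#' @param covariates Optional matrix/data frame.
#' @return List with `delta_r2`, `F`, `p`, and the two fitted models.
#' @export
moderation_test <- function(y, x, group, covariates = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) < 3))
    stop("need two groups with at least 3 observations each")
  dat <- data.frame(y = y, x = x, group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0("c", seq_along(covariates))
    dat <- cbind(dat, covariates)
    covterm <- paste("+", paste(names(covariates), collapse = " + "))
  } else covterm <- ""
  f_red <- stats::as.formula(paste("y ~ x + group", covterm))
  f_full <- stats::as.formula(paste("y ~ x + group + x:group", covterm))
  m_red <- lm(f_red, dat); m_full <- lm(f_full, dat)
  a <- anova(m_red, m_full)
  list(delta_r2 = summary(m_full)$r.squared - summary(m_red)$r.squared,
       F = a$F[2], p = a$`Pr(>F)`[2], full = m_full, reduced = m_red)
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether `cor(1,2)` differs from `cor(1,3)` given `cor(2,3)`, using
#' Steiger's (1980) Z with the pooled-correlation covariance estimate.
#'
#' @param r12,r13,r23 Sample correlations; the 3 x 3 correlation matrix they
#'   imply must be positive semi-definite.
#' @param n Sample size (> 3).
#' @return List with `Z` and two-sided `p`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  stopifnot(abs(r12) < 1, abs(r13) < 1, abs(r23) < 1, n > 3)
  Rm <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlations do not form a positive semi-definite matrix")
  z12 <- atanh(r12); z13 <- atanh(r13)
  rbar2 <- ((r12 + r13) / 2)^2
  psi <- r23 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r23^2)
  s <- psi / (1 - rbar2)^2
  Z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * s))
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch (unequal-variance) form instead of pooled.
#' @return List with `t`, `df`, two-sided `p`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tt <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Pearson chi-squared test of a 2 x 2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param a,b First row counts.
#' @param c,d Second row counts.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_squared_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("zero margin")
  chi2 <- n * (a * d - b * c)^2 / prod(m)
  list(chi2 = chi2, df = 1, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Group analysis of fractional occupancy components
#'
#' Runs the occupancy-component group comparison: PCA of the per-subject
#' fractional occupancy matrix with Kaiser retention, a Freedman-Lane
#' permutation GLM of the retained component scores on group with nuisance
#' covariates, selection of the component that best separates the groups (the
#' largest |t|), and its within-case correlation with the severity score
#' (adjusted for the same nuisance covariates). The separating component is
#' oriented so that cases score lower than controls on average, mirroring the
#' convention that the patient group is "more negative" on the component.
#'
#' @param fo n x K fractional occupancy matrix.
#' @param covariates Data frame with a two-level `group` column (cases =
#'   second level unless a `case` level is present), optional `severity`
#'   (defined for cases), and optional nuisance columns (`age`, `sex`,
#'   `motion`).
#' @param case_level Level of `group` treated as the patient group.
#' @param n_perm,seed Passed to [permutation_glm()].
#' @return List with `pca`, `glm` (permutation results for all retained
#'   components), `component` (index of the separating retained component),
#'   `p_fwe` (its FWE p), `scores_oriented` (its oriented scores), and
#'   `severity_r`/`severity_p` (within-case adjusted correlation, `NA` when no
#'   severity is supplied).
#' @export
fo_group_analysis <- function(fo, covariates, case_level = NULL,
                              n_perm = 10000, seed = 1) {
  fo <- as.matrix(fo)
  group <- as.factor(covariates$group)
  if (nlevels(group) != 2) stop("group must have two levels")
  if (is.null(case_level))
    case_level <- if ("case" %in% levels(group)) "case" else levels(group)[2]
  is_case <- group == case_level

  pca <- pca_kaiser(fo)
  ret <- pca$retained
  if (length(ret) == 0) ret <- 1L   # degenerate: fall back to the first component
  scores <- pca$scores[, ret, drop = FALSE]

  nuis <- intersect(c("age", "sex", "motion"), names(covariates))
  X <- cbind(intercept = 1, group = as.numeric(is_case))
  for (v in nuis) X <- cbind(X, as.numeric(covariates[[v]]))
  colnames(X) <- c("intercept", "group", nuis)
  res <- permutation_glm(scores, X, contrasts = "group", n_perm = n_perm,
                         seed = seed)

  sep <- which.max(abs(res$t))
  sc <- scores[, sep]
  if (mean(sc[is_case]) > mean(sc[!is_case])) sc <- -sc   # cases score lower

  severity_r <- NA_real_; severity_p <- NA_real_
  if (!is.null(covariates$severity)) {
    sev <- covariates$severity[is_case]
    covs <- if (length(nuis))
      as.matrix(as.data.frame(lapply(covariates[nuis], as.numeric)))[is_case, , drop = FALSE]
    else NULL
    pc <- partial_correlation(sc[is_case], sev, covs)
    severity_r <- pc$r; severity_p <- pc$p
  }
  list(pca = pca, glm = res, component = ret[sep], p_fwe = res$p_fwe[sep],
       t = res$t[sep], scores_oriented = sc,
       severity_r = severity_r, severity_p = severity_p)
}
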