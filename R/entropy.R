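# Sample entropy and multiscale entropy (MSE) of component timecourses.
#
# Sample entropy follows the Richman-Moorman convention: both template
# lengths draw their templates from the first T - m positions, pairs are
# counted with i < j and self-matches excluded, and the tolerance r is applied
# as a Chebyshev distance. MSE coarse-grains by non-overlapping window means
# and, following the Costa convention, keeps r fixed in units of the original
# (standardized) series rather than re-normalizing at each scale.

#' Coarse-grain a series by non-overlapping window means
#'
#' @param x Numeric series.
#' @param tau Scale factor (window length); `tau = 1` returns `x` unchanged.
#' @return Series of length `floor(length(x) / tau)`; element j is the mean of
#'   elements `(j-1)*tau + 1` to `j*tau`.
#' @export
coarse_grain <- function(x, tau) {
  stopifnot(tau >= 1, tau == round(tau))
  if (tau == 1) return(x)
  n <- floor(length(x) / tau)
  if (n < 1) stop("series too short for scale ", tau)
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A/B)` where B counts pairs of length-`m` templates within Chebyshev
#' distance `r` and A counts the same for length-`m+1` templates, both over
#' template start positions `1..T-m`, pairs `i < j`, self-matches excluded.
#' Lower values indicate a more repetitive (less complex) signal. When no
#' template pairs match at either length the value is undefined and `NA` is
#' returned (callers exclude and log such channels).
#'
#' @param x Numeric series of length >= m + 2.
#' @param m Template (pattern) length.
#' @param r Matching tolerance, in the units of `x`.
#' @return Non-negative scalar, or `NA_real_` if undefined.
#' @export
sample_entropy <- function(x, m = 1, r = 0.35) {
  stopifnot(m >= 1, r > 0)
  T <- length(x)
  if (T < m + 2) stop("series too short for template length ", m)
  N <- T - m                         # templates of both lengths start at 1..N
  # running Chebyshev distance over template offsets, as N x N matrices
  D <- abs(outer(x[seq_len(N)], x[seq_len(N)], "-"))
  if (m > 1) for (k in seq_len(m - 1)) {
    Dk <- abs(outer(x[seq_len(N) + k], x[seq_len(N) + k], "-"))
    D <- pmax(D, Dk)
  }
  upper <- upper.tri(D)
  B <- sum(D[upper] <= r)
  Dm1 <- pmax(D, abs(outer(x[seq_len(N) + m], x[seq_len(N) + m], "-")))
  A <- sum(Dm1[upper] <= r)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Multiscale-entropy parameters
#'
#' Default parameters: template length 1, tolerance 0.35 (in SD units of the
#' standardized series), and 4 scales for series of at least 300 volumes or 3
#' scales for at least 200 (fewer coarse-grained points inflate the entropy
#' estimate's error).
#'
#' @param T Series length the parameters must be valid for.
#' @param m,r,S Template length, tolerance and number of scales; `S = NULL`
#'   picks the length-based default.
#' @return List with class `entropy_params`.
#' @export
entropy_params <- function(T, m = 1, r = 0.35, S = NULL) {
  if (is.null(S)) S <- if (T >= 300) 4 else if (T >= 200) 3 else 2
  stopifnot(m >= 1, r > 0, S >= 1)
  if (floor(T / S) - m < 10)
    stop("coarsest scale leaves fewer than 10 usable points")
  structure(list(m = m, r = r, S = S), class = "entropy_params")
}

#' Multiscale entropy of one series
#'
#' Sample entropy of the coarse-grained series at scales `1..S`, and their
#' sum. With `renormalize = FALSE` (default) the tolerance r stays fixed
#' across scales in the units of the input series; with `TRUE` each
#' coarse-grained series is re-standardized first.
#'
#' @param x Numeric series (standardized by convention).
#' @param params An [entropy_params()] object.
#' @param renormalize Re-apply r per scale in that scale's SD units.
#' @return List with `per_scale` (length-S vector, possibly containing `NA`)
#'   and `mse` (sum over scales; `NA` if any scale is undefined).
#' @export
multiscale_entropy <- function(x, params = entropy_params(length(x)),
                               renormalize = FALSE) {
  per_scale <- vapply(seq_len(params$S), function(s) {
    cg <- coarse_grain(x, s)
    if (renormalize) cg <- as.numeric(scale(cg))
    sample_entropy(cg, params$m, params$r)
  }, 1)
  list(per_scale = per_scale, mse = sum(per_scale))
}

#' Subject-level multiscale entropy
#'
#' Per-channel MSE (sum of sample entropy over scales) averaged across
#' channels. Channels whose entropy is undefined at any scale are excluded
#' from the average with a warning reporting the count.
#'
#' @param x Timepoints x channels matrix of standardized series.
#' @param params An [entropy_params()] object.
#' @return List with `subject_mse` (scalar), `per_channel` (length-C vector of
#'   channel MSE sums, `NA` where undefined), `per_channel_per_scale` (C x S),
#'   and `n_undefined`.
#' @export
subject_mse <- function(x, params = entropy_params(nrow(x))) {
  x <- as.matrix(x)
  per <- t(apply(x, 2, function(ch) multiscale_entropy(ch, params)$per_scale))
  per <- matrix(per, nrow = ncol(x))   # C x S even when S = 1
  sums <- rowSums(per)
  bad <- sum(is.na(sums))
  if (bad == ncol(x)) stop("sample entropy undefined on every channel")
  if (bad > 0)
    warning(bad, " channel(s) with undefined entropy excluded from the average")
  list(subject_mse = mean(sums, na.rm = TRUE), per_channel = sums,
       per_channel_per_scale = per, n_undefined = bad)
}
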