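# Maximal overlap discrete wavelet transform (MODWT) and wavelet-correlation
# association matrices. The MODWT is shift-invariant and returns same-length
# detail series per dyadic frequency band; it is computed by the standard
# pyramid algorithm with periodic boundary handling, with rescaled
# (1/sqrt(2)) Daubechies extremal-phase filters.

# Daubechies extremal-phase scaling filters (DWT normalization, sum = sqrt 2).
daubechies_filter <- function(filter = c("d4", "d6", "d8", "haar")) {
  filter <- match.arg(filter)
  g <- switch(filter,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    d6 = c(0.332670552950083, 0.806891509311092, 0.459877502118491,
           -0.135011020010255, -0.085441273882027, 0.035226291885710),
    d8 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # quadrature mirror wavelet filter
  list(g = g / sqrt(2), h = h / sqrt(2), L = L, name = filter)
}

# One MODWT pyramid stage: circular filtering with the level-j upsampled filter.
modwt_stage <- function(v, f, j) {
  N <- length(v)
  step <- 2^(j - 1)
  out_w <- numeric(N); out_v <- numeric(N)
  idx0 <- seq_len(N) - 1L
  for (l in seq_along(f$g) - 1L) {
    src <- v[((idx0 - step * l) %% N) + 1L]
    out_w <- out_w + f$h[l + 1] * src
    out_v <- out_v + f$g[l + 1] * src
  }
  list(w = out_w, v = out_v)
}

#' MODWT decomposition
#'
#' Maximal overlap discrete wavelet transform of one series, to `level`
#' levels, with periodic boundary conditions. Detail series `d[[j]]` isolates
#' the j-th dyadic frequency band (see [band_frequency_range()]); all outputs
#' have the length of the input.
#'
#' @param x Numeric series.
#' @param level Decomposition depth.
#' @param filter `"d4"` (default), `"d6"`, `"d8"` or `"haar"`.
#' @return List with `d` (list of detail series), `s` (final smooth),
#'   `n_boundary` (per level, count of boundary-affected leading
#'   coefficients), `filter`, `level`.
#' @export
modwt <- function(x, level, filter = "d4") {
  f <- daubechies_filter(filter)
  N <- length(x)
  if (N < f$L * 2^level)
    stop("series too short for level ", level, " with filter ", f$name)
  d <- vector("list", level)
  nb <- integer(level)
  v <- x
  for (j in seq_len(level)) {
    st <- modwt_stage(v, f, j)
    d[[j]] <- st$w
    v <- st$v
    nb[j] <- min((2^j - 1) * (f$L - 1), N)  # L_j - 1 boundary coefficients
  }
  list(d = d, s = v, n_boundary = nb, filter = f$name, level = level)
}

#' Detail coefficients at one MODWT level
#'
#' @inheritParams modwt
#' @param drop_boundary Drop the leading boundary-affected coefficients.
#' @return Numeric vector of detail coefficients.
#' @export
modwt_detail <- function(x, level, filter = "d4", drop_boundary = FALSE) {
  w <- modwt(x, level, filter)
  out <- w$d[[level]]
  if (drop_boundary) out <- out[-seq_len(min(w$n_boundary[level], length(out) - 2))]
  out
}

#' Frequency band of a dyadic wavelet level
#'
#' With sampling interval `TR` seconds (sampling rate `fs = 1/TR`), wavelet
#' level j captures the band `(fs / 2^(j+1), fs / 2^j)` Hz.
#'
#' @param TR Repetition (sampling) interval in seconds.
#' @param level Wavelet level (>= 1).
#' @return Numeric vector `c(f_lo, f_hi)` in Hz.
#' @examples
#' band_frequency_range(2, 2)    # 0.0625-0.125 Hz
#' band_frequency_range(2.5, 2)  # 0.05-0.10 Hz
#' @export
band_frequency_range <- function(TR, level) {
  stopifnot(TR > 0, level >= 1)
  fs <- 1 / TR
  c(fs / 2^(level + 1), fs / 2^level)
}

#' Wavelet correlation association matrix
#'
#' Pearson correlations between all channel pairs' MODWT detail coefficients
#' at one level, after dropping the boundary-affected leading coefficients:
#' a band-limited functional-connectivity estimate.
#'
#' @param x Timepoints x channels matrix.
#' @param level Wavelet level selecting the frequency band (default 2).
#' @param filter Daubechies filter name.
#' @param TR Optional sampling interval; if given, the band in Hz is attached.
#' @return An R x R symmetric correlation matrix with unit diagonal, with
#'   attributes `level`, `filter` and (optionally) `band_hz`.
#' @export
wavelet_correlation_matrix <- function(x, level = 2, filter = "d4", TR = NULL) {
  x <- as.matrix(x)
  det <- apply(x, 2, modwt_detail, level = level, filter = filter,
               drop_boundary = TRUE)
  sds <- apply(det, 2, sd)
  if (any(sds == 0))
    stop("zero-variance detail series in channel(s) ",
         paste(which(sds == 0), collapse = ", "))
  R <- cor(det)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (!is.null(colnames(x))) dimnames(R) <- list(colnames(x), colnames(x))
  attr(R, "level") <- level
  attr(R, "filter") <- filter
  if (!is.null(TR)) attr(R, "band_hz") <- band_frequency_range(TR, level)
  R
}
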