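# Reference noise generators used in validation of the entropy and wavelet
# modules (white, 1/f "pink" via spectral synthesis, and AR(1)).

#' Generate a standardized noise series
#'
#' White Gaussian noise, 1/f (pink) noise synthesized in the frequency domain
#' (Fourier amplitudes scaled by `1/sqrt(f)`), or a stationary AR(1) series.
#' All outputs are standardized to mean 0, SD 1.
#'
#' @param n Series length.
#' @param type `"white"`, `"pink"` or `"ar1"`.
#' @param phi AR(1) coefficient (for `type = "ar1"`).
#' @param seed Optional integer seed.
#' @return Numeric series of length n.
#' @export
noise_series <- function(n, type = c("white", "pink", "ar1"), phi = 0.9,
                         seed = NULL) {
  type <- match.arg(type)
  gen <- function() {
    x <- switch(type,
      white = rnorm(n),
      ar1 = as.numeric(stats::filter(rnorm(n), phi, method = "recursive")),
      pink = {
        z <- fft(rnorm(n))
        f <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric freqs
        Re(fft(z / sqrt(f), inverse = TRUE)) / n
      })
    as.numeric(scale(x))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
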