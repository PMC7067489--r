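# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

#' Check a scalar is a finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a master seed
#'
#' Child seeds are `master + offset`, wrapped to stay inside the 32-bit
#' integer range so large master seeds remain valid R seeds.
#' @noRd
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + as.numeric(offset)) %% 2147483647)
}

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; mean direction `mu`, concentration
#' `kappa >= 0`. `kappa = 0` reduces to the uniform distribution on
#' (-pi, pi]. Very large `kappa` is handled by a wrapped-normal
#' approximation (sd = 1/sqrt(kappa)), accurate for kappa > 1e5.
#'
#' @param n number of draws
#' @param mu mean direction (radians)
#' @param kappa concentration (dimensionless, >= 0)
#' @return numeric vector of angles in (-pi, pi]
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 0) {
  abort_if(kappa < 0, "von Mises concentration must be >= 0, got %g", kappa)
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi))
  }
  if (kappa > 1e5) {
    th <- stats::rnorm(n, 0, 1 / sqrt(kappa))
    return(((th + mu + pi) %% (2 * pi)) - pi)
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

#' Synthesize 1/f^alpha Gaussian noise
#'
#' Spectral shaping of white Gaussian noise: the amplitude spectrum is
#' multiplied by f^(-alpha/2) (DC term zeroed) and the result rescaled to a
#' target RMS.
#'
#' @param n number of samples
#' @param fs sampling rate (Hz)
#' @param alpha spectral slope of the power spectrum (1/f^alpha)
#' @param rms target root-mean-square amplitude
#' @return numeric vector of length `n`
#' @keywords internal
noise_1f <- function(n, fs, alpha = 1, rms = 1) {
  if (rms == 0) return(numeric(n))
  N <- stats::nextn(n, 2)          # fast FFT length; truncate afterwards
  w <- stats::rnorm(N)
  sp <- stats::fft(w)
  freqs <- c(0, seq_len(N - 1)) * fs / N
  # two-sided frequency axis: mirror above Nyquist
  freqs <- pmin(freqs, fs - freqs)
  gain <- c(0, freqs[-1]^(-alpha / 2))
  x <- Re(stats::fft(sp * gain, inverse = TRUE))[seq_len(n)] / N
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * rms / s
}
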