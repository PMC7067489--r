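#' Logarithmic frequency grid for time-frequency analysis
#'
#' Geometric progression of `n` frequencies from `fmin` to `fmax` inclusive
#' (default 100 values, 2-250 Hz), with a fixed number of Morlet cycles per
#' frequency.
#'
#' @param fmin lowest frequency (Hz)
#' @param fmax highest frequency (Hz)
#' @param n number of frequencies
#' @param n_cycles Morlet wavelet cycles at every frequency
#' @return object of class `frequency_grid` with fields `frequencies` and
#'   `n_cycles`
#' @export
frequency_grid <- function(fmin = 2, fmax = 250, n = 100, n_cycles = 7) {
  abort_if(fmin <= 0 || fmax <= fmin, "need 0 < fmin < fmax")
  abort_if(n < 2, "need at least 2 frequencies")
  structure(list(frequencies = exp(seq(log(fmin), log(fmax), length.out = n)),
                 n_cycles = n_cycles),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("<frequency_grid> %d log-spaced frequencies %.3g..%.3g Hz, %g cycles\n",
              length(f), f[1], f[length(f)], x$n_cycles))
  invisible(x)
}

# Morlet temporal SD at frequency f for a given cycle count.
morlet_sigma_t <- function(f, n_cycles) n_cycles / (2 * pi * f)

# Frequency-domain gain of a complex Morlet wavelet on an N-point grid at
# sampling rate fs: a Gaussian centred on +f, normalized to unit peak
# frequency response so that a pure sinusoid yields maximal power at its
# own frequency bin (unit-energy normalization would tilt power by
# sqrt(sigma_t) across frequencies; ITPC is normalization-invariant either
# way).
morlet_gain <- function(f, fs, N, n_cycles) {
  sigma <- morlet_sigma_t(f, n_cycles)
  fk <- (seq_len(N) - 1) * fs / N
  fk <- ifelse(fk > fs / 2, fk - fs, fk)
  exp(-0.5 * (2 * pi * (fk - f))^2 * sigma^2)
}

# Complex Morlet coefficients for one contact via FFT convolution.
# x: trials x samples matrix. Returns a closure evaluated per frequency to
# keep peak memory at one frequency's worth of coefficients.
morlet_engine <- function(x, fs, n_cycles, fmin) {
  ns <- ncol(x)
  # pad by half the longest wavelet: circular wrap-around is then confined
  # to samples within half a wavelet of the epoch edges (already flagged as
  # edge-contaminated), at Gaussian-tail amplitude
  pad <- ceiling(fs * n_cycles / (2 * fmin))
  N <- stats::nextn(ns + pad, 2)
  # t(x) is samples x trials; zero-pad rows to N before the forward FFT
  X <- stats::mvfft(rbind(t(x), matrix(0, N - ns, nrow(x))))
  function(f) {
    H <- morlet_gain(f, fs, N, n_cycles)
    C <- stats::mvfft(X * H, inverse = TRUE) / N
    C[seq_len(ns), , drop = FALSE]                  # samples x trials
  }
}

#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet coefficients (7 cycles per frequency by default) for one
#' contact of an epoch array, over a logarithmic frequency grid. The epoch
#' must be at least as long as the longest wavelet (`n_cycles/fmin`
#' seconds). Samples closer than half the wavelet duration to either epoch
#' edge are flagged as edge-contaminated in `edge_ok`.
#'
#' @param epochs an `epoch_array`
#' @param grid a [frequency_grid()]
#' @param contact contact index or label (single channel)
#' @param keep_window optional length-2 numeric (s): crop the returned
#'   coefficients to this time window to bound memory
#' @return object of class `tf_decomposition`: complex `coefficients`
#'   (trials x frequencies x time), `grid`, `time_axis`, `edge_ok`
#'   (frequencies x time logical)
#' @export
morlet_tfr <- function(epochs, grid = frequency_grid(), contact = 1L,
                       keep_window = NULL) {
  abort_if(!inherits(epochs, "epoch_array"), "`epochs` must be an epoch_array")
  fs <- epochs$sampling_rate
  ta <- epochs$time_axis
  fmin <- min(grid$frequencies)
  min_dur <- grid$n_cycles / fmin
  abort_if(diff(range(ta)) < min_dur - 1e-9,
           "epoch (%.3g s) shorter than the longest wavelet; need >= %.3g s",
           diff(range(ta)), min_dur)
  x <- contact_matrix(epochs, contact)
  eng <- morlet_engine(x, fs, grid$n_cycles, fmin)
  keep <- if (is.null(keep_window)) seq_along(ta) else
    which(ta >= keep_window[1] - 1e-9 & ta <= keep_window[2] + 1e-9)
  nt <- nrow(x); nf <- length(grid$frequencies)
  coef <- array(0i, dim = c(nt, nf, length(keep)))
  edge_ok <- matrix(TRUE, nf, length(keep))
  for (fi in seq_len(nf)) {
    C <- eng(grid$frequencies[fi])                  # samples x trials
    coef[, fi, ] <- t(C[keep, , drop = FALSE])
    half <- grid$n_cycles / (2 * grid$frequencies[fi])
    tk <- ta[keep]
    edge_ok[fi, ] <- (tk - ta[1] >= half) & (ta[length(ta)] - tk >= half)
  }
  structure(list(coefficients = coef, grid = grid, time_axis = ta[keep],
                 edge_ok = edge_ok, sampling_rate = fs),
            class = "tf_decomposition")
}

#' Intertrial phase coherence map
#'
#' For every time-frequency point, the mean resultant length of the trials'
#' unit phase vectors: `ITPC(f, t) = | mean_k c_k(f,t) / |c_k(f,t)| |`.
#' Values lie in `[0, 1]`; 1 means perfect phase alignment across trials, 0
#' no consistency. Coefficients with zero magnitude carry no phase and are
#' excluded with the trial count adjusted at that point (recorded in
#' `n_used`).
#'
#' @param tf a `tf_decomposition` from [morlet_tfr()]
#' @return object of class `itpc_map`: `values` (frequencies x time in
#'   `[0,1]`), `time_axis`, `grid`, `n_trials`, `n_used`
#' @export
compute_itpc <- function(tf) {
  abort_if(!inherits(tf, "tf_decomposition"), "`tf` must be a tf_decomposition")
  d <- dim(tf$coefficients)
  abort_if(d[1] < 2, "ITPC needs at least 2 trials")
  mag <- Mod(tf$coefficients)
  ok <- mag > 0
  ph <- tf$coefficients
  ph[ok] <- ph[ok] / mag[ok]
  ph[!ok] <- 0i
  n_used <- apply(ok, c(2, 3), sum)
  sums <- apply(ph, c(2, 3), sum)
  vals <- matrix(0, d[2], d[3])
  nz <- n_used > 0
  vals[nz] <- Mod(sums[nz]) / n_used[nz]
  vals <- pmin(pmax(vals, 0), 1)        # resultant length is in [0,1] exactly
  structure(list(values = vals, time_axis = tf$time_axis, grid = tf$grid,
                 n_trials = d[1], n_used = n_used),
            class = "itpc_map")
}

# Number of samples in the one-cycle window at frequency f.
cycle_window_samples <- function(f, fs) max(1L, as.integer(round(fs / f)))

#' Average an ITPC map over one oscillatory cycle per frequency
#'
#' The ITPC spectrum: for each frequency `f` the map is averaged over the
#' half-open window `[0, 1/f)` seconds from stimulus onset (rounded to the
#' sample grid), so the window length follows the oscillation - 500 ms at
#' 2 Hz, 20 ms at 50 Hz.
#'
#' @param map an `itpc_map` whose time axis covers `[0, 1/fmin)`
#' @param sampling_rate sampling rate (Hz); taken from the map time axis
#'   when `NULL`
#' @return object of class `itpc_spectrum` with `raw` values in `[0,1]`,
#'   `window_s` (window length used per frequency, seconds) and `grid`;
#'   `normalized` is filled by [normalize_spectrum()]
#' @export
cycle_window_average <- function(map, sampling_rate = NULL) {
  abort_if(!inherits(map, "itpc_map"), "`map` must be an itpc_map")
  ta <- map$time_axis
  fs <- sampling_rate %||% (1 / stats::median(diff(ta)))
  freqs <- map$grid$frequencies
  i0 <- which.min(abs(ta))
  abort_if(abs(ta[i0]) > 1e-9, "map time axis must contain t = 0")
  raw <- numeric(length(freqs))
  window_s <- numeric(length(freqs))
  for (fi in seq_along(freqs)) {
    nw <- cycle_window_samples(freqs[fi], fs)
    idx <- i0 + seq_len(nw) - 1L
    abort_if(max(idx) > length(ta),
             "one-cycle window at %.3g Hz (%.3g s) exceeds the map time axis",
             freqs[fi], nw / fs)
    raw[fi] <- mean(map$values[fi, idx])
    window_s[fi] <- nw / fs
  }
  structure(list(raw = raw, normalized = NULL, grid = map$grid,
                 window_s = window_s, n_trials = map$n_trials),
            class = "itpc_spectrum")
}

#' Z-score an ITPC spectrum across frequencies
#'
#' Normalization used before any across-patient comparison: the raw
#' spectrum is standardized over its frequency bins (mean 0, SD 1).
#'
#' @param spectrum an `itpc_spectrum` with `raw` filled
#' @return the spectrum with `normalized` filled
#' @export
normalize_spectrum <- function(spectrum) {
  abort_if(!inherits(spectrum, "itpc_spectrum"),
           "`spectrum` must be an itpc_spectrum")
  s <- stats::sd(spectrum$raw)
  abort_if(!is.finite(s) || s == 0,
           "constant raw spectrum: z-score undefined")
  spectrum$normalized <- (spectrum$raw - mean(spectrum$raw)) / s
  spectrum
}

#' @export
print.itpc_spectrum <- function(x, ...) {
  f <- x$grid$frequencies
  cat(sprintf("<itpc_spectrum> %d frequencies %.3g..%.3g Hz, %d trials%s\n",
              length(f), f[1], f[length(f)], x$n_trials,
              if (is.null(x$normalized)) " (raw only)" else " (normalized)"))
  invisible(x)
}

#' ITPC spectrum of one contact, end to end
#'
#' Convenience wrapper running the Morlet decomposition, ITPC, one-cycle
#' averaging and z-normalization for a single contact. Uses a streaming
#' FFT path that never materializes the full trials x frequencies x time
#' coefficient block, so it is the route of choice for cohort-scale runs.
#'
#' @param epochs an `epoch_array`
#' @param grid a [frequency_grid()]
#' @param contact contact index or label
#' @return a normalized `itpc_spectrum`
#' @export
itpc_spectrum <- function(epochs, grid = frequency_grid(), contact = 1L) {
  abort_if(!inherits(epochs, "epoch_array"), "`epochs` must be an epoch_array")
  abort_if(n_trials(epochs) < 2, "ITPC needs at least 2 trials")
  fs <- epochs$sampling_rate
  ta <- epochs$time_axis
  fmin <- min(grid$frequencies)
  abort_if(diff(range(ta)) < grid$n_cycles / fmin - 1e-9,
           "epoch shorter than the longest wavelet; need >= %.3g s",
           grid$n_cycles / fmin)
  i0 <- onset_index(epochs)
  nmax <- cycle_window_samples(fmin, fs)
  abort_if(i0 + nmax - 1L > length(ta),
           "epoch must cover the one-cycle window [0, %.3g s)", nmax / fs)
  x <- contact_matrix(epochs, contact)
  eng <- morlet_engine(x, fs, grid$n_cycles, fmin)
  freqs <- grid$frequencies
  raw <- numeric(length(freqs))
  window_s <- numeric(length(freqs))
  for (fi in seq_along(freqs)) {
    nw <- cycle_window_samples(freqs[fi], fs)
    idx <- i0 + seq_len(nw) - 1L
    C <- eng(freqs[fi])[idx, , drop = FALSE]        # window samples x trials
    mag <- Mod(C)
    ok <- mag > 0
    C[ok] <- C[ok] / mag[ok]
    C[!ok] <- 0i
    n_used <- rowSums(ok)
    itpc_t <- ifelse(n_used > 0, Mod(rowSums(C)) / pmax(n_used, 1L), 0)
    raw[fi] <- min(max(mean(itpc_t), 0), 1)
    window_s[fi] <- nw / fs
  }
  normalize_spectrum(structure(
    list(raw = raw, normalized = NULL, grid = grid, window_s = window_s,
         n_trials = nrow(x)),
    class = "itpc_spectrum"))
}

#' ITPC at selected time-frequency points by direct convolution
#'
#' Independent slow path: complex Morlet coefficients are computed as
#' explicit time-domain inner products (wavelet truncated at 5 temporal
#' SDs), then converted to the mean resultant length across trials. Useful
#' for spot checks and for very large trial counts where only a few points
#' are needed.
#'
#' @param epochs an `epoch_array`
#' @param freqs frequencies (Hz) at which to evaluate
#' @param times times (s, relative to onset) at which to evaluate
#' @param n_cycles wavelet cycles
#' @param contact contact index or label
#' @return matrix `length(freqs)` x `length(times)` of ITPC values
#' @export
itpc_at <- function(epochs, freqs, times, n_cycles = 7, contact = 1L) {
  abort_if(!inherits(epochs, "epoch_array"), "`epochs` must be an epoch_array")
  abort_if(n_trials(epochs) < 2, "ITPC needs at least 2 trials")
  x <- contact_matrix(epochs, contact)
  fs <- epochs$sampling_rate
  ta <- epochs$time_axis
  out <- matrix(NA_real_, length(freqs), length(times))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- morlet_sigma_t(f, n_cycles)
    hw <- ceiling(5 * sigma * fs)
    toff <- (-hw:hw) / fs
    w <- exp(2i * pi * f * toff) * exp(-toff^2 / (2 * sigma^2))
    for (ti in seq_along(times)) {
      ci <- which.min(abs(ta - times[ti]))
      idx <- (ci - hw):(ci + hw)
      abort_if(min(idx) < 1 || max(idx) > length(ta),
               "wavelet at %.3g Hz does not fit inside the epoch at t = %.3g s",
               f, times[ti])
      coef <- x[, idx, drop = FALSE] %*% Conj(w)
      ph <- coef[Mod(coef) > 0]
      out[fi, ti] <- if (length(ph) > 0)
        min(Mod(mean(ph / Mod(ph))), 1) else 0
    }
  }
  out
}
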