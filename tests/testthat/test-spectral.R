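# Morlet decomposition, ITPC, one-cycle averaging, normalization.

test_that("frequency grid is log-spaced with exact endpoints", {
  g <- frequency_grid()
  f <- g$frequencies
  expect_length(f, 100)
  expect_equal(f[1], 2)
  expect_equal(f[100], 250)
  # log-uniform spacing: constant ratio
  expect_equal(diff(log(f)), rep(diff(log(f))[1], 99), tolerance = 1e-12)
  expect_equal(g$n_cycles, 7)
  expect_error(frequency_grid(fmin = 0), "fmin")
})

test_that("a pure sinusoid has maximal power at the nearest grid frequency", {
  g <- frequency_grid(20, 100, 30, n_cycles = 7)
  ep <- make_sine_epochs(3, 45, fs = 500, window = c(-2, 2))
  tf <- morlet_tfr(ep, g, keep_window = c(-0.1, 0.1))
  pow <- apply(Mod(tf$coefficients)^2, 2, mean)
  expect_equal(which.max(pow), which.min(abs(g$frequencies - 45)))
})

test_that("morlet_tfr validates epoch length and flags edges", {
  g <- frequency_grid(2, 50, 10)
  short <- make_sine_epochs(2, 10, fs = 250, window = c(-1, 1))
  expect_error(morlet_tfr(short, g), "wavelet")
  ok <- make_sine_epochs(2, 10, fs = 250, window = c(-2, 2))
  tf <- morlet_tfr(ok, g)
  # at the lowest frequency the 7-cycle wavelet half-length (1.75 s) leaves
  # only the central 0.5 s uncontaminated
  expect_false(tf$edge_ok[1, 1])
  expect_true(tf$edge_ok[1, which.min(abs(tf$time_axis))])
  # zero input gives zero coefficients
  z <- ok
  z$data[] <- 0
  expect_equal(max(Mod(morlet_tfr(z, g)$coefficients)), 0)
})

test_that("ITPC hits its analytic extremes", {
  g <- frequency_grid(5, 40, 8, n_cycles = 5)
  # identical trials -> ITPC 1 everywhere the signal has support
  ep <- make_sine_epochs(5, 10, fs = 250, window = c(-1.5, 1.5))
  m <- compute_itpc(morlet_tfr(ep, g, keep_window = c(-0.2, 0.5)))
  expect_true(all(m$values > 1 - 1e-9))
  expect_true(all(m$values <= 1 + 1e-12))
  # two antiphase trials -> ITPC 0 at the stimulation frequency
  ep2 <- make_sine_epochs(2, 10, fs = 250, window = c(-1.5, 1.5),
                          phases = c(0, pi))
  m2 <- compute_itpc(morlet_tfr(ep2, g, keep_window = c(-0.1, 0.1)))
  fi <- which.min(abs(g$frequencies - 10))
  expect_lt(max(m2$values[fi, ]), 1e-6)
  # single trial is rejected
  ep1 <- make_sine_epochs(2, 10, fs = 250, window = c(-1.5, 1.5))
  tf1 <- morlet_tfr(ep1, g, keep_window = c(0, 0.1))
  tf1$coefficients <- tf1$coefficients[1, , , drop = FALSE]
  expect_error(compute_itpc(tf1), "2 trials")
})

test_that("zero-magnitude coefficients are excluded with adjusted counts", {
  g <- frequency_grid(5, 40, 4, n_cycles = 5)
  ep <- make_sine_epochs(4, 10, fs = 250, window = c(-1.5, 1.5))
  tf <- morlet_tfr(ep, g, keep_window = c(0, 0.05))
  tf$coefficients[2, , ] <- 0i
  m <- compute_itpc(tf)
  expect_true(all(m$n_used == 3))
  expect_true(all(m$values >= 0 & m$values <= 1))
})

test_that("the one-cycle window length is exactly 1/f on the sample grid", {
  fs <- 1000
  g <- structure(list(frequencies = c(2, 8, 50), n_cycles = 5),
                 class = "frequency_grid")
  ta <- seq(-3, 3, by = 1 / fs)
  vals <- matrix(stats::runif(3 * length(ta)), 3)
  m <- structure(list(values = vals, time_axis = ta, grid = g, n_trials = 2,
                      n_used = NULL), class = "itpc_map")
  sp <- cycle_window_average(m)
  expect_equal(sp$window_s, c(0.5, 0.125, 0.02))
  # averaging identity on a constant map
  mc <- m
  mc$values[] <- 0.37
  expect_equal(cycle_window_average(mc)$raw, rep(0.37, 3))
  # window exceeding the epoch is an error
  m_short <- m
  keep <- ta <= 0.2
  m_short$values <- vals[, keep]
  m_short$time_axis <- ta[keep]
  expect_error(cycle_window_average(m_short), "exceeds")
  # manual check of the averaged samples at 8 Hz: [0, 125) ms
  i0 <- which(ta == 0)
  expect_equal(sp$raw[2], mean(vals[2, i0:(i0 + 124)]))
})

test_that("normalization is an exact z-score with affine invariance", {
  g <- frequency_grid(2, 250, 100)
  raw <- seq(0.01, 0.99, length.out = 100)   # linear ramp
  sp <- structure(list(raw = raw, normalized = NULL, grid = g,
                       window_s = NULL, n_trials = 10),
                  class = "itpc_spectrum")
  z <- normalize_spectrum(sp)$normalized
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  # closed-form standardized ramp
  expect_equal(z, (raw - mean(raw)) / stats::sd(raw))
  sp2 <- sp
  sp2$raw <- 3.7 * raw + 0.2
  expect_equal(normalize_spectrum(sp2)$normalized, z, tolerance = 1e-12)
  spc <- sp
  spc$raw <- rep(0.5, 100)
  expect_error(normalize_spectrum(spc), "constant")
})

test_that("the streaming spectrum path equals the canonical map path", {
  g <- frequency_grid(4, 60, 15, n_cycles = 5)
  withr::with_seed(13, {
    phases <- stats::runif(15, 0, 2 * pi)
  })
  ep <- make_sine_epochs(15, 12, fs = 250, window = c(-2, 2),
                         phases = phases, noise_sd = 0.5, seed = 14)
  fast <- itpc_spectrum(ep, g)
  slow <- normalize_spectrum(cycle_window_average(
    compute_itpc(morlet_tfr(ep, g))))
  expect_equal(fast$raw, slow$raw, tolerance = 1e-10)
  expect_equal(fast$normalized, slow$normalized, tolerance = 1e-10)
})

test_that("direct-convolution ITPC agrees with the FFT path", {
  g <- frequency_grid(6, 30, 5, n_cycles = 5)
  withr::with_seed(15, phases <- stats::runif(25, 0, 2 * pi))
  ep <- make_sine_epochs(25, 12, fs = 250, window = c(-2, 2),
                         phases = phases, noise_sd = 0.3, seed = 16)
  direct <- itpc_at(ep, g$frequencies[3], 0.1, n_cycles = 5)
  m <- compute_itpc(morlet_tfr(ep, g, keep_window = c(0.05, 0.15)))
  ti <- which.min(abs(m$time_axis - 0.1))
  expect_equal(as.numeric(direct), m$values[3, ti], tolerance = 1e-3)
})

test_that("phase-random trials match the mean-resultant-length null", {
  for (n in c(50, 500)) {
    withr::with_seed(n, phases <- stats::runif(n, 0, 2 * pi))
    ep <- make_sine_epochs(n, 10, fs = 250, window = c(-1.5, 1.5),
                           phases = phases)
    v <- as.numeric(itpc_at(ep, 10, 0.2, n_cycles = 5))
    oracle <- mrl_null_oracle(n)
    expect_lt(abs(v - oracle$mean), 3 * oracle$sd)
  }
})
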