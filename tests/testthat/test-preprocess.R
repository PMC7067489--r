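# Bipolar referencing, epoch rejection, AEP z-scoring, contact selection.

make_multi_electrode <- function(n_trials = 3, fs = 250,
                                 electrodes = c("A", "A", "A", "B", "B"),
                                 seed = 1) {
  ta <- seq(-0.5, 1, by = 1 / fs)
  nc <- length(electrodes)
  withr::with_seed(seed, {
    arr <- array(stats::rnorm(n_trials * nc * length(ta)),
                 dim = c(n_trials, nc, length(ta)))
  })
  epoch_array(arr, ta, fs,
              contact_labels = paste0(electrodes,
                                      stats::ave(seq_len(nc), electrodes,
                                                 FUN = seq_along)),
              electrodes = electrodes)
}

test_that("bipolar referencing pairs adjacent within-electrode contacts only", {
  ep <- make_multi_electrode(electrodes = rep("A", 15))
  bp <- bipolar_reference(ep)
  expect_equal(dim(bp$data)[2], 14)
  expect_identical(bp$montage, "bipolar")

  ep2 <- make_multi_electrode(electrodes = c(rep("A", 5), rep("B", 5)))
  bp2 <- bipolar_reference(ep2)
  expect_equal(dim(bp2$data)[2], 8)
  expect_false(any(grepl("^A.*-B", bp2$contact_labels)))

  # single-contact electrodes contribute nothing; all-single is an error
  ep3 <- make_multi_electrode(electrodes = c("A", "A", "C"))
  expect_equal(dim(bipolar_reference(ep3)$data)[2], 1)
  ep4 <- make_multi_electrode(electrodes = c("A", "B", "C"))
  expect_error(bipolar_reference(ep4), "bipolar")
  expect_error(bipolar_reference(bipolar_reference(ep)), "already")
})

test_that("bipolar referencing cancels common-mode signals and is linear", {
  ep <- make_multi_electrode(electrodes = rep("A", 4), seed = 5)
  # identical signal on all contacts -> all-zero channels
  com <- ep
  for (ch in 2:4) com$data[, ch, ] <- com$data[, 1, ]
  expect_equal(max(abs(bipolar_reference(com)$data)), 0)
  # adding a shared waveform to every contact leaves the output unchanged
  shifted <- ep
  shared <- sin(seq_len(dim(ep$data)[3]))
  for (tr in 1:3) for (ch in 1:4)
    shifted$data[tr, ch, ] <- shifted$data[tr, ch, ] + shared
  expect_equal(bipolar_reference(shifted)$data, bipolar_reference(ep)$data,
               tolerance = 1e-12)
  # linearity
  ep_b <- make_multi_electrode(electrodes = rep("A", 4), seed = 6)
  summed <- ep
  summed$data <- ep$data + ep_b$data
  expect_equal(bipolar_reference(summed)$data,
               bipolar_reference(ep)$data + bipolar_reference(ep_b)$data,
               tolerance = 1e-12)
})

test_that("epoch rejection removes exactly the injected artifact trials", {
  ep <- make_multi_electrode(n_trials = 10, seed = 2)
  # infinite threshold is the identity
  keep_all <- reject_epochs(ep, Inf)
  expect_equal(dim(keep_all$data)[1], 10)
  expect_length(attr(keep_all, "rejection_log")$rejected, 0)
  # inject a 10x spike into trial 4
  spiky <- ep
  spiky$data[4, 2, 100] <- 10 * max(abs(ep$data))
  thr <- 5 * max(abs(ep$data))
  cleaned <- reject_epochs(spiky, thr)
  expect_equal(attr(cleaned, "rejection_log")$rejected, 4L)
  expect_equal(dim(cleaned$data)[1], 9)
  # threshold below everything -> error naming the threshold
  expect_error(reject_epochs(ep, 1e-9), "threshold")
})

test_that("AEP z-scoring behaves like a per-trial z-score", {
  fs <- 1000
  ta <- seq(-0.5, 1, by = 1 / fs)
  n <- 40
  withr::with_seed(7, {
    arr <- array(stats::rnorm(n * 1 * length(ta)),
                 dim = c(n, 1, length(ta)))
  })
  ep <- epoch_array(arr, ta, fs)
  aep <- compute_aep(ep)
  expect_equal(aep$time_axis[1], -0.2, tolerance = 1e-9)
  expect_equal(aep$time_axis[length(aep$time_axis)], 0.635, tolerance = 1e-9)
  # pure noise: baseline of the averaged z-scored signal is ~0 with sd ~1/sqrt(n)
  bas <- aep$waveforms[1, aep$time_axis >= -0.15 & aep$time_axis <= 0.05]
  expect_lt(abs(mean(bas)), 4 / sqrt(n * length(bas)))
  # invariance to per-trial affine rescaling (positive scale)
  ep2 <- ep
  withr::with_seed(8, {
    scales <- stats::runif(n, 0.5, 3)
    offsets <- stats::rnorm(n, 0, 5)
  })
  for (i in seq_len(n))
    ep2$data[i, 1, ] <- scales[i] * ep$data[i, 1, ] + offsets[i]
  aep2 <- compute_aep(ep2)
  expect_equal(aep2$waveforms, aep$waveforms, tolerance = 1e-9)
  # constant signal -> zero baseline variance error
  epc <- ep
  epc$data[1, 1, ] <- 0
  expect_error(compute_aep(epc), "variance")
})

test_that("AEP converges to the z-scored evoked waveform as trials grow", {
  fs <- 250
  p <- spectral_profile(data.frame(freq = 10, amp = 6,
                                   n_cycles_duration = 4, onset = 0.05),
                        jitter_kappa = 1e300, noise_exponent = 1,
                        noise_amplitude = 2)
  big <- generate_evoked_epochs(p, 2000, fs, c(-0.5, 1), seed = 31)
  aep <- compute_aep(big)
  # noise-free reference waveform, z-scored against its own baseline stats:
  # with deterministic evoked + additive noise, the trial-mean z-score
  # converges to (evoked - baseline_mean)/E[baseline_sd]
  noisefree <- generate_evoked_epochs(
    spectral_profile(p$components, 1e300, 1, 0), 2, fs, c(-0.5, 1), seed = 1)
  ta <- noisefree$time_axis
  ev <- noisefree$data[1, 1, ]
  win <- ta >= -0.2 - 1e-9 & ta <= 0.635 + 1e-9
  peak_true <- max(abs(ev[win]))
  expect_equal(aep$peak_abs_amplitude, peak_true, tolerance = 0.1)
  # shape correlation of the averaged z-scored waveform with the evoked
  expect_gt(stats::cor(aep$waveforms[1, ], ev[win]), 0.98)
})

test_that("contact selection applies the threshold and the tie-break", {
  mk <- function(amps) {
    structure(list(time_axis = 0, waveforms = matrix(0, length(amps), 1),
                   peak_abs_amplitude = amps,
                   contacts = sprintf("c%d", seq_along(amps))),
              class = "aep_set")
  }
  sel <- select_contact(mk(c(35, 80, 60)), 40)
  expect_setequal(sel$kept, c("c2", "c3"))
  expect_identical(sel$best, "c2")
  expect_identical(names(sel$discarded), "c1")
  sel2 <- select_contact(mk(41), 40)
  expect_identical(sel2$best, "c1")
  sel3 <- select_contact(mk(c(80, 80)), 40)
  expect_identical(sel3$best, "c1")
  expect_error(select_contact(mk(c(10, 20)), 40), "no responsive contact")
})
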