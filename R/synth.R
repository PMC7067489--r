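#' Spectral profile of a synthetic evoked response
#'
#' A generative description of an impulse-evoked intracranial response: a
#' set of phase-locked damped oscillations riding on 1/f^alpha background
#' noise. Each component is a cosine at a fixed frequency under a smooth
#' alpha-function envelope that is zero before `onset`, rises quickly and
#' decays exponentially, staying above half maximum for about
#' `n_cycles_duration` oscillatory cycles. Trial-to-trial phase jitter is drawn from a von Mises
#' distribution with concentration `jitter_kappa` (0 = uniform phases, i.e.
#' no phase locking; large values = near-perfect locking), independently per
#' component.
#'
#' @param components data.frame with columns `freq` (Hz), `amp` (uV),
#'   `n_cycles_duration` (cycles), `onset` (s). At most one component per
#'   frequency.
#' @param jitter_kappa von Mises concentration of the trial phase jitter
#'   (dimensionless, >= 0)
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background
#' @param noise_amplitude RMS amplitude of the background noise (uV)
#' @return an object of class `spectral_profile`
#' @export
spectral_profile <- function(components, jitter_kappa = 5,
                             noise_exponent = 1, noise_amplitude = 1) {
  if (!is.data.frame(components)) components <- as.data.frame(components)
  need <- c("freq", "amp", "n_cycles_duration", "onset")
  miss <- setdiff(need, names(components))
  for (m in miss) {
    components[[m]] <- switch(m, n_cycles_duration = 2, onset = 0,
                              stop("components need columns freq and amp"))
  }
  abort_if(any(components$freq <= 0), "component frequencies must be > 0")
  abort_if(any(components$amp < 0), "component amplitudes must be >= 0")
  abort_if(anyDuplicated(components$freq) > 0,
           "at most one component per frequency")
  abort_if(!is_number(jitter_kappa) || jitter_kappa < 0,
           "jitter_kappa must be a single number >= 0")
  abort_if(noise_amplitude < 0, "noise_amplitude must be >= 0")
  structure(
    list(components = components[need], jitter_kappa = jitter_kappa,
         noise_exponent = noise_exponent, noise_amplitude = noise_amplitude),
    class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %d components, kappa = %g, noise 1/f^%g @ %g uV RMS\n",
              nrow(x$components), x$jitter_kappa, x$noise_exponent,
              x$noise_amplitude))
  print(x$components)
  invisible(x)
}

#' Default region x hemisphere spectral profiles
#'
#' Frequency pairs follow the reported group peak locations: left
#' association cortex theta/gamma (5/45 Hz), right association cortex
#' delta/beta (2.5/16 Hz), and a shared theta + beta-gamma pair (6/25 Hz)
#' in primary and secondary cortex bilaterally. Amplitudes are equal across
#' components; durations default to 5 cycles.
#'
#' Amplitudes default to 250 uV per component over 100 uV RMS background
#' noise: large enough that bipolar-montage AEPs clear the 40 uV
#' responsiveness threshold, while the single-trial wavelet-band SNR stays
#' of order one so intertrial coherence remains below its phase-jitter
#' ceiling and the ITPC spectrum shows localized (non-saturated) peaks.
#' Component durations default to 2 cycles at half maximum: the one-cycle
#' averaging window is designed for responses whose time constant is about
#' one oscillatory period, and transients much longer than that bias the
#' measured peak downward in frequency (the window at lower-frequency bins
#' integrates more of a still-rising envelope).
#'
#' @param jitter_kappa phase-jitter concentration shared by all profiles
#' @param noise_amplitude background noise RMS (uV)
#' @param amp evoked component amplitude (uV)
#' @return named list of `spectral_profile` objects, names `region.hemisphere`
#' @export
default_profiles <- function(jitter_kappa = 5, noise_amplitude = 100,
                             amp = 250) {
  comp <- function(freqs) data.frame(freq = freqs, amp = amp,
                                     n_cycles_duration = 2, onset = 0)
  mk <- function(freqs) spectral_profile(comp(freqs), jitter_kappa,
                                         1, noise_amplitude)
  list(
    AAC.left  = mk(c(5, 45)),
    AAC.right = mk(c(2.5, 16)),
    PAC.left  = mk(c(6, 25)),
    PAC.right = mk(c(6, 25)),
    SAC.left  = mk(c(6, 25)),
    SAC.right = mk(c(6, 25)))
}

# One damped-oscillation transient: cosine at `freq` under an alpha-function
# envelope env(t) = (t/tau) exp(1 - t/tau), which is exactly zero at onset
# (no spectral splatter from an onset step), rises quickly and decays
# exponentially. tau is set so the envelope stays above half maximum for
# n_cycles/freq seconds (the half-max width of x e^(1-x) is ~2.446 tau).
# A truncated symmetric Gabor instead injects a phase-locked broadband
# onset click that contaminates high-frequency ITPC bins.
damped_component <- function(time_axis, freq, amp, n_cycles, onset, phase) {
  tau <- n_cycles / (2.446 * freq)
  tt <- (time_axis - onset) / tau
  env <- ifelse(tt > 0, tt * exp(1 - tt), 0)
  amp * env * cos(2 * pi * freq * (time_axis - onset) + phase)
}

#' Generate synthetic evoked epochs
#'
#' Each trial is the sum of the profile's Gabor components, with the phase
#' of every component drawn independently per trial from
#' von Mises(0, jitter_kappa), plus independent 1/f^alpha noise. The
#' pre-onset segment contains noise only. Identical seeds give bit-identical
#' output.
#'
#' @param profile a [spectral_profile()]
#' @param n_trials number of trials (>= 2)
#' @param sampling_rate sampling rate in Hz
#' @param epoch_window length-2 numeric, epoch start/end in seconds relative
#'   to stimulus onset (must span t = 0)
#' @param n_contacts number of contacts on the (single) electrode shaft; all
#'   contacts see the same evoked components, scaled by `contact_gains`, and
#'   receive independent noise
#' @param contact_gains per-contact gain on the evoked signal, emulating
#'   distance to the generator along the shaft. Default: 1 for a single
#'   contact, otherwise a linear fall-off from 1 to 0 so adjacent-contact
#'   (bipolar) differences retain the evoked response.
#' @param seed integer RNG seed
#' @return an `epoch_array` (monopolar montage)
#' @export
generate_evoked_epochs <- function(profile, n_trials, sampling_rate = 1000,
                                   epoch_window = c(-5, 5), n_contacts = 1L,
                                   contact_gains = NULL, seed = 1L) {
  abort_if(!inherits(profile, "spectral_profile"),
           "`profile` must be a spectral_profile")
  abort_if(n_trials < 2, "need at least 2 trials")
  abort_if(epoch_window[1] > 0 || epoch_window[2] < 0,
           "epoch window must span stimulus onset t = 0")
  nyq <- sampling_rate / 2
  bad <- profile$components$freq >= nyq
  abort_if(any(bad),
           "component at %g Hz is at or above the Nyquist frequency (%g Hz)",
           profile$components$freq[which(bad)[1]], nyq)
  if (is.null(contact_gains)) {
    contact_gains <- if (n_contacts == 1L) 1
    else seq(1, 0, length.out = n_contacts)
  }
  abort_if(length(contact_gains) != n_contacts,
           "need one contact gain per contact")
  ta <- seq(epoch_window[1], epoch_window[2], by = 1 / sampling_rate)
  ns <- length(ta)
  nc <- nrow(profile$components)
  arr <- array(0, dim = c(n_trials, n_contacts, ns))
  withr::with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      evoked <- numeric(ns)
      if (nc > 0) {
        phases <- rvonmises(nc, 0, profile$jitter_kappa)
        for (ci in seq_len(nc)) {
          cm <- profile$components[ci, ]
          evoked <- evoked + damped_component(ta, cm$freq, cm$amp,
                                             cm$n_cycles_duration,
                                             cm$onset, phases[ci])
        }
      }
      for (ch in seq_len(n_contacts)) {
        arr[tr, ch, ] <- contact_gains[ch] * evoked +
          noise_1f(ns, sampling_rate, profile$noise_exponent,
                   profile$noise_amplitude)
      }
    }
  })
  epoch_array(arr, ta, sampling_rate,
              contact_labels = sprintf("E1-%02d", seq_len(n_contacts)),
              electrodes = rep("E1", n_contacts), montage = "monopolar")
}

#' Generate epochs with extra spectral components
#'
#' Emulates responses to acoustically richer stimuli (syllables), where
#' additional alpha (~10 Hz) and gamma (>25 Hz) components emerge
#' bilaterally: the base profile's component list is merged with
#' `extra_components` and epochs generated exactly as in
#' [generate_evoked_epochs()]. An empty `extra_components` therefore
#' reproduces the base output under the same seed.
#'
#' @param profile a [spectral_profile()]
#' @param extra_components data.frame of additional components with the same
#'   columns as in [spectral_profile()] (missing `n_cycles_duration`/`onset`
#'   default as there)
#' @inheritParams generate_evoked_epochs
#' @return an `epoch_array`
#' @export
generate_syllable_like_epochs <- function(profile, extra_components = NULL,
                                          n_trials, sampling_rate = 1000,
                                          epoch_window = c(-5, 5),
                                          n_contacts = 1L,
                                          contact_gains = NULL, seed = 1L) {
  comps <- profile$components
  if (!is.null(extra_components) && NROW(extra_components) > 0) {
    ex <- as.data.frame(extra_components)
    if (is.null(ex$n_cycles_duration)) ex$n_cycles_duration <- 5
    if (is.null(ex$onset)) ex$onset <- 0
    comps <- rbind(comps, ex[names(comps)])
  }
  merged <- spectral_profile(comps, profile$jitter_kappa,
                             profile$noise_exponent, profile$noise_amplitude)
  generate_evoked_epochs(merged, n_trials, sampling_rate, epoch_window,
                         n_contacts, contact_gains, seed)
}

#' Specification of a synthetic multi-patient cohort
#'
#' @param groups named list of `spectral_profile` objects; names are
#'   `region.hemisphere` (e.g. `"AAC.left"`)
#' @param n_patients_per_group patients per group (single count, recycled)
#' @param n_trials trials per patient (>= 2)
#' @param n_contacts contacts per patient
#' @param sampling_rate Hz
#' @param epoch_window length-2 numeric (s), spans t = 0
#' @param seed master seed; patient k (in generation order) uses seed
#'   `seed + k`
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(groups, n_patients_per_group = 12L, n_trials = 40L,
                        n_contacts = 1L, sampling_rate = 1000,
                        epoch_window = c(-5, 5), seed = 1L) {
  abort_if(length(groups) == 0, "group map must not be empty")
  abort_if(!all(vapply(groups, inherits, TRUE, "spectral_profile")),
           "all groups must be spectral_profile objects")
  abort_if(n_trials < 2, "n_trials must be >= 2")
  abort_if(epoch_window[1] > 0 || epoch_window[2] < 0,
           "epoch window must span stimulus onset t = 0")
  structure(
    list(groups = groups,
         n_patients_per_group = rep_len(as.integer(n_patients_per_group),
                                        length(groups)),
         n_trials = as.integer(n_trials), n_contacts = as.integer(n_contacts),
         sampling_rate = sampling_rate, epoch_window = epoch_window,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Patient seeds are derived deterministically from the master seed
#' (`seed + k` for the k-th patient in generation order), so identical specs
#' yield bit-identical cohorts.
#'
#' @param spec a [cohort_spec()]
#' @return an object of class `cohort`: a list with element `patients`, each
#'   entry holding `patient_id`, `hemisphere`, `region` and an `epoch_array`
#' @export
generate_cohort <- function(spec) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  patients <- list()
  k <- 0L
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    parts <- strsplit(gname, ".", fixed = TRUE)[[1]]
    region <- parts[1]
    hemisphere <- if (length(parts) > 1) parts[2] else "unknown"
    np <- spec$n_patients_per_group[gi]
    for (p in seq_len(np)) {
      k <- k + 1L
      ep <- generate_evoked_epochs(
        spec$groups[[gi]], spec$n_trials, spec$sampling_rate,
        spec$epoch_window, spec$n_contacts,
        seed = derive_seed(spec$seed, k))
      patients[[k]] <- list(
        patient_id = sprintf("P%03d_%s_%s", k, region, hemisphere),
        hemisphere = hemisphere, region = region, epochs = ep)
    }
  }
  structure(list(patients = patients, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$patients, function(p)
    paste(p$region, p$hemisphere), ""))
  cat(sprintf("<cohort> %d patients\n", length(x$patients)))
  for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  invisible(x)
}
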