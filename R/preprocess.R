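#' Re-reference an epoch array to a bipolar montage
#'
#' Each output channel is the difference between a contact and its closest
#' neighbour on the same electrode shaft (`contact_i - contact_{i+1}`, in
#' shaft order). Pairs never span electrodes; electrodes with a single
#' contact contribute no channels.
#'
#' @param epochs a monopolar `epoch_array`
#' @return a bipolar `epoch_array` with one channel per adjacent
#'   within-electrode contact pair
#' @export
bipolar_reference <- function(epochs) {
  abort_if(!inherits(epochs, "epoch_array"), "`epochs` must be an epoch_array")
  abort_if(epochs$montage != "monopolar",
           "input is already in a %s montage", epochs$montage)
  idx_a <- integer(0); idx_b <- integer(0)
  for (el in unique(epochs$electrodes)) {
    members <- which(epochs$electrodes == el)
    if (length(members) < 2) next
    idx_a <- c(idx_a, members[-length(members)])
    idx_b <- c(idx_b, members[-1])
  }
  abort_if(length(idx_a) == 0,
           "no electrode has >= 2 contacts; bipolar montage impossible")
  d <- dim(epochs$data)
  out <- epochs$data[, idx_a, , drop = FALSE] -
    epochs$data[, idx_b, , drop = FALSE]
  labels <- paste(epochs$contact_labels[idx_a],
                  epochs$contact_labels[idx_b], sep = "-")
  epoch_array(out, epochs$time_axis, epochs$sampling_rate,
              contact_labels = labels,
              electrodes = epochs$electrodes[idx_a], montage = "bipolar")
}

#' Reject high-amplitude epochs
#'
#' Automatic surrogate for visual artifact/spike rejection: a trial is
#' removed when its peak absolute voltage on any channel exceeds
#' `abs_threshold`. When `abs_threshold` is `NULL` it defaults to
#' `6 * median(per-channel robust SD)` where the robust SD is the MAD of the
#' channel's pooled samples.
#'
#' @param epochs an `epoch_array`
#' @param abs_threshold absolute voltage threshold in uV (> 0), or `NULL`
#'   for the robust default
#' @return the `epoch_array` restricted to kept trials, with attribute
#'   `rejection_log` (list: threshold, rejected trial indices)
#' @export
reject_epochs <- function(epochs, abs_threshold = NULL) {
  abort_if(!inherits(epochs, "epoch_array"), "`epochs` must be an epoch_array")
  if (is.null(abs_threshold)) {
    rsd <- apply(epochs$data, 2, function(ch) stats::mad(as.numeric(ch)))
    abs_threshold <- 6 * stats::median(rsd)
  }
  abort_if(!is_number(abs_threshold) && !is.infinite(abs_threshold) ||
             abs_threshold <= 0, "abs_threshold must be > 0")
  peak <- apply(abs(epochs$data), 1, max)
  rejected <- which(peak > abs_threshold)
  abort_if(length(rejected) == dim(epochs$data)[1],
           "all trials exceed the rejection threshold (%g uV)", abs_threshold)
  kept <- setdiff(seq_len(dim(epochs$data)[1]), rejected)
  out <- epoch_array(epochs$data[kept, , , drop = FALSE], epochs$time_axis,
                     epochs$sampling_rate, epochs$contact_labels,
                     epochs$electrodes, epochs$montage)
  attr(out, "rejection_log") <- list(threshold = abs_threshold,
                                     rejected = rejected)
  out
}

#' Compute auditory evoked potentials with baseline z-scoring
#'
#' Per trial and channel, the signal is z-scored against the
#' `[-150, 50]` ms pre/peri-stimulus baseline (mean subtracted, divided by
#' baseline SD), then averaged across trials and cropped to
#' `[-200, 635]` ms. The peak absolute amplitude used for responsiveness
#' thresholding is computed on the *raw* (pre-z-score) trial average within
#' the same window, so it stays in microvolts.
#'
#' @param epochs an `epoch_array` whose time axis covers `[-200, 635]` ms
#' @param window AEP window in seconds, default `c(-0.2, 0.635)`
#' @param baseline baseline window in seconds, default `c(-0.15, 0.05)`
#' @return an object of class `aep_set`: list with `time_axis`, `waveforms`
#'   (channels x samples matrix of z-scored trial averages),
#'   `peak_abs_amplitude` (uV, per channel) and `contacts`
#' @export
compute_aep <- function(epochs, window = c(-0.2, 0.635),
                        baseline = c(-0.15, 0.05)) {
  abort_if(!inherits(epochs, "epoch_array"), "`epochs` must be an epoch_array")
  ta <- epochs$time_axis
  abort_if(ta[1] > window[1] + 1e-9 || ta[length(ta)] < window[2] - 1e-9,
           "epoch does not cover the AEP window [%g, %g] s",
           window[1], window[2])
  win <- which(ta >= window[1] - 1e-9 & ta <= window[2] + 1e-9)
  bas <- which(ta >= baseline[1] - 1e-9 & ta <= baseline[2] + 1e-9)
  d <- dim(epochs$data)
  nchan <- d[2]
  wave <- matrix(0, nchan, length(win))
  peak <- numeric(nchan)
  for (ch in seq_len(nchan)) {
    m <- contact_matrix(epochs, ch)                   # trials x samples
    bm <- rowMeans(m[, bas, drop = FALSE])
    bs <- apply(m[, bas, drop = FALSE], 1, stats::sd)
    abort_if(any(bs == 0),
             "zero baseline variance on channel %s (constant signal)",
             epochs$contact_labels[ch])
    z <- (m - bm) / bs
    wave[ch, ] <- colMeans(z[, win, drop = FALSE])
    peak[ch] <- max(abs(colMeans(m[, win, drop = FALSE])))
  }
  structure(list(time_axis = ta[win], waveforms = wave,
                 peak_abs_amplitude = peak,
                 contacts = epochs$contact_labels),
            class = "aep_set")
}

#' Select the most responsive contact from AEP amplitudes
#'
#' Contacts whose raw-average peak absolute amplitude falls below
#' `min_amplitude` (default 40 uV) are discarded as non-responsive; among
#' the kept contacts the one with the largest amplitude is selected, ties
#' broken by lowest contact index.
#'
#' @param aeps an `aep_set` from [compute_aep()]
#' @param min_amplitude responsiveness threshold in uV
#' @return list of class `contact_selection` with `kept`, `discarded`
#'   (named by reason), `best` (contact label) and `best_index`
#' @export
select_contact <- function(aeps, min_amplitude = 40) {
  abort_if(!inherits(aeps, "aep_set"), "`aeps` must be an aep_set")
  amp <- aeps$peak_abs_amplitude
  keep <- amp >= min_amplitude
  abort_if(!any(keep),
           "no responsive contact: all AEP amplitudes below %g uV",
           min_amplitude)
  kept <- aeps$contacts[keep]
  best_i <- which(keep)[which.max(amp[keep])]   # which.max -> lowest index tie
  structure(list(kept = kept,
                 discarded = stats::setNames(
                   rep("AEP below threshold", sum(!keep)),
                   aeps$contacts[!keep]),
                 best = aeps$contacts[best_i], best_index = best_i,
                 amplitudes = amp),
            class = "contact_selection")
}
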