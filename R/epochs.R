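#' Epoched multi-trial voltage recordings
#'
#' The pipeline's universal input: a trials x contacts x samples voltage
#' block (microvolts) with a time axis relative to stimulus onset. Contacts
#' carry an electrode membership so bipolar referencing can pair adjacent
#' contacts within (and never across) electrode shafts.
#'
#' @param data numeric array, trials x contacts x samples
#' @param time_axis numeric vector of sample times (s), strictly increasing
#'   with uniform step `1/sampling_rate` and containing `t = 0`
#' @param sampling_rate sampling rate in Hz
#' @param contact_labels character vector, one label per contact
#' @param electrodes character vector giving the electrode each contact
#'   belongs to (same length as `contact_labels`); contacts are assumed
#'   ordered along the shaft within an electrode
#' @param montage `"monopolar"` or `"bipolar"`
#' @return an object of class `epoch_array`
#' @export
epoch_array <- function(data, time_axis, sampling_rate,
                        contact_labels = NULL, electrodes = NULL,
                        montage = c("monopolar", "bipolar")) {
  montage <- match.arg(montage)
  abort_if(!is.array(data) || length(dim(data)) != 3L,
           "`data` must be a trials x contacts x samples array")
  d <- dim(data)
  abort_if(d[1] < 1L, "need at least one trial")
  abort_if(length(time_axis) != d[3],
           "time axis length (%d) does not match sample count (%d)",
           length(time_axis), d[3])
  dt <- diff(time_axis)
  abort_if(any(dt <= 0), "time axis must be strictly increasing")
  abort_if(max(abs(dt - 1 / sampling_rate)) > 1e-9,
           "time axis step must equal 1/sampling_rate")
  abort_if(min(abs(time_axis)) > 1e-9,
           "time axis must contain the stimulus onset t = 0")
  if (is.null(contact_labels)) contact_labels <- sprintf("c%02d", seq_len(d[2]))
  if (is.null(electrodes)) electrodes <- rep("E1", d[2])
  abort_if(length(contact_labels) != d[2] || length(electrodes) != d[2],
           "contact_labels/electrodes must have one entry per contact")
  structure(
    list(data = data, time_axis = as.numeric(time_axis),
         sampling_rate = sampling_rate,
         contact_labels = as.character(contact_labels),
         electrodes = as.character(electrodes), montage = montage),
    class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array> %d trials x %d contacts x %d samples (%s montage)\n",
    d[1], d[2], d[3], x$montage))
  cat(sprintf("  time: %.3f .. %.3f s @ %g Hz; electrodes: %s\n",
              x$time_axis[1], x$time_axis[length(x$time_axis)],
              x$sampling_rate, paste(unique(x$electrodes), collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

#' Number of trials in an epoch array
#' @param x an `epoch_array`
#' @return integer trial count
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Index of the stimulus-onset sample (t = 0)
#' @param x an `epoch_array`
#' @return integer sample index
#' @export
onset_index <- function(x) which.min(abs(x$time_axis))

#' Extract one contact as a trials x samples matrix
#' @param x an `epoch_array`
#' @param contact contact index or label
#' @return numeric matrix, trials x samples
#' @export
contact_matrix <- function(x, contact = 1L) {
  if (is.character(contact)) {
    contact <- match(contact, x$contact_labels)
    abort_if(is.na(contact), "unknown contact label")
  }
  m <- x$data[, contact, , drop = FALSE]
  dim(m) <- dim(x$data)[c(1, 3)]
  m
}

#' Write a labelled cohort to a directory of plain-text files
#'
#' One whitespace-free CSV per patient holding the voltage block flattened
#' as samples x (trial, contact) columns, plus a JSON sidecar with the time
#' axis origin, sampling rate and contact metadata, and a cohort-level CSV
#' manifest (patient_id, hemisphere, region, path).
#'
#' @param cohort a `cohort` object from [generate_cohort()]
#' @param dir output directory (created if absent)
#' @return the manifest as a data.frame, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$patients, function(p) {
    d <- dim(p$epochs$data)
    flat <- matrix(aperm(p$epochs$data, c(3, 1, 2)), nrow = d[3])
    path <- file.path(dir, paste0(p$patient_id, ".csv"))
    data.table::fwrite(data.table::as.data.table(flat), path,
                       col.names = FALSE)
    meta <- list(
      patient_id = p$patient_id, hemisphere = p$hemisphere,
      region = p$region, n_trials = d[1], n_contacts = d[2],
      n_samples = d[3], sampling_rate = p$epochs$sampling_rate,
      t_start = p$epochs$time_axis[1],
      contact_labels = p$epochs$contact_labels,
      electrodes = p$epochs$electrodes, montage = p$epochs$montage)
    jsonlite::write_json(meta, file.path(dir, paste0(p$patient_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(patient_id = p$patient_id, hemisphere = p$hemisphere,
               region = p$region, path = basename(path),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory holding `manifest.csv` and per-patient files
#' @return a `cohort` object
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  abort_if(!file.exists(mpath), "no manifest.csv under %s", dir)
  manifest <- data.table::fread(mpath, data.table = FALSE)
  patients <- lapply(seq_len(nrow(manifest)), function(i) {
    pid <- manifest$patient_id[i]
    meta <- jsonlite::read_json(file.path(dir, paste0(pid, ".json")),
                                simplifyVector = TRUE)
    flat <- as.matrix(data.table::fread(file.path(dir, manifest$path[i]),
                                        header = FALSE, data.table = FALSE))
    arr <- aperm(array(flat, dim = c(meta$n_samples, meta$n_trials,
                                     meta$n_contacts)), c(2, 3, 1))
    ta <- meta$t_start + (seq_len(meta$n_samples) - 1) / meta$sampling_rate
    ep <- epoch_array(arr, ta, meta$sampling_rate, meta$contact_labels,
                      meta$electrodes, meta$montage)
    list(patient_id = pid, hemisphere = meta$hemisphere,
         region = meta$region, epochs = ep)
  })
  structure(list(patients = patients), class = "cohort")
}
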