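#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis with the
#' reference defaults: 100 log-spaced frequencies 2-250 Hz with 7 wavelet
#' cycles, peak constraints of 22 grid points and 0.01 prominence, k = 4
#' NMF components with an 80/20 cross-validation split, and a 40 uV AEP
#' responsiveness threshold. The configuration round-trips losslessly
#' through JSON via [write_config()] / [read_config()].
#'
#' @param groups named list of [spectral_profile()] objects
#'   (`region.hemisphere`); defaults to [default_profiles()]
#' @param n_patients_per_group patients per group
#' @param n_trials trials per patient
#' @param n_contacts contacts per patient (single shaft)
#' @param sampling_rate Hz
#' @param epoch_window length-2 numeric (s)
#' @param fmin,fmax,nfreq,n_cycles spectral grid parameters
#' @param min_distance,min_prominence peak-extraction parameters
#' @param min_aep AEP responsiveness threshold (uV)
#' @param reject_threshold absolute rejection threshold (uV) or `NULL` for
#'   the robust default
#' @param use_bipolar re-reference to a bipolar montage when possible
#' @param classify_region,nmf_region region analyzed by the classifier/NMF
#' @param similarity_exponent exponent of the inverse-MSE similarity
#' @param k NMF components
#' @param train_fraction NMF cross-validation training fraction
#' @param seed master seed; stage seeds are derived at documented offsets
#' @return object of class `run_config`
#' @export
run_config <- function(groups = default_profiles(),
                       n_patients_per_group = 12L, n_trials = 220L,
                       n_contacts = 5L, sampling_rate = 1000,
                       epoch_window = c(-5, 5),
                       fmin = 2, fmax = 250, nfreq = 100L, n_cycles = 7,
                       min_distance = 22, min_prominence = 0.01,
                       min_aep = 40, reject_threshold = NULL,
                       use_bipolar = TRUE,
                       classify_region = "AAC", nmf_region = "AAC",
                       similarity_exponent = 2,
                       k = 4L, train_fraction = 0.8, seed = 1L) {
  cfg <- list(groups = groups, n_patients_per_group = n_patients_per_group,
              n_trials = n_trials, n_contacts = n_contacts,
              sampling_rate = sampling_rate, epoch_window = epoch_window,
              fmin = fmin, fmax = fmax, nfreq = nfreq, n_cycles = n_cycles,
              min_distance = min_distance, min_prominence = min_prominence,
              min_aep = min_aep, reject_threshold = reject_threshold,
              use_bipolar = use_bipolar, classify_region = classify_region,
              nmf_region = nmf_region,
              similarity_exponent = similarity_exponent,
              k = k, train_fraction = train_fraction, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to JSON
#' @param config a `run_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  ser$groups <- lapply(config$groups, function(p) list(
    components = p$components, jitter_kappa = p$jitter_kappa,
    noise_exponent = p$noise_exponent, noise_amplitude = p$noise_amplitude))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path file written by [write_config()]
#' @return a `run_config`
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(raw$groups, function(g)
    spectral_profile(as.data.frame(g$components), g$jitter_kappa,
                     g$noise_exponent, g$noise_amplitude))
  raw$groups <- NULL
  cfg <- do.call(run_config, c(list(groups = groups), raw))
  cfg
}

# Preprocess one patient's epochs: optional bipolar referencing, amplitude
# rejection, AEP computation and contact selection.
preprocess_patient <- function(epochs, config) {
  ep <- epochs
  if (isTRUE(config$use_bipolar) &&
      any(table(ep$electrodes) >= 2) && dim(ep$data)[2] >= 2)
    ep <- bipolar_reference(ep)
  ep <- reject_epochs(ep, config$reject_threshold)
  aeps <- compute_aep(ep)
  sel <- select_contact(aeps, config$min_aep)
  keep_idx <- match(sel$kept, ep$contact_labels)
  list(epochs = ep, aeps = aeps, selection = sel, kept_idx = keep_idx)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, preprocess, ITPC, peak extraction, LOOCV hemisphere
#' classification, NMF decomposition and group statistics, writing every
#' stage's tables under `out_dir` (spectra and peak tables as CSV, reports
#' and the manifest as JSON). Deterministic stage outputs are bit-identical
#' across reruns with the same configuration.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created)
#' @return list with the in-memory stage results, invisibly; side effect:
#'   files under `out_dir`
#' @export
run_pipeline <- function(config, out_dir) {
  abort_if(!inherits(config, "run_config"), "`config` must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "nmf"), showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.json"))
  grid <- frequency_grid(config$fmin, config$fmax, config$nfreq,
                         config$n_cycles)

  stage <- "simulate"
  res <- tryCatch({
    spec <- cohort_spec(config$groups, config$n_patients_per_group,
                        config$n_trials, config$n_contacts,
                        config$sampling_rate, config$epoch_window,
                        seed = derive_seed(config$seed, 0L))
    cohort <- generate_cohort(spec)
    manifest <- data.frame(
      patient_id = vapply(cohort$patients, `[[`, "", "patient_id"),
      hemisphere = vapply(cohort$patients, `[[`, "", "hemisphere"),
      region = vapply(cohort$patients, `[[`, "", "region"))
    data.table::fwrite(manifest, file.path(out_dir, "cohort_manifest.csv"))

    stage <- "preprocess"
    prep <- lapply(cohort$patients, function(p)
      preprocess_patient(p$epochs, config))
    rej_path <- file.path(out_dir, "rejections.jsonl")
    writeLines(vapply(seq_along(prep), function(i) {
      log <- attr(prep[[i]]$epochs, "rejection_log")
      jsonlite::toJSON(list(patient = cohort$patients[[i]]$patient_id,
                            threshold = log$threshold,
                            rejected_trials = as.integer(log$rejected)),
                       auto_unbox = TRUE, digits = NA)
    }, ""), rej_path)

    stage <- "itpc"
    spectra <- vector("list", length(prep))
    contact_spectra <- list()   # all kept contacts, for the NMF region
    for (i in seq_along(prep)) {
      p <- cohort$patients[[i]]
      if (p$region == config$nmf_region) {
        # compute all kept contacts once; the best contact is among them
        kept_specs <- lapply(prep[[i]]$kept_idx, function(ci)
          itpc_spectrum(prep[[i]]$epochs, grid, ci))
        sp <- kept_specs[[match(prep[[i]]$selection$best_index,
                                prep[[i]]$kept_idx)]]
      } else {
        sp <- itpc_spectrum(prep[[i]]$epochs, grid,
                            prep[[i]]$selection$best_index)
      }
      spectra[[i]] <- sp
      data.table::fwrite(
        data.frame(frequency_hz = grid$frequencies, raw_itpc = sp$raw,
                   z_itpc = sp$normalized),
        file.path(out_dir, "spectra", paste0(p$patient_id, ".csv")))
      jsonlite::write_json(
        list(patient = p$patient_id, region = p$region,
             hemisphere = p$hemisphere, n_trials = sp$n_trials,
             contact = prep[[i]]$selection$best),
        file.path(out_dir, "spectra", paste0(p$patient_id, ".json")),
        auto_unbox = TRUE, digits = NA)
      if (p$region == config$nmf_region) {
        for (j in seq_along(prep[[i]]$kept_idx)) {
          ci <- prep[[i]]$kept_idx[j]
          contact_spectra[[length(contact_spectra) + 1L]] <- list(
            spectrum = kept_specs[[j]],
            patient = p$patient_id, hemisphere = p$hemisphere,
            contact = paste0(p$patient_id, ":",
                             prep[[i]]$epochs$contact_labels[ci]))
        }
      }
    }

    stage <- "peaks"
    peak_rows <- lapply(seq_along(spectra), function(i) {
      p <- cohort$patients[[i]]
      ps <- find_two_peaks(spectra[[i]], config$min_distance,
                           config$min_prominence)$peaks
      data.frame(patient = p$patient_id, region = p$region,
                 hemisphere = p$hemisphere,
                 peak1_hz = if (nrow(ps) >= 1) ps$frequency[1] else NA_real_,
                 peak2_hz = if (nrow(ps) >= 2) ps$frequency[2] else NA_real_,
                 height1 = if (nrow(ps) >= 1) ps$height[1] else NA_real_,
                 height2 = if (nrow(ps) >= 2) ps$height[2] else NA_real_)
    })
    peaks_tab <- do.call(rbind, peak_rows)
    data.table::fwrite(peaks_tab, file.path(out_dir, "peaks.csv"))

    stage <- "classify"
    regions <- vapply(cohort$patients, `[[`, "", "region")
    hemis <- vapply(cohort$patients, `[[`, "", "hemisphere")
    in_cls <- regions == config$classify_region
    loocv <- NULL
    if (sum(in_cls) >= 4 && length(unique(hemis[in_cls])) == 2) {
      loocv <- loocv_classify(spectra[in_cls], hemis[in_cls],
                              ids = manifest$patient_id[in_cls],
                              exponent = config$similarity_exponent)
      jsonlite::write_json(
        list(accuracy = loocv$accuracy,
             accuracy_by_side = as.list(loocv$accuracy_by_side),
             results = loocv$results),
        file.path(out_dir, "loocv.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows")
      data.table::fwrite(
        loocv$results[, c("id", "hemisphere", "similarity_same",
                          "similarity_opposite", "predicted")],
        file.path(out_dir, "loocv_scatter.csv"))
    }

    stage <- "nmf"
    nmf <- NULL
    if (length(contact_spectra) >= config$k + 2) {
      V <- build_spectrum_matrix(
        lapply(contact_spectra, `[[`, "spectrum"),
        vapply(contact_spectra, `[[`, "", "contact"))
      model <- fit_nmf(V, k = config$k,
                       seed = derive_seed(config$seed, 1000L))
      cv <- explained_variance_cv(V, k = config$k,
                                  train_fraction = config$train_fraction,
                                  seed = derive_seed(config$seed, 2000L))
      cmap <- classify_components(model, grid)
      labels <- data.frame(
        contact = vapply(contact_spectra, `[[`, "", "contact"),
        patient = vapply(contact_spectra, `[[`, "", "patient"),
        hemisphere = vapply(contact_spectra, `[[`, "", "hemisphere"))
      wr <- hemisphere_weight_report(model, cmap, labels)
      data.table::fwrite(as.data.frame(model$W),
                         file.path(out_dir, "nmf", "W.csv"))
      data.table::fwrite(as.data.frame(model$H),
                         file.path(out_dir, "nmf", "H.csv"))
      data.table::fwrite(cmap, file.path(out_dir, "nmf", "class_map.csv"))
      data.table::fwrite(cbind(contact = rownames(wr$contact_weights),
                               as.data.frame(wr$contact_weights)),
                         file.path(out_dir, "nmf", "weights_contact.csv"))
      data.table::fwrite(cbind(patient = rownames(wr$patient_weights),
                               as.data.frame(wr$patient_weights)),
                         file.path(out_dir, "nmf", "weights_patient.csv"))
      data.table::fwrite(cbind(hemisphere = rownames(wr$hemisphere_weights),
                               as.data.frame(wr$hemisphere_weights)),
                         file.path(out_dir, "nmf", "weights_hemisphere.csv"))
      data.table::fwrite(wr$dominance,
                         file.path(out_dir, "nmf", "dominance.csv"))
      jsonlite::write_json(
        list(k = config$k, r2_in_sample = model$r2, r2_cv = cv$r2_cv,
             objective = model$objective),
        file.path(out_dir, "nmf", "nmf.json"), auto_unbox = TRUE,
        digits = NA)
      nmf <- list(model = model, cv = cv, class_map = cmap, weights = wr)
    }

    stage <- "stats"
    stat_rows <- list()
    for (rg in unique(peaks_tab$region)) {
      sub <- peaks_tab[peaks_tab$region == rg, ]
      sides <- sort(unique(sub$hemisphere))
      if (length(sides) != 2) next
      for (pk in c("peak1_hz", "peak2_hz")) {
        a <- sub[[pk]][sub$hemisphere == sides[1]]
        b <- sub[[pk]][sub$hemisphere == sides[2]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) == 0 || length(b) == 0) next
        tr <- mann_whitney_u(a, b)
        stat_rows[[length(stat_rows) + 1L]] <- data.frame(
          test = tr$test_name, comparison = sprintf("%s %s: %s vs %s",
                                                    rg, pk, sides[1], sides[2]),
          n1 = tr$n1, n2 = tr$n2, statistic = tr$statistic,
          p_value = tr$p_value)
      }
    }
    if (!is.null(nmf)) {
      pw <- nmf$weights$patient_weights
      hemi <- nmf$weights$dominance$hemisphere
      for (cl in colnames(pw)) {
        sides <- sort(unique(hemi))
        if (length(sides) != 2) next
        a <- pw[hemi == sides[1], cl]; b <- pw[hemi == sides[2], cl]
        if (length(a) < 2 || length(b) < 2) next
        tr <- tryCatch(unpaired_t(a, b), error = function(e) NULL)
        if (is.null(tr)) next
        stat_rows[[length(stat_rows) + 1L]] <- data.frame(
          test = tr$test_name,
          comparison = sprintf("NMF weight '%s': %s vs %s", cl,
                               sides[1], sides[2]),
          n1 = tr$n1, n2 = tr$n2, statistic = tr$statistic,
          p_value = tr$p_value)
      }
    }
    if (length(stat_rows) > 0)
      data.table::fwrite(do.call(rbind, stat_rows),
                         file.path(out_dir, "stats.csv"))

    jsonlite::write_json(
      list(package = "itpcflow",
           version = as.character(utils::packageVersion("itpcflow")),
           seed = config$seed,
           stages = c("simulate", "preprocess", "itpc", "peaks", "classify",
                      "nmf", "stats"),
           n_patients = length(cohort$patients),
           parameters = list(fmin = config$fmin, fmax = config$fmax,
                             nfreq = config$nfreq, n_cycles = config$n_cycles,
                             min_distance = config$min_distance,
                             min_prominence = config$min_prominence,
                             k = config$k,
                             train_fraction = config$train_fraction)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

    list(cohort = cohort, spectra = spectra, peaks = peaks_tab,
         loocv = loocv, nmf = nmf,
         stats = if (length(stat_rows)) do.call(rbind, stat_rows) else NULL)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs under `run_dir` and emits figure-level summary
#' tables (group-mean ITPC spectra with SEM per region and hemisphere, peak
#' box-plot data, the LOOCV similarity scatter, NMF component spectra and
#' class weights) under `run_dir/report/`, plus a PDF of quick-look plots.
#' Stages absent from the run (e.g. no classifier region in the cohort) are
#' skipped without error; an empty or incomplete run directory is an error
#' listing the missing stages.
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @param plots also write `report/summary.pdf`
#' @return invisible list of the summary tables
#' @export
report <- function(run_dir, plots = TRUE) {
  need <- c("cohort_manifest.csv", "peaks.csv")
  have <- file.exists(file.path(run_dir, need))
  spectra_files <- list.files(file.path(run_dir, "spectra"),
                              pattern = "\\.json$", full.names = TRUE)
  missing <- need[!have]
  if (length(spectra_files) == 0) missing <- c(missing, "spectra/")
  abort_if(length(missing) > 0, "incomplete run; missing: %s",
           paste(missing, collapse = ", "))
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)

  specs <- lapply(spectra_files, function(jf) {
    meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
    tab <- data.table::fread(sub("\\.json$", ".csv", jf), data.table = FALSE)
    cbind(tab, patient = meta$patient, region = meta$region,
          hemisphere = meta$hemisphere)
  })
  allspec <- do.call(rbind, specs)
  key <- allspec[c("region", "hemisphere", "frequency_hz")]
  group <- stats::aggregate(allspec$z_itpc, by = key, FUN = mean)
  names(group)[4] <- "mean_z"
  sem <- stats::aggregate(allspec$z_itpc, by = key,
                          FUN = function(v) stats::sd(v) / sqrt(length(v)))
  group$sem_z <- sem$x
  nn <- stats::aggregate(allspec$z_itpc, by = key, FUN = length)
  group$n <- nn$x
  group <- group[order(group$region, group$hemisphere, group$frequency_hz), ]
  data.table::fwrite(group, file.path(rep_dir, "group_spectra.csv"))

  peaks_tab <- data.table::fread(file.path(run_dir, "peaks.csv"),
                                 data.table = FALSE)
  data.table::fwrite(peaks_tab, file.path(rep_dir, "peak_box_data.csv"))

  out <- list(group_spectra = as.data.frame(group), peaks = peaks_tab)
  scat_path <- file.path(run_dir, "loocv_scatter.csv")
  if (file.exists(scat_path)) {
    scat <- data.table::fread(scat_path, data.table = FALSE)
    data.table::fwrite(scat, file.path(rep_dir, "loocv_scatter.csv"))
    out$loocv_scatter <- scat
  }
  w_path <- file.path(run_dir, "nmf", "weights_hemisphere.csv")
  if (file.exists(w_path)) {
    out$nmf_weights <- data.table::fread(w_path, data.table = FALSE)
    data.table::fwrite(out$nmf_weights,
                       file.path(rep_dir, "nmf_weights_hemisphere.csv"))
  }

  if (isTRUE(plots)) {
    grDevices::pdf(file.path(rep_dir, "summary.pdf"), width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (rg in unique(group$region)) {
      sub <- group[group$region == rg, ]
      graphics::plot(NULL, xlim = range(log10(sub$frequency_hz)),
                     ylim = range(sub$mean_z),
                     xlab = "log10 frequency (Hz)", ylab = "ITPC (z)",
                     main = sprintf("Group ITPC spectrum - %s", rg))
      cols <- c(left = "goldenrod", right = "steelblue")
      colof <- function(h) {
        cl <- unname(cols[h]); ifelse(is.na(cl), "gray40", cl)
      }
      for (h in unique(sub$hemisphere)) {
        s2 <- sub[sub$hemisphere == h, ]
        graphics::lines(log10(s2$frequency_hz), s2$mean_z,
                        col = colof(h), lwd = 2)
      }
      graphics::legend("topright", legend = unique(sub$hemisphere),
                       col = colof(unique(sub$hemisphere)),
                       lwd = 2, bty = "n")
    }
  }
  invisible(out)
}
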