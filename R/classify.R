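#' Group-level template from individual ITPC spectra
#'
#' Pointwise mean of normalized ITPC spectra sharing a frequency grid: the
#' prototypical spectral response of a hemisphere, against which individual
#' spectra are compared.
#'
#' @param spectra list of normalized `itpc_spectrum` objects on a common grid
#' @param hemisphere optional label carried on the template
#' @return object of class `itpc_template`: `spectrum` (numeric),
#'   `frequencies`, `hemisphere`, `n_contributors`
#' @export
build_template <- function(spectra, hemisphere = NA_character_) {
  abort_if(length(spectra) < 1, "need at least one spectrum")
  vecs <- lapply(spectra, function(s) {
    abort_if(!inherits(s, "itpc_spectrum"), "inputs must be itpc_spectrum")
    abort_if(is.null(s$normalized), "spectra must be normalized first")
    s$normalized
  })
  f0 <- spectra[[1]]$grid$frequencies
  for (s in spectra)
    abort_if(length(s$grid$frequencies) != length(f0) ||
               max(abs(s$grid$frequencies - f0)) > 1e-9,
             "spectra are on mismatched frequency grids")
  structure(list(spectrum = Reduce(`+`, vecs) / length(vecs),
                 frequencies = f0, hemisphere = hemisphere,
                 n_contributors = length(vecs)),
            class = "itpc_template")
}

#' MSE-based similarity of a spectrum to a template
#'
#' The error of fit is the mean squared difference over the frequency bins;
#' the similarity index is its squared inverse, `1/(MSE + eps)^2` (with a
#' small floor `eps` so a perfect fit stays finite). Because the transform
#' is strictly decreasing, any positive `exponent` yields the same
#' classification; 2 is the default.
#'
#' @param spectrum a normalized `itpc_spectrum` (or numeric vector)
#' @param template an `itpc_template` (or numeric vector)
#' @param exponent exponent of the inverse-MSE transform
#' @param eps floor added to the MSE before inversion
#' @return list with `mse` and `similarity`
#' @export
similarity <- function(spectrum, template, exponent = 2, eps = 1e-12) {
  x <- if (inherits(spectrum, "itpc_spectrum"))
    (spectrum$normalized %||% spectrum$raw) else as.numeric(spectrum)
  y <- if (inherits(template, "itpc_template")) template$spectrum
  else as.numeric(template)
  abort_if(length(x) != length(y),
           "spectrum (%d) and template (%d) grids differ", length(x), length(y))
  mse <- mean((x - y)^2)
  list(mse = mse, similarity = 1 / (mse + eps)^exponent)
}

#' Leave-one-out hemisphere classification from ITPC spectra
#'
#' For each patient, the same-hemisphere template is rebuilt from all
#' *other* patients of that hemisphere, while the opposite-hemisphere
#' template uses all of its patients; the predicted side is the one with
#' the larger similarity index (smaller MSE). Exact similarity ties are
#' labelled `"tie"` and counted as incorrect.
#'
#' @param spectra list of normalized `itpc_spectrum` objects
#' @param hemispheres character vector (`"left"`/`"right"`), one per spectrum
#' @param ids optional patient identifiers
#' @param exponent,eps passed to [similarity()]
#' @return object of class `loocv_report`: data.frame `results` (per
#'   patient: mse/similarity for both sides, prediction, correctness),
#'   `accuracy`, `accuracy_by_side`, `n`
#' @export
loocv_classify <- function(spectra, hemispheres, ids = NULL,
                           exponent = 2, eps = 1e-12) {
  abort_if(length(spectra) != length(hemispheres),
           "one hemisphere label per spectrum required")
  hemispheres <- as.character(hemispheres)
  sides <- sort(unique(hemispheres))
  abort_if(length(sides) != 2, "need exactly two hemisphere labels, got: %s",
           paste(sides, collapse = ", "))
  for (s in sides)
    abort_if(sum(hemispheres == s) < 2,
             "hemisphere '%s' has fewer than 2 patients", s)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(spectra))
  rows <- lapply(seq_along(spectra), function(i) {
    own <- hemispheres[i]
    opp <- setdiff(sides, own)
    same_idx <- setdiff(which(hemispheres == own), i)
    opp_idx <- which(hemispheres == opp)
    t_same <- build_template(spectra[same_idx], own)
    t_opp <- build_template(spectra[opp_idx], opp)
    s_same <- similarity(spectra[[i]], t_same, exponent, eps)
    s_opp <- similarity(spectra[[i]], t_opp, exponent, eps)
    predicted <- if (s_same$similarity > s_opp$similarity) own
    else if (s_same$similarity < s_opp$similarity) opp
    else "tie"
    data.frame(id = ids[i], hemisphere = own,
               mse_same = s_same$mse, mse_opposite = s_opp$mse,
               similarity_same = s_same$similarity,
               similarity_opposite = s_opp$similarity,
               predicted = predicted, correct = identical(predicted, own),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  acc_side <- vapply(sides, function(s)
    mean(results$correct[results$hemisphere == s]), 0)
  structure(list(results = results, accuracy = mean(results$correct),
                 accuracy_by_side = acc_side, n = nrow(results)),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d patients, accuracy %.3f (%s)\n", x$n,
              x$accuracy,
              paste(sprintf("%s %.2f", names(x$accuracy_by_side),
                            x$accuracy_by_side), collapse = ", ")))
  invisible(x)
}
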