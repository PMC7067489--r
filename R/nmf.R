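#' Assemble the frequency x contact ITPC spectrum matrix
#'
#' Stacks per-contact ITPC spectra as columns of the non-negative input
#' matrix V for the factorization. Raw ITPC spectra (values in `[0,1]`) are
#' the default, being naturally non-negative; `mode = "shifted_z"` instead
#' uses z-normalized spectra shifted by their per-contact minimum, for
#' pipelines that normalize before decomposing.
#'
#' @param spectra list of `itpc_spectrum` objects on a common grid
#' @param contact_labels optional column names
#' @param mode `"raw"` or `"shifted_z"`
#' @return numeric matrix, frequencies x contacts, all entries >= 0
#' @export
build_spectrum_matrix <- function(spectra, contact_labels = NULL,
                                  mode = c("raw", "shifted_z")) {
  mode <- match.arg(mode)
  abort_if(length(spectra) < 1, "need at least one spectrum")
  f0 <- spectra[[1]]$grid$frequencies
  cols <- lapply(spectra, function(s) {
    abort_if(!inherits(s, "itpc_spectrum"), "inputs must be itpc_spectrum")
    abort_if(max(abs(s$grid$frequencies - f0)) > 1e-9,
             "spectra are on mismatched frequency grids")
    if (mode == "raw") s$raw else {
      z <- s$normalized %||% stop("shifted_z mode needs normalized spectra")
      z - min(z)
    }
  })
  V <- do.call(cbind, cols)
  abort_if(any(V < 0), "negative entries in the spectrum matrix")
  rownames(V) <- sprintf("f%03d", seq_along(f0))
  colnames(V) <- contact_labels %||% sprintf("contact%03d", seq_len(ncol(V)))
  attr(V, "frequencies") <- f0
  V
}

# Deterministic NNDSVDa initialization (Boutsidis & Gallopoulos 2008):
# non-negative parts of the leading singular vectors, zeros backfilled with
# the matrix mean so multiplicative updates cannot lock them at zero.
nndsvda_init <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  m <- nrow(V); n <- ncol(V)
  W <- matrix(0, m, k); H <- matrix(0, k, n)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  avg <- mean(V)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

#' Non-negative matrix factorization of ITPC spectra
#'
#' Approximates the non-negative frequency x contact matrix `V` as the
#' product of non-negative factors `W` (frequencies x k, the prototypical
#' spectral components / "cluster centroids") and `H` (k x contacts, the
#' per-contact component weights), minimizing the squared Frobenius norm
#' `||V - WH||_F^2` by Lee-Seung multiplicative updates from a
#' deterministic SVD-based (NNDSVDa) initialization. Components are
#' reordered by descending total weight (`rowSums(H)`) for stable
#' numbering.
#'
#' @param V non-negative matrix, frequencies x contacts
#' @param k number of components (default 4)
#' @param seed RNG seed (kept for interface stability; the default
#'   initialization is deterministic)
#' @param max_iter maximum multiplicative updates
#' @param tol relative objective decrease below which iteration stops
#' @return object of class `nmf_model`: `W`, `H`, `k`, `objective`
#'   (squared Frobenius error), `r2` (in-sample variance explained),
#'   `iterations`, `converged`
#' @export
fit_nmf <- function(V, k = 4, seed = 1L, max_iter = 1000L, tol = 1e-7) {
  V <- as.matrix(V)
  abort_if(any(V < 0), "V must be non-negative")
  abort_if(k > min(dim(V)), "k must not exceed min(dim(V))")
  init <- nndsvda_init(V, k)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  obj_prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj <- sum((V - W %*% H)^2)
    if (obj <= 1e-12 * sum(V^2) ||
        (is.finite(obj_prev) && (obj_prev - obj) <= tol * max(obj_prev, eps))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (!converged)
    warning(sprintf("NMF did not converge in %d iterations; returning best iterate",
                    max_iter))
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  obj <- sum((V - W %*% H)^2)
  tot <- sum((V - mean(V))^2)
  structure(list(W = W, H = H, k = k, objective = obj,
                 r2 = 1 - obj / tot, iterations = it, converged = converged,
                 frequencies = attr(V, "frequencies")),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("<nmf_model> k = %d, %d x %d, objective %.4g, in-sample r2 %.3f\n",
              x$k, nrow(x$W), ncol(x$H), x$objective, x$r2))
  invisible(x)
}

#' Non-negative least squares (Lawson-Hanson)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the active-set method.
#'
#' @param A design matrix
#' @param b response vector
#' @return non-negative coefficient vector
#' @export
nnls_solve <- function(A, b) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) break
      bad <- P[s[P] <= tol]
      alpha <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + alpha * (s - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Cross-validated variance explained by an NMF model
#'
#' Columns (contacts) are split into a training set (default 80%) and a
#' held-out test set. `W` is fit on the training columns; the test columns'
#' weights are solved with `W` fixed by non-negative least squares, and the
#' variance explained on the held-out reconstruction is
#' `r2 = 1 - ||V_test - W H_test||_F^2 / ||V_test - mean(V_test)||_F^2`.
#'
#' @param V non-negative matrix, frequencies x contacts
#' @param k number of components
#' @param train_fraction fraction of columns used for training
#' @param seed seed for the column split
#' @param ... passed to [fit_nmf()]
#' @return list with `r2_cv`, `model` (trained on the training columns),
#'   `test_columns`
#' @export
explained_variance_cv <- function(V, k = 4, train_fraction = 0.8, seed = 1L,
                                  ...) {
  V <- as.matrix(V)
  n <- ncol(V)
  n_train <- floor(train_fraction * n)
  abort_if(n_train < k || n_train >= n,
           "degenerate split: %d train / %d test columns with k = %d",
           n_train, n - n_train, k)
  train <- withr::with_seed(seed, sort(sample.int(n, n_train)))
  test <- setdiff(seq_len(n), train)
  fit <- fit_nmf(V[, train, drop = FALSE], k = k, seed = seed, ...)
  H_test <- vapply(test, function(j) nnls_solve(fit$W, V[, j]),
                   numeric(k))
  H_test <- matrix(H_test, nrow = k)
  resid <- V[, test, drop = FALSE] - fit$W %*% H_test
  tot <- sum((V[, test, drop = FALSE] - mean(V[, test, drop = FALSE]))^2)
  list(r2_cv = 1 - sum(resid^2) / tot, model = fit, test_columns = test)
}

#' Classify NMF components by spectral profile
#'
#' Each basis column of `W` is z-scored and its two highest noncontiguous
#' peaks extracted (same routine as for patient spectra). Classes follow
#' the canonical bimodal patterns: `"delta/beta"` (low peak < 4.5 Hz, high
#' peak 10-25 Hz), `"theta/gamma"` (low peak 4-8 Hz, high peak > 25 Hz),
#' single-peak `"alpha"` (8-13 Hz) or `"gamma"` (> 25 Hz), and `"other"`
#' as fallback.
#'
#' @param model an `nmf_model` (or bare W matrix with a `frequencies`
#'   attribute)
#' @param grid a [frequency_grid()] matching the rows of W; defaults to the
#'   frequencies stored in the model
#' @param min_distance,min_prominence peak-detection parameters
#' @return object of class `component_class_map`: data.frame with one row
#'   per component (`component`, `class`, `peak1_hz`, `peak2_hz`)
#' @export
classify_components <- function(model, grid = NULL, min_distance = 22,
                                min_prominence = 0.01) {
  W <- if (inherits(model, "nmf_model")) model$W else as.matrix(model)
  freqs <- if (!is.null(grid)) grid$frequencies
  else if (inherits(model, "nmf_model")) model$frequencies
  else attr(model, "frequencies")
  abort_if(is.null(freqs) || length(freqs) != nrow(W),
           "need a frequency grid matching the rows of W")
  rows <- lapply(seq_len(ncol(W)), function(j) {
    w <- W[, j]
    s <- stats::sd(w)
    z <- if (is.finite(s) && s > 0) (w - mean(w)) / s else w * 0
    ps <- find_two_peaks_vec(z, freqs, min_distance, min_prominence)
    p <- ps$peaks
    cls <- "other"
    if (nrow(p) == 2) {
      lo <- p$frequency[1]; hi <- p$frequency[2]
      if (lo < 4.5 && hi >= 10 && hi <= 25) cls <- "delta/beta"
      else if (lo >= 4 && lo <= 8 && hi > 25) cls <- "theta/gamma"
    } else if (nrow(p) == 1) {
      f1 <- p$frequency[1]
      if (f1 >= 8 && f1 <= 13) cls <- "alpha"
      else if (f1 > 25) cls <- "gamma"
    }
    data.frame(component = j, class = cls,
               peak1_hz = if (nrow(p) >= 1) p$frequency[1] else NA_real_,
               peak2_hz = if (nrow(p) >= 2) p$frequency[2] else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("component_class_map",
                                            "data.frame"))
}

# find_two_peaks on a bare vector with an explicit frequency axis.
find_two_peaks_vec <- function(z, freqs, min_distance, min_prominence) {
  ps <- find_two_peaks(z, min_distance, min_prominence)
  ps$peaks$frequency <- freqs[ps$peaks$grid_index]
  ps
}

#' Per-hemisphere component-class weight report
#'
#' Sums the H rows of each spectral class per contact, normalizes so the
#' class weights of a contact sum to 1, then averages within patient
#' (intra-patient contact mean) and within hemisphere. Each patient is
#' labelled by the dominant class (`"balanced"` on exact ties).
#'
#' @param model an `nmf_model`
#' @param class_map a `component_class_map` from [classify_components()]
#' @param labels data.frame with one row per column of H: columns
#'   `contact`, `patient`, `hemisphere`
#' @return object of class `weight_report`: `contact_weights`
#'   (contacts x classes), `patient_weights`, `hemisphere_weights`,
#'   `dominance` (per patient)
#' @export
hemisphere_weight_report <- function(model, class_map, labels) {
  H <- model$H
  abort_if(nrow(labels) != ncol(H),
           "labels (%d rows) must cover every contact column of H (%d)",
           nrow(labels), ncol(H))
  abort_if(any(is.na(labels$patient)) || any(is.na(labels$hemisphere)),
           "unlabeled contact column")
  classes <- sort(unique(class_map$class))
  cw <- vapply(classes, function(cl)
    colSums(H[class_map$class == cl, , drop = FALSE]), numeric(ncol(H)))
  cw <- matrix(cw, ncol = length(classes),
               dimnames = list(labels$contact, classes))
  tot <- rowSums(cw)
  abort_if(any(tot == 0), "contact with zero total weight")
  cw <- cw / tot
  pats <- unique(labels$patient)
  pw <- matrix(NA_real_, length(pats), length(classes),
               dimnames = list(pats, classes))
  for (i in seq_along(pats))
    pw[i, ] <- colMeans(cw[labels$patient == pats[i], , drop = FALSE])
  hemi <- vapply(pats, function(p)
    as.character(labels$hemisphere[match(p, labels$patient)]), "")
  sides <- unique(hemi)
  hw <- matrix(NA_real_, length(sides), length(classes),
               dimnames = list(sides, classes))
  for (i in seq_along(sides))
    hw[i, ] <- colMeans(pw[hemi == sides[i], , drop = FALSE])
  dominance <- apply(pw, 1, function(r) {
    m <- max(r)
    top <- classes[r == m]
    if (length(top) > 1) "balanced" else top
  })
  structure(list(contact_weights = cw, patient_weights = pw,
                 hemisphere_weights = hw,
                 dominance = data.frame(patient = pats, hemisphere = hemi,
                                        dominant_class = dominance,
                                        stringsAsFactors = FALSE)),
            class = "weight_report")
}
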