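# Interior local maxima of a numeric vector (plateau-aware: the first sample
# of a flat top counts, endpoints never do).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Topographic prominence of a local maximum at index p: height above the
# higher of the two flanking minima, where each flank extends to the nearest
# strictly higher sample (or the array edge).
peak_prominence <- function(x, p) {
  n <- length(x)
  left <- x[p]
  i <- p - 1L
  lmin <- x[p]
  while (i >= 1L && x[i] <= x[p]) { lmin <- min(lmin, x[i]); i <- i - 1L }
  right <- x[p]
  i <- p + 1L
  rmin <- x[p]
  while (i <= n && x[i] <= x[p]) { rmin <- min(rmin, x[i]); i <- i + 1L }
  x[p] - max(lmin, rmin)
}

#' Extract the two highest noncontiguous peaks of an ITPC spectrum
#'
#' Finds interior local maxima with topographic prominence at least
#' `min_prominence`, then selects greedily by height subject to a pairwise
#' index distance of at least `min_distance` grid points: the highest
#' qualifying maximum is taken first, then the highest remaining candidate
#' far enough from it. Up to two peaks are returned in ascending frequency
#' order ("first peak" = lower frequency). Grid endpoints are never peaks.
#' Defaults (22 points on the 100-point grid, prominence 0.01) follow the
#' reference analysis; `min_distance` is rescaled proportionally when the
#' grid size differs from 100.
#'
#' @param spectrum an `itpc_spectrum` (its `normalized` values are used,
#'   falling back to `raw`), or a bare numeric vector
#' @param min_distance minimal index distance between the two peaks, in
#'   grid points of a 100-point grid
#' @param min_prominence minimal topographic prominence (z-units)
#' @return object of class `peak_set`: data.frame `peaks` with columns
#'   `frequency`, `height`, `grid_index` (0, 1 or 2 rows, ascending
#'   frequency), plus `n_candidates`
#' @export
find_two_peaks <- function(spectrum, min_distance = 22, min_prominence = 0.01) {
  if (inherits(spectrum, "itpc_spectrum")) {
    x <- spectrum$normalized %||% spectrum$raw
    freqs <- spectrum$grid$frequencies
  } else {
    x <- as.numeric(spectrum)
    freqs <- seq_along(x)
  }
  n <- length(x)
  dist <- if (n == 100L) min_distance else max(1, round(min_distance * n / 100))
  cand <- local_maxima(x)
  cand <- cand[vapply(cand, function(p) peak_prominence(x, p), 0) >=
                 min_prominence]
  sel <- integer(0)
  if (length(cand) > 0) {
    ord <- cand[order(-x[cand], cand)]       # height desc, index asc tie-break
    sel <- ord[1]
    far <- ord[abs(ord - sel) >= dist]
    if (length(far) > 0) sel <- c(sel, far[1])
  }
  sel <- sort(sel)
  structure(
    list(peaks = data.frame(frequency = freqs[sel], height = x[sel],
                            grid_index = sel),
         n_candidates = length(cand), min_distance = dist,
         min_prominence = min_prominence),
    class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  if (nrow(x$peaks) == 0) {
    cat("<peak_set> no qualifying peaks\n")
  } else {
    cat(sprintf("<peak_set> %d peak(s): %s\n", nrow(x$peaks),
                paste(sprintf("%.3g Hz (h=%.3g)", x$peaks$frequency,
                              x$peaks$height), collapse = ", ")))
  }
  invisible(x)
}
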