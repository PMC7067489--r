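#' Unpaired Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The reported statistic is
#' `min(U_a, U_b)` (the convention is recorded in the result). The
#' two-sided p-value is exact - computed by full enumeration of group
#' assignments - whenever `choose(n1 + n2, n1)` does not exceed
#' `exact_limit`; otherwise a normal approximation with tie correction and
#' a 0.5 continuity correction is used.
#'
#' @param sample_a,sample_b numeric vectors (non-empty)
#' @param exact_limit largest number of assignments enumerated exactly
#' @return object of class `test_result` (list): `statistic` (U),
#'   `p_value`, `n1`, `n2`, `test_name`, `method` ("exact enumeration" or
#'   "normal approximation"), `convention`
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_limit = 400) {
  abort_if(length(sample_a) == 0 || length(sample_b) == 0,
           "both samples must be non-empty")
  n1 <- length(sample_a); n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  u_of <- function(idx_a) {
    r <- rank(pooled)
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  ua <- u_of(seq_len(n1))
  ub <- n1 * n2 - ua
  mu <- n1 * n2 / 2
  n_comb <- choose(n1 + n2, n1)
  if (n_comb <= exact_limit) {
    r <- rank(pooled)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(ua - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (abs(ua - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal approximation"
  }
  structure(list(statistic = min(ua, ub), U_a = ua, U_b = ub,
                 p_value = min(p, 1), n1 = n1, n2 = n2,
                 test_name = "Mann-Whitney U", method = method,
                 convention = "U = min(U_a, U_b)"),
            class = "test_result")
}

#' Unpaired two-sample t test (pooled variance)
#'
#' Classical equal-variance two-sample t statistic with a two-sided
#' p-value from the t distribution on `n1 + n2 - 2` degrees of freedom.
#'
#' @param sample_a,sample_b numeric vectors of length >= 2
#' @return object of class `test_result`: `statistic` (t), `p_value`, `df`,
#'   `n1`, `n2`, `test_name`
#' @export
unpaired_t <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  abort_if(n1 < 2 || n2 < 2, "each sample needs at least 2 observations")
  v1 <- stats::var(sample_a); v2 <- stats::var(sample_b)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  abort_if(sp2 == 0, "zero pooled variance: t statistic undefined")
  tval <- (mean(sample_a) - mean(sample_b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  structure(list(statistic = tval, p_value = 2 * stats::pt(-abs(tval), df),
                 df = df, n1 = n1, n2 = n2,
                 test_name = "unpaired t (pooled variance)"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Benjamini-Hochberg adjustment for a set of test results
#'
#' Off by default in the pipeline (matching single-test reporting); exposed
#' for users comparing many frequency bands at once.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
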