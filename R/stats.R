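#' Wilcoxon signed-rank statistic for paired allelic counts
#'
#' Computes the raw signed rank sum for the paired differences
#' `d = x2 - x1`: zero differences are excluded, the absolute values of the
#' remaining differences are ranked with midranks for ties, and the
#' statistic is the sum of the signed ranks. All-zero differences give 0.
#' The statistic is positive when the second allele is higher.
#'
#' @param x1,x2 numeric vectors of equal length `S >= 2` (allele-1 and
#'   allele-2 counts across samples).
#' @return the signed rank sum, a single number in
#'   `[-S(S+1)/2, S(S+1)/2]`.
#' @export
signed_rank_stat <- function(x1, x2) {
  if (length(x1) != length(x2)) .stopf("'x1' and 'x2' must have equal length")
  if (length(x1) < 2L) .stopf("at least 2 samples required")
  d <- x2 - x1
  nz <- d != 0
  if (!any(nz)) return(0)
  r <- rank(abs(d[nz]))
  sum(sign(d[nz]) * r)
}

# Row-wise signed ranks of a difference matrix D [features x samples]:
# per row, zeros excluded from ranking (and contribute 0), midranks for
# ties among the nonzero |d|. Returns a matrix of the same shape whose
# rowSums are the signed-rank statistics.
.row_signed_ranks <- function(D) {
  out <- t(apply(D, 1L, function(d) {
    nz <- d != 0
    r <- numeric(length(d))
    if (any(nz)) r[nz] <- rank(abs(d[nz]))
    sign(d) * r
  }))
  # apply() drops to a vector when D has one row
  if (nrow(D) == 1L) out <- matrix(out, nrow = 1L)
  out
}

# Row-wise midranks of a matrix [features x samples] (all entries ranked).
.row_ranks <- function(X) {
  out <- t(apply(X, 1L, rank))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L)
  out
}

# Row-standardize a matrix: subtract row mean, divide by row sd (n-1
# denominator). Constant rows become all zeros (correlation treated as 0).
.row_standardize <- function(X) {
  m <- rowMeans(X)
  Xc <- X - m
  s <- .row_sds(X)
  zero <- s <= 0 | !is.finite(s)
  s[zero] <- 1
  Z <- Xc / s
  Z[zero, ] <- 0
  Z
}

#' Permutation p-values and q-values from a pooled null
#'
#' Converts per-feature observed statistics and a pooled permutation null
#' into two-sided empirical p-values and FDR q-values. The p-value is the
#' add-one-corrected absolute-value tail
#' \deqn{p_i = (1 + \#\{|null| \ge |obs_i|\}) / (1 + \#null),}
#' which guarantees p > 0 and super-uniformity under the null. The null
#' proportion \eqn{\pi_0} is estimated by Storey's smoother on the p-value
#' histogram (lambda grid 0.05 to 0.95 in steps of 0.05, cubic smoothing
#' spline, evaluated at the largest lambda, clipped to `[1/N, 1]`), and
#' q-values are the Benjamini-Hochberg step-up values scaled by
#' \eqn{\pi_0} and monotonized.
#'
#' @param observed numeric vector of per-feature statistics.
#' @param null numeric vector (or matrix) of pooled permutation statistics;
#'   all features' permuted statistics are pooled into one null.
#' @param pi0 optional fixed null proportion overriding the Storey
#'   estimate.
#' @return list with components `pvalue`, `qvalue`, `pi0`.
#' @export
qvalue_from_null <- function(observed, null, pi0 = NULL) {
  null <- as.numeric(null)
  n_null <- length(null)
  if (n_null == 0L) .stopf("empty permutation null")
  n <- length(observed)
  sorted <- sort(abs(null))
  # count of |null| >= |obs|: total minus strict-less count
  cnt_ge <- n_null - findInterval(abs(observed), sorted, left.open = TRUE)
  p <- (1 + cnt_ge) / (1 + n_null)

  if (is.null(pi0)) pi0 <- .estimate_pi0(p)
  pi0 <- min(max(pi0, 1 / max(n, 1L)), 1)

  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  i <- seq(n, 1L)
  q <- pmin(1, cummin(pi0 * n / i * p[o]))[ro]
  list(pvalue = p, qvalue = q, pi0 = pi0)
}

# Storey pi0 estimate, smoother variant with fixed lambda grid.
.estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  n <- length(p)
  if (n == 0L) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) min(pi0_l[length(pi0_l)], 1))
  min(max(pi0, 1 / n), 1)
}
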