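#' Beta-binomial test for allelic imbalance (point estimates only)
#'
#' Comparator method that ignores inferential uncertainty: for each
#' feature, the rounded allele-2 counts are modelled as beta-binomial
#' successes out of the rounded total allelic counts across samples, with a
#' logit-mean intercept and a free overdispersion (precision) parameter
#' estimated by maximum likelihood. The p-value is the Wald test of the
#' intercept against 0 (balanced alleles, log odds ratio 0), and q-values
#' are Benjamini-Hochberg adjusted.
#'
#' The beta-binomial is parameterised by mean `p = plogis(beta)` and
#' precision `theta`, with shape parameters `a = p * theta` and
#' `b = (1 - p) * theta`; `theta -> Inf` recovers the binomial.
#'
#' @param m an [allelic_matrix()]; only point estimates are used.
#' @param min_samples features need a positive total in at least this many
#'   samples (default 3) to be fit.
#' @return an object of class `"ai_test"` (type `beta_binomial`) with
#'   columns `feature_id`, `stat` (Wald z), `log2fc` (estimated allelic
#'   log2 odds ratio), `pvalue`, `qvalue`, and a logical `converged`
#'   column; features that fail to converge get `NA` p-values.
#' @export
beta_binomial_test <- function(m, min_samples = 3L) {
  n_feat <- length(m$feature_ids)
  y <- round(matrix(m$counts[, , 2], nrow = n_feat))
  n <- round(matrix(m$counts[, , 1], nrow = n_feat)) + y

  est <- z <- p <- rep(NA_real_, n_feat)
  conv <- logical(n_feat)
  for (i in seq_len(n_feat)) {
    ok <- n[i, ] > 0
    if (sum(ok) < min_samples) next
    fit <- .fit_betabinom(y[i, ok], n[i, ok])
    if (is.null(fit)) next
    est[i] <- fit$beta
    z[i] <- fit$z
    p[i] <- fit$p
    conv[i] <- TRUE
  }
  q <- rep(NA_real_, n_feat)
  q[conv] <- stats::p.adjust(p[conv], method = "BH")

  out <- data.frame(feature_id = m$feature_ids,
                    stat = z,
                    log2fc = est / log(2),
                    pvalue = p,
                    qvalue = q,
                    converged = conv,
                    stringsAsFactors = FALSE)
  structure(out, type = "beta_binomial", level = m$level, pi0 = NA_real_,
            config = list(min_samples = min_samples),
            class = c("ai_test", "data.frame"))
}

# Intercept-only beta-binomial MLE on (y successes out of n), parameters
# (beta = logit mean, log theta = log precision). Returns NULL on failure.
.fit_betabinom <- function(y, n) {
  nll <- function(par) {
    pr <- stats::plogis(par[1])
    th <- exp(par[2])
    a <- pr * th
    b <- (1 - pr) * th
    ll <- lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }
  phat <- (sum(y) + 0.5) / (sum(n) + 1)
  start <- c(stats::qlogis(min(max(phat, 1e-4), 1 - 1e-4)), log(10))
  fit <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B", hessian = TRUE,
                 lower = c(-20, -10), upper = c(20, 15),
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  v <- tryCatch(solve(fit$hessian)[1, 1], error = function(e) NA_real_)
  if (!is.finite(v) || v <= 0) {
    # near the binomial limit the precision direction is flat and the full
    # hessian can be numerically singular; fall back to the beta curvature
    v <- 1 / fit$hessian[1, 1]
  }
  if (!is.finite(v) || v <= 0) return(NULL)
  se <- sqrt(v)
  z <- fit$par[1] / se
  list(beta = fit$par[1], se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), theta = exp(fit$par[2]))
}
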