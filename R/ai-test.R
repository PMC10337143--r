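#' Test for allelic imbalance across samples
#'
#' The package's central fitting function. Tests each feature of an
#' [allelic_matrix()] for allelic imbalance (AI) with a nonparametric
#' statistic computed on every bootstrap inferential replicate and averaged
#' over replicates, so that quantification uncertainty flows into the test.
#' Significance is assessed against a permutation null pooled over all
#' features and permutations, followed by Storey-type q-values
#' ([qvalue_from_null()]).
#'
#' Three tests are available:
#' \describe{
#'   \item{`global`}{consistent AI across all samples. Statistic: Wilcoxon
#'     signed-rank sum of the paired within-sample allele differences
#'     (allele 2 minus allele 1), averaged over bootstraps. Null: allele
#'     labels are swapped within a random subset of samples
#'     (sign-flipping the paired differences), one shared flip vector per
#'     permutation applied to all features.}
#'   \item{`dynamic`}{AI changing along a continuous covariate. Statistic:
#'     Pearson (or Spearman) correlation between the per-sample
#'     pseudocounted allelic log2 fold changes and the covariate, averaged
#'     over bootstraps. Null: the covariate is permuted across samples, the
#'     same permutation for all features per draw.}
#'   \item{`differential`}{AI differing between two groups of samples.
#'     Statistic: centered Mann-Whitney rank sum comparing the per-sample
#'     allelic log2 fold changes between the groups, averaged over
#'     bootstraps. Null: group labels permuted.}
#' }
#'
#' The reported `log2fc` is the mean over samples and bootstrap replicates
#' of `log2((a2 + c) / (a1 + c))` with pseudocount `c` (default 5);
#' positive values mean the second (paternal/alternate) allele is higher.
#'
#' No depth normalisation is applied: both alleles of a sample share its
#' sequencing depth, so the within-sample comparison is depth-free.
#'
#' @param object an [allelic_matrix()], typically aggregated and filtered
#'   (see [aggregate_allelic()], [filter_uninformative()],
#'   [filter_min_count()]).
#' @param type which test to run.
#' @param covariate for `type = "dynamic"`: numeric vector (one value per
#'   sample) or the name of a numeric column of the object's sample
#'   metadata. Needs at least 3 distinct values.
#' @param group for `type = "differential"`: two-level factor (one value
#'   per sample) or name of a metadata column; both levels need >= 2
#'   samples.
#' @param pseudocount pseudocount `c > 0` added to both allelic counts in
#'   log fold changes (default 5).
#' @param n_perm number of permutations (default 100). The pooled null has
#'   `n_perm * n_features` values, so the attainable p-value resolution is
#'   about `1 / (n_perm * n_features)`.
#' @param cor_method correlation type for the dynamic test.
#' @param n_boot number of bootstrap replicates to use (default: all).
#' @param seed integer seed for the permutation draws; the caller's RNG
#'   state is restored afterwards. Results are reproducible given the seed.
#' @return an object of class `"ai_test"`: a `data.frame` with columns
#'   `feature_id`, `stat`, `log2fc`, `pvalue`, `qvalue`, plus attributes
#'   `type`, `level`, `pi0`, and `config`.
#' @examples
#' sim <- simulate_allelic(sim_design(n_genes = 40, n_ai_genes = 10,
#'                                    lib_size = 5e4, n_boot = 8), seed = 1)
#' m <- filter_min_count(filter_uninformative(sim$matrix))
#' fit <- ai_test(m, "global", n_perm = 50, seed = 2)
#' head(as.data.frame(fit))
#' @export
ai_test <- function(object, type = c("global", "dynamic", "differential"),
                    covariate = NULL, group = NULL,
                    pseudocount = 5, n_perm = 100L,
                    cor_method = c("pearson", "spearman"),
                    n_boot = NULL, seed = NULL) {
  type <- match.arg(type)
  cor_method <- match.arg(cor_method)
  if (!inherits(object, "allelic_matrix"))
    .stopf("'object' must be an allelic_matrix")
  n_feat <- length(object$feature_ids)
  S <- length(object$sample_ids)
  if (n_feat == 0L) .stopf("no features left to test (all filtered?)")
  if (S < 2L) .stopf("at least 2 samples required")
  if (type == "global" && S < 3L)
    .warnf("fewer than 3 samples: the global AI test will have little power")
  if (pseudocount <= 0) .stopf("'pseudocount' must be > 0")
  if (n_perm < 1L) .stopf("'n_perm' must be >= 1")
  if (n_perm < 10L)
    .warnf("n_perm = %d gives a very coarse permutation null", n_perm)
  B_all <- n_bootstraps(object)
  B <- if (is.null(n_boot)) B_all else min(as.integer(n_boot), B_all)
  if (B < 1L) .stopf("need at least one bootstrap replicate")

  covariate <- .resolve_sample_var(object, covariate, "covariate")
  group <- .resolve_sample_var(object, group, "group")

  a1 <- function(b) matrix(object$bootstraps[, , 1L, b], nrow = n_feat)
  a2 <- function(b) matrix(object$bootstraps[, , 2L, b], nrow = n_feat)

  # mean pseudocounted log2 fold change over samples and bootstraps
  log2fc <- numeric(n_feat)
  for (b in seq_len(B))
    log2fc <- log2fc +
      rowMeans(log2((a2(b) + pseudocount) / (a1(b) + pseudocount)))
  log2fc <- log2fc / B

  fit <- .with_seed(seed, {
    if (type == "global") {
      A <- matrix(0, n_feat, S)
      for (b in seq_len(B))
        A <- A + .row_signed_ranks(a2(b) - a1(b))
      A <- A / B
      obs <- rowSums(A)
      flips <- matrix(sample(c(-1, 1), S * n_perm, replace = TRUE), S, n_perm)
      null <- A %*% flips
    } else if (type == "dynamic") {
      if (is.null(covariate))
        .stopf("the dynamic AI test needs a 'covariate'")
      if (length(covariate) != S)
        .stopf("'covariate' must have one value per sample")
      if (length(unique(covariate)) < 3L)
        .stopf("'covariate' must have at least 3 distinct values")
      cv <- if (cor_method == "spearman") rank(covariate) else covariate
      cs <- stats::sd(cv)
      zc <- (cv - mean(cv)) / cs
      Z <- matrix(0, n_feat, S)
      for (b in seq_len(B)) {
        L <- log2((a2(b) + pseudocount) / (a1(b) + pseudocount))
        if (cor_method == "spearman") L <- .row_ranks(L)
        Z <- Z + .row_standardize(L)
      }
      Z <- Z / B
      obs <- as.numeric(Z %*% zc) / (S - 1)
      perms <- replicate(n_perm, zc[sample.int(S)])
      null <- Z %*% perms / (S - 1)
    } else { # differential
      if (is.null(group))
        .stopf("the differential AI test needs a 'group'")
      g <- factor(group)
      if (nlevels(g) != 2L)
        .stopf("'group' must have exactly two levels")
      if (min(table(g)) < 2L)
        .stopf("both groups need at least 2 samples")
      ind <- as.numeric(g == levels(g)[2])
      n2 <- sum(ind)
      center <- n2 * (S + 1) / 2
      A <- matrix(0, n_feat, S)
      for (b in seq_len(B)) {
        L <- log2((a2(b) + pseudocount) / (a1(b) + pseudocount))
        A <- A + .row_ranks(L)
      }
      A <- A / B
      obs <- as.numeric(A %*% ind) - center
      perms <- replicate(n_perm, ind[sample.int(S)])
      null <- A %*% perms - center
    }
    c(qvalue_from_null(obs, null), list(stat = obs, n_null = length(null)))
  })

  out <- data.frame(feature_id = object$feature_ids,
                    stat = fit$stat,
                    log2fc = log2fc,
                    pvalue = fit$pvalue,
                    qvalue = fit$qvalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            type = type, level = object$level, pi0 = fit$pi0,
            config = list(pseudocount = pseudocount, n_perm = n_perm,
                          cor_method = cor_method, n_boot = B, seed = seed,
                          n_null = fit$n_null),
            class = c("ai_test", "data.frame"))
}

.resolve_sample_var <- function(object, x, what) {
  if (is.null(x)) {
    if (!is.null(object$metadata) && what %in% names(object$metadata))
      return(object$metadata[[what]])
    return(NULL)
  }
  if (is.character(x) && length(x) == 1L) {
    if (is.null(object$metadata) || !x %in% names(object$metadata))
      .stopf("'%s' column not found in sample metadata", x)
    return(object$metadata[[x]])
  }
  x
}

#' @export
print.ai_test <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("%s AI test (%s level): %d features, %d bootstraps, %d permutations\n",
              attr(x, "type"), attr(x, "level"), nrow(x),
              cfg$n_boot, cfg$n_perm))
  cat(sprintf("pi0 estimate: %.3f; features with q < 0.05: %d\n",
              attr(x, "pi0"), sum(x$qvalue < 0.05)))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat(sprintf("... and %d more features\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
summary.ai_test <- function(object, cutoffs = c(0.01, 0.05, 0.1), ...) {
  out <- data.frame(
    nominal_fdr = cutoffs,
    n_significant = vapply(cutoffs, function(a) sum(object$qvalue < a),
                           integer(1)))
  cat(sprintf("%s AI test at %s level: %d features tested, pi0 = %.3f\n",
              attr(object, "type"), attr(object, "level"), nrow(object),
              attr(object, "pi0")))
  print(out, row.names = FALSE)
  invisible(out)
}

#' Volcano-style plot of an AI test
#'
#' Plots the mean allelic log2 fold change against -log10 p-value, marking
#' features significant at the given q-value cutoff.
#'
#' @param x an `"ai_test"` object
#' @param alpha q-value cutoff used for highlighting (default 0.05)
#' @param ... passed to [graphics::plot()]
#' @export
plot.ai_test <- function(x, alpha = 0.05, ...) {
  sig <- x$qvalue < alpha
  graphics::plot(x$log2fc, -log10(x$pvalue),
                 col = ifelse(sig, "firebrick", "grey50"),
                 pch = 16, cex = 0.6,
                 xlab = "mean allelic log2 fold change (a2/a1)",
                 ylab = expression(-log[10] ~ p), ...)
  graphics::legend("topleft", bty = "n", pch = 16,
                   col = c("firebrick", "grey50"),
                   legend = c(sprintf("q < %.2g", alpha), "not significant"))
  invisible(x)
}
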