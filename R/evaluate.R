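#' Propagate group-level AI calls to transcripts
#'
#' A transcript is called positive iff its group (TSS group or gene) is
#' significant at the given q-value cutoff. For transcript-level results
#' (`gmap = NULL`) calls pass through unchanged. Optionally the propagated
#' set is restricted to a set of expressed transcripts (e.g. those
#' surviving [filter_min_count()] at transcript level).
#'
#' @param results an `"ai_test"` object (or any `data.frame` with
#'   `feature_id` and `qvalue` columns).
#' @param gmap the `group_map` whose groups were tested, or `NULL` for
#'   transcript-level results.
#' @param alpha q-value cutoff (default 0.05).
#' @param expressed optional character vector of expressed transcript ids
#'   to intersect the propagated calls with.
#' @return character vector of called transcript ids.
#' @export
propagate_calls <- function(results, gmap = NULL, alpha = 0.05,
                            expressed = NULL) {
  called <- results$feature_id[!is.na(results$qvalue) &
                                 results$qvalue < alpha]
  if (is.null(gmap)) {
    out <- called
  } else {
    gmap_df <- as.data.frame(gmap)
    info <- attr(gmap, "group_info")
    missing <- setdiff(results$feature_id, info$group_id)
    if (length(missing) > 0L)
      .stopf("tested feature(s) absent from the group map: %s",
             paste(utils::head(missing, 5), collapse = ", "))
    out <- gmap_df$tx_id[gmap_df$group_id %in% called]
  }
  if (!is.null(expressed)) out <- intersect(out, expressed)
  out
}

#' Score a transcript call set against simulation truth
#'
#' Computes the observed false discovery rate and the true positive rate
#' (sensitivity), overall and stratified by type of AI (concordant vs
#' discordant), against a ground-truth table. True positives are
#' transcripts whose truth status is not `balanced`. Conventions:
#' `FDR = FP / max(1, FP + TP)` (0 for an empty call set) and
#' `TPR = TP / P`.
#'
#' @param calls character vector of transcripts called positive.
#' @param truth a `"sim_truth"` table (needs `tx_id`, `status`); must cover
#'   every called transcript.
#' @param eligible optional character vector restricting the evaluation
#'   universe (e.g. expressed transcripts); truth rows outside it are
#'   ignored when counting positives.
#' @return one-row `data.frame`: `n_called`, `fdr`, `tpr`,
#'   `tpr_concordant`, `tpr_discordant`.
#' @export
fdr_tpr <- function(calls, truth, eligible = NULL) {
  if (!all(calls %in% truth$tx_id))
    .stopf("call set contains transcripts absent from the truth table")
  if (!is.null(eligible)) truth <- truth[truth$tx_id %in% eligible, ]
  pos <- truth$tx_id[truth$status != "balanced"]
  tp <- length(intersect(calls, pos))
  fp <- length(calls) - tp
  str_tpr <- function(st) {
    p <- truth$tx_id[truth$status == st]
    if (length(p) == 0L) return(NA_real_)
    length(intersect(calls, p)) / length(p)
  }
  data.frame(n_called = length(calls),
             fdr = fp / max(1L, fp + tp),
             tpr = if (length(pos) > 0L) tp / length(pos) else NA_real_,
             tpr_concordant = str_tpr("concordant"),
             tpr_discordant = str_tpr("discordant"))
}

#' Bootstrap-interval coverage of true counts
#'
#' For every feature, sample and allele, builds the normal-approximation
#' 95% bootstrap interval `boot_mean +/- 1.959964 * boot_sd` from the
#' first `B_sub` replicates and records whether the true count falls
#' inside. Features are divided into three expression tertiles on the true
#' counts pooled over samples and alleles (ties broken by rank order), and
#' the coverage rate is summarised per tertile (and overall) as the mean
#' and standard deviation across samples.
#'
#' @param m an [allelic_matrix()] at any aggregation level.
#' @param truth_counts numeric array `[features x samples x 2]` of true
#'   counts aligned to `m` (aggregate with [aggregate_counts()] when `m`
#'   is at TSS or gene level).
#' @param B_sub number of replicates to use (2 <= B_sub <= B); using
#'   nested prefixes of the replicates makes coverage comparable across
#'   `B_sub` on the identical dataset.
#' @param z interval half-width multiplier (default the 97.5% normal
#'   quantile, 1.959964).
#' @return `data.frame` with rows for tertiles `low`/`mid`/`high` and
#'   `overall`: `level`, `B`, `tertile`, `mean_coverage`, `sd_coverage`
#'   (across samples), `n_intervals`.
#' @export
bootstrap_coverage <- function(m, truth_counts, B_sub = n_bootstraps(m),
                               z = stats::qnorm(0.975)) {
  B <- n_bootstraps(m)
  if (B_sub < 2L) .stopf("'B_sub' must be >= 2 (bootstrap sd undefined)")
  if (B_sub > B) .stopf("'B_sub' exceeds the stored number of replicates")
  if (!identical(dim(truth_counts), dim(m$counts)))
    .stopf("'truth_counts' dimensions must match the matrix")
  n_feat <- dim(m$counts)[1]
  S <- dim(m$counts)[2]

  flat <- matrix(m$bootstraps[, , , seq_len(B_sub), drop = FALSE],
                 nrow = n_feat * S * 2L)
  bm <- rowMeans(flat)
  bs <- .row_sds(flat)
  tr <- as.numeric(truth_counts)
  covered <- array(tr >= bm - z * bs & tr <= bm + z * bs,
                   dim = c(n_feat, S, 2L))

  tot_true <- apply(truth_counts, 1L, sum)
  tert <- ceiling(3 * rank(tot_true, ties.method = "first") / n_feat)
  tert_lab <- c("low", "mid", "high")[tert]

  rows <- lapply(c("low", "mid", "high", "overall"), function(lab) {
    f <- if (lab == "overall") rep(TRUE, n_feat) else tert_lab == lab
    per_sample <- vapply(seq_len(S),
                         function(s) mean(covered[f, s, ]), numeric(1))
    data.frame(level = m$level, B = B_sub, tertile = lab,
               mean_coverage = mean(per_sample),
               sd_coverage = stats::sd(per_sample),
               n_intervals = sum(f) * S * 2L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
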