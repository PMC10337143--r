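#' Aggregate allelic estimates to TSS-group or gene level
#'
#' Sums both the point-estimate counts and every bootstrap replicate (and
#' TPM, when present) across the member transcripts of each group, per
#' sample and per allele. Summation is performed identically on every
#' bootstrap replicate so that the aggregated object carries a full
#' inferential-uncertainty representation at the new level. The grand total
#' count is conserved exactly (point estimates and each replicate).
#'
#' No library-size scaling is applied at any point: the allelic tests
#' compare the two alleles within a sample, where sequencing depth affects
#' both alleles equally, so depth normalisation is unnecessary and is
#' deliberately omitted.
#'
#' @param m an [allelic_matrix()] at transcript level.
#' @param gmap a `group_map` from [make_tx2tss()] or [make_tx2gene()].
#'   Features of `m` not present in the map are dropped with a warning.
#' @return an `allelic_matrix` at the map's level, with one feature per
#'   group (ordered as in the map's `group_info`).
#' @export
aggregate_allelic <- function(m, gmap) {
  gmap_df <- as.data.frame(gmap)
  idx <- match(m$feature_ids, gmap_df$tx_id)
  unmapped <- is.na(idx)
  if (all(unmapped))
    .stopf("none of the features are present in the group map")
  if (any(unmapped)) {
    .warnf("dropping %d feature(s) absent from the group map", sum(unmapped))
    m <- m[!unmapped, ]
    idx <- idx[!unmapped]
  }
  groups <- gmap_df$group_id[idx]
  info <- attr(gmap, "group_info")
  levels_out <- intersect(info$group_id, unique(groups))

  n_feat <- length(m$feature_ids)
  n_s <- length(m$sample_ids)
  B <- n_bootstraps(m)

  roll <- function(arr) {
    flat <- matrix(arr, nrow = n_feat)
    agg <- rowsum(flat, group = groups, reorder = FALSE)
    agg <- agg[match(levels_out, rownames(agg)), , drop = FALSE]
    agg
  }
  counts <- array(roll(m$counts), dim = c(length(levels_out), n_s, 2L))
  boot <- array(roll(m$bootstraps), dim = c(length(levels_out), n_s, 2L, B))
  tpm <- if (!is.null(m$tpm))
    array(roll(m$tpm), dim = c(length(levels_out), n_s, 2L)) else NULL

  allelic_matrix(counts, boot, tpm = tpm,
                 feature_ids = levels_out, sample_ids = m$sample_ids,
                 allele_labels = m$allele_labels,
                 level = attr(gmap, "level"),
                 metadata = m$metadata)
}

.add_filter_report <- function(m, dropped, reason) {
  rep0 <- attr(m, "filter_report")
  if (is.null(rep0))
    rep0 <- data.frame(feature = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (length(dropped) > 0L)
    rep0 <- rbind(rep0, data.frame(feature = dropped, reason = reason,
                                   stringsAsFactors = FALSE))
  rep0
}

#' Drop features carrying no allelic information
#'
#' When no read carries information distinguishing the two alleles of a
#' feature (identical allele sequences, or no reads covering a difference),
#' the quantifier splits the feature's total count exactly equally between
#' the alleles in every sample, so the estimated allelic fold change is
#' identically 1. Such features are uninformative for imbalance testing and
#' are removed before testing.
#'
#' Equality of the two alleles' point estimates is checked with a tiny
#' absolute tolerance to be robust to text round-trips.
#'
#' @param m an [allelic_matrix()]
#' @param tol absolute tolerance for count equality (default 1e-8)
#' @return the filtered `allelic_matrix`; dropped ids are recorded in the
#'   attribute `"filter_report"` (see [filter_report()]).
#' @export
filter_uninformative <- function(m, tol = 1e-8) {
  d <- abs(m$counts[, , 1, drop = FALSE] - m$counts[, , 2, drop = FALSE])
  equal_all <- apply(d <= tol, 1L, all)
  dropped <- m$feature_ids[equal_all]
  out <- m[!equal_all, ]
  attr(out, "filter_report") <- .add_filter_report(m, dropped, "uninformative")
  out
}

#' Minimum-count filter
#'
#' Keeps a feature if at least `min_n` of its allele-sample point-estimate
#' columns (2 alleles x S samples by default) have a count of at least
#' `min_count`. With `per_sample_total = TRUE` the criterion is applied to
#' per-sample totals (a1 + a2) instead, a stricter reading.
#'
#' @param m an [allelic_matrix()]
#' @param min_count minimum count (default 10)
#' @param min_n minimum number of qualifying columns (default 3)
#' @param per_sample_total apply the threshold to per-sample allele totals
#'   rather than individual allele-sample columns
#' @return the filtered `allelic_matrix` with an updated `"filter_report"`.
#' @export
filter_min_count <- function(m, min_count = 10, min_n = 3L,
                             per_sample_total = FALSE) {
  if (min_count <= 0) .stopf("'min_count' must be > 0")
  if (min_n < 1L) .stopf("'min_n' must be >= 1")
  if (per_sample_total) {
    cols <- matrix(m$counts[, , 1], nrow = length(m$feature_ids)) +
      matrix(m$counts[, , 2], nrow = length(m$feature_ids))
  } else {
    cols <- cbind(matrix(m$counts[, , 1], nrow = length(m$feature_ids)),
                  matrix(m$counts[, , 2], nrow = length(m$feature_ids)))
  }
  keep <- rowSums(cols >= min_count) >= min_n
  dropped <- m$feature_ids[!keep]
  out <- m[keep, ]
  attr(out, "filter_report") <- .add_filter_report(m, dropped, "min_count")
  out
}

#' Retrieve the filter report of an allelic matrix
#'
#' @param m an `allelic_matrix` that has passed through
#'   [filter_uninformative()] and/or [filter_min_count()]
#' @return `data.frame` with columns `feature`, `reason`
#' @export
filter_report <- function(m) {
  rep0 <- attr(m, "filter_report")
  if (is.null(rep0))
    rep0 <- data.frame(feature = character(), reason = character(),
                       stringsAsFactors = FALSE)
  rep0
}

#' Aggregate a plain [features x samples x 2] count array by a group map
#'
#' Utility used to carry simulation ground-truth counts to the same
#' aggregation level as a tested [allelic_matrix()], e.g. for
#' bootstrap-interval coverage evaluation.
#'
#' @param counts numeric array `[features x samples x 2]`
#' @param feature_ids ids of the array's first dimension
#' @param gmap a `group_map`
#' @return list with `counts` (aggregated array) and `feature_ids` (group
#'   ids, in map order)
#' @export
aggregate_counts <- function(counts, feature_ids, gmap) {
  gmap_df <- as.data.frame(gmap)
  idx <- match(feature_ids, gmap_df$tx_id)
  keep <- !is.na(idx)
  if (!any(keep)) .stopf("none of the features are present in the group map")
  counts <- counts[keep, , , drop = FALSE]
  groups <- gmap_df$group_id[idx[keep]]
  info <- attr(gmap, "group_info")
  levels_out <- intersect(info$group_id, unique(groups))
  flat <- matrix(counts, nrow = sum(keep))
  agg <- rowsum(flat, group = groups, reorder = FALSE)
  agg <- agg[match(levels_out, rownames(agg)), , drop = FALSE]
  list(counts = array(agg, dim = c(length(levels_out), dim(counts)[2], 2L)),
       feature_ids = levels_out)
}
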