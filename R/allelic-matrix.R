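#' Allele-level count matrix with bootstrap inferential replicates
#'
#' The central container of the package: estimated read counts for each
#' feature (transcript, TSS group, or gene) in each sample, resolved into the
#' two alleles of a phased diploid sample, together with B bootstrap
#' replicate count arrays capturing quantification uncertainty.
#'
#' Every feature is present for both alleles (paired structure). The first
#' allele label (`a1`) conventionally denotes the maternal/reference allele
#' and the second (`a2`) the paternal/alternate allele; a positive allelic
#' fold change means `a2` is higher.
#'
#' @param counts numeric array `[features x samples x 2]` of non-negative
#'   estimated counts; allele is the third dimension.
#' @param bootstraps numeric array `[features x samples x 2 x B]` of
#'   bootstrap replicate counts, `B >= 1`.
#' @param tpm optional numeric array `[features x samples x 2]` of
#'   abundances (TPM). May be `NULL`; operations needing abundances raise an
#'   error in that case.
#' @param feature_ids,sample_ids character identifiers; defaults taken from
#'   dimnames when present.
#' @param allele_labels length-2 character vector naming the alleles, in
#'   order (a1 = maternal/reference first).
#' @param level resolution of the features: `"txp"`, `"tss"`, or `"gene"`.
#' @param metadata optional `data.frame` of per-sample metadata with a
#'   `sample_id` column and optionally `covariate` (numeric) and `group`
#'   (two-level factor) columns, in sample order.
#'
#' @return An object of class `"allelic_matrix"`.
#' @seealso [assemble_allelic()], [aggregate_allelic()], [ai_test()]
#' @export
allelic_matrix <- function(counts, bootstraps, tpm = NULL,
                           feature_ids = NULL, sample_ids = NULL,
                           allele_labels = c("a1", "a2"),
                           level = c("txp", "tss", "gene"),
                           metadata = NULL) {
  level <- match.arg(level)
  if (length(dim(counts)) != 3L || dim(counts)[3] != 2L)
    .stopf("'counts' must be a [features x samples x 2] array")
  if (length(dim(bootstraps)) != 4L)
    .stopf("'bootstraps' must be a [features x samples x 2 x B] array")
  if (!identical(dim(bootstraps)[1:3], dim(counts)))
    .stopf("bootstrap dimensions (%s) do not match counts (%s)",
           paste(dim(bootstraps)[1:3], collapse = "x"),
           paste(dim(counts), collapse = "x"))
  if (dim(bootstraps)[4] < 1L) .stopf("at least one bootstrap replicate required (B >= 1)")
  if (anyNA(counts) || anyNA(bootstraps))
    .stopf("counts and bootstraps must not contain NA")
  if (min(counts) < 0 || min(bootstraps) < 0)
    .stopf("counts and bootstraps must be non-negative")
  if (length(allele_labels) != 2L)
    .stopf("'allele_labels' must have length 2")

  if (is.null(feature_ids)) feature_ids <- dimnames(counts)[[1]]
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(dim(counts)[1]))
  if (is.null(sample_ids)) sample_ids <- dimnames(counts)[[2]]
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(dim(counts)[2]))
  if (length(feature_ids) != dim(counts)[1])
    .stopf("feature_ids length does not match counts")
  if (length(sample_ids) != dim(counts)[2])
    .stopf("sample_ids length does not match counts")
  if (!is.null(tpm) && !identical(dim(tpm), dim(counts)))
    .stopf("'tpm' dimensions must match counts")
  if (!is.null(metadata)) {
    if (!"sample_id" %in% names(metadata))
      .stopf("metadata must have a 'sample_id' column")
    if (!identical(as.character(metadata$sample_id), as.character(sample_ids)))
      .stopf("metadata sample_id does not match sample_ids (order matters)")
  }

  dimnames(counts) <- list(feature_ids, sample_ids, allele_labels)
  dimnames(bootstraps) <- list(feature_ids, sample_ids, allele_labels, NULL)
  if (!is.null(tpm)) dimnames(tpm) <- dimnames(counts)

  structure(
    list(counts = counts, bootstraps = bootstraps, tpm = tpm,
         feature_ids = as.character(feature_ids),
         sample_ids = as.character(sample_ids),
         allele_labels = as.character(allele_labels),
         level = level, metadata = metadata),
    class = "allelic_matrix")
}

#' @export
print.allelic_matrix <- function(x, ...) {
  cat(sprintf("allelic_matrix: %d features (%s level), %d samples, 2 alleles (%s/%s), %d bootstraps\n",
              length(x$feature_ids), x$level, length(x$sample_ids),
              x$allele_labels[1], x$allele_labels[2], n_bootstraps(x)))
  if (!is.null(x$tpm)) cat("  with TPM abundances\n")
  if (!is.null(x$metadata))
    cat(sprintf("  sample metadata columns: %s\n",
                paste(names(x$metadata), collapse = ", ")))
  invisible(x)
}

#' @export
dim.allelic_matrix <- function(x) {
  c(features = length(x$feature_ids), samples = length(x$sample_ids),
    alleles = 2L, bootstraps = n_bootstraps(x))
}

#' Number of bootstrap replicates stored in an allelic matrix
#' @param x an `allelic_matrix`
#' @export
n_bootstraps <- function(x) dim(x$bootstraps)[4]

#' Extract the point-estimate count matrix for one allele
#'
#' @param x an `allelic_matrix`
#' @param allele 1 or 2, or an allele label
#' @return numeric matrix `[features x samples]`
#' @export
allele_counts <- function(x, allele = 1L) {
  if (is.character(allele)) allele <- match(allele, x$allele_labels)
  if (is.na(allele) || !allele %in% 1:2) .stopf("unknown allele")
  x$counts[, , allele, drop = FALSE][, , 1]
}

#' Extract one bootstrap replicate as a [features x samples x 2] array
#' @param x an `allelic_matrix`
#' @param b replicate index in `1..B`
#' @export
bootstrap_counts <- function(x, b) {
  if (b < 1L || b > n_bootstraps(x)) .stopf("bootstrap index out of range")
  x$bootstraps[, , , b, drop = FALSE][, , , 1]
}

#' Subset an allelic matrix by features and/or samples
#'
#' `x[i, j]` keeps features `i` and samples `j` (indices, logicals, or
#' names), subsetting counts, bootstraps, TPM and metadata consistently.
#'
#' @param x an `allelic_matrix`
#' @param i,j feature and sample subscripts
#' @param ... ignored
#' @export
`[.allelic_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$feature_ids)
  if (missing(j)) j <- seq_along(x$sample_ids)
  if (is.character(i)) i <- match(i, x$feature_ids)
  if (is.character(j)) j <- match(j, x$sample_ids)
  out <- x
  out$counts <- x$counts[i, j, , drop = FALSE]
  out$bootstraps <- x$bootstraps[i, j, , , drop = FALSE]
  if (!is.null(x$tpm)) out$tpm <- x$tpm[i, j, , drop = FALSE]
  out$feature_ids <- x$feature_ids[i]
  out$sample_ids <- x$sample_ids[j]
  if (!is.null(x$metadata)) {
    out$metadata <- x$metadata[j, , drop = FALSE]
    rownames(out$metadata) <- NULL
  }
  fr <- attr(x, "filter_report")
  if (!is.null(fr)) attr(out, "filter_report") <- fr
  out
}
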