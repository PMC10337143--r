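#' Read a per-sample allele-level quantification table
#'
#' Reads a quant.sf-dialect TSV (columns exactly `Name`, `Length`,
#' `EffectiveLength`, `TPM`, `NumReads`) in which every transcript appears
#' twice, once per allele, distinguished by an allele suffix on the `Name`
#' (e.g. `tx1_M` and `tx1_P`). Rows are paired by base transcript id.
#'
#' @param path path to the TSV file.
#' @param allele_suffixes length-2 character vector of allele suffixes; the
#'   first suffix is allele 1 (maternal/reference).
#' @return a `data.frame` with columns `feature`, `length`, `tpm_a1`,
#'   `tpm_a2`, `count_a1`, `count_a2`, ordered by first appearance of the
#'   allele-1 rows, with attribute `"raw_names"` preserving the file's
#'   original `Name` order (used to validate bootstrap files).
#' @export
read_allelic_quant <- function(path, allele_suffixes = c("_M", "_P")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  if (!identical(names(tab), expected))
    .stopf("malformed quant table header in '%s': expected columns %s, got %s",
           path, paste(expected, collapse = "/"), paste(names(tab), collapse = "/"))
  .pair_alleles(tab, allele_suffixes, path)
}

.pair_alleles <- function(tab, allele_suffixes, src = "<table>") {
  s1 <- allele_suffixes[1]; s2 <- allele_suffixes[2]
  has1 <- endsWith(tab$Name, s1)
  has2 <- endsWith(tab$Name, s2)
  if (any(!has1 & !has2))
    .stopf("rows in '%s' without a recognized allele suffix (%s/%s): %s",
           src, s1, s2, paste(utils::head(tab$Name[!has1 & !has2], 5), collapse = ", "))
  base1 <- substr(tab$Name[has1], 1L, nchar(tab$Name[has1]) - nchar(s1))
  base2 <- substr(tab$Name[has2], 1L, nchar(tab$Name[has2]) - nchar(s2))
  orphans <- c(setdiff(base1, base2), setdiff(base2, base1))
  if (length(orphans) > 0L)
    .stopf("missing partner allele row in '%s' for: %s", src,
           paste(sort(orphans), collapse = ", "))
  if (anyDuplicated(base1) || anyDuplicated(base2))
    .stopf("duplicated transcript ids in '%s'", src)
  t1 <- tab[has1, ]; t2 <- tab[has2, ]
  t2 <- t2[match(base1, base2), ]
  out <- data.frame(feature = base1,
                    length = t1$Length,
                    tpm_a1 = t1$TPM, tpm_a2 = t2$TPM,
                    count_a1 = t1$NumReads, count_a2 = t2$NumReads,
                    stringsAsFactors = FALSE)
  attr(out, "raw_names") <- tab$Name
  attr(out, "allele_suffixes") <- allele_suffixes
  out
}

#' Write a paired quantification table in quant.sf dialect
#'
#' Inverse of [read_allelic_quant()]: writes one row per transcript-allele
#' with the allele suffix appended to the base id. `EffectiveLength` is
#' written equal to `length` (the simulator does not model fragment-length
#' effects).
#'
#' @param quant a paired table as returned by [read_allelic_quant()]
#' @param path output path
#' @param allele_suffixes length-2 character vector of allele suffixes
#' @export
write_quant_table <- function(quant, path, allele_suffixes = c("_M", "_P")) {
  n <- nrow(quant)
  idx <- rep(seq_len(n), each = 2L)
  allele <- rep(1:2, times = n)
  out <- data.frame(
    Name = paste0(quant$feature[idx], allele_suffixes[allele]),
    Length = quant$length[idx],
    EffectiveLength = quant$length[idx],
    TPM = ifelse(allele == 1L, quant$tpm_a1[idx], quant$tpm_a2[idx]),
    NumReads = ifelse(allele == 1L, quant$count_a1[idx], quant$count_a2[idx]),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bootstrap replicate count tables for one sample
#'
#' Each replicate is a two-column TSV (`Name`, `NumReads`) whose rows must
#' follow the exact `Name` order of the sample's quantification table. The
#' replicates are paired by allele and stacked into an array.
#'
#' @param paths character vector of replicate file paths (length B >= 1).
#' @param quant the paired table from [read_allelic_quant()] for the same
#'   sample (supplies the expected feature ordering and suffixes).
#' @return numeric array `[features x 2 x B]` aligned to `quant$feature`.
#' @export
read_bootstrap_tables <- function(paths, quant) {
  B <- length(paths)
  if (B < 1L) .stopf("at least one bootstrap replicate file required (B >= 1)")
  raw_names <- attr(quant, "raw_names")
  suff <- attr(quant, "allele_suffixes")
  if (is.null(raw_names) || is.null(suff))
    .stopf("'quant' must come from read_allelic_quant()")
  n_feat <- nrow(quant)
  out <- array(NA_real_, dim = c(n_feat, 2L, B))
  a1_names <- paste0(quant$feature, suff[1])
  a2_names <- paste0(quant$feature, suff[2])
  for (b in seq_len(B)) {
    tab <- utils::read.delim(paths[b], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!identical(names(tab), c("Name", "NumReads")))
      .stopf("malformed bootstrap table header in '%s'", paths[b])
    if (nrow(tab) != length(raw_names) || !identical(tab$Name, raw_names))
      .stopf("bootstrap replicate '%s' does not match the quant table (%d rows vs %d expected, or feature order differs)",
             paths[b], nrow(tab), length(raw_names))
    if (anyNA(tab$NumReads)) .stopf("NA counts in bootstrap replicate '%s'", paths[b])
    counts <- tab$NumReads
    names(counts) <- tab$Name
    out[, 1L, b] <- counts[a1_names]
    out[, 2L, b] <- counts[a2_names]
  }
  dimnames(out) <- list(quant$feature, NULL, NULL)
  out
}

#' Write bootstrap replicate tables for one sample
#'
#' @param boots array `[features x 2 x B]` as read by
#'   [read_bootstrap_tables()]
#' @param feature_ids base feature ids (length = first dimension)
#' @param dir output directory; files are named `bootstrap_<b>.tsv`
#' @param allele_suffixes allele suffixes appended to the ids
#' @return the paths written, invisibly
#' @export
write_bootstrap_tables <- function(boots, feature_ids, dir,
                                   allele_suffixes = c("_M", "_P")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  B <- dim(boots)[3]
  n <- length(feature_ids)
  idx <- rep(seq_len(n), each = 2L)
  allele <- rep(1:2, times = n)
  nm <- paste0(feature_ids[idx], allele_suffixes[allele])
  paths <- file.path(dir, sprintf("bootstrap_%d.tsv", seq_len(B)))
  for (b in seq_len(B)) {
    vals <- as.vector(rbind(boots[, 1L, b], boots[, 2L, b]))
    utils::write.table(data.frame(Name = nm, NumReads = vals),
                       paths[b], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, optional `covariate` (numeric, e.g. day)
#' and optional `group` (two-level factor). The row order of this table
#' defines the sample order of the assembled dataset.
#'
#' @param path path to the TSV
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    .stopf("sample metadata must have a 'sample_id' column")
  md$sample_id <- as.character(md$sample_id)
  if ("covariate" %in% names(md) && !is.numeric(md$covariate))
    .stopf("'covariate' column must be numeric")
  md
}

#' Assemble per-sample tables and bootstraps into an allelic matrix
#'
#' @param quants named list of paired quant tables (one per sample, from
#'   [read_allelic_quant()]); names are sample ids.
#' @param bootstraps named list of `[features x 2 x B]` arrays (from
#'   [read_bootstrap_tables()]), same names as `quants`.
#' @param metadata sample metadata `data.frame` with `sample_id`; its row
#'   order defines the column order of the result.
#' @param allele_labels labels for the two alleles of the output.
#' @return an [allelic_matrix()] at `txp` level.
#' @export
assemble_allelic <- function(quants, bootstraps, metadata,
                             allele_labels = c("a1", "a2")) {
  sample_ids <- as.character(metadata$sample_id)
  if (is.null(names(quants)) || !setequal(names(quants), sample_ids))
    .stopf("names of 'quants' must match metadata sample_id")
  if (is.null(names(bootstraps)) || !setequal(names(bootstraps), sample_ids))
    .stopf("names of 'bootstraps' must match metadata sample_id")
  quants <- quants[sample_ids]
  bootstraps <- bootstraps[sample_ids]

  feats <- quants[[1]]$feature
  for (s in sample_ids) {
    fs <- quants[[s]]$feature
    if (!identical(fs, feats)) {
      d <- union(setdiff(fs, feats), setdiff(feats, fs))
      if (length(d) > 0L)
        .stopf("feature sets differ across samples; offending ids: %s",
               paste(utils::head(sort(d), 10), collapse = ", "))
      .stopf("feature ordering differs across samples; reorder the tables")
    }
  }
  n_feat <- length(feats)
  n_s <- length(sample_ids)
  B <- dim(bootstraps[[1]])[3]

  counts <- array(0, dim = c(n_feat, n_s, 2L))
  tpm <- array(0, dim = c(n_feat, n_s, 2L))
  boot <- array(0, dim = c(n_feat, n_s, 2L, B))
  for (j in seq_len(n_s)) {
    q <- quants[[j]]
    counts[, j, 1L] <- q$count_a1
    counts[, j, 2L] <- q$count_a2
    tpm[, j, 1L] <- q$tpm_a1
    tpm[, j, 2L] <- q$tpm_a2
    bj <- bootstraps[[j]]
    if (!identical(dim(bj), c(n_feat, 2L, B)))
      .stopf("bootstrap array for sample '%s' has wrong dimensions", sample_ids[j])
    boot[, j, , ] <- aperm(bj, c(1, 2, 3))
  }
  allelic_matrix(counts, boot, tpm = tpm,
                 feature_ids = feats, sample_ids = sample_ids,
                 allele_labels = allele_labels, level = "txp",
                 metadata = metadata)
}
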