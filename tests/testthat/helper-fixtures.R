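# Small programmatic fixtures shared across test files.

# Build an allelic_matrix directly from a1/a2 count matrices; bootstraps
# default to B identical copies of the point estimates.
toy_matrix <- function(a1, a2, B = 2L, boots = NULL, metadata = NULL,
                       level = "txp", feature_ids = NULL, tpm = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1); S <- ncol(a1)
  counts <- array(c(a1, a2), dim = c(n, S, 2L))
  if (is.null(boots)) {
    boots <- array(0, dim = c(n, S, 2L, B))
    for (b in seq_len(B)) boots[, , , b] <- counts
  }
  if (is.null(feature_ids)) feature_ids <- paste0("tx", seq_len(n))
  allelic_matrix(counts, boots, tpm = tpm, feature_ids = feature_ids,
                 sample_ids = if (is.null(metadata)) paste0("s", seq_len(S))
                              else metadata$sample_id,
                 level = level, metadata = metadata)
}

# Null allelic matrix: both alleles iid NB(mu, size), bootstraps redrawn
# around each sample's counts via emulate_bootstraps with no ambiguity but
# total resampling (so replicates vary).
null_matrix <- function(n_feat, S = 10L, B = 5L, mu = 100, size = 100,
                        rho = 0.2) {
  counts <- array(rnbinom(n_feat * S * 2L, mu = mu, size = size),
                  dim = c(n_feat, S, 2L))
  boots <- emulate_bootstraps(counts, rho = rho, B = B)
  allelic_matrix(counts, boots)
}

# Minimal GTF text for grouping tests
write_test_gtf <- function(path, rows) {
  # rows: data.frame tx, gene, chrom, strand, exon_start, exon_end (list cols)
  lines <- character(0)
  for (i in seq_len(nrow(rows))) {
    st <- rows$exon_start[[i]]; en <- rows$exon_end[[i]]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        rows$gene[i], rows$tx[i])
    lines <- c(lines, paste(rows$chrom[i], "test", "exon", st, en, ".",
                            rows$strand[i], ".", attr_str, sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# quant table data.frame in the paired in-memory layout
toy_quant <- function(n = 5L, seed = 1L) {
  set.seed(seed)
  data.frame(feature = paste0("tx", seq_len(n)),
             length = sample(500:2000, n, replace = TRUE),
             tpm_a1 = round(runif(n, 0, 50), 4),
             tpm_a2 = round(runif(n, 0, 50), 4),
             count_a1 = round(runif(n, 0, 500), 3),
             count_a2 = round(runif(n, 0, 500), 3),
             stringsAsFactors = FALSE)
}
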