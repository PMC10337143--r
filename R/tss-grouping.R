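#' Parse transcript annotation from a GTF file
#'
#' Reads an Ensembl-dialect GTF and derives one record per transcript with
#' its strand-aware transcription start site (TSS): the minimum exon start
#' on the `+` strand, the maximum exon end on the `-` strand. Exon features
#' are used when present, otherwise transcript features.
#'
#' @param path path to the GTF file.
#' @return a `data.frame` with columns `tx_id`, `gene_id`, `chrom`,
#'   `strand`, `tss` (1-based). Transcripts without a defined strand are
#'   skipped with a warning giving their count.
#' @export
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  use <- if (any(type == "exon")) type == "exon" else type == "transcript"
  if (!any(use)) .stopf("no exon or transcript features found in '%s'", path)
  gr <- gr[use]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id))
    .stopf("GTF features must carry gene_id and transcript_id attributes")

  df <- data.frame(tx_id = as.character(mc$transcript_id),
                   gene_id = as.character(mc$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  undef <- !df$strand %in% c("+", "-")
  if (any(undef)) {
    n_skip <- length(unique(df$tx_id[undef]))
    .warnf("skipped %d transcript(s) without a defined strand", n_skip)
    df <- df[!undef, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    return(data.frame(tx_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      tss = integer(), stringsAsFactors = FALSE))
  first <- !duplicated(df$tx_id)
  min_start <- tapply(df$start, df$tx_id, min)
  max_end <- tapply(df$end, df$tx_id, max)
  out <- df[first, c("tx_id", "gene_id", "chrom", "strand")]
  out$tss <- ifelse(out$strand == "+",
                    as.integer(min_start[out$tx_id]),
                    as.integer(max_end[out$tx_id]))
  rownames(out) <- NULL
  out
}

.new_group_map <- function(map, info, level, window = NULL) {
  structure(map,
            group_info = info, level = level, window = window,
            class = c("group_map", "data.frame"))
}

#' Group transcripts by transcription start site
#'
#' Builds a transcript-to-group map in which isoforms of a gene sharing a
#' TSS (exactly, or within a basepair tolerance window) form one group.
#' Fuzzy grouping is single-linkage: within each gene and strand, distinct
#' TSS positions are sorted and chained into one group while consecutive
#' positions differ by at most `window` bp. Groups never span genes or
#' strands. Group ids have the form `<gene_id>-<k>` with `k` assigned by
#' ascending genomic coordinate of each group's minimum TSS.
#'
#' @param annotation transcript annotation from [parse_gtf()] (columns
#'   `tx_id`, `gene_id`, `chrom`, `strand`, `tss`).
#' @param window non-negative tolerance in bp; `0` means exact-position
#'   grouping; the default 50 merges nearby start sites ("fuzzy" groups).
#' @return a `group_map`: a `data.frame` with columns `tx_id`, `group_id`
#'   and attribute `group_info` describing each group (gene, TSS range,
#'   member count).
#' @export
make_tx2tss <- function(annotation, window = 50L) {
  if (window < 0) .stopf("'window' must be >= 0")
  if (nrow(annotation) == 0L)
    return(.new_group_map(
      data.frame(tx_id = character(), group_id = character(),
                 stringsAsFactors = FALSE),
      data.frame(group_id = character(), gene_id = character(),
                 chrom = character(), strand = character(),
                 tss_min = integer(), tss_max = integer(), n_tx = integer(),
                 stringsAsFactors = FALSE),
      level = "tss", window = window))

  ann <- annotation[order(annotation$gene_id, annotation$strand,
                          annotation$tss), , drop = FALSE]
  key <- paste(ann$gene_id, ann$strand, sep = "\r")
  pieces <- split(seq_len(nrow(ann)), key)

  cluster_of <- integer(nrow(ann))   # cluster index within gene+strand
  for (idx in pieces) {
    tss <- ann$tss[idx]              # already sorted
    new_cluster <- c(TRUE, diff(tss) > window)
    cluster_of[idx] <- cumsum(new_cluster)
  }
  cl_key <- paste(key, cluster_of, sep = "\r")

  # summarise clusters, then order within gene by minimum TSS to assign k
  cl_first <- !duplicated(cl_key)
  cl_min <- tapply(ann$tss, cl_key, min)
  cl_max <- tapply(ann$tss, cl_key, max)
  cl_n <- tapply(ann$tss, cl_key, length)
  info <- data.frame(cl_key = cl_key[cl_first],
                     gene_id = ann$gene_id[cl_first],
                     chrom = ann$chrom[cl_first],
                     strand = ann$strand[cl_first],
                     stringsAsFactors = FALSE)
  info$tss_min <- as.integer(cl_min[info$cl_key])
  info$tss_max <- as.integer(cl_max[info$cl_key])
  info$n_tx <- as.integer(cl_n[info$cl_key])
  info <- info[order(info$gene_id, info$tss_min, info$strand), , drop = FALSE]
  k <- stats::ave(seq_len(nrow(info)), info$gene_id, FUN = seq_along)
  info$group_id <- paste0(info$gene_id, "-", k)

  map <- data.frame(tx_id = ann$tx_id,
                    group_id = info$group_id[match(cl_key, info$cl_key)],
                    stringsAsFactors = FALSE)
  map <- map[match(annotation$tx_id, map$tx_id), , drop = FALSE]
  rownames(map) <- NULL
  info <- info[, c("group_id", "gene_id", "chrom", "strand",
                   "tss_min", "tss_max", "n_tx")]
  rownames(info) <- NULL
  .new_group_map(map, info, level = "tss", window = window)
}

#' Group transcripts by gene
#'
#' One group per gene, containing all of its annotated isoforms.
#'
#' @param annotation transcript annotation from [parse_gtf()].
#' @return a `group_map` at gene level; group ids equal gene ids.
#' @export
make_tx2gene <- function(annotation) {
  map <- data.frame(tx_id = annotation$tx_id,
                    group_id = annotation$gene_id,
                    stringsAsFactors = FALSE)
  first <- !duplicated(annotation$gene_id)
  info <- data.frame(group_id = annotation$gene_id[first],
                     gene_id = annotation$gene_id[first],
                     chrom = annotation$chrom[first],
                     strand = annotation$strand[first],
                     stringsAsFactors = FALSE)
  info$tss_min <- as.integer(tapply(annotation$tss, annotation$gene_id, min)[info$gene_id])
  info$tss_max <- as.integer(tapply(annotation$tss, annotation$gene_id, max)[info$gene_id])
  info$n_tx <- as.integer(table(annotation$gene_id)[info$gene_id])
  rownames(info) <- NULL
  .new_group_map(map, info, level = "gene", window = NULL)
}

#' @export
print.group_map <- function(x, ...) {
  info <- attr(x, "group_info")
  cat(sprintf("group_map (%s level): %d transcripts in %d groups",
              attr(x, "level"), nrow(x), nrow(info)))
  if (!is.null(attr(x, "window")))
    cat(sprintf(" (window %d bp)", attr(x, "window")))
  cat("\n")
  invisible(x)
}

#' Serialize a group map as a two-column TSV (tx_id, group_id)
#' @param gmap a `group_map`
#' @param path output path
#' @export
write_group_map <- function(gmap, path) {
  utils::write.table(as.data.frame(gmap)[, c("tx_id", "group_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a serialized group map
#' @param path path to a two-column TSV written by [write_group_map()]
#' @param level the aggregation level the map encodes (`"tss"` or `"gene"`)
#' @export
read_group_map <- function(path, level = c("tss", "gene")) {
  level <- match.arg(level)
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!identical(names(map), c("tx_id", "group_id")))
    .stopf("group map file must have columns tx_id, group_id")
  first <- !duplicated(map$group_id)
  info <- data.frame(group_id = map$group_id[first],
                     gene_id = sub("-[0-9]+$", "", map$group_id[first]),
                     chrom = NA_character_, strand = NA_character_,
                     tss_min = NA_integer_, tss_max = NA_integer_,
                     n_tx = as.integer(table(map$group_id)[map$group_id[first]]),
                     stringsAsFactors = FALSE)
  rownames(info) <- NULL
  .new_group_map(map, info, level = level)
}
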