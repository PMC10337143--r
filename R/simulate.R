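#' Simulation design for two-allele count datasets
#'
#' Parameters of the count-level F1-cross simulation: a diploid
#' transcriptome with genes carrying 1-6 isoforms, a subset of genes with
#' allelic imbalance (half concordant across isoforms, half discordant with
#' gene-level compensation), negative binomial across-sample noise,
#' library-size scaling, allelic read ambiguity, and emulated bootstrap
#' inferential replicates.
#'
#' Two profiles are provided. `"paper"` matches the benchmark design the
#' simulator emulates: 14,821 genes of which 1000 have AI (500 concordant /
#' 500 discordant). `"desk"` is a scaled-down profile for routine testing:
#' 2000 genes, 500 AI (250/250), 2M read pairs. All fields can be
#' overridden individually.
#'
#' @param profile `"desk"` (default) or `"paper"`.
#' @param n_genes number of genes.
#' @param n_ai_genes number of AI genes (split evenly concordant /
#'   discordant); AI-eligible genes have 3-6 isoforms, at least two
#'   isoforms sharing a TSS, and at least two distinct TSS.
#' @param n_samples number of samples (default 10).
#' @param lib_size mean library size (reads per sample); per-sample depths
#'   are jittered uniformly within +/-20% of this mean.
#' @param nb_size negative binomial dispersion parameter (`size`), default
#'   100: variance `mu + mu^2/100`.
#' @param conc_effect concordant AI effect: paternal abundance multiplied
#'   by `1 + conc_effect` (up) or `1 - conc_effect` (down), default 0.25.
#' @param ambiguity fraction `rho` in `[0, 1)` of a feature's reads that is
#'   allelically ambiguous (default 0.2).
#' @param n_boot number of emulated bootstrap replicates (default 30).
#' @param tx_length_range range of simulated transcript lengths (bp).
#' @param abundance_range range of the log-uniform maternal abundance.
#' @return an object of class `"sim_design"` (a validated list).
#' @export
sim_design <- function(profile = c("desk", "paper"),
                       n_genes = NULL, n_ai_genes = NULL,
                       n_samples = 10L, lib_size = NULL,
                       nb_size = 100, conc_effect = 0.25,
                       ambiguity = 0.2, n_boot = 30L,
                       tx_length_range = c(500L, 3000L),
                       abundance_range = c(1, 100)) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    desk = list(n_genes = 2000L, n_ai_genes = 500L, lib_size = 2e6),
    paper = list(n_genes = 14821L, n_ai_genes = 1000L, lib_size = 5e7))
  if (is.null(n_genes)) n_genes <- defaults$n_genes
  if (is.null(n_ai_genes)) n_ai_genes <- defaults$n_ai_genes
  if (is.null(lib_size)) lib_size <- defaults$lib_size

  d <- structure(list(profile = profile,
                      n_genes = as.integer(n_genes),
                      n_ai_genes = as.integer(n_ai_genes),
                      n_samples = as.integer(n_samples),
                      lib_size = lib_size, nb_size = nb_size,
                      conc_effect = conc_effect, ambiguity = ambiguity,
                      n_boot = as.integer(n_boot),
                      tx_length_range = as.integer(tx_length_range),
                      abundance_range = abundance_range),
                 class = "sim_design")
  if (d$n_ai_genes > d$n_genes) .stopf("n_ai_genes must be <= n_genes")
  if (d$n_samples < 2L) .stopf("need at least 2 samples")
  if (d$ambiguity < 0 || d$ambiguity >= 1) .stopf("'ambiguity' must be in [0, 1)")
  if (d$n_boot < 1L) .stopf("'n_boot' must be >= 1")
  if (d$conc_effect <= 0 || d$conc_effect >= 1)
    .stopf("'conc_effect' must be in (0, 1)")
  if (d$nb_size <= 0) .stopf("'nb_size' must be > 0")
  d
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design ('%s'): %d genes (%d AI: %d concordant / %d discordant)\n",
              x$profile, x$n_genes, x$n_ai_genes,
              ceiling(x$n_ai_genes / 2), floor(x$n_ai_genes / 2)))
  cat(sprintf("  %d samples, mean library %.3g, NB size %g, ambiguity %.2f, %d bootstraps\n",
              x$n_samples, x$lib_size, x$nb_size, x$ambiguity, x$n_boot))
  invisible(x)
}

#' Build synthetic gene models
#'
#' Draws the gene/isoform/TSS structure of the simulated diploid
#' transcriptome. Background genes have 1-6 isoforms (uniform); AI-eligible
#' genes have 3-6 isoforms (uniform) and a TSS assignment guaranteeing at
#' least two distinct TSS and at least two isoforms sharing one TSS (the
#' number of distinct TSS is drawn uniformly between 2 and one less than
#' the isoform count, and isoforms are assigned to start sites by a random
#' surjection, so some site always hosts two or more isoforms). Distinct
#' TSS within a gene are spaced at least 200 bp apart, well beyond the
#' default 50 bp fuzzy-grouping window. Transcripts are single-exon with
#' lengths drawn uniformly from the design's length range; genes are laid
#' out on four synthetic chromosomes with random strands.
#'
#' @param design a [sim_design()]
#' @param seed optional integer seed (RNG state restored afterwards);
#'   `NULL` continues the caller's RNG stream.
#' @return list of class `"gene_models"`: `annotation` (`data.frame` with
#'   `tx_id`, `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`,
#'   `length`) and `genes` (`gene_id`, `status` in
#'   balanced/concordant/discordant, `n_tx`, `n_tss`).
#' @export
build_gene_models <- function(design, seed = NULL) {
  .with_seed(seed, {
    ng <- design$n_genes
    nai <- design$n_ai_genes
    n_conc <- ceiling(nai / 2)
    status <- rep("balanced", ng)
    ai_idx <- sample.int(ng, nai)
    status[ai_idx[seq_len(n_conc)]] <- "concordant"
    if (nai > n_conc) status[ai_idx[(n_conc + 1):nai]] <- "discordant"

    n_tx <- ifelse(status == "balanced",
                   sample(1:6, ng, replace = TRUE),
                   sample(3:6, ng, replace = TRUE))
    # distinct TSS per gene; AI genes: 2..(k-1) so that a surjection forces
    # one shared site (pigeonhole); background: 1..k
    n_tss <- integer(ng)
    for (g in seq_len(ng)) {
      k <- n_tx[g]
      n_tss[g] <- if (status[g] == "balanced") {
        if (k == 1L) 1L else sample.int(k, 1L)
      } else {
        1L + sample.int(k - 2L, 1L)   # uniform on 2..(k-1); k >= 3 here
      }
    }

    chroms <- paste0("sim", (seq_len(ng) - 1L) %% 4L + 1L)
    cursor <- stats::setNames(rep(1L, 4), paste0("sim", 1:4))
    len_r <- design$tx_length_range

    rows <- vector("list", ng)
    for (g in seq_len(ng)) {
      k <- n_tx[g]; t <- n_tss[g]
      slot <- c(seq_len(t), if (k > t) sample.int(t, k - t, replace = TRUE))
      slot <- sample(slot)  # shuffle isoform -> TSS-slot assignment
      gaps <- if (t > 1L) sample(200:2000, t - 1L, replace = TRUE) else integer()
      tss_off <- cumsum(c(0L, gaps))
      lens <- sample(len_r[1]:len_r[2], k, replace = TRUE)
      strand <- sample(c("+", "-"), 1L)
      chrom <- chroms[g]
      base <- cursor[chrom] + max(lens) + 100L   # room for minus-strand exons
      tss <- base + tss_off[slot]
      if (strand == "+") {
        start <- tss; end <- tss + lens - 1L
      } else {
        end <- tss; start <- tss - lens + 1L
      }
      cursor[chrom] <- max(end) + 10000L
      gid <- sprintf("G%05d", g)
      rows[[g]] <- data.frame(
        tx_id = sprintf("%s.t%d", gid, seq_len(k)),
        gene_id = gid, chrom = chrom, strand = strand,
        tss = as.integer(tss), start = as.integer(start),
        end = as.integer(end), length = as.integer(lens),
        stringsAsFactors = FALSE)
    }
    annotation <- do.call(rbind, rows)
    rownames(annotation) <- NULL
    genes <- data.frame(gene_id = sprintf("G%05d", seq_len(ng)),
                        status = status, n_tx = n_tx, n_tss = n_tss,
                        stringsAsFactors = FALSE)
    structure(list(annotation = annotation, genes = genes),
              class = "gene_models")
  })
}

#' Assign allelic abundances and ground-truth AI status
#'
#' The maternal abundance of each transcript is a constant drawn
#' log-uniformly over the design's abundance range. Paternal abundances
#' encode the AI design: concordant genes have all isoforms multiplied by
#' `1 + e` or `1 - e` (e = `conc_effect`, chosen at random per gene);
#' discordant genes have one TSS chosen at random whose `n` isoforms are
#' upregulated by the fold `1 + 1/(2n)`, while the remaining isoforms are
#' scaled down by the unique common factor that keeps the gene's total
#' paternal abundance equal to its maternal total (gene-level balance). If
#' a TSS choice would require a negative down-scaling factor it is
#' resampled among the gene's other start sites.
#'
#' @param models output of [build_gene_models()]
#' @param design the [sim_design()]
#' @param seed optional integer seed; `NULL` continues the RNG stream.
#' @return a `data.frame` of class `"sim_truth"`, one row per transcript:
#'   `tx_id`, `gene_id`, `tss`, `length`, `status`, `direction`
#'   (`up`/`down`/`none`), `fold` (paternal/maternal), `abundance_m`,
#'   `abundance_p`.
#' @export
assign_abundances <- function(models, design, seed = NULL) {
  .with_seed(seed, {
    ann <- models$annotation
    genes <- models$genes
    n <- nrow(ann)
    ab_r <- design$abundance_range
    status <- genes$status[match(ann$gene_id, genes$gene_id)]

    abundance_m <- 10^stats::runif(n, log10(ab_r[1]), log10(ab_r[2]))
    fold <- rep(1, n)
    direction <- rep("none", n)

    for (g in which(genes$status != "balanced")) {
      gid <- genes$gene_id[g]
      rows <- which(ann$gene_id == gid)
      if (genes$status[g] == "concordant") {
        up <- stats::runif(1) < 0.5
        fold[rows] <- if (up) 1 + design$conc_effect else 1 - design$conc_effect
        direction[rows] <- if (up) "up" else "down"
      } else {
        repeat {
          ok <- FALSE
          for (sel_tss in sample(unique(ann$tss[rows]))) {
            sel <- rows[ann$tss[rows] == sel_tss]
            oth <- setdiff(rows, sel)
            n_sel <- length(sel)
            up_fold <- 1 + 1 / (2 * n_sel)
            extra <- sum(abundance_m[sel]) * (up_fold - 1)
            down_fold <- 1 - extra / sum(abundance_m[oth])
            if (down_fold > 0) {
              fold[sel] <- up_fold
              fold[oth] <- down_fold
              direction[sel] <- "up"
              direction[oth] <- "down"
              ok <- TRUE
              break
            }
          }
          if (ok) break
          # no feasible TSS: redraw this gene's maternal abundances
          abundance_m[rows] <- 10^stats::runif(length(rows),
                                               log10(ab_r[1]), log10(ab_r[2]))
        }
      }
    }

    out <- data.frame(tx_id = ann$tx_id, gene_id = ann$gene_id,
                      tss = ann$tss, length = ann$length,
                      status = status, direction = direction, fold = fold,
                      abundance_m = abundance_m,
                      abundance_p = abundance_m * fold,
                      stringsAsFactors = FALSE)
    class(out) <- c("sim_truth", "data.frame")
    out
  })
}

#' Expected allelic counts from abundances
#'
#' Expected counts are proportional to abundance times transcript length,
#' normalised so that the expected counts of one sample sum to its library
#' size (across all transcript-alleles).
#'
#' @param truth a `"sim_truth"` table from [assign_abundances()]
#' @param design the [sim_design()]
#' @param lib_sizes optional per-sample library sizes; default: the
#'   design's mean library size for every sample.
#' @return numeric array `[transcripts x samples x 2]` of expected counts
#'   (allele 1 = maternal).
#' @export
expected_counts <- function(truth, design, lib_sizes = NULL) {
  if (is.null(lib_sizes))
    lib_sizes <- rep(design$lib_size, design$n_samples)
  w_m <- truth$abundance_m * truth$length
  w_p <- truth$abundance_p * truth$length
  denom <- sum(w_m) + sum(w_p)
  if (denom <= 0) .stopf("total abundance is zero")
  n <- nrow(truth)
  S <- length(lib_sizes)
  mu <- array(0, dim = c(n, S, 2L))
  for (s in seq_len(S)) {
    mu[, s, 1L] <- w_m / denom * lib_sizes[s]
    mu[, s, 2L] <- w_p / denom * lib_sizes[s]
  }
  dimnames(mu) <- list(truth$tx_id, NULL, c("a1", "a2"))
  mu
}

#' Draw observed counts with negative binomial noise
#'
#' Counts are drawn independently per transcript-allele-sample from a
#' negative binomial with mean `mu` and dispersion parameter `size`
#' (variance `mu + mu^2/size`), adding across-sample biological variation
#' to the allelic counts. `mu = 0` always yields 0.
#'
#' @param mu array of expected counts (any shape)
#' @param nb_size NB size parameter (default 100)
#' @param seed optional integer seed; `NULL` continues the RNG stream.
#' @return integer-valued array of the same shape as `mu`
#' @export
sample_counts <- function(mu, nb_size = 100, seed = NULL) {
  .with_seed(seed, {
    x <- stats::rnbinom(length(mu), mu = as.numeric(mu), size = nb_size)
    x <- array(as.numeric(x), dim = dim(mu), dimnames = dimnames(mu))
    x
  })
}

# Emulate the quantifier's point estimates from true allele-of-origin
# counts: within each sample, transcript-pair totals are redistributed by
# one multinomial draw of the sample's reads (assignment noise on totals),
# and the allelically ambiguous fraction rho of each feature's reads is
# split exactly equally between the alleles (what an EM quantifier does
# when reads carry no allelic information).
.quantifier_estimates <- function(true_counts, rho, seed = NULL) {
  .with_seed(seed, {
    n <- dim(true_counts)[1]
    S <- dim(true_counts)[2]
    rho <- rep_len(rho, n)
    est <- array(0, dim = dim(true_counts), dimnames = dimnames(true_counts))
    for (s in seq_len(S)) {
      a1 <- true_counts[, s, 1L]
      a2 <- true_counts[, s, 2L]
      tot <- a1 + a2
      N <- sum(tot)
      if (N == 0) next
      tot_est <- as.numeric(stats::rmultinom(1L, size = N, prob = tot / N))
      p1 <- ifelse(tot > 0, a1 / tot, 0.5)
      est[, s, 1L] <- (1 - rho) * p1 * tot_est + rho * tot_est / 2
      est[, s, 2L] <- tot_est - est[, s, 1L]
    }
    est
  })
}

#' Emulate bootstrap inferential replicates
#'
#' Stands in for the read-resampling bootstrap of an alignment-free
#' quantifier. The input counts are interpreted as quantifier point
#' estimates in which a fraction `rho` of each feature's reads is
#' allelically ambiguous and has been split equally between the alleles;
#' the unambiguous allele shares are recovered by inverting that split.
#' Each replicate then (i) redraws the transcript-pair totals by one
#' multinomial resample of the sample's reads (unless
#' `resample_totals = FALSE`), and (ii) redraws the ambiguous portion of
#' each feature to the two alleles as Binomial(m, 1/2), keeping the
#' unambiguous portion with its allele. Replicate totals per sample equal
#' the observed total. With `rho = 0` and `resample_totals = FALSE` every
#' replicate equals the input exactly.
#'
#' @param counts array `[features x samples x 2]` of point-estimate counts
#' @param rho ambiguity fraction in `[0, 1]`, scalar or per-feature vector
#' @param B number of replicates (>= 1)
#' @param seed optional integer seed; `NULL` continues the RNG stream.
#' @param resample_totals whether replicates also resample transcript
#'   totals (multinomial over the sample's reads); default `TRUE`.
#' @return array `[features x samples x 2 x B]`
#' @export
emulate_bootstraps <- function(counts, rho = 0.2, B = 30L, seed = NULL,
                               resample_totals = TRUE) {
  if (B < 1L) .stopf("'B' must be >= 1")
  if (any(rho < 0) || any(rho > 1)) .stopf("'rho' must be in [0, 1]")
  .with_seed(seed, {
    n <- dim(counts)[1]
    S <- dim(counts)[2]
    rho <- rep_len(rho, n)
    boot <- array(0, dim = c(n, S, 2L, B))
    for (s in seq_len(S)) {
      a1 <- counts[, s, 1L]
      a2 <- counts[, s, 2L]
      tot <- a1 + a2
      N <- sum(tot)
      # unambiguous allele-1 share, inverting the quantifier's equal split
      p1u <- ifelse(tot > 0 & rho < 1,
                    (a1 - rho * tot / 2) / ((1 - rho) * tot),
                    0.5)
      p1u <- pmin(pmax(p1u, 0), 1)
      for (b in seq_len(B)) {
        tot_b <- if (resample_totals && N > 0)
          as.numeric(stats::rmultinom(1L, size = round(N), prob = tot / N))
        else tot
        m <- round(rho * tot_b)
        x <- stats::rbinom(n, size = m, prob = 0.5)
        boot[, s, 1L, b] <- (tot_b - m) * p1u + x
        boot[, s, 2L, b] <- tot_b - boot[, s, 1L, b]
      }
    }
    dn <- dimnames(counts)
    dimnames(boot) <- list(dn[[1]], dn[[2]], c("a1", "a2"), NULL)
    boot
  })
}

#' Simulate a complete two-allele dataset
#'
#' Runs the full generator: gene models, allelic abundances with
#' concordant/discordant AI, expected counts scaled to per-sample library
#' sizes (jittered uniformly within +/-20% of the design mean), negative
#' binomial observed counts, quantifier-style point estimates with allelic
#' ambiguity, and emulated bootstrap replicates. All randomness flows from
#' the single `seed`.
#'
#' @param design a [sim_design()]
#' @param seed integer seed; identical seeds give identical datasets.
#' @param rho optional per-transcript ambiguity overriding the design's
#'   scalar `ambiguity` (e.g. to make some features fully ambiguous).
#' @return list of class `"allelic_sim"`: `design`, `models`, `truth`,
#'   `lib_sizes`, `mu` (expected counts), `true_counts` (NB draws, the
#'   allele-of-origin truth), `rho`, and `matrix` (an [allelic_matrix()]
#'   with point estimates, TPM and bootstraps, plus sample metadata with a
#'   unit-spaced `covariate`).
#' @export
simulate_allelic <- function(design = sim_design(), seed = NULL, rho = NULL) {
  .with_seed(seed, {
    models <- build_gene_models(design)
    truth <- assign_abundances(models, design)
    S <- design$n_samples
    lib_sizes <- design$lib_size * stats::runif(S, 0.8, 1.2)
    mu <- expected_counts(truth, design, lib_sizes)
    true_counts <- sample_counts(mu, design$nb_size)
    if (is.null(rho)) rho <- rep(design$ambiguity, nrow(truth))
    est <- .quantifier_estimates(true_counts, rho)
    boot <- emulate_bootstraps(est, rho = rho, B = design$n_boot)

    # TPM from the point estimates: rate = count / length, normalised per
    # sample over the full diploid transcriptome
    tpm <- est
    for (s in seq_len(S)) {
      rate <- est[, s, ] / truth$length
      tpm[, s, ] <- rate / sum(rate) * 1e6
    }

    metadata <- data.frame(sample_id = paste0("s", seq_len(S)),
                           covariate = seq_len(S),
                           stringsAsFactors = FALSE)
    m <- allelic_matrix(est, boot, tpm = tpm,
                        feature_ids = truth$tx_id,
                        sample_ids = metadata$sample_id,
                        allele_labels = c("M", "P"),
                        level = "txp", metadata = metadata)
    structure(list(design = design, models = models, truth = truth,
                   lib_sizes = lib_sizes, mu = mu,
                   true_counts = true_counts, rho = rho, matrix = m),
              class = "allelic_sim")
  })
}

#' @export
print.allelic_sim <- function(x, ...) {
  cat(sprintf("allelic_sim: %d transcripts in %d genes, %d samples\n",
              nrow(x$truth), x$design$n_genes, x$design$n_samples))
  print(table(truth_status = x$models$genes$status))
  print(x$matrix)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the import functions consume: one quant.sf
#' dialect TSV and a directory of bootstrap TSVs per sample, a synthetic
#' GTF of the gene models, the ground-truth table, and the sample metadata.
#'
#' @param sim an `"allelic_sim"` from [simulate_allelic()]
#' @param dir output directory (created if needed)
#' @param allele_suffixes allele name suffixes used in the quant tables
#' @return invisibly, a list of the paths written
#' @export
write_dataset <- function(sim, dir, allele_suffixes = c("_M", "_P")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- sim$matrix
  truth <- sim$truth
  S <- length(m$sample_ids)
  quant_paths <- character(S)
  boot_dirs <- character(S)
  for (s in seq_len(S)) {
    sd <- file.path(dir, m$sample_ids[s])
    if (!dir.exists(sd)) dir.create(sd)
    q <- data.frame(feature = m$feature_ids,
                    length = truth$length,
                    tpm_a1 = m$tpm[, s, 1L], tpm_a2 = m$tpm[, s, 2L],
                    count_a1 = m$counts[, s, 1L],
                    count_a2 = m$counts[, s, 2L],
                    stringsAsFactors = FALSE)
    quant_paths[s] <- file.path(sd, "quant.sf")
    write_quant_table(q, quant_paths[s], allele_suffixes)
    boot_dirs[s] <- file.path(sd, "bootstraps")
    write_bootstrap_tables(m$bootstraps[, s, , , drop = TRUE],
                           m$feature_ids, boot_dirs[s], allele_suffixes)
  }
  gtf_path <- file.path(dir, "models.gtf")
  .write_gtf(sim$models$annotation, gtf_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md_path <- file.path(dir, "samples.tsv")
  utils::write.table(m$metadata, md_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(quant = quant_paths, bootstraps = boot_dirs,
                 gtf = gtf_path, truth = truth_path, metadata = md_path))
}

# minimal Ensembl-dialect GTF writer for the synthetic annotation
.write_gtf <- function(annotation, path) {
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      annotation$gene_id, annotation$tx_id)
  fmt <- function(feature)
    paste(annotation$chrom, "sim", feature, annotation$start, annotation$end,
          ".", annotation$strand, ".", attr_str, sep = "\t")
  lines <- as.vector(rbind(fmt("transcript"), fmt("exon")))
  writeLines(lines, path)
  invisible(path)
}

#' Import a simulated dataset written by [write_dataset()]
#'
#' Convenience round-trip reader: reads the sample metadata, per-sample
#' quant tables and bootstrap replicates, and assembles an
#' [allelic_matrix()].
#'
#' @param dir the dataset directory
#' @param allele_suffixes allele suffixes used when writing
#' @return an `allelic_matrix` at transcript level
#' @export
read_dataset <- function(dir, allele_suffixes = c("_M", "_P")) {
  metadata <- read_sample_metadata(file.path(dir, "samples.tsv"))
  quants <- list()
  boots <- list()
  for (s in metadata$sample_id) {
    q <- read_allelic_quant(file.path(dir, s, "quant.sf"), allele_suffixes)
    bdir <- file.path(dir, s, "bootstraps")
    paths <- file.path(bdir, sprintf("bootstrap_%d.tsv",
                                     seq_along(list.files(bdir))))
    quants[[s]] <- q
    boots[[s]] <- read_bootstrap_tables(paths, q)
  }
  assemble_allelic(quants, boots, metadata,
                   allele_labels = sub("^_", "", allele_suffixes))
}
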