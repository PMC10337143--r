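desk_toy <- function() sim_design(n_genes = 60, n_ai_genes = 20,
                                  lib_size = 1e5, n_boot = 3)

test_that("sim_design profiles carry the documented defaults", {
  d <- sim_design("paper")
  expect_equal(d$n_genes, 14821L)
  expect_equal(d$n_ai_genes, 1000L)
  expect_equal(d$nb_size, 100)
  expect_equal(d$n_boot, 30L)
  dd <- sim_design("desk")
  expect_equal(dd$n_genes, 2000L)
  expect_equal(dd$n_ai_genes, 500L)
  expect_error(sim_design(n_genes = 10, n_ai_genes = 20), "n_ai_genes")
  expect_error(sim_design(ambiguity = 1), "ambiguity")
})

test_that("AI-designated genes satisfy all eligibility criteria", {
  mods <- build_gene_models(desk_toy(), seed = 1)
  ann <- mods$annotation
  for (g in mods$genes$gene_id[mods$genes$status != "balanced"]) {
    rows <- ann[ann$gene_id == g, ]
    expect_true(nrow(rows) >= 3 && nrow(rows) <= 6)
    expect_gte(length(unique(rows$tss)), 2L)          # >= 2 distinct TSS
    expect_gte(max(table(rows$tss)), 2L)              # a shared TSS exists
  }
  # isoform-count histogram of AI genes supported on {3,4,5,6}
  big <- build_gene_models(sim_design(n_genes = 400, n_ai_genes = 200,
                                      lib_size = 1e5), seed = 2)
  n_tx_ai <- big$genes$n_tx[big$genes$status != "balanced"]
  expect_setequal(sort(unique(n_tx_ai)), 3:6)
})

test_that("gene models are deterministic given the seed", {
  m1 <- build_gene_models(desk_toy(), seed = 33)
  m2 <- build_gene_models(desk_toy(), seed = 33)
  expect_identical(m1, m2)
  s1 <- simulate_allelic(desk_toy(), seed = 33)
  s2 <- simulate_allelic(desk_toy(), seed = 33)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$matrix$bootstraps, s2$matrix$bootstraps)
})

test_that("truth composition matches the benchmark design at paper scale", {
  mods <- build_gene_models(sim_design("paper"), seed = 4)
  tab <- table(mods$genes$status)
  expect_equal(unname(tab["concordant"]), 500L)
  expect_equal(unname(tab["discordant"]), 500L)
  expect_equal(unname(tab["balanced"]), 13821L)
  expect_equal(unname(tab["balanced"]) / sum(tab), 13821 / 14821)
})

test_that("concordant folds are +/-25% and discordant folds follow 1 + 1/(2n)", {
  d <- desk_toy()
  mods <- build_gene_models(d, seed = 6)
  truth <- assign_abundances(mods, d, seed = 7)
  conc <- truth[truth$status == "concordant", ]
  expect_setequal(round(unique(conc$fold), 10), c(1.25, 0.75))
  # per gene a single direction
  expect_true(all(tapply(conc$fold, conc$gene_id,
                         function(x) length(unique(x))) == 1L))

  disc <- truth[truth$status == "discordant", ]
  for (g in unique(disc$gene_id)) {
    rows <- disc[disc$gene_id == g, ]
    up <- rows[rows$direction == "up", ]
    n_sel <- nrow(up)
    expect_gte(n_sel, 1L)
    expect_equal(unique(up$fold), 1 + 1 / (2 * n_sel))
    expect_equal(length(unique(up$tss)), 1L)     # one selected TSS
    # gene-level allelic balance, exact
    expect_equal(sum(rows$abundance_p), sum(rows$abundance_m),
                 tolerance = 1e-12)
  }
  expect_true(all(truth$fold[truth$status == "balanced"] == 1))
})

test_that("the conservation equation reproduces the worked 4-isoform case", {
  # gene with 4 equal-abundance isoforms, selected TSS shared by n = 2:
  # up factor 1 + 1/4 = 1.25, the others 0.75, totals conserved
  m_ab <- rep(2.5, 4)
  n_sel <- 2
  up <- 1 + 1 / (2 * n_sel)
  extra <- sum(m_ab[1:2]) * (up - 1)
  down <- 1 - extra / sum(m_ab[3:4])
  expect_equal(up, 1.25)
  expect_equal(down, 0.75)
  expect_equal(sum(m_ab[1:2] * up + m_ab[3:4] * down), sum(m_ab))
  # and a single-isoform selected TSS gives a 1.5 fold
  expect_equal(1 + 1 / (2 * 1), 1.5)
})

test_that("expected counts are proportional to abundance x length and sum to depth", {
  toy_truth <- data.frame(tx_id = c("t1", "t2"), gene_id = "G1",
                          tss = c(1, 2), length = c(100, 300),
                          status = "balanced", direction = "none", fold = 1,
                          abundance_m = c(10, 10), abundance_p = c(10, 10))
  d <- sim_design(n_genes = 2, n_ai_genes = 0, n_samples = 3, lib_size = 1e4)
  mu <- expected_counts(toy_truth, d)
  expect_equal(mu[2, 1, 1] / mu[1, 1, 1], 3)      # length 300 vs 100
  for (s in 1:3) expect_equal(sum(mu[, s, ]), 1e4)
  # doubling one transcript's abundance doubles its weight: within-sample
  # mu ratios equal abundance x length ratios
  t2 <- toy_truth; t2$abundance_m <- c(20, 10); t2$abundance_p <- c(20, 10)
  mu2 <- expected_counts(t2, d)
  expect_equal(unname(mu2[1, 1, 1] / mu2[2, 1, 1]), (20 * 100) / (10 * 300))
  expect_error(expected_counts(transform(toy_truth, abundance_m = 0,
                                         abundance_p = 0), d), "zero")
})

test_that("negative binomial sampling has the designed moments", {
  set.seed(20)
  x <- sample_counts(array(1000, dim = c(20000, 1, 1)), nb_size = 100)
  v <- var(as.numeric(x))
  expect_equal(mean(x), 1000, tolerance = 0.01)
  # variance mu + mu^2/size = 11,000; MC tolerance ~5%
  expect_equal(v, 11000, tolerance = 0.06)
  expect_true(all(sample_counts(array(0, dim = c(10, 1, 1))) == 0))
  # large size approaches Poisson
  y <- sample_counts(array(1000, dim = c(20000, 1, 1)), nb_size = 1e9)
  expect_equal(var(as.numeric(y)), 1000, tolerance = 0.05)
})

test_that("bootstrap emulation degenerates correctly", {
  counts <- array(c(30, 70, 10, 90), dim = c(2, 1, 2))
  b0 <- emulate_bootstraps(counts, rho = 0, B = 4, seed = 1,
                           resample_totals = FALSE)
  for (b in 1:4) expect_equal(unname(b0[, , , b]), unname(counts[, , ]))
  # rho = 1: replicates split around 50/50, means near half the total
  b1 <- emulate_bootstraps(counts, rho = 1, B = 400, seed = 2,
                           resample_totals = FALSE)
  prop <- rowMeans(b1[, 1, 1, ]) / (counts[, 1, 1] + counts[, 1, 2])
  expect_equal(unname(prop), c(0.5, 0.5), tolerance = 0.05)
})

test_that("replicate totals per sample always equal the observed total", {
  set.seed(30)
  counts <- array(rpois(40 * 3 * 2, 50), dim = c(40, 3, 2))
  boot <- emulate_bootstraps(counts, rho = 0.3, B = 5, seed = 3)
  for (s in 1:3) for (b in 1:5)
    expect_equal(sum(boot[, s, , b]), sum(counts[, s, ]))
})

test_that("replicate-mean allelic proportion matches (1-rho) p + rho/2", {
  # composed pipeline property: true origin proportion p is shrunk toward
  # 1/2 by the ambiguous fraction in the quantifier point estimates, and
  # bootstrap replicates are centred on those estimates
  d <- sim_design(n_genes = 150, n_ai_genes = 50, n_samples = 4,
                  lib_size = 4e5, n_boot = 40, ambiguity = 0.4)
  sim <- simulate_allelic(d, seed = 44)
  tot_true <- sim$true_counts[, , 1] + sim$true_counts[, , 2]
  big <- rowSums(tot_true) > 800          # stable proportions only
  p_true <- rowSums(sim$true_counts[, , 2]) / rowSums(tot_true)
  rep_mean <- apply(sim$matrix$bootstraps[, , 2, ], 1, sum) /
    apply(sim$matrix$bootstraps, 1, sum)
  expect_equal(rep_mean[big], (1 - 0.4) * p_true[big] + 0.4 / 2,
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("all randomness flows from the single simulation seed", {
  d <- desk_toy()
  s1 <- simulate_allelic(d, seed = 99)
  set.seed(123)  # perturb ambient RNG; must not matter
  s2 <- simulate_allelic(d, seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$matrix$bootstraps, s2$matrix$bootstraps)
  s3 <- simulate_allelic(d, seed = 100)
  expect_false(identical(s1$matrix$counts, s3$matrix$counts))
})

test_that("the simulated dataset drives the whole pipeline end to end", {
  d <- sim_design(n_genes = 80, n_ai_genes = 20, lib_size = 2e5, n_boot = 4)
  sim <- simulate_allelic(d, seed = 12)
  expect_equal(nrow(sim$truth), nrow(sim$models$annotation))
  ann <- sim$models$annotation
  m <- aggregate_allelic(sim$matrix, make_tx2tss(ann, 50))
  m <- filter_min_count(filter_uninformative(m))
  fit <- ai_test(m, "global", n_perm = 30, seed = 2)
  expect_s3_class(fit, "ai_test")
  expect_true(all(fit$pvalue > 0 & fit$pvalue <= 1))
  # the synthetic GTF round-trips through the annotation parser
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  ann2 <- parse_gtf(file.path(dir, "models.gtf"))
  ann2 <- ann2[match(ann$tx_id, ann2$tx_id), ]
  expect_equal(ann2$tss, ann$tss)
  expect_equal(ann2$gene_id, ann$gene_id)
  truth2 <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth2), nrow(sim$truth))
})
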