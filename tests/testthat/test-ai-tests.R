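# helper: matrix with a single bootstrap equal to the point estimates
point_matrix <- function(a1, a2, metadata = NULL) {
  toy_matrix(a1, a2, B = 1L, metadata = metadata)
}

test_that("signed-rank statistic matches hand ranking and handles zeros", {
  expect_equal(signed_rank_stat(c(3, 9, 1), c(3, 9, 1)), 0)
  expect_equal(signed_rank_stat(c(10, 12, 8, 20), c(15, 14, 9, 26)), 10)
  # zero differences excluded, midranks for ties
  expect_equal(signed_rank_stat(c(5, 5, 5), c(5, 7, 3)), 0)  # +1.5, -1.5
  expect_error(signed_rank_stat(1, 2), "at least 2")
  expect_error(signed_rank_stat(1:3, 1:4), "equal length")
})

test_that("signed-rank agrees with the classical Wilcoxon V for n <= 10", {
  # oracle: wilcox.test's V is the positive-rank sum; with no zeros/ties,
  # W = 2V - n(n+1)/2
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    x1 <- runif(n, 0, 100)
    x2 <- x1 + runif(n, -30, 30)     # continuous: no zeros or ties
    V <- suppressWarnings(wilcox.test(x2, x1, paired = TRUE))$statistic
    expect_equal(signed_rank_stat(x1, x2), unname(2 * V - n * (n + 1) / 2))
  }
})

test_that("signed-rank exact permutation p matches full enumeration", {
  # two-sided p over all 2^n sign flips for the worked 4-sample example
  x1 <- c(10, 12, 8, 20); x2 <- c(15, 14, 9, 26)
  W <- signed_rank_stat(x1, x2)
  d <- x2 - x1
  r <- rank(abs(d))
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  null <- flips %*% (sign(d) * r)
  expect_equal(W, 10)
  expect_equal(mean(abs(null) >= abs(W)), 0.125)
})

test_that("a uniformly doubled allele gives the maximal signed-rank statistic", {
  S <- 10
  a1 <- matrix(rep(seq(10, 100, 10), 50), nrow = 50, byrow = TRUE)
  m <- toy_matrix(a1, 2 * a1, B = 3L)
  fit <- ai_test(m, "global", n_perm = 50, seed = 1)
  expect_true(all(fit$stat == S * (S + 1) / 2))
  expect_true(all(fit$log2fc > 0))
})

test_that("swapping allele labels negates statistics and keeps p-values", {
  sim <- simulate_allelic(sim_design(n_genes = 30, n_ai_genes = 10,
                                     lib_size = 1e5, n_boot = 4), seed = 9)
  m <- sim$matrix
  swapped <- m
  swapped$counts <- m$counts[, , 2:1]
  swapped$bootstraps <- m$bootstraps[, , 2:1, , drop = FALSE]

  f1 <- ai_test(m, "global", n_perm = 60, seed = 4)
  f2 <- ai_test(swapped, "global", n_perm = 60, seed = 4)
  expect_equal(f2$stat, -f1$stat)
  expect_equal(f2$pvalue, f1$pvalue)
  expect_equal(f2$log2fc, -f1$log2fc)

  md <- m$metadata
  f3 <- ai_test(m, "dynamic", covariate = md$covariate, n_perm = 60, seed = 4)
  f4 <- ai_test(swapped, "dynamic", covariate = md$covariate,
                n_perm = 60, seed = 4)
  expect_equal(f4$stat, -f3$stat, tolerance = 1e-12)
  expect_equal(f4$pvalue, f3$pvalue)
})

test_that("global test is calibrated under a complete null", {
  set.seed(31)
  m <- null_matrix(n_feat = 400, S = 10, B = 3)
  fit <- ai_test(m, "global", n_perm = 100, seed = 13)
  frac <- mean(fit$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(frac, 0.05 + 3 * se)
})

test_that("results are bit-reproducible given the seed", {
  set.seed(77)
  m <- null_matrix(n_feat = 50, S = 6, B = 3)
  f1 <- ai_test(m, "global", n_perm = 40, seed = 101)
  f2 <- ai_test(m, "global", n_perm = 40, seed = 101)
  expect_identical(f1$pvalue, f2$pvalue)
  expect_identical(f1$qvalue, f2$qvalue)
  f3 <- ai_test(m, "dynamic", covariate = 1:6, n_perm = 40, seed = 101)
  f4 <- ai_test(m, "dynamic", covariate = 1:6, n_perm = 40, seed = 101)
  expect_identical(f3$stat, f4$stat)
  expect_identical(f3$qvalue, f4$qvalue)
})

test_that("dynamic test: equal alleles give stat 0 and p near 1", {
  a1 <- matrix(rep(c(30, 40, 50, 60, 70), 20), nrow = 20, byrow = TRUE)
  m <- point_matrix(a1, a1)
  fit <- ai_test(m, "dynamic", covariate = 1:5, n_perm = 50, seed = 2)
  expect_true(all(fit$stat == 0))
  expect_true(all(fit$pvalue > 0.9))
})

test_that("dynamic test: LFC exactly linear in the covariate gives stat 1", {
  cov <- c(1, 2, 3, 4, 5)
  c0 <- 5
  a1 <- matrix(100, 4, 5)
  lfc <- 0.1 * cov          # target log2 fold changes
  a2 <- matrix(rep((100 + c0) * 2^lfc - c0, each = 4), 4, 5)
  m <- point_matrix(a1, a2)
  fit <- ai_test(m, "dynamic", covariate = cov, pseudocount = c0,
                 n_perm = 30, seed = 3)
  expect_equal(fit$stat, rep(1, 4), tolerance = 1e-12)
})

test_that("dynamic test with B=1 equals a direct correlation on LFCs", {
  set.seed(12)
  S <- 8
  a1 <- matrix(rpois(5 * S, 80), 5)
  a2 <- matrix(rpois(5 * S, 80), 5)
  cov <- c(2, 4, 6, 8, 10, 12, 14, 16)
  m <- point_matrix(a1, a2)
  fit <- ai_test(m, "dynamic", covariate = cov, pseudocount = 5,
                 n_perm = 20, seed = 1)
  oracle <- apply(log2((a2 + 5) / (a1 + 5)), 1, cor, y = cov)
  expect_equal(fit$stat, oracle, tolerance = 1e-12)
  # spearman variant
  fitS <- ai_test(m, "dynamic", covariate = cov, cor_method = "spearman",
                  n_perm = 20, seed = 1)
  oracleS <- apply(log2((a2 + 5) / (a1 + 5)), 1, cor, y = cov,
                   method = "spearman")
  expect_equal(fitS$stat, oracleS, tolerance = 1e-12)
})

test_that("dynamic test input contracts", {
  m <- point_matrix(matrix(1, 2, 4), matrix(2, 2, 4))
  expect_error(ai_test(m, "dynamic"), "covariate")
  expect_error(ai_test(m, "dynamic", covariate = rep(1, 4)), "distinct")
  expect_error(ai_test(m, "dynamic", covariate = c(1, 1, 2, 2)), "distinct")
})

test_that("differential test: constructed separation gives the maximal rank sum", {
  # group A: a2 = 2*a1 (LFC > 0); group B: a2 = a1/2 (LFC < 0)
  a1 <- matrix(100, 6, 8)
  a2 <- cbind(matrix(200, 6, 4), matrix(50, 6, 4))
  md <- data.frame(sample_id = paste0("s", 1:8),
                   group = rep(c("A", "B"), each = 4))
  m <- point_matrix(a1, a2, metadata = md)
  fit <- ai_test(m, "differential", group = "group", n_perm = 40, seed = 6)
  # ranks of group B (second level) are 1..4: centered stat = 10 - 18 = -8
  expect_true(all(fit$stat == -8))
  swapped_md <- md
  swapped_md$group <- rep(c("B", "A"), each = 4)
  m2 <- m; m2$metadata <- swapped_md
  fit2 <- ai_test(m2, "differential", group = "group", n_perm = 40, seed = 6)
  expect_equal(fit2$stat, -fit$stat)
})

test_that("differential test is centered under identical LFC distributions", {
  set.seed(18)
  a1c <- matrix(100, 200, 10)
  m <- toy_matrix(a1c, 2 * a1c, B = 2L)
  g <- rep(c("A", "B"), each = 5)
  fit <- ai_test(m, "differential", group = g, n_perm = 100, seed = 8)
  expect_true(all(fit$stat == 0))   # identical LFCs everywhere: all midranks
  # with noise, p-values behave uniformly
  a1 <- matrix(rpois(200 * 10, 100), 200)
  a2 <- matrix(rpois(200 * 10, 100), 200)
  m2 <- toy_matrix(a1, a2, B = 2L)
  fit2 <- ai_test(m2, "differential", group = g, n_perm = 100, seed = 8)
  expect_gt(mean(fit2$pvalue), 0.35)
  expect_lt(mean(fit2$pvalue < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_error(ai_test(m2, "differential", group = rep(c("A", "B", "B"),
                                                       c(1, 8, 1))),
               "at least 2")
})

test_that("bootstrap subsetting and config validation work", {
  set.seed(2)
  m <- null_matrix(20, S = 5, B = 6)
  f_all <- ai_test(m, "global", n_perm = 20, seed = 3)
  f_sub <- ai_test(m, "global", n_perm = 20, seed = 3, n_boot = 2)
  expect_equal(attr(f_all, "config")$n_boot, 6L)
  expect_equal(attr(f_sub, "config")$n_boot, 2L)
  expect_error(ai_test(m, "global", pseudocount = 0), "pseudocount")
  expect_error(ai_test(m, "global", n_perm = 0), "n_perm")
  expect_warning(ai_test(m, "global", n_perm = 5, seed = 1), "coarse")
})
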