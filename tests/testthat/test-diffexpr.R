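# Normalization, dispersion, the NB exact test and induced-gene calls.

test_that("size factors: identity, doubling, worked 3x3 median-of-ratios", {
  m <- matrix(c(10, 100, 1), 3, 4, dimnames = list(paste0("g", 1:3),
                                                   paste0("s", 1:4)))
  expect_equal(size_factors(m), setNames(rep(1, 4), paste0("s", 1:4)))

  m2 <- cbind(a = c(10, 100, 1), b = c(20, 200, 2))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  m3 <- cbind(s1 = c(10, 100, 1), s2 = c(20, 200, 2), s3 = c(10, 100, 1))
  rownames(m3) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m3)), c(1, 2, 1) / 2^(1 / 3))

  mz <- rbind(g1 = c(0, 5), g2 = c(3, 0))
  expect_error(size_factors(mz), "reference gene")
})

test_that("dispersion estimate: near zero for Poisson, recovers NB phi, clips negatives", {
  phis0 <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(rpois(2000 * 6, 100), 2000, 6,
                dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
    estimate_dispersion(m, rep(c("a", "b"), each = 3))
  }, numeric(1))
  expect_lte(mean(phis0), 0.02)

  phis1 <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), 2000, 6,
                dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
    estimate_dispersion(m, rep(c("a", "b"), each = 3))
  }, numeric(1))
  expect_gte(mean(phis1), 0.05)
  expect_lte(mean(phis1), 0.2)

  # single gene with identical replicates: variance 0, estimate clipped
  m <- matrix(c(50, 50, 50, 50), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(estimate_dispersion(m, rep("a", 4), sf = rep(1, 4)), 0)
  expect_error(estimate_dispersion(m, c("a", "b", "c", "d"), sf = rep(1, 4)),
               "replicates")
})

test_that("exact test: symmetry, zero-total convention, clamping", {
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), phi = 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), phi = 0.2), 1)
  p <- nb_exact_test(c(200, 190), c(10, 12), phi = 0.05)
  expect_true(p >= 0 && p < 1e-4)
})

test_that("exact test equals the independent enumeration oracle (N <= 100)", {
  set.seed(77)
  for (i in 1:200) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    phi <- sample(c(0, 0.01, 0.1, 0.5), 1)
    ya <- rpois(na, sample(1:12, 1))
    yb <- rpois(nb, sample(1:12, 1))
    if (sum(ya) + sum(yb) > 100) next
    p <- nb_exact_test(ya, yb, phi)
    p_oracle <- oracle_exact_p(sum(ya), sum(yb), na, nb, phi)
    expect_lt(abs(p - p_oracle), 1e-12)
  }
})

test_that("exact test at phi=0 reduces to the minimum-likelihood binomial test", {
  set.seed(42)
  for (i in 1:50) {
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    ya <- rpois(na, 20); yb <- rpois(nb, 20)
    N <- sum(ya) + sum(yb)
    if (N == 0 || N > 200) next
    p <- nb_exact_test(ya, yb, phi = 0)
    p_binom <- oracle_binom_p(sum(ya), N, na / (na + nb))
    expect_lt(abs(p - p_binom), 1e-12)
  }
})

test_that("BH adjustment: hand cases and order preservation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(9)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= 0 & q <= 1))
  # q is a monotone transform of p: sorting by p sorts q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("run_contrast: null gene flat, strict >1 threshold, group errors", {
  # with identical columns the size factors are exactly 1 and a flat
  # gene has log2FC exactly 0
  cm0 <- null_count_matrix(30, seed = 3L)
  cm0$counts[] <- cm0$counts[, 1]
  de0 <- run_contrast(cm0, "WT:MMC:40 vs WT:none:0", phi = 0.05)
  expect_equal(de0$log2FC, rep(0, 30))
  expect_false(any(de0$induced))
  expect_true(all(de0$p == 1))

  # with noisy libraries a flat gene stays near 0 and uninduced
  cm <- null_count_matrix(50, seed = 3L)
  cm$counts["g0001", ] <- 100L
  de <- run_contrast(cm, "WT:MMC:40 vs WT:none:0")
  row <- de[de$gene_id == "g0001", ]
  expect_equal(row$log2FC, 0, tolerance = 0.15)
  expect_false(row$induced)

  # a gene at log2FC just under 1 with a tiny p is NOT induced:
  # the threshold is strict
  expect_false(with(list(lfc = 0.95, p = 1e-10, q = 1e-8),
                    lfc > 1 && p < 0.01 && q < 0.1))
  cm2 <- null_count_matrix(20, seed = 4L)
  expect_error(run_contrast(cm2, "WT:MMC:99 vs WT:none:0"),
               "zero samples")
})

test_that("scale invariance: renormalizing a scaled sample restores p exactly", {
  set.seed(6)
  for (i in 1:50) {
    ya <- rpois(3, 60); yb <- rpois(3, 60)
    p0 <- nb_exact_test(ya, yb, phi = 0)
    ya2 <- ya; ya2[1] <- ya2[1] * 5L # one sample scaled by an integer
    p1 <- nb_exact_test(ya2, yb, phi = 0, sf_a = c(5, 1, 1))
    expect_lt(abs(p0 - p1), 1e-6)
  }
  # whole-matrix path: estimated factors absorb most of the scaling
  cm <- null_count_matrix(300, phi = 0, seed = 6L)
  de1 <- run_contrast(cm, "WT:MMC:40 vs WT:none:0", phi = 0)
  cm2 <- cm
  cm2$counts[, 1] <- cm2$counts[, 1] * 3L
  de2 <- run_contrast(cm2, "WT:MMC:40 vs WT:none:0", phi = 0)
  expect_gt(cor(de1$p, de2$p), 0.99)
  expect_equal(mean(de1$induced), mean(de2$induced))
})

test_that("exact test agrees with the edgeR implementation on shared ground", {
  skip_if_not_installed("edgeR")
  set.seed(15)
  n <- 200
  counts <- matrix(rnbinom(n * 6, mu = 100, size = 1 / 0.05), n, 6,
                   dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  counts[1:10, 4:6] <- matrix(
    rnbinom(30, mu = 500, size = 1 / 0.05), 10, 3)
  grp <- rep(c("a", "b"), each = 3)
  p_ours <- vapply(seq_len(n), function(g) {
    nb_exact_test(counts[g, 1:3], counts[g, 4:6], phi = 0.05)
  }, numeric(1))
  y <- edgeR::DGEList(counts = counts, group = grp)
  y$samples$norm.factors <- 1
  et <- edgeR::exactTest(y, dispersion = 0.05, pair = c("a", "b"))
  p_edger <- et$table$PValue
  expect_gt(cor(-log10(p_ours + 1e-300), -log10(p_edger + 1e-300)), 0.98)
  # same induced calls at the working threshold for nearly all genes
  expect_gte(mean((p_ours < 0.01) == (p_edger < 0.01)), 0.95)
})
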