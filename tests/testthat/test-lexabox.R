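# Promoter extraction, dyad OOPS-EM discovery, PWM scoring, box
# features, one-hot PCA, group comparisons.

test_that("promoter extraction honours the coordinate contract on both strands", {
  g <- random_genome(10000, seed = 1L)
  ann <- toy_annotation()
  prom <- extract_promoters(ann, g)
  expect_equal(unname(nchar(prom)), c(275L, 275L))
  # plus strand: genome[s-200, s+75)
  expect_identical(prom[["geneA"]], substr(g, 1000 - 200 + 1, 1000 + 75))
  # minus strand: revcomp of genome[e-75, e+200) with CDS start at end-1
  expect_identical(prom[["geneB"]],
                   revcomp(substr(g, 3600 - 75 + 1, 3600 + 200)))

  # window wrapping the origin of the circular genome
  ann_wrap <- data.frame(gene_id = "gw", tu_id = "tw", start = 100L,
                         end = 1000L, strand = "+", stringsAsFactors = FALSE)
  pw <- extract_promoters(ann_wrap, g)
  expect_equal(nchar(pw[["gw"]]), 275L)
  expect_identical(substr(pw[["gw"]], 101, 275),
                   substr(g, 1, 175)) # tail after the wrap
  expect_error(extract_promoters(ann, g, genes = "nope"), "absent")
})

test_that("dyad EM recovers planted boxes and both GTTC half-sites", {
  cfg <- small_config(seed = 17L)
  sim <- plant_lexa_boxes(simulate_annotation(cfg), cfg)
  prom <- extract_promoters(sim$annotation, sim$genome,
                            genes = sim$boxes$gene_id)
  disc <- discover_boxes(prom)
  expect_equal(disc$spacer_len, 7L)
  cons <- disc$pwm$consensus
  expect_identical(substr(cons, 1, 4), "GTTC")
  expect_identical(substr(cons, 12, 15), "GTTC")
  # at this small scale (~10 promoters) most planted offsets come back
  # exactly; the >= 90% bar is asserted at default scale in acceptance
  hit <- merge(disc$boxes, sim$boxes, by = "gene_id")
  expect_gte(mean(hit$offset.x == hit$offset.y), 0.8)
  # EM objective (penalized log-likelihood) is non-decreasing
  expect_true(all(diff(disc$objective) >= -1e-9))
})

test_that("pure random promoters with a strict floor come back box-less", {
  set.seed(23)
  prom <- setNames(vapply(1:12, function(i) random_genome(275, seed = 100 + i),
                          character(1)), paste0("p", 1:12))
  res <- tryCatch(discover_boxes(prom, score_floor = 18),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "seed matches")
  } else {
    expect_equal(nrow(res$boxes), 0L)
  }
})

test_that("strand symmetry: discovery on reverse-complemented promoters mirrors", {
  cfg <- small_config(seed = 19L)
  sim <- plant_lexa_boxes(simulate_annotation(cfg), cfg)
  prom <- extract_promoters(sim$annotation, sim$genome,
                            genes = sim$boxes$gene_id)
  fwd <- discover_boxes(prom)
  rev <- discover_boxes(setNames(vapply(prom, revcomp, character(1)),
                                 names(prom)))
  # same per-promoter best scores (the PWM may come out reverse
  # complemented, scores are strand symmetric)
  a <- fwd$boxes[order(fwd$boxes$gene_id), ]
  b <- rev$boxes[order(rev$boxes$gene_id), ]
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$score, b$score, tolerance = 1e-6)
})

test_that("PWM scoring: identical boxes score identically, consensus is maximal", {
  cfg <- small_config(seed = 17L)
  sim <- plant_lexa_boxes(simulate_annotation(cfg), cfg)
  prom <- extract_promoters(sim$annotation, sim$genome,
                            genes = sim$boxes$gene_id)
  pwm <- discover_boxes(prom)$pwm

  # two promoters carrying the same printed operator score equally
  box <- toupper("GTTCttgttatGTTC")
  s1 <- score_box(pwm, paste0(random_genome(30, 1), box, random_genome(30, 2)), 31)
  s2 <- score_box(pwm, paste0(random_genome(30, 3), box, random_genome(30, 4)), 31)
  expect_identical(s1, s2)

  # the consensus string achieves the maximal possible score
  cons_score <- score_box(pwm, pwm$consensus, 1)
  expect_equal(cons_score, sum(apply(pwm$logodds, 2, max)))

  # brute-force per-position table lookup oracle on random 15-mers
  set.seed(5)
  for (i in 1:20) {
    s <- random_genome(15, seed = 200 + i)
    manual <- sum(vapply(1:15, function(j) {
      pwm$logodds[substr(s, j, j), j]
    }, numeric(1)))
    expect_equal(score_box(pwm, s, 1), manual)
  }
  expect_error(score_box(pwm, "GTTCNNNNNNNGTTC", 1), "non-ACGT")
  expect_error(score_box(pwm, "GTTC", 1), "outside")
})

test_that("box features: adjacency convention, printed spacer, negative distances", {
  boxes <- data.frame(
    gene_id = c("a", "b", "c"),
    offset = c(-15L, -40L, 10L),
    strand = "+",
    seq = c(toupper("GTTCttgttatGTTC"), toupper("GTTCttgttatGTTC"),
            toupper("GTTCgcgcgcgGTTC")),
    score = 1, stringsAsFactors = FALSE)
  f <- box_features(boxes)
  # box ending 1 bp before the CDS start: distance 0
  expect_equal(f$distance_to_cds[1], 0)
  expect_equal(f$distance_to_cds[2], 25)
  # box starting downstream of the CDS start: negative distance
  expect_equal(f$distance_to_cds[3], -25)
  expect_equal(f$spacer[1], "TTGTTAT")
  expect_equal(f$spacer_len[1], 7L)
  expect_equal(f$spacer_gc[1], 1 / 7)
  expect_equal(f$spacer_gc[3], 1)
})

test_that("one-hot PCA: degenerate, rank-1 and normalization cases", {
  expect_error(onehot_pca(c("ACGT", "ACGT")), "at least 3")

  same <- rep("ACGTACGT", 5)
  res <- onehot_pca(same)
  expect_true(res$degenerate)

  two <- c(rep("AAAA", 3), rep("AATT", 2))
  res2 <- onehot_pca(two)
  expect_false(res2$degenerate)
  expect_equal(res2$var_explained[1], 1) # exactly two distinct -> rank 1

  set.seed(31)
  rnd <- vapply(1:12, function(i) random_genome(15, seed = 300 + i),
                character(1))
  res3 <- onehot_pca(rnd)
  expect_equal(sum(res3$var_explained), 1, tolerance = 1e-10)
  # scores reproduce pairwise structure: total variance matches
  expect_equal(sum(res3$scores^2),
               sum(scale(onehot_matrix_oracle(rnd), scale = FALSE)^2),
               tolerance = 1e-8)
})

test_that("group comparisons: exact Mann-Whitney enumeration and t test", {
  # (1,2,3) vs (4,5,6): U = 0, exact two-sided p = 2/20
  mw <- compare_groups(c(1, 2, 3), c(4, 5, 6), "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)

  # identical groups under the midrank convention: p = 1
  mw2 <- compare_groups(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(mw2$p, 1)

  tt <- compare_groups(c(1, 2, 3), c(4, 5, 6), "t_unpaired")
  expect_equal(tt$p, t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$p.value)
  expect_error(compare_groups(c(1, 1), c(1, 1), "t_unpaired"),
               "zero variance")

  # power at a 2 SD shift, n = 15/15
  set.seed(41)
  rej <- vapply(1:200, function(i) {
    a <- rnorm(15); b <- rnorm(15, 2)
    compare_groups(a, b, "mann_whitney")$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)

  # large-sample path agrees with the exact path on moderate data
  set.seed(43)
  a <- rnorm(8); b <- rnorm(40, 0.5)
  p_exact <- compare_groups(a, b, "mann_whitney")$p
  p_norm <- local({
    r <- rank(c(a, b)); u <- sum(r[1:8]) - 8 * 9 / 2
    mu <- 8 * 40 / 2; sig <- sqrt(8 * 40 * 49 / 12)
    2 * pnorm(-(abs(u - mu) - 0.5) / sig)
  })
  expect_equal(p_exact, p_norm, tolerance = 0.05)
})
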