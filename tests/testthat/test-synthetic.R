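# Generator contracts: determinism, packing, truth bookkeeping and the
# statistical laws of the simulated layers.

test_that("annotation simulation is deterministic and respects packing", {
  cfg <- small_config(seed = 3L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  one <- simulate_annotation(sim_config(n_genes = 1, n_sos_genes = 0,
                                        genome_length = 10000L))
  expect_equal(nrow(one$annotation), 1L)
  expect_equal(length(unique(one$annotation$tu_id)), 1L)

  expect_error(simulate_annotation(sim_config(n_genes = 100,
                                              n_sos_genes = 0,
                                              genome_length = 5000L)),
               "infeasible packing")
})

test_that("TU structure: recount of unique TU ids matches, operons shrink TU count", {
  cfg <- sim_config(n_genes = 50L, n_sos_genes = 10L, operon_fraction = 0.4,
                    genome_length = 150000L, seed = 11L)
  ann <- simulate_annotation(cfg)$annotation
  expect_equal(nrow(ann), 50L)
  n_tu <- length(unique(ann$tu_id))
  expect_lt(n_tu, 50L)
  # independent recount: per-TU sizes sum to the gene count
  expect_equal(sum(table(ann$tu_id)), 50L)
  # genes within a TU share a strand and are ordered 5'->3'
  for (tid in unique(ann$tu_id)) {
    rows <- ann[ann$tu_id == tid, ]
    expect_length(unique(rows$strand), 1L)
    if (nrow(rows) > 1) {
      if (rows$strand[1] == "+") expect_true(all(diff(rows$start) > 0))
      else expect_true(all(diff(rows$start) < 0))
    }
  }
})

test_that("SOS truth bookkeeping: counts and beta ranges agree with config", {
  cfg <- small_config(seed = 5L)
  ann <- simulate_annotation(cfg)$annotation
  expect_equal(sum(ann$is_sos), cfg$n_sos_genes)
  expect_true(all(is.na(ann$beta[!ann$is_sos])))
  eb <- ann$beta[ann$is_sos & ann$class == "early"]
  lb <- ann$beta[ann$is_sos & ann$class == "late"]
  expect_true(all(eb >= cfg$beta_early[1] & eb <= cfg$beta_early[2]))
  expect_true(all(lb >= cfg$beta_late[1] & lb <= cfg$beta_late[2]))
  expect_gt(min(eb), max(lb))
})

test_that("planted boxes: point-mass PWM plants the exact string, zero SOS leaves genome intact", {
  # point mass on the printed operator GTTCttgttatGTTC
  box <- toupper("GTTCttgttatGTTC")
  pm <- matrix(0, 4, 15, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:15) pm[substr(box, j, j), j] <- 1
  cfg <- small_config(seed = 2L, box_pwm = pm)
  sim <- plant_lexa_boxes(simulate_annotation(cfg), cfg)
  expect_true(all(sim$boxes$box_seq == box))
  # every planted box is present in the genome at its recorded spot
  for (i in seq_len(nrow(sim$boxes))) {
    got <- circ_substr(sim$genome, sim$boxes$genome_start[i], 15L)
    if (sim$boxes$strand[i] == "-") got <- revcomp(got)
    expect_identical(got, box)
  }
  # one box per SOS TU
  expect_equal(sort(sim$boxes$tu_id),
               sort(unique(sim$annotation$tu_id[sim$annotation$is_sos])))

  cfg0 <- sim_config(n_genes = 20L, n_sos_genes = 0L,
                     genome_length = 60000L, seed = 2L)
  sim0 <- simulate_annotation(cfg0)
  planted0 <- plant_lexa_boxes(sim0, cfg0)
  expect_identical(planted0$genome, sim0$genome)
  expect_equal(nrow(planted0$boxes), 0L)
})

test_that("planted offsets are recoverable by an exhaustive PWM scan", {
  cfg <- small_config(seed = 7L)
  sim <- plant_lexa_boxes(simulate_annotation(cfg), cfg)
  prom <- extract_promoters(sim$annotation, sim$genome,
                            genes = sim$boxes$gene_id)
  # scan with the generative PWM itself: best-match position per
  # promoter should sit at the planted offset
  hits <- vapply(seq_along(prom), function(i) {
    sc <- vapply(1:(nchar(prom[i]) - 14L), function(s)
      score_box(cfg$box_pwm, prom[[i]], s), numeric(1))
    which.max(sc) - 1L - 200L # back to CDS-relative offset
  }, integer(1))
  expect_gte(mean(hits == sim$boxes$offset), 0.9)
})

test_that("count law: Poisson at phi=0, derepression mean at 2^beta, determinism", {
  # phi = 0, no SOS genes: per-condition sample mean within 3 SE of basal
  cfg <- sim_config(n_genes = 300L, n_sos_genes = 0L, phi = 0,
                    genome_length = 600000L, basal_mu = 100,
                    lib_factor_range = c(1, 1), n_replicates = 3L, seed = 4L)
  ann <- simulate_annotation(cfg)$annotation
  cm <- simulate_counts(cfg, ann)
  for (s in seq_len(ncol(cm$counts))) {
    se <- sqrt(100 / 300)
    expect_lt(abs(mean(cm$counts[, s]) - 100), 3 * se)
  }

  # SOS gene with beta=3 in the derepressed background: mean ~ 800
  ann1 <- data.frame(gene_id = "g1", tu_id = "t1", start = 0L, end = 900L,
                     strand = "+", is_sos = TRUE, class = "early", beta = 3,
                     stringsAsFactors = FALSE)
  cfg1 <- sim_config(n_genes = 1L, n_sos_genes = 1L, genome_length = 10000L,
                     basal_mu = 100, phi = 0.05, n_replicates = 1000L,
                     lib_factor_range = c(1, 1), seed = 8L)
  cm1 <- simulate_counts(cfg1, ann1)
  dlexa <- cm1$samples$genotype == "dlexa"
  m <- mean(cm1$counts[1, dlexa])
  se <- sqrt((800 + 0.05 * 800^2) / 1000)
  expect_lt(abs(m - 800), 3 * se)

  # byte-identical across runs at a fixed seed
  expect_identical(simulate_counts(cfg1, ann1), simulate_counts(cfg1, ann1))
  expect_error(simulate_counts(modifyList(cfg1, list(phi = -1)), ann1),
               "phi")
})

test_that("trace kinetics: no-damage control is flat, closed form holds, beta_max dominance", {
  # k_c = 0: repression never lifts, trace flat up to noise
  cfg <- sim_config(k_c = 0, trace_noise_cv = 0, seed = 1L)
  tr <- simulate_traces(cfg, n_cells = 5L)
  mt <- mean_trace(tr$traces)
  expect_lt(diff(range(mt$mean)) / mt$mean[1], 1e-6)

  # h -> infinity, L0 >> K_d, noiseless, no background: once L crosses
  # K_d at t* = log(L0/K_d)/k_c the reporter follows
  # F = (beta/delta)(1 - exp(-delta (t - t*)))
  cfg2 <- sim_config(h = 200, L0 = 1000, K_d = 10, k_c = 0.1,
                     trace_noise_cv = 0, cell_cv_beta = 0, bg_au = 0,
                     dt = 0.01, t_obs = 10, t_max = 240, seed = 1L)
  tr2 <- simulate_traces(cfg2, n_cells = 1L)
  t_star <- log(cfg2$L0 / cfg2$K_d) / cfg2$k_c
  d <- tr2$traces
  late <- d$t_min > t_star + 1
  expected <- (cfg2$beta_max / cfg2$delta) *
    (1 - exp(-cfg2$delta * (d$t_min[late] - t_star)))
  observed <- d$intensity_au[late] / d$area_px[late]
  expect_lt(max(abs(observed - expected) / expected), 0.01)

  # 2x beta_max separation: higher-beta population mean lies above at
  # every t > 0
  cfg_hi <- sim_config(seed = 21L)
  cfg_lo <- sim_config(seed = 21L, beta_max = cfg_hi$beta_max / 2)
  hi <- mean_trace(simulate_traces(cfg_hi, 200L, seed = 31L)$traces)
  lo <- mean_trace(simulate_traces(cfg_lo, 200L, seed = 32L)$traces)
  expect_true(all(hi$mean[hi$t_min > 0] > lo$mean[lo$t_min > 0]))
})

test_that("coverage: mass conservation, pure background, summit at planted center", {
  ann <- toy_annotation()
  boxes <- data.frame(gene_id = "geneA", tu_id = "tuA", offset = -50L,
                      box_seq = strrep("A", 15), strand = "+",
                      genome_start = 950L, stringsAsFactors = FALSE)
  cfg <- sim_config(genome_length = 10000L, n_genes = 2L, n_sos_genes = 0L,
                    lambda_bg = 0, peak_area = 1000, peak_sd = 30, seed = 5L)
  cov <- simulate_coverage(ann, boxes, cfg)
  expect_equal(sum(cov$track), 1000)

  cfg_bg <- modifyList(cfg, list(lambda_bg = 2))
  cov_bg <- simulate_coverage(ann, boxes[0, ], cfg_bg)
  se <- sqrt(2 / 10000)
  expect_lt(abs(mean(cov_bg$track) - 2), 3 * se)

  # summit of the smoothed peak sits at the planted center +/- sd/2
  sm <- smooth_gaussian(cov$track, 20)
  center <- boxes$genome_start + 7L
  expect_lt(abs(which.max(sm) - 1L - center), cfg$peak_sd / 2)
})
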