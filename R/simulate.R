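# Synthetic-data generator. All coordinates are 0-based, half-open and
# circular (modulo genome length). Every generator takes an explicit
# integer seed so identical seeds give byte-identical output.

#' Simulate a circular genome with non-overlapping gene annotation
#'
#' Genes are packed sequentially around the circle in transcriptional
#' units (TUs): singletons plus a configurable fraction of 2-3 gene
#' operons, each TU on a random strand with room left upstream of every
#' TU for a promoter window. A subset of TUs is labelled as the
#' damage-inducible (SOS) set; all genes of an SOS TU share the TU's
#' temporal class (early/late) and promoter strength beta, mirroring
#' operonic co-transcription.
#'
#' @param config a [sim_config()] object
#' @param seed integer seed (default derived from `config$seed`)
#' @return list with elements `genome` (character string), `annotation`
#'   (data.frame: gene_id, tu_id, start, end, strand, is_sos, class,
#'   beta; 0-based half-open), `ori` (0-based origin position)
#' @export
simulate_annotation <- function(config,
                                seed = derive_seed(config$seed, "annotation")) {
  validate_sim_config(config)
  set.seed(seed)
  G <- config$genome_length
  n <- config$n_genes

  # TU structure: draw sizes until genes are exhausted
  tu_sizes <- integer(0)
  left <- n
  while (left > 0) {
    sz <- if (runif(1) < config$operon_fraction && left >= 2) {
      sample(2:min(3, left), 1)
    } else 1L
    tu_sizes <- c(tu_sizes, sz)
    left <- left - sz
  }
  n_tu <- length(tu_sizes)

  gene_len <- sample(300:1500, n, replace = TRUE)
  intra_gap <- sample(20:100, n, replace = TRUE)     # within operons
  inter_gap <- sample(300:600, n_tu, replace = TRUE) # between TUs
  need <- sum(gene_len) + sum(inter_gap) + sum(intra_gap[seq_len(max(0, n - n_tu))])
  if (need > G) {
    stop("infeasible packing: ", need, " bp of genes/gaps exceed genome_length ", G)
  }

  strand <- sample(c("+", "-"), n_tu, replace = TRUE)
  ann <- vector("list", n_tu)
  pos <- 0L
  gi <- 0L
  for (k in seq_len(n_tu)) {
    pos <- pos + inter_gap[k]
    sz <- tu_sizes[k]
    starts <- ends <- integer(sz)
    for (j in seq_len(sz)) {
      gi <- gi + 1L
      starts[j] <- pos
      ends[j] <- pos + gene_len[gi]
      pos <- ends[j] + if (j < sz) intra_gap[gi] else 0L
    }
    ids <- seq.int(gi - sz + 1L, gi)
    # on the minus strand the 5'-most (promoter-proximal) gene is the
    # right-most one; order genes in transcription direction
    ord <- if (strand[k] == "+") seq_len(sz) else rev(seq_len(sz))
    ann[[k]] <- data.frame(
      gene_id = sprintf("gene_%04d", ids[ord]),
      tu_id = sprintf("tu_%04d", k),
      start = starts[ord], end = ends[ord],
      strand = strand[k], stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, ann)

  # SOS labelling at TU level so operon members co-induce
  ann$is_sos <- FALSE
  ann$class <- NA_character_
  ann$beta <- NA_real_
  if (config$n_sos_genes > 0) {
    tu_of <- split(seq_len(nrow(ann)), ann$tu_id)
    tu_ids <- sample(names(tu_of)) # random priority order
    remaining <- config$n_sos_genes
    chosen <- character(0)
    for (tid in tu_ids) {
      sz <- length(tu_of[[tid]])
      if (sz <= remaining) {
        chosen <- c(chosen, tid)
        remaining <- remaining - sz
      }
      if (remaining == 0) break
    }
    if (remaining > 0) {
      stop("could not assemble exactly ", config$n_sos_genes,
           " SOS genes from whole TUs; adjust n_sos_genes or operon_fraction")
    }
    n_early <- round(config$fraction_early * length(chosen))
    early_tus <- head(chosen, n_early) # chosen is already in random order
    for (tid in chosen) {
      rows <- tu_of[[tid]]
      cls <- if (tid %in% early_tus) "early" else "late"
      rng <- if (cls == "early") config$beta_early else config$beta_late
      ann$is_sos[rows] <- TRUE
      ann$class[rows] <- cls
      ann$beta[rows] <- runif(1, rng[1], rng[2])
    }
  }

  genome <- paste(sample(DNA_BASES, G, replace = TRUE), collapse = "")
  rownames(ann) <- NULL
  list(genome = genome, annotation = ann, ori = 0L)
}

#' 0-based position of the first transcribed base of each gene
#'
#' For plus-strand genes this is `start`; for minus-strand genes it is
#' `end - 1` (the right-most base of the half-open interval).
#' @param annotation annotation data.frame
#' @return integer vector named by gene_id
#' @export
cds_start0 <- function(annotation) {
  setNames(ifelse(annotation$strand == "+", annotation$start,
                  annotation$end - 1L),
           annotation$gene_id)
}

#' First (promoter-proximal) gene of each transcriptional unit
#' @param annotation annotation data.frame (genes ordered in
#'   transcription direction within each TU, as produced by
#'   [simulate_annotation()])
#' @return data.frame tu_id, gene_id, strand
#' @export
tu_promoter_genes <- function(annotation) {
  first <- !duplicated(annotation$tu_id)
  data.frame(tu_id = annotation$tu_id[first],
             gene_id = annotation$gene_id[first],
             strand = annotation$strand[first],
             stringsAsFactors = FALSE)
}

#' Sample one sequence from a probability PWM
#' @noRd
sample_from_pwm <- function(pwm) {
  paste(apply(pwm, 2, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

#' Plant one operator box into each SOS promoter
#'
#' For every SOS transcriptional unit, one box is sampled from the
#' operator PWM and written into the genome on the coding strand of the
#' TU's promoter gene, at a start offset drawn from
#' `config$box_offset_range` relative to the CDS start (negative =
#' upstream). Non-SOS promoters are untouched.
#'
#' @param sim output of [simulate_annotation()]
#' @param config a [sim_config()] object
#' @param seed integer seed
#' @return `sim` with a modified `genome` plus a `boxes` data.frame
#'   (gene_id, tu_id, offset, box_seq, strand, genome_start) where
#'   `genome_start` is the 0-based genomic start of the box interval
#' @export
plant_lexa_boxes <- function(sim, config,
                             seed = derive_seed(config$seed, "boxes")) {
  L <- ncol(config$box_pwm)
  win_up <- 200L; win_down <- 75L
  if (L > win_up + win_down) stop("box longer than the promoter window")
  if (config$box_offset_range[1] < -win_up ||
      config$box_offset_range[2] + L > win_down) {
    stop("box_offset_range places boxes outside the promoter window")
  }
  set.seed(seed)
  promoters <- tu_promoter_genes(sim$annotation)
  sos_tus <- unique(sim$annotation$tu_id[sim$annotation$is_sos])
  promoters <- promoters[promoters$tu_id %in% sos_tus, , drop = FALSE]
  genome <- sim$genome
  G <- nchar(genome)
  cds <- cds_start0(sim$annotation)
  out <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    g <- promoters$gene_id[i]
    box <- sample_from_pwm(config$box_pwm)
    off <- sample(seq(config$box_offset_range[1], config$box_offset_range[2]), 1)
    c0 <- cds[[g]]
    if (promoters$strand[i] == "+") {
      gstart <- pmod(c0 + off, G)
      genome <- circ_substr_set(genome, gstart, box)
    } else {
      # coding-strand offset x maps to genomic position c0 - x
      gstart <- pmod(c0 - off - L + 1L, G)
      genome <- circ_substr_set(genome, gstart, revcomp(box))
    }
    out[[i]] <- data.frame(gene_id = g, tu_id = promoters$tu_id[i],
                           offset = off, box_seq = box,
                           strand = promoters$strand[i],
                           genome_start = gstart, stringsAsFactors = FALSE)
  }
  sim$genome <- genome
  sim$boxes <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), tu_id = character(),
               offset = integer(), box_seq = character(),
               strand = character(), genome_start = integer())
  sim
}

#' Condition design of the expression experiment
#'
#' Six conditions: wild type untreated and at 20/40 min of damage,
#' repressor deletion untreated, recA deletion untreated and at 40 min
#' of damage.
#' @noRd
design_conditions <- function() {
  data.frame(
    genotype = c("WT", "WT", "WT", "dlexa", "drecA", "drecA"),
    treatment = c("none", "MMC", "MMC", "none", "none", "MMC"),
    timepoint = c(0L, 20L, 40L, 0L, 0L, 40L),
    stringsAsFactors = FALSE
  )
}

#' Expected (noise-free) mean count for one gene in one condition
#' @noRd
condition_mu <- function(basal, beta, is_sos, class, genotype, treatment,
                         timepoint, g_early, g_late) {
  if (!is_sos) return(basal)
  if (genotype == "dlexa") return(basal * 2^beta)
  if (genotype == "drecA") return(basal) # no damage signalling
  if (treatment == "none") return(basal)
  g <- if (class == "early") g_early else g_late
  frac <- unname(g[as.character(timepoint)])
  if (is.na(frac)) frac <- 0
  basal * (1 + (2^beta - 1) * frac)
}

#' Simulate a genotype x treatment x timepoint count matrix
#'
#' Counts are negative binomial with Var = mu + phi mu^2 (Poisson when
#' `phi = 0`); per-sample library factors are drawn uniformly from
#' `config$lib_factor_range` and multiply every gene mean of that
#' sample.
#'
#' @param config a [sim_config()] object
#' @param annotation annotation data.frame with is_sos/class/beta
#' @param seed integer seed
#' @return a [count_matrix()] (list: `counts` genes x samples integer
#'   matrix, `samples` metadata data.frame)
#' @export
simulate_counts <- function(config, annotation,
                            seed = derive_seed(config$seed, "counts")) {
  if (config$phi < 0) stop("dispersion phi must be >= 0")
  set.seed(seed)
  cond <- design_conditions()
  nrep <- config$n_replicates
  samples <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    data.frame(sample_id = sample_label(cond$genotype[i], cond$treatment[i],
                                        cond$timepoint[i], seq_len(nrep)),
               genotype = cond$genotype[i], treatment = cond$treatment[i],
               timepoint = cond$timepoint[i], replicate = seq_len(nrep),
               stringsAsFactors = FALSE)
  }))
  samples$lib_factor <- runif(nrow(samples), config$lib_factor_range[1],
                              config$lib_factor_range[2])
  n_g <- nrow(annotation)
  counts <- matrix(0L, n_g, nrow(samples),
                   dimnames = list(annotation$gene_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu <- vapply(seq_len(n_g), function(g) {
      condition_mu(config$basal_mu, annotation$beta[g], annotation$is_sos[g],
                   annotation$class[g], samples$genotype[s],
                   samples$treatment[s], samples$timepoint[s],
                   config$g_early, config$g_late)
    }, numeric(1)) * samples$lib_factor[s]
    counts[, s] <- if (config$phi == 0) rpois(n_g, mu) else
      rnbinom(n_g, mu = mu, size = 1 / config$phi)
  }
  count_matrix(counts, samples)
}

#' Simulate per-cell reporter fluorescence traces
#'
#' Per cell, a maximal promoter activity is drawn lognormally around
#' `beta_max` (mean-preserving, CV = `cell_cv_beta`), the repressor
#' decays exponentially after damage, promoter activity follows a Hill
#' repression law and the reporter obeys dF/dt = a(t) - delta F,
#' integrated by explicit Euler from the repressed steady state
#' F(0) = a(0)/delta. The observed area-normalized intensity is
#' (F + bg_au) x (1 + noise); the recorded intensity channel is that
#' value times a slowly growing cell area.
#'
#' @param config a [sim_config()] object
#' @param n_cells number of cells
#' @param seed integer seed
#' @return list: `traces` data.frame (cell_id, t_min, intensity_au,
#'   area_px), `cell_truth` data.frame (cell_id, beta_cell)
#' @export
simulate_traces <- function(config, n_cells = 25L,
                            seed = derive_seed(config$seed, "traces")) {
  if (config$dt > 1) stop("dt must be <= 1 min")
  if (config$t_max < 60) stop("t_max must be >= 60 min")
  if (config$delta == 0 && config$t_max * config$beta_max * 4 > 1e9) {
    stop("delta = 0 with this t_max and beta_max would overflow the reporter")
  }
  set.seed(seed)
  cv <- config$cell_cv_beta
  sdl <- sqrt(log(1 + cv^2))
  beta_cell <- config$beta_max * exp(rnorm(n_cells, -sdl^2 / 2, sdl))

  tt <- seq(0, config$t_max, by = config$dt)
  L <- config$L0 * exp(-config$k_c * tt)
  rep_frac <- 1 / (1 + (L / config$K_d)^config$h) # shared by all cells
  nt <- length(tt)
  FF <- matrix(0, n_cells, nt)
  if (config$delta > 0) {
    FF[, 1] <- beta_cell * rep_frac[1] / config$delta
  }
  for (i in seq_len(nt - 1)) {
    a <- beta_cell * rep_frac[i]
    FF[, i + 1] <- FF[, i] + config$dt * (a - config$delta * FF[, i])
  }

  keep <- which(pmod(round(tt / config$dt), round(config$t_obs / config$dt)) == 0)
  t_out <- tt[keep]
  area0 <- rnorm(n_cells, 300, 30)
  growth <- 0.005 # 1/min, slow pad growth
  traces <- do.call(rbind, lapply(seq_len(n_cells), function(c) {
    norm_int <- (FF[c, keep] + config$bg_au) *
      (1 + rnorm(length(keep), 0, config$trace_noise_cv))
    area <- area0[c] * exp(growth * t_out)
    data.frame(cell_id = sprintf("cell_%03d", c), t_min = t_out,
               intensity_au = norm_int * area, area_px = area,
               stringsAsFactors = FALSE)
  }))
  list(traces = traces,
       cell_truth = data.frame(cell_id = sprintf("cell_%03d", seq_len(n_cells)),
                               beta_cell = beta_cell, stringsAsFactors = FALSE))
}

#' Simulate a per-bp ChIP coverage track
#'
#' Poisson background plus, for each planted operator box, a read pile
#' of `config$peak_area` reads multinomially distributed under a
#' Gaussian (sd `config$peak_sd`) centred on the box midpoint,
#' circular-aware.
#'
#' @param annotation annotation data.frame (for the genome length check)
#' @param boxes planted box table from [plant_lexa_boxes()]
#' @param config a [sim_config()] object
#' @param seed integer seed
#' @return list: `track` integer vector of per-bp read counts (length =
#'   genome length), `total_reads` its sum
#' @export
simulate_coverage <- function(annotation, boxes, config,
                              seed = derive_seed(config$seed, "coverage")) {
  set.seed(seed)
  G <- config$genome_length
  track <- rpois(G, config$lambda_bg)
  L <- ncol(config$box_pwm)
  if (nrow(boxes) > 0 && config$peak_area > 0) {
    half <- ceiling(4 * config$peak_sd)
    offs <- seq(-half, half)
    w <- dnorm(offs, 0, config$peak_sd)
    for (i in seq_len(nrow(boxes))) {
      center <- boxes$genome_start[i] + L %/% 2L
      reads <- rmultinom(1, size = config$peak_area, prob = w)[, 1]
      pos <- pmod(center + offs, G) + 1L
      track[pos] <- track[pos] + reads
    }
  }
  list(track = track, total_reads = sum(track))
}

#' Generate a complete synthetic SOS dataset
#'
#' Convenience wrapper running annotation, box planting, counts and
#' coverage with seeds derived from `config$seed`.
#'
#' @param config a [sim_config()] object
#' @return list: genome, annotation, ori, boxes, counts
#'   (a [count_matrix()]), coverage (list track/total_reads)
#' @export
simulate_sos_dataset <- function(config = sim_config()) {
  sim <- simulate_annotation(config)
  sim <- plant_lexa_boxes(sim, config)
  sim$counts <- simulate_counts(config, sim$annotation)
  sim$coverage <- simulate_coverage(sim$annotation, sim$boxes, config)
  sim$config <- config
  sim
}
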