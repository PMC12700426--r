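# End-to-end orchestration: simulate -> differential expression ->
# regulon -> boxes -> coverage -> kinetics -> strength -> summary.

#' Standard contrast strings of the experimental design
#' @noRd
standard_contrasts <- function() {
  c(wt20 = "WT:MMC:20 vs WT:none:0",
    wt40 = "WT:MMC:40 vs WT:none:0",
    dlexa = "dlexa:none:0 vs WT:none:0",
    dreca40 = "drecA:MMC:40 vs drecA:none:0")
}

#' Expand peak-bound promoter genes to whole transcriptional units
#'
#' Operon members are transcribed from the TU promoter, so repressor
#' binding at the promoter covers every gene of the TU.
#' @noRd
expand_bound_to_tus <- function(bound_genes, annotation) {
  promoters <- tu_promoter_genes(annotation)
  bound_tus <- promoters$tu_id[promoters$gene_id %in% bound_genes]
  union(bound_genes,
        annotation$gene_id[annotation$tu_id %in% bound_tus])
}

#' Run the full synthetic SOS temporal-hierarchy pipeline
#'
#' Generates a dataset from `config`, runs the four standard
#' differential-expression contrasts, processes the ChIP track
#' (rpm normalization, Gaussian smoothing, summit calling, the
#' +/-100 bp assignment rule), applies the three-criteria regulon
#' filter with the binding requirement, collapses to TUs, classifies
#' early/late, discovers and scores operator boxes, simulates and
#' analyses reporter kinetics for a strong and a weak promoter, and
#' assembles the promoter-strength table with its headline
#' correlation.
#'
#' @param config a [sim_config()]
#' @param outdir optional directory; when given, all tables plus a
#'   manifest are written there
#' @param n_cells cells per simulated reporter trace set
#' @param chip_sigma smoothing sigma (bp) for the coverage track
#' @param run_kinetics set FALSE to skip the trace stage
#' @return list (results bundle): sim, de (list of 4 tables), regulon,
#'   tus, temporal, boxes, box_pwm, pca, strength, kinetics, summary,
#'   manifest
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         n_cells = 25L, chip_sigma = 20,
                         run_kinetics = TRUE) {
  t_start <- Sys.time()
  sim <- simulate_sos_dataset(config)
  ann <- sim$annotation
  G <- config$genome_length

  de <- lapply(standard_contrasts(), function(ct) run_contrast(sim$counts, ct))

  # ChIP processing
  rpm <- normalize_rpm(sim$coverage$track, sim$coverage$total_reads)
  sm <- smooth_gaussian(rpm, chip_sigma)
  min_h <- 5 * median(sm)
  summits <- call_summits(sm, min_height = min_h, min_sep = 200L)
  assignments <- assign_summits(summits, ann, margin = 100L,
                                genome_length = G)
  bound <- expand_bound_to_tus(
    unique(assignments$gene_id[!is.na(assignments$gene_id)]), ann)

  # Regulon
  calls <- call_sos_regulon(de$wt40, de$dlexa, de$dreca40, bound)
  tus <- collapse_to_tus(calls, ann)
  temporal <- classify_temporal(tus, de$wt20, de$wt40, ann)

  # Operator boxes on the called promoters
  boxes <- NULL; pwm <- NULL; pca <- NULL
  if (nrow(temporal) >= 5) {
    prom <- extract_promoters(ann, sim$genome, genes = temporal$promoter_gene)
    disc <- discover_boxes(prom)
    pwm <- disc$pwm
    boxes <- box_features(disc$boxes)
    boxes$class <- temporal$class[match(boxes$gene_id,
                                        temporal$promoter_gene)]
    if (nrow(boxes) >= 3 && length(unique(nchar(boxes$seq))) == 1) {
      pca <- onehot_pca(setNames(boxes$seq, boxes$gene_id))
    }
  }

  # Reporter kinetics: a strong (early-like) and a half-strength
  # (late-like) promoter construct
  kinetics <- NULL
  if (run_kinetics) {
    cfg_hi <- config
    cfg_lo <- config
    cfg_lo$beta_max <- config$beta_max / 2
    tr_hi <- simulate_traces(cfg_hi, n_cells,
                             seed = derive_seed(config$seed, "traces_hi"))
    tr_lo <- simulate_traces(cfg_lo, n_cells,
                             seed = derive_seed(config$seed, "traces_lo"))
    kinetics <- list(strong = analyze_traces(tr_hi$traces),
                     weak = analyze_traces(tr_lo$traces))
  }

  strength <- if (nrow(temporal) > 0) {
    strength_table(temporal, de$dlexa, de$wt40, sim$counts, ann,
                   sim$ori, G)
  } else NULL

  summary <- build_summary(de, calls, temporal, strength, assignments,
                           kinetics)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sostempo")),
    seed = config$seed,
    config = config[setdiff(names(config), "box_pwm")],
    n_cells = n_cells, chip_sigma = chip_sigma,
    stages = c(simulate = TRUE, diffexpr = TRUE, chip = TRUE,
               regulon = TRUE, lexabox = nrow(temporal) >= 5,
               kinetics = isTRUE(run_kinetics), strength = !is.null(strength)),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  bundle <- list(sim = sim, de = de, summits = summits,
                 assignments = assignments, bound = bound,
                 regulon = calls, tus = tus, temporal = temporal,
                 boxes = boxes, box_pwm = pwm, pca = pca,
                 kinetics = kinetics, strength = strength,
                 summary = summary, manifest = manifest)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' @noRd
build_summary <- function(de, calls, temporal, strength, assignments,
                          kinetics) {
  s <- list(
    n_induced = lapply(de, function(d) sum(d$induced)),
    n_members = sum(calls$member),
    n_tus = length(unique(temporal$tu_id)),
    n_early = sum(temporal$class == "early"),
    n_late = sum(temporal$class == "late")
  )
  if (!is.null(strength) && nrow(strength) >= 3) {
    ok <- complete.cases(strength[c("beta_proxy", "damage_lfc")])
    if (sum(ok) >= 3) {
      pr <- pearson_r2(strength$beta_proxy[ok], strength$damage_lfc[ok])
      s$r2_beta_damage <- pr$r2
      s$r_beta_damage <- pr$r
    }
    e <- strength$beta_proxy[strength$class == "early"]
    l <- strength$beta_proxy[strength$class == "late"]
    if (length(e) >= 2 && length(l) >= 2) {
      s$p_beta_early_vs_late <- compare_groups(e, l, "mann_whitney")$p
      s$p_rpkm_early_vs_late <- compare_groups(
        strength$basal_rpkm[strength$class == "early"],
        strength$basal_rpkm[strength$class == "late"], "mann_whitney")$p
    }
    early_g <- strength$promoter_gene[strength$class == "early"]
    late_g <- strength$promoter_gene[strength$class == "late"]
    if (length(early_g)) s$bound_frac_early <- fraction_bound(early_g, assignments)
    if (length(late_g)) s$bound_frac_late <- fraction_bound(late_g, assignments)
  }
  if (!is.null(kinetics)) {
    s$T_ind_strong <- kinetics$strong$induction$T_ind
    s$T_ind_weak <- kinetics$weak$induction$T_ind
  }
  s
}

#' Write the results bundle as plain-text tables plus a JSON manifest
#'
#' @param bundle result of [run_pipeline()]
#' @param outdir output directory (created if missing)
#' @return invisibly, the vector of written paths
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (nm in names(bundle$de)) wt(bundle$de[[nm]], paste0("de_", nm, ".tsv"))
  wt(bundle$regulon, "regulon.tsv")
  wt(bundle$tus, "tus.tsv")
  wt(bundle$temporal, "temporal.tsv")
  if (!is.null(bundle$boxes)) wt(bundle$boxes, "boxes.tsv")
  if (!is.null(bundle$strength)) wt(bundle$strength, "strength.tsv")
  if (!is.null(bundle$box_pwm)) {
    p <- file.path(outdir, "box_pwm.tsv")
    write.table(bundle$box_pwm$prob, p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
  }
  js <- file.path(outdir, "summary.json")
  jsonlite::write_json(bundle$summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, js, mf))
}

#' Render a small human-readable report from a results bundle
#'
#' Writes `report.txt` plus (best effort) diagnostic figures: a
#' volcano of the 40 min damage contrast, the strength scatter with
#' its r^2, and mean kinetic traces. Plot failures never affect the
#' text summary.
#'
#' @param bundle result of [run_pipeline()]
#' @param outdir output directory
#' @return invisibly, the report path
#' @export
make_report <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- bundle$summary
  lines <- c(
    "SOS temporal-hierarchy pipeline report",
    sprintf("regulon members: %d genes in %d TUs (%d early, %d late)",
            s$n_members, s$n_tus, s$n_early, s$n_late),
    sprintf("induced genes per contrast: %s",
            paste(sprintf("%s=%d", names(s$n_induced),
                          unlist(s$n_induced)), collapse = ", ")))
  if (!is.null(s$r2_beta_damage)) {
    lines <- c(lines, sprintf(
      "r^2 (derepression beta proxy vs damage log2FC): %.4f",
      s$r2_beta_damage))
  }
  if (!is.null(s$T_ind_strong)) {
    lines <- c(lines, sprintf(
      "T_ind strong promoter: %.1f min; weak promoter: %.1f min",
      s$T_ind_strong, s$T_ind_weak))
  }
  if (s$n_members == 0) lines <- c(lines, "regulon is empty")
  writeLines(lines, file.path(outdir, "report.txt"))

  tryCatch({
    pdf(file.path(outdir, "figures.pdf"), width = 6, height = 5)
    on.exit(dev.off(), add = TRUE)
    d <- bundle$de$wt40
    plot(d$log2FC, -log10(pmax(d$p, 1e-300)), pch = 16, cex = 0.5,
         col = ifelse(d$induced, "firebrick", "grey50"),
         xlab = "log2FC (damage 40 min)", ylab = "-log10 p",
         main = "Damage induction, 40 min")
    abline(v = 1, h = 2, lty = 2)
    if (!is.null(bundle$strength) && nrow(bundle$strength) >= 3) {
      st <- bundle$strength
      plot(st$beta_proxy, st$damage_lfc,
           col = ifelse(st$class == "early", "dodgerblue3", "firebrick"),
           pch = 16, xlab = "derepression log2FC (beta proxy)",
           ylab = "damage log2FC (40 min)",
           main = sprintf("r^2 = %.3f", s$r2_beta_damage))
      legend("topleft", legend = c("early", "late"), pch = 16,
             col = c("dodgerblue3", "firebrick"), bty = "n")
    }
    if (!is.null(bundle$kinetics)) {
      for (nm in names(bundle$kinetics)) {
        mt <- bundle$kinetics[[nm]]$mean
        plot(mt$t_min, mt$mean, type = "l", lwd = 2,
             xlab = "time (min)", ylab = "normalized intensity (a.u.)",
             main = paste("mean reporter trace:", nm))
        ti <- bundle$kinetics[[nm]]$induction
        if (!ti$censored) abline(v = ti$T_ind, lty = 2)
      }
    }
  }, error = function(e) {
    warning("figure rendering failed (report text unaffected): ",
            conditionMessage(e))
  })
  invisible(file.path(outdir, "report.txt"))
}
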