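#' Default planted operator model: a GTTC-N7-GTTC dyad PWM
#'
#' Probability matrix (4 x 15, rows A/C/G/T) describing the LexA operator
#' dyad: two strongly conserved GTTC half-sites separated by a 7 bp
#' unconstrained spacer. Half-site positions put probability
#' `consensus_p` on the consensus base and split the remainder evenly;
#' spacer columns are uniform.
#'
#' @param spacer_len spacer length between half-sites (bp)
#' @param consensus_p probability of the consensus base at half-site
#'   positions
#' @return 4 x (8 + spacer_len) probability matrix with rownames ACGT
#' @export
#' @examples
#' p <- default_box_pwm()
#' colSums(p)  # all 1
default_box_pwm <- function(spacer_len = 7L, consensus_p = 0.95) {
  stopifnot(spacer_len >= 1, consensus_p > 0.25, consensus_p <= 1)
  half <- c("G", "T", "T", "C")
  L <- 8L + spacer_len
  pwm <- matrix(0.25, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  off <- (1 - consensus_p) / 3
  for (i in seq_len(4)) {
    for (col in c(i, spacer_len + 4L + i)) {
      pwm[, col] <- off
      pwm[half[i], col] <- consensus_p
    }
  }
  pwm
}

#' Build a validated simulation configuration
#'
#' Central parameter object for the synthetic-data generator. Defaults
#' describe the world the downstream analysis assumes: a circular
#' bacterial chromosome carrying a minority of damage-inducible
#' (SOS) genes whose promoters hold one planted operator box, negative
#' binomial counts whose means follow LexA-repression logic across
#' genotypes and timepoints, Gaussian ChIP peaks over bound promoters,
#' and single-cell reporter traces produced by a repressor-decay /
#' Hill-repression / dilution kinetic model.
#'
#' Expression model (per gene g, condition c): counts ~ NB(mu, phi) with
#' Var = mu + phi mu^2. Non-SOS genes sit at `basal_mu` everywhere. SOS
#' genes sit at basal in untreated wild type and in recA-deleted cells
#' (no damage signalling), at basal * 2^beta in the repressor deletion,
#' and at basal * (1 + (2^beta - 1) * g(t)) in damage-treated wild type,
#' where the induction fraction g(t) differs between early and late
#' classes (`g_early`, `g_late` at 20 and 40 min).
#'
#' Kinetic model (per cell): repressor L(t) = L0 exp(-k_c t); promoter
#' activity a(t) = beta_cell / (1 + (L/K_d)^h); reporter
#' dF/dt = a - delta * F integrated by explicit Euler from the repressed
#' steady state; the observed, area-normalized intensity adds a
#' beta-independent cellular background `bg_au` and multiplicative
#' noise.
#'
#' @param genome_length circular genome size (bp)
#' @param n_genes total gene count
#' @param n_sos_genes number of damage-inducible (planted SOS) genes
#' @param fraction_early fraction of SOS genes in the early class
#' @param operon_fraction fraction of transcriptional units that are
#'   2-3 gene operons
#' @param basal_mu basal mean count per gene per sample
#' @param beta_early,beta_late ranges (log2 units) from which per-gene
#'   promoter strengths beta are drawn; the early range must lie
#'   strictly above the late range
#' @param g_early,g_late induction fractions at 20 and 40 min for the
#'   two temporal classes
#' @param phi negative binomial dispersion (Var = mu + phi mu^2)
#' @param n_replicates replicates per condition
#' @param box_pwm 4 x L probability matrix for the planted operator
#' @param box_offset_range range (bp, relative to CDS start, negative =
#'   upstream) for the planted box start position
#' @param lib_factor_range per-sample library-size factors are drawn
#'   uniformly from this range
#' @param lambda_bg ChIP background coverage (Poisson mean per bp)
#' @param peak_area,peak_sd reads per planted ChIP peak and its
#'   Gaussian spread (bp)
#' @param L0 initial repressor level (a.u.)
#' @param k_c repressor decay rate after damage (1/min)
#' @param K_d repression half-saturation (same units as L0)
#' @param h Hill coefficient of repression
#' @param beta_max population-mean maximal promoter activity
#'   (a.u./min) of the reporter construct
#' @param delta reporter dilution/decay rate (1/min)
#' @param bg_au beta-independent background intensity added to the
#'   observed trace (a.u.)
#' @param trace_noise_cv multiplicative observation noise CV
#' @param cell_cv_beta lognormal CV of the per-cell beta_max draw
#' @param dt Euler integration step (min)
#' @param t_obs observation interval of the recorded trace (min)
#' @param t_max trace duration (min)
#' @param seed master seed; stage seeds are derived from it
#' @return object of class `sim_config` (a validated list)
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, n_sos_genes = 10)
#' cfg$n_genes
sim_config <- function(genome_length = 400000L,
                       n_genes = 200L,
                       n_sos_genes = 30L,
                       fraction_early = 0.4,
                       operon_fraction = 0.2,
                       basal_mu = 100,
                       beta_early = c(3, 5),
                       beta_late = c(1.8, 2.8),
                       g_early = c(`20` = 0.8, `40` = 1.0),
                       g_late = c(`20` = 0.1, `40` = 0.7),
                       phi = 0.05,
                       n_replicates = 3L,
                       box_pwm = default_box_pwm(),
                       box_offset_range = c(-100L, -20L),
                       lib_factor_range = c(0.7, 1.3),
                       lambda_bg = 1,
                       peak_area = 2000,
                       peak_sd = 50,
                       L0 = 100,
                       k_c = 0.05,
                       K_d = 10,
                       h = 2,
                       beta_max = 50,
                       delta = 0.01,
                       bg_au = 1000,
                       trace_noise_cv = 0.05,
                       cell_cv_beta = 0.25,
                       dt = 0.1,
                       t_obs = 10,
                       t_max = 360,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    n_sos_genes = as.integer(n_sos_genes), fraction_early = fraction_early,
    operon_fraction = operon_fraction, basal_mu = basal_mu,
    beta_early = beta_early, beta_late = beta_late,
    g_early = g_early, g_late = g_late, phi = phi,
    n_replicates = as.integer(n_replicates), box_pwm = box_pwm,
    box_offset_range = as.integer(box_offset_range),
    lib_factor_range = lib_factor_range, lambda_bg = lambda_bg,
    peak_area = peak_area, peak_sd = peak_sd,
    L0 = L0, k_c = k_c, K_d = K_d, h = h, beta_max = beta_max,
    delta = delta, bg_au = bg_au, trace_noise_cv = trace_noise_cv,
    cell_cv_beta = cell_cv_beta, dt = dt, t_obs = t_obs, t_max = t_max,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      genome_length > 0, n_genes >= 1, n_sos_genes >= 0,
      n_sos_genes <= n_genes,
      fraction_early >= 0, fraction_early <= 1,
      operon_fraction >= 0, operon_fraction <= 1,
      basal_mu > 0, phi >= 0, n_replicates >= 1,
      L0 >= 0, k_c >= 0, K_d > 0, h > 0, beta_max > 0, delta >= 0,
      bg_au >= 0, trace_noise_cv >= 0, cell_cv_beta >= 0,
      dt > 0, t_obs >= dt, t_max > 0,
      lambda_bg >= 0, peak_area >= 0, peak_sd > 0,
      is.matrix(box_pwm), nrow(box_pwm) == 4,
      all(abs(colSums(box_pwm) - 1) < 1e-8)
    )
    if (n_sos_genes > 0 && min(beta_early) <= max(beta_late)) {
      stop("early beta range must lie strictly above the late range")
    }
  })
  invisible(cfg)
}
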