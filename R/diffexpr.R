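# Differential expression: median-of-ratios normalization, common
# NB dispersion, exact conditional test on group sums, BH-FDR.

#' Construct a count matrix with sample metadata
#'
#' @param counts genes x samples matrix of non-negative integers with
#'   gene ids as rownames and sample ids as colnames
#' @param samples data.frame with at least sample_id, genotype,
#'   treatment, timepoint, replicate; one row per column of `counts`
#' @return object of class `count_matrix`
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(rownames(counts)), !anyDuplicated(rownames(counts)),
            nrow(samples) == ncol(counts),
            all(c("sample_id", "genotype", "treatment", "timepoint",
                  "replicate") %in% names(samples)),
            identical(samples$sample_id, colnames(counts)),
            !anyNA(samples[c("genotype", "treatment", "timepoint")]))
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over reference genes
#' (genes with nonzero counts in every sample) of the ratio of that
#' sample's count to the gene's geometric-mean count; factors are then
#' rescaled to geometric mean 1.
#'
#' @param counts genes x samples matrix or a [count_matrix()]
#' @return positive numeric vector, one factor per sample
#' @export
#' @examples
#' m <- cbind(a = c(10, 100, 1), b = c(20, 200, 2), c = c(10, 100, 1))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m) # proportional to (1, 2, 1)
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    stop("no gene has nonzero counts in all samples; ",
         "size factors need at least one all-detected reference gene")
  }
  ref <- counts[ok, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  f <- apply(ref, 2, function(col) median(exp(log(col) - log_geo)))
  f / exp(mean(log(f)))
}

#' Common negative binomial dispersion by method of moments
#'
#' On size-factor-normalized counts, each gene's dispersion is
#' estimated as (pooled within-group variance - mean)/mean^2 and the
#' common dispersion is the median over genes, clipped below at 0.
#' Because the sampling distribution of a pooled variance is right
#' skewed, the raw median underestimates the dispersion (the median of
#' s^2 sits at qchisq(0.5, df)/df of its mean); the estimate is
#' corrected by inverting that relation at the median gene mean, which
#' restores type-I calibration of the downstream exact test while
#' keeping the outlier robustness of the median.
#'
#' @param counts genes x samples matrix or [count_matrix()]
#' @param groups factor/character of group labels, one per sample
#' @param sf size factors (computed from `counts` if missing)
#' @return single dispersion estimate phi >= 0
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  tab <- table(groups)
  if (!any(tab >= 2)) stop("need >= 2 replicates in at least one group")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  use <- names(tab)[tab >= 2]
  ssq <- matrix(0, nrow(counts), length(use))
  dfs <- numeric(length(use))
  gm <- matrix(0, nrow(counts), length(use))
  for (i in seq_along(use)) {
    cols <- which(groups == use[i])
    sub <- norm[, cols, drop = FALSE]
    gm[, i] <- rowMeans(sub)
    ssq[, i] <- rowSums((sub - gm[, i])^2)
    dfs[i] <- length(cols) - 1
  }
  pooled_var <- rowSums(ssq) / sum(dfs)
  mu <- as.vector(gm %*% (dfs + 1)) / sum(dfs + 1)
  keep <- mu > 0
  if (!any(keep)) stop("all genes have zero mean; cannot estimate dispersion")
  phi_g <- (pooled_var[keep] - mu[keep]) / mu[keep]^2
  m_raw <- median(phi_g)
  # chi-square median bias correction:
  # median(phi_g) ~ m*phi - (1-m)/mu with m = qchisq(0.5, df)/df
  df <- sum(dfs)
  m <- stats::qchisq(0.5, df) / df
  mu_typ <- median(mu[keep])
  max(0, (m_raw + (1 - m) / mu_typ) / m)
}

#' NB density of a sum of iid negative binomial replicates
#'
#' Sum of n iid NB(mean mu, dispersion phi) is NB(mean n mu,
#' dispersion phi/n); phi = 0 degenerates to Poisson.
#' @noRd
dnb_sum <- function(x, total_mean, n_rep, phi) {
  if (phi == 0) dpois(x, total_mean)
  else dnbinom(x, mu = total_mean, size = n_rep / phi)
}

#' Exact conditional test for a difference between two NB groups
#'
#' Counts are first brought to a common scale by dividing by their size
#' factors and rounding (pseudo-counts); the test then conditions on
#' the total of the two group sums. Under the null the two sums are
#' negative binomial with means proportional to their replicate numbers
#' and dispersion phi scaled by replicate number; the two-sided p-value
#' sums the probabilities of all outcome pairs no more likely than the
#' observed one (minimum-likelihood convention), normalized over all
#' pairs with the observed total.
#'
#' @param ya,yb integer count vectors for the two groups (one gene)
#' @param phi common NB dispersion
#' @param sf_a,sf_b size factors for the two groups (default 1)
#' @return two-sided p-value in \[0, 1\]
#' @export
#' @examples
#' nb_exact_test(c(10, 12), c(11, 11), phi = 0.1) # balanced, p = 1
#' nb_exact_test(c(100, 110), c(10, 12), phi = 0.05)
nb_exact_test <- function(ya, yb, phi, sf_a = rep(1, length(ya)),
                          sf_b = rep(1, length(yb))) {
  stopifnot(phi >= 0, length(sf_a) == length(ya), length(sf_b) == length(yb))
  sa <- sum(round(ya / sf_a))
  sb <- sum(round(yb / sf_b))
  N <- sa + sb
  if (N == 0) return(1)
  na <- length(ya); nb <- length(yb)
  mu1 <- N / (na + nb) # per-replicate null mean on the common scale
  a <- 0:N
  pa <- dnb_sum(a, na * mu1, na, phi)
  pb <- dnb_sum(N - a, nb * mu1, nb, phi)
  joint <- pa * pb
  obs <- joint[sa + 1]
  # tolerance absorbs floating-point asymmetry between (a,b) and (b,a)
  p <- sum(joint[joint <= obs * (1 + 1e-10)]) / sum(joint)
  min(1, max(0, p))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return q-values (monotone step-up adjustment), same length
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Parse a contrast such as "WT:MMC:40 vs WT:none:0"
#' @noRd
parse_contrast <- function(spec) {
  parts <- strsplit(spec, "\\s+vs\\s+")[[1]]
  if (length(parts) != 2) stop("contrast must be '<g>:<trt>:<t> vs <g>:<trt>:<t>'")
  parse_side <- function(x) {
    f <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(f) != 3) stop("bad contrast side: ", x)
    list(genotype = f[1], treatment = f[2], timepoint = as.integer(f[3]))
  }
  list(treated = parse_side(parts[1]), reference = parse_side(parts[2]),
       label = spec)
}

#' @noRd
select_samples <- function(samples, side) {
  which(samples$genotype == side$genotype &
          samples$treatment == side$treatment &
          samples$timepoint == side$timepoint)
}

#' Run one differential-expression contrast
#'
#' Normalizes the two groups with median-of-ratios size factors
#' (computed over the samples of the contrast), estimates a common
#' dispersion, applies the NB exact test per gene, adjusts with BH and
#' flags genes as induced at the standard thresholds (strict
#' log2FC > 1, p < 0.01, FDR < 0.1). log2FC uses a pseudo-count of 0.5
#' on normalized group means.
#'
#' @param cm a [count_matrix()]
#' @param contrast contrast string, e.g. `"WT:MMC:40 vs WT:none:0"`,
#'   sides being `genotype:treatment:timepoint`
#' @param lfc_cut,p_cut,q_cut induction thresholds (strict
#'   inequalities)
#' @param phi optional fixed dispersion; estimated from the contrast
#'   samples when `NULL`
#' @return data.frame (one row per gene): gene_id, contrast, log2FC,
#'   p, q, induced
#' @export
run_contrast <- function(cm, contrast, lfc_cut = 1, p_cut = 0.01,
                         q_cut = 0.1, phi = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  cn <- parse_contrast(contrast)
  ia <- select_samples(cm$samples, cn$treated)
  ib <- select_samples(cm$samples, cn$reference)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("contrast group with zero samples: ", contrast)
  }
  sub <- cm$counts[, c(ia, ib), drop = FALSE]
  sf <- size_factors(sub)
  sf_a <- sf[seq_along(ia)]
  sf_b <- sf[length(ia) + seq_along(ib)]
  groups <- rep(c("a", "b"), c(length(ia), length(ib)))
  if (is.null(phi)) phi <- estimate_dispersion(sub, groups, sf)
  norm <- sweep(sub, 2, sf, "/")
  mean_a <- rowMeans(norm[, seq_along(ia), drop = FALSE])
  mean_b <- rowMeans(norm[, length(ia) + seq_along(ib), drop = FALSE])
  log2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  p <- vapply(seq_len(nrow(sub)), function(g) {
    nb_exact_test(sub[g, seq_along(ia)], sub[g, length(ia) + seq_along(ib)],
                  phi, sf_a, sf_b)
  }, numeric(1))
  q <- bh_fdr(p)
  data.frame(
    gene_id = rownames(sub), contrast = cn$label,
    log2FC = log2fc, p = p, q = q,
    induced = log2fc > lfc_cut & p < p_cut & q < q_cut,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
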