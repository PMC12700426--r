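# Promoter-strength proxies and genomic context features: beta_max via
# derepression fold change, basal RPKM, ori distance, TU length,
# Pearson correlation with Fisher-z CI.

#' Promoter strength proxy from the derepression contrast
#'
#' The maximal promoter output in the absence of its repressor
#' (beta_max) is proxied by the log2 fold change of the repressor
#' deletion versus wild type without damage; this op is a provenance-
#' preserving pass-through of that contrast.
#'
#' @param de_dlexa DE table from [run_contrast()] for the repressor
#'   deletion vs wild type (no damage)
#' @param genes gene ids to report (default: all in the table)
#' @return named numeric vector of beta proxies
#' @export
beta_proxy <- function(de_dlexa, genes = de_dlexa$gene_id) {
  idx <- match(genes, de_dlexa$gene_id)
  if (anyNA(idx)) stop("genes missing from the derepression contrast: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  setNames(de_dlexa$log2FC[idx], genes)
}

#' Basal expression in RPKM
#'
#' RPKM = count / ((CDS length / 1e3) x (library size / 1e6)),
#' averaged over the selected (untreated wild-type) replicates.
#'
#' @param cm a [count_matrix()]
#' @param annotation annotation data.frame (CDS length = end - start)
#' @param samples sample ids to average over; default = untreated
#'   wild-type samples
#' @return named numeric vector of per-gene RPKM
#' @export
basal_rpkm <- function(cm, annotation,
                       samples = cm$samples$sample_id[
                         cm$samples$genotype == "WT" &
                           cm$samples$treatment == "none"]) {
  stopifnot(inherits(cm, "count_matrix"), length(samples) >= 1)
  sub <- cm$counts[, samples, drop = FALSE]
  libsize <- colSums(sub)
  if (any(libsize == 0)) stop("zero library size in sample(s): ",
                              paste(samples[libsize == 0], collapse = ", "))
  len <- setNames(annotation$end - annotation$start, annotation$gene_id)
  len <- len[rownames(sub)]
  stopifnot(all(len > 0), !anyNA(len))
  rpkm <- sweep(sub, 2, libsize / 1e6, "/") / (len / 1e3)
  rowMeans(rpkm)
}

#' Shortest circular distance from gene starts to the origin
#'
#' @param annotation annotation data.frame
#' @param ori 0-based origin position
#' @param genome_length circular genome length
#' @param genes gene ids (default: all)
#' @return named integer vector of distances in \[0, genome_length/2\]
#' @export
ori_distance <- function(annotation, ori, genome_length,
                         genes = annotation$gene_id) {
  starts <- cds_start0(annotation)[genes]
  if (anyNA(starts)) stop("unknown genes")
  setNames(circ_dist(unname(starts), ori, genome_length), genes)
}

#' Transcriptional unit length
#'
#' Span from the first CDS start to the last CDS end of the TU along
#' the coding strand, circular-aware.
#'
#' @param annotation annotation data.frame
#' @param tu_id TU identifier(s)
#' @return named numeric vector of spans (bp)
#' @export
tu_length <- function(annotation, tu_id = unique(annotation$tu_id)) {
  G <- attr(annotation, "genome_length")
  vapply(setNames(tu_id, tu_id), function(tid) {
    rows <- annotation[annotation$tu_id == tid, , drop = FALSE]
    if (nrow(rows) == 0) stop("unknown TU: ", tid)
    if (length(unique(rows$strand)) != 1) stop("TU with mixed strands: ", tid)
    if (rows$strand[1] == "+") {
      first <- rows$start[1]; last <- max(rows$end)
    } else {
      first <- min(rows$start); last <- rows$end[1]
    }
    span <- last - first
    if (!is.null(G)) span <- pmod(span, G)
    if (span <= 0) stop("non-positive TU span for ", tid)
    span
  }, numeric(1))
}

#' Pearson correlation with r^2, Fisher-z CI and p-value
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance)
#' @return list: r, r2, ci (95% Fisher-z interval on r), p (two-sided,
#'   t distribution), n
#' @export
#' @examples
#' pearson_r2(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))  # r = 0.8
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  n <- length(x)
  r <- cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, r2 = r^2, ci = ci, p = p, n = n)
}

#' Assemble the per-promoter strength table
#'
#' One row per regulon TU (represented by its promoter gene):
#' beta proxy, damage log2FC, basal RPKM, TU length, ori distance and
#' temporal class.
#'
#' @param temporal data.frame from [classify_temporal()]
#' @param de_dlexa,de_wt40 DE tables
#' @param cm a [count_matrix()]
#' @param annotation annotation data.frame
#' @param ori origin position (0-based)
#' @param genome_length circular genome length
#' @return data.frame with one row per classified TU
#' @export
strength_table <- function(temporal, de_dlexa, de_wt40, cm, annotation,
                           ori, genome_length) {
  genes <- temporal$promoter_gene
  rpkm <- basal_rpkm(cm, annotation)
  data.frame(
    tu_id = temporal$tu_id,
    promoter_gene = genes,
    class = temporal$class,
    beta_proxy = unname(beta_proxy(de_dlexa, genes)),
    damage_lfc = de_wt40$log2FC[match(genes, de_wt40$gene_id)],
    basal_rpkm = unname(rpkm[genes]),
    tu_length = unname(tu_length(annotation, temporal$tu_id)),
    ori_distance = unname(ori_distance(annotation, ori, genome_length,
                                       genes)),
    stringsAsFactors = FALSE
  )
}
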