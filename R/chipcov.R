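# ChIP coverage processing on circular per-bp tracks: rpm
# normalization, Gaussian smoothing, peak heights, summit calling,
# the +/-100 bp peak-to-gene rule, bound fractions, meta-profiles.

#' Normalize a raw coverage track to reads per million
#'
#' @param track per-bp numeric vector of raw coverage
#' @param total_reads total mapped reads of the library
#' @return track scaled by 1e6 / total_reads
#' @export
normalize_rpm <- function(track, total_reads) {
  if (total_reads <= 0) stop("total_reads must be > 0")
  track * 1e6 / total_reads
}

#' Circular Gaussian smoothing of a coverage track
#'
#' Convolution with a unit-mass Gaussian kernel truncated at 4 sigma
#' and renormalized; the convolution wraps around the circular genome.
#' `sigma = 0` is the identity.
#'
#' @param track per-bp numeric vector
#' @param sigma kernel standard deviation (bp)
#' @return smoothed track of identical length and total mass
#' @export
smooth_gaussian <- function(track, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(track)
  half <- ceiling(4 * sigma)
  kern <- dnorm(seq(-half, half), 0, sigma)
  kern <- kern / sum(kern)
  n <- length(track)
  if (2 * half + 1 > n) stop("kernel wider than the track")
  out <- stats::filter(track, kern, method = "convolution", sides = 2,
                       circular = TRUE)
  as.numeric(out)
}

#' Peak height over a gene's promoter window
#'
#' Maximum of the (smoothed) track within the promoter window of the
#' gene, `up` bp upstream to `down` bp downstream of the CDS start on
#' the coding strand.
#'
#' @param track per-bp numeric vector (normalized/smoothed upstream of
#'   this call)
#' @param annotation annotation data.frame
#' @param gene gene id
#' @param up,down window extent (bp)
#' @return maximum track value in the window
#' @export
promoter_peak_height <- function(track, annotation, gene,
                                 up = PROMOTER_UP, down = PROMOTER_DOWN) {
  i <- match(gene, annotation$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene)
  G <- length(track)
  c0 <- cds_start0(annotation)[[gene]]
  pos <- if (annotation$strand[i] == "+") {
    seq(c0 - up, c0 + down - 1L)
  } else {
    seq(c0 - down + 1L, c0 + up)
  }
  max(track[pmod(pos, G) + 1L])
}

#' Call peak summits as separated local maxima
#'
#' Local maxima of the (smoothed) circular track above `min_height`
#' are collected in descending height order; a summit is kept only if
#' it lies at least `min_sep` bp (circular distance) from every summit
#' already kept.
#'
#' @param track per-bp numeric vector (smoothed)
#' @param min_height minimum summit height
#' @param min_sep minimum circular distance between summits (bp)
#' @return data.frame: pos (0-based), height; ordered by height
#' @export
call_summits <- function(track, min_height, min_sep = 200L) {
  n <- length(track)
  left <- track[c(n, seq_len(n - 1))]
  right <- track[c(seq(2, n), 1)]
  is_max <- track >= left & track > right & track > min_height
  cand <- which(is_max)
  if (length(cand) == 0) {
    return(data.frame(pos = integer(), height = numeric()))
  }
  cand <- cand[order(track[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (length(kept) == 0 || all(circ_dist(p, kept, n) >= min_sep)) {
      kept <- c(kept, p)
    }
  }
  data.frame(pos = kept - 1L, height = track[kept])
}

#' Assign peak summits to genes by the +/-100 bp rule
#'
#' A summit is assigned to a gene when it falls within `margin` bp of
#' the anchor: the CDS start (`anchor = "start"`, the default) or
#' anywhere within the CDS span extended by `margin` on both sides
#' (`anchor = "span"`). Ties go to the gene with the nearest CDS
#' start.
#'
#' @param summits data.frame from [call_summits()]
#' @param annotation annotation data.frame
#' @param margin window half-width (bp)
#' @param anchor "start" or "span"
#' @param genome_length circular genome length (bp)
#' @return data.frame: pos, height, gene_id (NA when unassigned),
#'   dist_to_start (signed circular offset summit - CDS start)
#' @export
assign_summits <- function(summits, annotation, margin = 100L,
                           anchor = c("start", "span"),
                           genome_length) {
  anchor <- match.arg(anchor)
  stopifnot(margin >= 0)
  G <- genome_length
  cds <- cds_start0(annotation)
  out <- summits
  out$gene_id <- rep(NA_character_, nrow(summits))
  out$dist_to_start <- rep(NA_integer_, nrow(summits))
  for (i in seq_len(nrow(summits))) {
    p <- summits$pos[i]
    d_start <- circ_dist(p, unname(cds), G)
    ok <- if (anchor == "start") {
      d_start <= margin
    } else {
      vapply(seq_len(nrow(annotation)), function(g) {
        s <- annotation$start[g]; e <- annotation$end[g]
        lo <- pmod(s - margin, G)
        len <- (e - s) + 2L * margin
        pmod(p - lo, G) < len
      }, logical(1))
    }
    if (any(ok)) {
      j <- which(ok)[which.min(d_start[ok])]
      out$gene_id[i] <- annotation$gene_id[j]
      out$dist_to_start[i] <- d_start[j]
    }
  }
  out
}

#' Fraction of a gene set with an assigned peak
#'
#' @param genes character vector of gene ids (nonempty)
#' @param assignments data.frame from [assign_summits()]
#' @return percentage (0-100) of `genes` with at least one summit
#'   assigned
#' @export
fraction_bound <- function(genes, assignments) {
  if (length(genes) == 0) stop("empty gene set")
  100 * mean(genes %in% assignments$gene_id)
}

#' Coverage meta-profile around gene boundaries
#'
#' Per-gene coverage vectors oriented along the coding strand, anchored
#' at the CDS start and at the CDS end (two blocks, because CDS
#' lengths differ), each extending `flank` bp on both sides of its
#' anchor. Minus-strand genes are flipped so position axes always run
#' 5'->3'.
#'
#' @param track per-bp numeric vector
#' @param annotation annotation data.frame
#' @param genes gene ids to profile
#' @param flank flank width (bp)
#' @return list of two matrices (`start_anchored`, `end_anchored`),
#'   genes x (2 flank + 1) positions; column names are offsets
#'   relative to the anchor
#' @export
meta_profile <- function(track, annotation, genes = annotation$gene_id,
                         flank = 500L) {
  stopifnot(flank >= 1)
  G <- length(track)
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx)) stop("unknown genes: ", paste(genes[is.na(idx)], collapse = ", "))
  offs <- seq(-flank, flank)
  grab <- function(center, strand) {
    pos <- if (strand == "+") center + offs else center - offs
    track[pmod(pos, G) + 1L]
  }
  starts <- cds_start0(annotation)
  one <- function(which_anchor) {
    m <- t(vapply(idx, function(i) {
      anchor <- if (which_anchor == "start") {
        starts[[annotation$gene_id[i]]]
      } else if (annotation$strand[i] == "+") {
        annotation$end[i] - 1L
      } else {
        annotation$start[i]
      }
      grab(anchor, annotation$strand[i])
    }, numeric(length(offs))))
    dimnames(m) <- list(annotation$gene_id[idx], offs)
    m
  }
  list(start_anchored = one("start"), end_anchored = one("end"))
}
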