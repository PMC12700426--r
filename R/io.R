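# Readers/writers for the standard formats the pipeline exchanges:
# FASTA (Biostrings), GFF3/bedGraph (rtracklayer), TSV, JSON.
# Internal coordinates are 0-based half-open; files use the native
# convention of each format.

#' Write the genome as FASTA
#' @param genome character string
#' @param path output file
#' @param name sequence name
#' @export
write_genome_fasta <- function(genome, path, name = "chr") {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a single-sequence genome FASTA
#' @param path FASTA file
#' @return character string (first sequence)
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as.character(ss[[1]])
}

#' Write gene annotation as GFF3 (CDS features)
#'
#' Attributes carry locus_tag (gene id), tu_id and, when present, the
#' simulation truth columns is_sos/class/beta.
#'
#' @param annotation annotation data.frame (0-based half-open)
#' @param path output file
#' @param chrom sequence name
#' @export
write_annotation_gff3 <- function(annotation, path, chrom = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "sostempo"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$locus_tag <- annotation$gene_id
  S4Vectors::mcols(gr)$tu_id <- annotation$tu_id
  if ("is_sos" %in% names(annotation)) {
    S4Vectors::mcols(gr)$is_sos <- tolower(as.character(annotation$is_sos))
    S4Vectors::mcols(gr)$class <- annotation$class
    S4Vectors::mcols(gr)$beta <- annotation$beta
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a GFF3 annotation back into the internal data.frame
#' @param path GFF3 file
#' @return annotation data.frame (0-based half-open)
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  m <- S4Vectors::mcols(gr)
  ann <- data.frame(
    gene_id = m$locus_tag,
    tu_id = m$tu_id,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if ("is_sos" %in% names(m)) {
    ann$is_sos <- m$is_sos == "true"
    ann$class <- m$class
    ann$beta <- as.numeric(m$beta)
  }
  ann
}

#' Write a count matrix plus sidecar sample metadata
#' @param cm a [count_matrix()]
#' @param counts_path,meta_path output TSVs
#' @export
write_counts_tsv <- function(cm, counts_path, meta_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param counts_path,meta_path TSV files
#' @return a [count_matrix()]
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  df <- read.table(counts_path, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  meta <- read.table(meta_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Write a per-bp coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed; intervals are 0-based
#' half-open per the bedGraph convention.
#'
#' @param track per-bp numeric vector
#' @param path output file
#' @param chrom sequence name
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = starts + 1L,
                                                end = ends),
                               score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track into a per-bp vector
#' @param path bedGraph file
#' @param genome_length track length (bp)
#' @return numeric vector of length `genome_length`
#' @export
read_bedgraph <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- numeric(genome_length)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  v <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) track[s[i]:e[i]] <- v[i]
  track
}

#' Write single-cell traces as TSV
#' @param traces trace data.frame
#' @param path output file
#' @export
write_traces_tsv <- function(traces, path) {
  write.table(traces, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a traces TSV
#' @param path TSV with cell_id, t_min, intensity_au, area_px
#' @return trace data.frame
#' @export
read_traces_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
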