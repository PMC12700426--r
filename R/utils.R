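# Circular-coordinate helpers. Contract used throughout the package:
# genome positions are 0-based, half-open intervals [start, end), all
# arithmetic modulo the genome length.

#' Positive modulus
#' @noRd
pmod <- function(x, m) ((x %% m) + m) %% m

#' Extract a (possibly wrapping) substring from a circular sequence
#'
#' @param genome single character string, the full circular sequence
#' @param start0 0-based start position (may be negative or >= length)
#' @param len number of bases to extract
#' @return character string of length `len`
#' @noRd
circ_substr <- function(genome, start0, len) {
  G <- nchar(genome)
  stopifnot(len >= 0, len <= G)
  if (len == 0L) return("")
  s <- pmod(start0, G)
  if (s + len <= G) {
    substr(genome, s + 1L, s + len)
  } else {
    paste0(substr(genome, s + 1L, G), substr(genome, 1L, s + len - G))
  }
}

#' Write a (possibly wrapping) substring into a circular sequence
#' @noRd
circ_substr_set <- function(genome, start0, value) {
  G <- nchar(genome)
  len <- nchar(value)
  s <- pmod(start0, G)
  if (s + len <= G) {
    substr(genome, s + 1L, s + len) <- value
  } else {
    k <- G - s
    substr(genome, s + 1L, G) <- substr(value, 1L, k)
    substr(genome, 1L, len - k) <- substr(value, k + 1L, len)
  }
  genome
}

#' Shortest circular distance between two positions
#' @noRd
circ_dist <- function(a, b, G) {
  d <- pmod(abs(a - b), G)
  pmin(d, G - d)
}

#' Reverse complement of a DNA string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Derive a reproducible stage seed from a master seed
#'
#' Keeps derived seeds inside 32-bit integer range so they are valid
#' arguments to [set.seed()].
#' @noRd
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(pmod(as.numeric(master) * 48271 + h * 7919 + 12345, 2^31 - 1))
}

#' Sample-name builder shared by the simulator and the contrast parser
#' @noRd
sample_label <- function(genotype, treatment, timepoint, replicate) {
  sprintf("%s_%s_t%02d_r%d", genotype, treatment, timepoint, replicate)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Split a DNA string into a character vector of single bases
#' @noRd
str_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
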