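# Shared fixtures: tiny configs and hand-built annotations.

small_config <- function(seed = 1L, ...) {
  sim_config(genome_length = 120000L, n_genes = 60L, n_sos_genes = 12L,
             seed = seed, ...)
}

# A hand-built two-gene annotation on a small circular genome:
# gene A on the plus strand, gene B on the minus strand.
toy_annotation <- function() {
  data.frame(
    gene_id = c("geneA", "geneB"),
    tu_id = c("tuA", "tuB"),
    start = c(1000L, 3000L),
    end = c(1900L, 3600L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
}

random_genome <- function(n, seed = 42L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Null count matrix: two 3-replicate groups, no signal.
null_count_matrix <- function(n_genes, mu = 100, phi = 0.05, seed = 1L,
                              n_rep = 3L) {
  set.seed(seed)
  n_s <- 2L * n_rep
  counts <- matrix(
    if (phi == 0) rpois(n_genes * n_s, mu) else
      rnbinom(n_genes * n_s, mu = mu, size = 1 / phi),
    n_genes, n_s,
    dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                    sprintf("s%d", seq_len(n_s))))
  meta <- data.frame(
    sample_id = colnames(counts), genotype = "WT",
    treatment = rep(c("none", "MMC"), each = n_rep),
    timepoint = rep(c(0L, 40L), each = n_rep),
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Independent enumeration oracle for the conditional exact test:
# per-pair probabilities from the log-gamma NB formula written out by
# hand, a plain loop, explicit normalization.
oracle_exact_p <- function(sa, sb, na, nb, phi) {
  N <- sa + sb
  if (N == 0) return(1)
  lp <- function(x, mu, size) {
    if (phi == 0) return(x * log(mu) - mu - lgamma(x + 1))
    lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
      size * log(size / (size + mu)) + x * log(mu / (size + mu))
  }
  mu1 <- N / (na + nb)
  tot <- 0; obs <- NA; probs <- numeric(N + 1)
  for (a in 0:N) {
    la <- lp(a, na * mu1, na / phi)
    lb <- lp(N - a, nb * mu1, nb / phi)
    probs[a + 1] <- exp(la + lb)
  }
  obs <- probs[sa + 1]
  sum(probs[probs <= obs * (1 + 1e-10)]) / sum(probs)
}

# Plain one-hot encoding oracle (independent of the package encoder).
onehot_matrix_oracle <- function(seqs) {
  L <- nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  X <- matrix(0, length(seqs), 4 * L)
  for (i in seq_along(seqs)) {
    for (j in seq_len(L)) {
      b <- match(substr(seqs[i], j, j), bases)
      X[i, (j - 1) * 4 + b] <- 1
    }
  }
  X
}

# Minimum-likelihood two-sided exact binomial test (oracle for phi=0).
oracle_binom_p <- function(sa, N, pr) {
  d <- dbinom(0:N, N, pr)
  sum(d[d <= d[sa + 1] * (1 + 1e-10)])
}
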