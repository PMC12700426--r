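# Operator (LexA-box) discovery and scoring: promoter extraction,
# dyad-seeded one-occurrence-per-sequence EM, PWM log-odds scoring,
# box features, one-hot PCA and group comparisons.

PROMOTER_UP <- 200L
PROMOTER_DOWN <- 75L

#' Extract promoter windows on the coding strand
#'
#' For each gene the window runs from `up` bp upstream to `down` bp
#' downstream of the CDS start, reported 5'->3' on the coding strand
#' (minus-strand genes are reverse-complemented), wrapping across the
#' origin of the circular genome when needed.
#'
#' @param annotation annotation data.frame (gene_id, start, end,
#'   strand; 0-based half-open)
#' @param genome genome sequence as a single character string
#' @param up,down window extent around the CDS start (bp)
#' @param genes optional subset of gene ids (default: all)
#' @return named character vector of promoter sequences, length
#'   `up + down` each
#' @export
extract_promoters <- function(annotation, genome, up = PROMOTER_UP,
                              down = PROMOTER_DOWN,
                              genes = annotation$gene_id) {
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx)) stop("gene ids absent from annotation: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  cds <- cds_start0(annotation)
  out <- vapply(idx, function(i) {
    c0 <- cds[[annotation$gene_id[i]]]
    if (annotation$strand[i] == "+") {
      circ_substr(genome, c0 - up, up + down)
    } else {
      revcomp(circ_substr(genome, c0 - down + 1L, up + down))
    }
  }, character(1))
  setNames(out, annotation$gene_id[idx])
}

#' Build a PWM object from aligned sites
#'
#' @param sites character vector of equal-length sequences
#' @param pseudocount added per base per position
#' @param background length-4 base probabilities (A,C,G,T)
#' @return object of class `pwm`: list(prob, logodds (log2), background,
#'   pseudocount, consensus)
#' @export
build_pwm <- function(sites, pseudocount = 0.25,
                      background = rep(0.25, 4)) {
  stopifnot(length(sites) >= 1, length(unique(nchar(sites))) == 1)
  L <- nchar(sites[1])
  codes <- seq_codes(sites)
  counts <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(L)) counts[, j] <- tabulate(codes[, j], 4)
  pwm_from_counts(counts, pseudocount, background)
}

#' @noRd
pwm_from_counts <- function(counts, pseudocount, background) {
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  rownames(prob) <- DNA_BASES
  lo <- log2(prob / background)
  # consensus = per-position log-odds argmax, so it attains the maximal
  # achievable score by construction
  structure(list(prob = prob, logodds = lo,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount,
                 consensus = paste(DNA_BASES[apply(lo, 2, which.max)],
                                   collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm: length", ncol(x$prob), "consensus", x$consensus, "\n")
  invisible(x)
}

#' Encode equal-length sequences as a matrix of base codes 1..4
#' @noRd
seq_codes <- function(seqs) {
  m <- do.call(rbind, lapply(seqs, function(s) {
    code <- match(str_bases(s), DNA_BASES)
    if (anyNA(code)) stop("non-ACGT character in sequence: ", s)
    code
  }))
  m
}

#' Score a PWM at one position of a sequence
#'
#' Sum over motif positions of the log2 odds of the observed base
#' against the PWM background.
#'
#' @param pwm a `pwm` object (or plain 4 x L probability matrix, scored
#'   against a uniform background)
#' @param sequence character string (ACGT only)
#' @param start 1-based start of the scored window
#' @return numeric score; higher = closer to consensus
#' @export
score_box <- function(pwm, sequence, start = 1L) {
  if (!inherits(pwm, "pwm")) {
    pwm <- pwm_from_counts(pwm * 1000, 0, rep(0.25, 4))
  }
  L <- ncol(pwm$logodds)
  if (start < 1 || start + L - 1 > nchar(sequence)) {
    stop("window [", start, ", ", start + L - 1, "] outside sequence")
  }
  win <- substr(sequence, start, start + L - 1)
  code <- match(str_bases(win), DNA_BASES)
  if (anyNA(code)) stop("non-ACGT character in scored window: ", win)
  sum(pwm$logodds[cbind(code, seq_len(L))])
}

#' Scan half-site dyads GTTC-N_k-GTTC in one sequence
#' @noRd
dyad_hits <- function(seq, k_range, max_mm) {
  bases <- str_bases(seq)
  n <- length(bases)
  half <- c("G", "T", "T", "C")
  hits <- list()
  for (k in k_range) {
    L <- 8L + k
    if (n < L) next
    for (s in seq_len(n - L + 1L)) {
      mm1 <- sum(bases[s:(s + 3)] != half)
      if (mm1 > max_mm) next
      mm2 <- sum(bases[(s + 4 + k):(s + 7 + k)] != half)
      if (mm2 > max_mm) next
      hits[[length(hits) + 1L]] <- c(start = s, k = k)
    }
  }
  hits
}

#' Discover operator boxes by dyad-seeded OOPS-EM
#'
#' Stage 1 enumerates candidate windows matching the dyad
#' GTTC-N_k-GTTC (k in `k_range`, up to `max_mm` mismatches per
#' half-site) on both strands of every promoter; the most common k
#' fixes the motif length and the matching windows build the initial
#' PWM. Stage 2 refines the PWM by one-occurrence-per-sequence EM over
#' all window positions and both strands until the log-likelihood gain
#' drops below `tol` (or `max_iter`). The best-scoring window per
#' promoter is reported; promoters whose best score falls below
#' `score_floor` are reported box-less.
#'
#' @param promoters named character vector from [extract_promoters()]
#' @param k_range candidate spacer lengths
#' @param max_mm mismatches tolerated per half-site in the seed scan
#' @param pseudocount PWM pseudocount per base
#' @param score_floor minimum log2-odds score for a reported box
#' @param max_iter,tol EM stopping rule
#' @param up upstream extent of the promoter window (to convert window
#'   indices to CDS-relative offsets)
#' @return list: `pwm` (class `pwm`), `boxes` data.frame (gene_id,
#'   offset = box start relative to CDS start, strand relative to the
#'   coding strand, seq, score), `loglik` and `objective`
#'   per-iteration traces (the objective adds the Dirichlet
#'   pseudocount penalty and is the monotone quantity), `spacer_len`
#'   chosen k
#' @export
discover_boxes <- function(promoters, k_range = 5:9, max_mm = 1L,
                           pseudocount = 0.25, score_floor = 0,
                           max_iter = 50L, tol = 1e-4,
                           up = PROMOTER_UP) {
  if (length(promoters) < 5) stop("need at least 5 promoter sequences")
  rc <- vapply(promoters, revcomp, character(1))

  # background = promoter base composition, complement-symmetrized so
  # that forward and reverse-complement scans score identically
  all_codes <- unlist(lapply(promoters, function(s) match(str_bases(s), DNA_BASES)))
  if (anyNA(all_codes)) stop("non-ACGT character in promoters")
  bg <- tabulate(all_codes, 4)
  bg <- bg / sum(bg)
  bg <- (bg + rev(bg)) / 2 # A<->T, C<->G averaging

  # seed scan on both strands
  seeds <- list()
  for (i in seq_along(promoters)) {
    for (s in list(promoters[[i]], rc[[i]])) {
      for (h in dyad_hits(s, k_range, max_mm)) {
        seeds[[length(seeds) + 1L]] <-
          list(seq = substr(s, h["start"], h["start"] + 7 + h["k"]), k = h[["k"]])
      }
    }
  }
  if (length(seeds) == 0) {
    stop("no dyad seed matches found; consider relaxing max_mm or k_range")
  }
  ks <- vapply(seeds, `[[`, numeric(1), "k")
  k_best <- as.integer(names(which.max(table(ks))))
  L <- 8L + k_best
  init_sites <- vapply(seeds[ks == k_best], `[[`, character(1), "seq")
  pwm <- build_pwm(init_sites, pseudocount, bg)

  # precompute window code matrices per promoter and strand
  W <- nchar(promoters[[1]])
  stopifnot(all(nchar(promoters) == W), W >= L)
  n_pos <- W - L + 1L
  make_windows <- function(s) {
    code <- match(str_bases(s), DNA_BASES)
    do.call(cbind, lapply(seq_len(L), function(j) code[j:(j + n_pos - 1L)]))
  }
  fwd <- lapply(promoters, make_windows)
  rev_ <- lapply(rc, make_windows)
  log_bg <- log(bg)

  window_logratio <- function(codes, logp) {
    out <- numeric(nrow(codes))
    for (j in seq_len(L)) {
      out <- out + logp[codes[, j], j] - log_bg[codes[, j]]
    }
    out
  }

  loglik <- numeric(0)
  objective <- numeric(0) # loglik + Dirichlet pseudocount penalty
  for (iter in seq_len(max_iter)) {
    logp <- log(pwm$prob)
    counts <- matrix(0, 4, L)
    ll <- 0
    for (i in seq_along(promoters)) {
      r <- c(window_logratio(fwd[[i]], logp), window_logratio(rev_[[i]], logp))
      m <- max(r)
      z <- exp(r - m)
      ll <- ll + m + log(sum(z)) - log(2 * n_pos)
      z <- z / sum(z)
      zf <- z[seq_len(n_pos)]; zr <- z[n_pos + seq_len(n_pos)]
      for (j in seq_len(L)) {
        cf <- fwd[[i]][, j]; cr <- rev_[[i]][, j]
        for (b in 1:4) {
          counts[b, j] <- counts[b, j] + sum(zf[cf == b]) + sum(zr[cr == b])
        }
      }
    }
    loglik <- c(loglik, ll)
    objective <- c(objective, ll + pseudocount * sum(logp))
    pwm <- pwm_from_counts(counts, pseudocount, bg)
    if (iter > 1 && objective[iter] - objective[iter - 1] < tol) break
  }

  # best site per promoter under the final PWM
  lo <- pwm$logodds / log2(exp(1)) # natural-log for the scan below
  boxes <- lapply(seq_along(promoters), function(i) {
    score_nat <- function(codes) {
      out <- numeric(nrow(codes))
      for (j in seq_len(L)) out <- out + lo[codes[, j], j]
      out
    }
    sf <- score_nat(fwd[[i]]); sr <- score_nat(rev_[[i]])
    if (max(sf) >= max(sr)) {
      jj <- which.max(sf); strand <- "+"
      seq <- substr(promoters[[i]], jj, jj + L - 1L)
      off <- jj - 1L - up
      sc <- sf[jj]
    } else {
      jj <- which.max(sr); strand <- "-"
      seq <- substr(rc[[i]], jj, jj + L - 1L)
      # start of the window on the coding strand
      off <- (W - (jj + L - 1L)) - up
      sc <- sr[jj]
    }
    sc <- sc * log2(exp(1)) # back to log2 odds
    if (sc < score_floor) return(NULL)
    data.frame(gene_id = names(promoters)[i], offset = off, strand = strand,
               seq = seq, score = sc, stringsAsFactors = FALSE)
  })
  boxes <- Filter(Negate(is.null), boxes)
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(gene_id = character(), offset = integer(),
               strand = character(), seq = character(), score = numeric(),
               stringsAsFactors = FALSE)
  list(pwm = pwm, boxes = boxes, loglik = loglik, objective = objective,
       spacer_len = k_best)
}

#' Fill distance and spacer features of operator boxes
#'
#' Distance to CDS is the gap (bp) between the box 3' end and the CDS
#' start on the coding strand: 0 = the box ends immediately before the
#' CDS start; negative values (down to -`down`) indicate boxes
#' overlapping or downstream of the start. The spacer is the N_k core
#' between the two 4 bp half-sites.
#'
#' @param boxes data.frame from [discover_boxes()] (needs offset, seq)
#' @return `boxes` with distance_to_cds, spacer, spacer_len, spacer_gc
#'   columns added
#' @export
box_features <- function(boxes) {
  L <- nchar(boxes$seq)
  boxes$distance_to_cds <- -boxes$offset - L
  boxes$spacer <- substr(boxes$seq, 5L, L - 4L)
  boxes$spacer_len <- L - 8L
  boxes$spacer_gc <- vapply(boxes$spacer, function(s) {
    b <- str_bases(s)
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
  boxes
}

#' PCA of one-hot-encoded box sequences
#'
#' Each box is encoded as a 4L-long one-hot vector, columns are
#' centred, and the scores/variances come from the SVD of the centred
#' matrix.
#'
#' @param box_seqs character vector (>= 3) of equal-length sequences
#' @return list: `scores` (boxes x components), `var_explained`
#'   (fractions summing to 1), `degenerate` (TRUE when all boxes are
#'   identical and there is no variance to decompose)
#' @export
onehot_pca <- function(box_seqs) {
  if (length(box_seqs) < 3) stop("need at least 3 boxes for PCA")
  stopifnot(length(unique(nchar(box_seqs))) == 1)
  codes <- seq_codes(box_seqs)
  L <- ncol(codes)
  X <- matrix(0, length(box_seqs), 4L * L)
  for (j in seq_len(L)) {
    X[cbind(seq_along(box_seqs), (j - 1L) * 4L + codes[, j])] <- 1
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    return(list(scores = matrix(0, length(box_seqs), 1),
                var_explained = NA_real_, degenerate = TRUE))
  }
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- names(box_seqs)
  list(scores = scores,
       var_explained = sv$d[keep]^2 / sum(sv$d^2),
       degenerate = FALSE)
}

#' Compare a feature between two groups
#'
#' Student's unpaired t test (pooled variance) or the Mann-Whitney U
#' test. The U test uses the exact permutation null (midrank
#' convention, two-sided by deviation of U from its null mean) when the
#' smaller group has <= 8 observations and the enumeration is feasible;
#' otherwise a normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b numeric vectors (each length >= 2)
#' @param method "t_unpaired" or "mann_whitney"
#' @return list: statistic, p, method
#' @export
compare_groups <- function(a, b, method = c("t_unpaired", "mann_whitney")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (method == "t_unpaired") {
    if (var(a) + var(b) == 0) stop("zero variance in both groups")
    tt <- t.test(a, b, var.equal = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                method = "t_unpaired"))
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_from <- function(ra_sum) ra_sum - na * (na + 1) / 2
  u_obs <- u_from(sum(r[seq_len(na)]))
  mu <- na * nb / 2
  if (min(na, nb) <= 8 && choose(n, min(na, nb)) <= 5e5) {
    k <- min(na, nb)
    sets <- combn(n, k)
    sums <- colSums(matrix(r[sets], nrow = k))
    if (k == na) {
      devs <- abs(u_from(sums) - mu)
    } else { # enumerate the smaller group b; U_a = na*nb - U_b
      devs <- abs(na * nb - (sums - nb * (nb + 1) / 2) - mu)
    }
    p <- mean(devs >= abs(u_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-z))
  }
  list(statistic = u_obs, p = p, method = "mann_whitney")
}
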