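---
title: "Methods: temporal hierarchy analysis of the bacterial SOS regulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal hierarchy analysis of the bacterial SOS regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sostempo)
```

# The analysis in one paragraph

Upon DNA damage, RecA filaments stimulate auto-cleavage of the LexA
repressor and the SOS regulon de-represses — early promoters within
~20 minutes, late ones after ~40. `sostempo` reconstructs this
hierarchy from four ingredients: genotype × treatment × timepoint count
matrices (wild type, ΔlexA, ΔrecA; untreated and damage-treated),
repressor ChIP coverage, promoter sequence, and single-cell reporter
traces. Every stage also has a seeded synthetic generator so the whole
chain runs and is tested without external data.

# Differential expression

## Model and test

Counts are modeled negative binomial with the mean/dispersion
parameterization Var = μ + φμ². Two groups are compared by an exact
conditional test on their group sums: counts are first divided by
size factors and rounded ("pseudo-counts"), the two group sums are
conditioned on their total, under the null each sum is NB with mean
proportional to its replicate number and dispersion φ/n, and the
two-sided p-value adds up the probabilities of all outcome pairs no
more likely than the observed one (minimum-likelihood convention),
normalized over the conditioning total. With φ = 0 this reduces
exactly to the minimum-likelihood exact binomial test, which the test
suite asserts to 1e-12 alongside a brute-force enumeration oracle.

A gene is *induced* when log₂FC > 1 **and** p < 0.01 **and**
FDR < 0.1, all inequalities strict: a gene at log₂FC = 0.95 with an
arbitrarily small p is not induced. log₂FC is computed on normalized
group means with a pseudo-count of 0.5 so zero-count genes stay
finite.

## Normalization

Median-of-ratios size factors (per sample: the median over
all-detected genes of the ratio to the gene's geometric mean),
rescaled to geometric mean 1. This is deliberately simpler than the
TMM normalization an edgeR-based analysis would use; on data without
strong composition bias the two behave equivalently, and
median-of-ratios is fully specified in a dozen lines. Note one
consequence: multiplying a single sample by a constant perturbs the
common pseudo-count scale by the 1/S-th power of that constant, so
p-values after re-estimating factors are close but not bit-identical;
exact invariance holds when the known factor is supplied directly to
`nb_exact_test()`.

## Dispersion

A single common dispersion: per gene, on normalized counts,
φ_g = (pooled within-group variance − mean)/mean², summarized by the
median over genes and clipped at zero. The raw median is biased low —
a pooled variance is right-skewed, its median sits at
qchisq(0.5, df)/df of its mean — and with 3 + 3 replicates the
deficit is ~20%, enough to visibly inflate the null rate of p < 0.01.
We therefore invert that relation at the median gene mean
(`estimate_dispersion()`); with the correction the measured null
fraction of p < 0.01 is statistically indistinguishable from 0.01
(acceptance test 2). The median (rather than the mean) of φ_g is kept
because it is robust to the minority of strongly differential genes,
whose pooled variance mixes two different means and overstates φ.
Tagwise/empirical-Bayes dispersion is intentionally out of scope.

# Regulon calling and temporal classes

Membership is the conjunction of four Booleans: induced in damaged
wild type at 40 min; de-repressed in ΔlexA without damage; *not*
induced in ΔrecA under damage; repressor-bound at the promoter. Genes
that cannot display de-repression for technical reasons (e.g. deleted
in the ΔlexA strain) are passed as explicit overrides with a recorded
reason — never hard-coded names. Criteria use the 40-min contrast;
"induced at 20 min" uses the identical threshold triple.

Members collapse to transcriptional units (TUs); the TU's promoter
gene is its first gene in transcription direction, where
promoter-proximal operators sit. A TU is **early** if any member gene
is induced at 20 min, **late** if induction appears only at 40 min;
TUs induced at neither are dropped with a warning. Relaxing any
threshold can only grow the member set (monotonicity is
property-tested).

# Operator (LexA-box) discovery and scoring

Promoter windows run 200 bp upstream to 75 bp downstream of the CDS
start, extracted 5′→3′ on the coding strand of the circular genome
(all internal coordinates are 0-based, half-open, modulo genome
length). Discovery replaces a generic motif finder with a fixed,
testable two-stage algorithm:

1. **Dyad seeding**: enumerate windows matching GTTC-N_k-GTTC
   (k ∈ 5..9, ≤1 mismatch per half-site) on both strands; the modal k
   fixes the motif length and the matches build the initial PWM
   (pseudocount 0.25 per base; background = promoter base
   composition, complement-symmetrized so both strands score
   identically).
2. **OOPS-EM**: one-occurrence-per-sequence expectation maximization
   over all window positions and both strands, stopping when the
   pseudocount-penalized objective gains < 1e-4 or after 50
   iterations. The penalized objective (log likelihood plus the
   Dirichlet term matching the pseudocount update) is the monotone
   quantity; the raw likelihood alone is not guaranteed monotone
   under a pseudocounted M-step, which is why both traces are
   returned.

Each promoter reports its best-scoring window; a configurable score
floor (default 0 log₂-odds) lets genuinely box-less promoters come
back empty. Scores are per-position log₂-odds sums against the
background; the PWM's consensus is defined as the per-position
log-odds argmax, so the consensus string attains the maximal
achievable score by construction (with a non-uniform background the
probability argmax would not guarantee this). Box features follow a
fixed convention: distance-to-CDS is the gap between the box 3′ end
and the CDS start on the coding strand (0 = immediately adjacent,
negative down to −75 for boxes overlapping the start), the spacer is
the N_k core, spacer GC its G+C fraction. The sequence PCA one-hot
encodes boxes (4L columns), centers, and takes the SVD; all-identical
boxes are reported as a degenerate case rather than an error.

Group comparisons use Student's unpaired t (pooled variance) or
Mann–Whitney U. The U test enumerates the exact permutation null
(midrank ties, two-sided by deviation of U from its null mean) when
the smaller group has ≤8 observations and the enumeration stays under
5×10⁵ subsets, else a normal approximation with tie and continuity
corrections; the exact path reproduces hand-enumerated cases like
U = 0, p = 2/20 for (1,2,3) vs (4,5,6).

# ChIP coverage

Tracks are per-bp vectors over the circular genome: rpm normalization
(×10⁶/total reads), Gaussian smoothing by circular convolution with a
unit-mass kernel truncated at 4σ and renormalized (so smoothing
conserves mass and commutes with rpm scaling to machine precision),
promoter peak heights as the window maximum, and a summit caller that
keeps local maxima above a threshold in descending height order with
a greedy minimum-separation rule — a deliberate, fully specified
replacement for an external peak caller. Summits attach to genes when
within ±100 bp of the CDS start (nearest start breaks ties); a
`span` anchor option extends the window around the whole CDS instead,
for users who prefer the laxer reading of "within ±100 bp of the
CDS". Meta-profiles report start- and end-anchored blocks separately
because CDS lengths differ; minus-strand genes are flipped so axes
always run 5′→3′.

# Reporter kinetics

Traces are area-normalized (intensity/area per frame), averaged over
cells sharing one time grid (resampling is out of scope and a grid
mismatch is an error), and fitted with the 4-parameter logistic
F(t) = b + A/(1 + exp(−r(t − t₀))). The baseline b is included
because pre-damage fluorescence is nonzero. Fitting is bounded
least-squares (b, A ≥ 0, 0 < r ≤ 10) from a data-driven start
(b = min, A = range, t₀ = half-rise time, r from the 25–75% rise
span) plus four deterministically seeded multiplicative
perturbations, keeping the best SSE; values are pre-scaled to unit
maximum so the fit is exactly equivariant under intensity rescaling.
A fit "converges" only when R² > 0.95 (configurable), and that gate
censors the downstream statistic.

**T_ind** is the time the *fitted* curve reaches twice the *observed*
mean initial intensity (anchoring the threshold to data at t = 0, not
to the fitted baseline). It has a closed form, with explicit
censoring: plateau below threshold ("threshold never reached"),
unconverged fit ("poor fit"), and a clamped-to-zero boundary when the
crossing precedes t = 0; censored-but-rising profiles still report
the time of maximal fitted slope so near-threshold constructs remain
comparable. CV is the sample SD over the mean.

# Promoter strength

β_max is proxied by the ΔlexA-vs-WT log₂FC without damage — a
pass-through of that contrast with provenance, summarized per TU by
its promoter gene. Basal RPKM uses CDS length (a config choice; TU
length would be the alternative) over untreated wild-type samples.
ori distance is the shorter circular arc from the CDS start; TU
length spans first CDS start to last CDS end, circular-aware. The
headline statistic is Pearson r² between β proxy and damage log₂FC
with a Fisher-z 95% CI on r; both r and r² are reported because a CI
printed for such analyses can refer to either scale and the two are
easy to conflate.

# The synthetic world

`sim_config()` states the generated world once; the defaults are the
conditions the analysis assumes, not dials:

* **Design**: 200 genes (30 SOS) on a 400 kb circular genome;
  singleton TUs plus 20% operons of 2–3 genes; 3 replicates of six
  conditions (WT untreated/20 min/40 min damage, ΔlexA untreated,
  ΔrecA untreated/40 min damage); library factors uniform on
  [0.7, 1.3].
* **Counts**: NB with φ = 0.05 and basal mean 100. SOS genes sit at
  basal × 2^β in ΔlexA, at basal in untreated WT and in ΔrecA
  (no damage signalling), and at basal × (1 + (2^β − 1)·g(t)) in
  damaged WT, with induction fractions g(20) = 0.8, g(40) = 1.0
  (early) and g(20) = 0.1, g(40) = 0.7 (late) — chosen so early genes
  cross the induction thresholds at 20 min and late genes only at
  40 min, which is exactly what the temporal classifier must detect.
  β is drawn per TU: early U(3, 5), late U(1.8, 2.8); the early range
  sits strictly above the late range so ordering questions are
  well-posed.
* **Boxes**: one operator per SOS TU, sampled from a dyad PWM with
  95% consensus probability at the eight GTTC half-site positions
  (functional operators keep their half-sites nearly intact — that is
  what makes GTTC-N₇-GTTC a consensus; at much lower conservation a
  sizable fraction of planted boxes would carry ≥2 broken half-site
  bases and be unrecoverable by *any* scanner, which describes a
  different biology than a bound regulon), planted 20–100 bp upstream
  of the CDS start on the coding strand.
* **Coverage**: Poisson background (1 read/bp) plus 2000 reads per
  bound promoter spread multinomially under a Gaussian (σ = 50 bp)
  centred on the planted box — so mass recounts exactly and summits
  land near box centres.
* **Traces**: per cell, β_cell is lognormal around β_max = 50 a.u./min
  (CV 0.25); repressor L(t) = L0·e^(−k_c t) with L0/K_d = 10 and
  k_c = 0.05/min (repression releases ~46 min after damage); activity
  follows a Hill law (h = 2); the reporter integrates
  dF/dt = a − δF (δ = 0.01/min, stable-protein dilution) by explicit
  Euler at dt = 0.1 min from the repressed steady state, against
  which a closed-form oracle bounds the integration error at 1%.
  The observed area-normalized intensity adds a β-independent
  cellular background of 1000 a.u. and 5% multiplicative noise; the
  recorded intensity channel multiplies by a slowly growing area.
  The background deserves emphasis: without a β-independent term the
  entire trajectory scales linearly with β_max and the
  doubling-of-initial-mean statistic is *mathematically invariant* to
  promoter strength; with a realistic autofluorescence floor
  (comparable to the repressed signal, giving the observed ~3–5×
  dynamic range over 6 h), stronger promoters reach doubling sooner,
  which is the phenomenon under study.

What the generator does **not** emulate: read-level sequencing noise,
composition bias between libraries, operon-internal promoters,
replication-associated gene dosage, cell division and lineage
structure in traces, photobleaching, or peak shape asymmetries. A
green test suite therefore establishes the *logic* of the pipeline
(criteria conjunctions, conventions, estimators, recovery under the
stated noise), not robustness to every artifact of real data.

# Numerical conventions and degenerate inputs

* Coordinates 0-based half-open, circular; all extraction helpers
  wrap across the origin.
* Exact-test tie comparison uses a 1 + 1e-10 relative tolerance so
  mathematically tied outcome pairs are not split by floating-point
  asymmetry; p is clamped to [0, 1]; total 0 gives p = 1.
* Zero-variance inputs: flat trace → degenerate SST → unconverged
  fit → censored; both-groups-constant t test → error; all-identical
  boxes → degenerate PCA flag.
* Summit ties at plateau edges resolve to the left-most position of
  the plateau (strictly-greater-than-next, at-least-previous rule);
  assignment ties go to the nearest CDS start.
* Seeds: every generator takes an explicit seed derived from the
  master seed by a fixed integer hash, kept below 2³¹; identical
  seeds give byte-identical outputs.

# Known limitations

* The common dispersion ignores gene-wise variation; severe
  mean-dispersion trends in real data would call for edgeR/DESeq2.
* The kinetic model is a stand-in capturing the β_max-ordering
  mechanism, not a fitted model of any real strain; absolute T_ind
  values should not be compared across packages.
* The motif machinery assumes a single fixed-length dyad per
  promoter (best-scoring box kept when several occur) and rejects
  non-ACGT characters rather than handling ambiguity codes.
* The summit caller is threshold-based and intentionally simple;
  enrichment modeling against an input track is out of scope.
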