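# sostempo

Tools for dissecting the **temporal hierarchy of the bacterial SOS
response** from multi-genotype expression data, operator-motif analysis,
ChIP coverage, and single-cell reporter kinetics. The motivating system
is *Caulobacter crescentus*: upon DNA damage, RecA-stimulated
auto-cleavage removes the LexA repressor and de-represses a regulon of
damage-response genes — but not all at once. Some promoters fire within
20 minutes ("early"), others only later ("late"), and a promoter's
intrinsic maximal output (its strength, β_max) is a strong predictor of
when it fires.

The package is aimed at microbial genomicists who want a fully
specified, reproducible version of this analysis that runs end-to-end
on simulated data (no downloads) and whose individual stages can be
pointed at real count tables, coverage tracks, and trace tables.

## What it computes

**Regulon calling.** A gene is an SOS-regulon member when it is

1. induced in damaged wild type at 40 min (log₂FC > 1, p < 0.01,
   FDR < 0.1, all strict),
2. de-repressed in a ΔlexA background without damage,
3. recA-dependent (NOT induced in ΔrecA under damage), and
4. bound by LexA at its promoter (ChIP summit within ±100 bp of the
   CDS start).

P-values come from a conditional negative-binomial exact test on group
sums (NB mean/dispersion parameterization, Var = μ + φμ²; two-sided by
minimum-likelihood mass summation), with median-of-ratios
normalization, a bias-corrected moment estimate of the common
dispersion, and Benjamini–Hochberg FDR. Members are collapsed to
transcriptional units and classified **early** (induced at 20 min) or
**late** (induced at 40 min only).

**Operator boxes.** Promoter windows (200 bp upstream to 75 bp
downstream of the CDS start) are scanned for the dyad consensus
GTTC-N₇-GTTC; a dyad-seeded one-occurrence-per-sequence EM refines a
PWM, every promoter gets its best-scoring box (log₂-odds score), plus
distance-to-CDS, spacer length/GC features and a one-hot PCA.

**Kinetics.** Area-normalized single-cell fluorescence traces are
averaged, fitted with a 4-parameter logistic
F(t) = b + A/(1 + e^{−r(t−t₀)}) (R² > 0.95 gate), and summarized by the
induction time **T_ind** — the time at which the fitted mean reaches
twice its initial value — with explicit censoring rules, plus the
coefficient of variation across cells.

**Promoter strength.** β_max is proxied by the ΔlexA-vs-WT log₂ fold
change without damage; the package correlates it with damage
induction (Pearson r² with a Fisher-z CI) and compares early vs late
distributions (exact Mann–Whitney for small groups), alongside basal
RPKM, TU length, and circular ori distance.

**Synthetic data.** `sim_config()` + `simulate_sos_dataset()` generate
a circular annotated genome with operons, planted operator boxes,
negative-binomial counts following LexA-repression logic across
genotypes/timepoints, Gaussian-peak coverage tracks, and
kinetic-model fluorescence traces — each stage seeded and
deterministic, so the whole analysis is testable offline.

## Worked example

```r
library(sostempo)
bundle <- run_pipeline(sim_config(seed = 1))
bundle$summary
```

With the default configuration (200 genes, 30 planted SOS genes, 3
replicates, dispersion 0.05) this prints, among other entries:

```
members: 30  TUs: 25  early: 10  late: 15
induced wt20: 13  wt40: 30
r2: 0.9456   p(beta early > late): 7.3e-05
T_ind strong 69.6  weak 102.6
```

Reading: all 30 planted SOS genes (25 transcriptional units) are
recovered with no false positives; 13 genes are already induced at
20 min (the early wave) and all 30 at 40 min; the de-repression fold
change (β_max proxy) explains ~95% of the variance in damage
induction across regulon promoters, and early promoters have
significantly higher β_max than late ones. The simulated reporter with
twice the promoter strength doubles its initial fluorescence ~33 min
sooner (T_ind 69.6 vs 102.6 min) — the single-cell signature of the
same hierarchy.

Per-promoter tables live in `bundle$strength`, `bundle$boxes`,
`bundle$temporal`; `write_bundle(bundle, "out/")` writes everything as
TSV/JSON and `make_report(bundle, "out/")` adds a text report and
diagnostic figures. A shell entry point is included at
`inst/scripts/run_pipeline.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full synthetic pipeline from scratch with the given seed
(simulation → differential expression → ChIP processing → regulon →
boxes → kinetics → strength), logs the headline numbers to stderr and
writes the machine-readable result to `--out`.
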