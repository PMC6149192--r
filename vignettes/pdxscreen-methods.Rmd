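---
title: "Methods: PDX genomics and the plasma CCND1/CDKN2A biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDX genomics and the plasma CCND1/CDKN2A biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxscreen)
```

# Scope and model

`pdxscreen` implements the computational core of an integrated
patient-derived xenograft (PDX) genomics workflow for nasopharyngeal
carcinoma (NPC) and the liquid-biopsy biomarker it motivates. PDX tumors
mix human tumor cells with mouse stroma, so sequencing reads must first be
deconvolved by origin; per-gene copy number is then estimated from exome
read density against a panel of normal white-blood-cell (WBC) samples;
somatic variants are filtered and summarized as a 12-class substitution
spectrum; treated-vs-control transcriptomes are compared by RPKM fold
change; and, on the clinical side, plasma cell-free DNA (cfDNA) copy
numbers of *CCND1* and *CDKN2A* are quantified by qPCR and their ratio is
regressed on log10 EBV DNA load to classify CDK4/6-inhibitor candidates.

Every input the pipeline consumes can be generated by the seeded
simulation layer, which plants known truth (copy numbers, read origins,
substitution spectra, regression coefficients, fold changes) so that each
estimator can be validated by parameter recovery.

# Read deconvolution

The origin filter is a canonical k-mer containment classifier
(`kmer_index()`, `classify_reads()`): a read is scored by how many of its
k-mers occur in the human and in the mouse reference, and called for the
genome leading by at least `margin` k-mers. This replaces a two-pass
alignment filter because the scientific contract is binary — keep
human-origin reads, discard mouse-origin reads — not an alignment
algorithm. Defaults are k = 15 and margin = 1: at the human–mouse
coding-sequence divergence the simulator emulates (10% per base), a
100-bp read from one genome contains essentially no intact 15-mers from
the other, while margin 1 prevents ties from passing silently. Reads
with no score lead either way are *ambiguous*, a class the underlying
protocol never defines; they are set aside and counted rather than
assigned, which is conservative for downstream copy-number work. With
identical references every read is ambiguous by construction.

# Read-density copy number

For gene $g$ with total (merged) exon length $L_g$ and unique-read count
$c_g$, the read density is $d_g = c_g / L_g$. The panel baseline is the
per-gene mean density over normal-karyotype WBC samples, and

$$\widehat{\mathrm{CN}}(g) \;=\; \pi_g \,
\frac{d_g^{\mathrm{tumor}} / \bar d^{\mathrm{tumor}}}
     {d_g^{\mathrm{normal}} / \bar d^{\mathrm{normal}}},$$

where $\pi_g$ is the baseline ploidy (2 autosomal, 1 on X/Y — all modeled
samples are male; a female mode is rejected explicitly rather than
mishandled) and $\bar d$ is the sample's genome-wide mean density. The
division by $\bar d$ is a library-size normalization: without it a deeper
tumor library would inflate every copy number, and with it the profile is
exactly invariant to rescaling any sample's counts. It assumes the bulk of
the exome is copy-neutral; a genome where most genes are altered would
bias all estimates by the mean alteration. Genes whose baseline density
is zero cannot normalize anything and are omitted with a message, not
imputed. Input counts must already be unique-read counts; the package does
not inspect alignments.

Gain/loss calls use absolute thresholds on the autosomal scale (defaults:
gain at $\ge 3$, loss at $\le 1$ — a one-copy change from diploid),
scaled by $\pi_g/2$ for sex chromosomes, with closed boundaries. Because
the defaults sit exactly at copy numbers 1 and 3, an estimate for a gene
truly at one of those values falls on either side of the threshold with
roughly equal probability under count noise; the tests therefore require
correct calls only for events strictly beyond a threshold and forbid
wrong-direction calls at the boundary.

Profile concordance (`cn_correlation()`) is the Pearson correlation of
$\log_2(\mathrm{CN} + 0.01)$ over shared genes. The pseudocount keeps
homozygous deletions finite on the log scale; 0.01 is two orders of
magnitude below a single copy, so it does not distort non-zero values.

# Amplicon panel

The panel preprocessing applies two stated quality rules to the control
samples: amplicons whose mean count is at or below the empirical 5th
percentile of detectable (nonzero-mean) amplicons are removed, as are
amplicons with coefficient of variation $\ge 0.3$. The CV uses the sample
(n−1) standard deviation across control samples — the protocol does not
say whether variation is over samples or replicates, and across-samples is
the interpretation that the available data structure supports. The
percentile uses R's default linear-interpolation quantile with ties at the
threshold removed. A percentile rule re-applied to its own survivors
re-estimates the cut and removes another ~5%, so this is by nature a
single-pass filter; the CV rule, in contrast, reaches a fixpoint after one
pass.

Primer-pool bias is corrected by equalizing pool medians within each
sample. Two targets are offered: the sample's global median (default;
keeps counts in familiar units) and `"relative"` (each pool divided by its
own median), the scale-free convention under which gene-level copy numbers
are invariant to sequencing depth. Gene copy number is twice the median
over the gene's amplicons of the tumor/mean-normal count ratio —
median-of-ratios is robust to single-amplicon dropouts and replaces a full
segmentation model, which gene-level biomarker logic does not need.

# Somatic variants

Records are retained iff coverage $\ge 25$, variant allele frequency
$\ge 5\%$, and population minor allele frequency missing or $\le 1\%$
(higher MAF is treated as a germline polymorphism). The boundaries are
read literally from the stated rules ("lower than 25", "lower than 5%",
"> 1%"), so values exactly at 25, 5% and 1% are retained. The "frequency"
filter is interpreted as VAF because the population-MAF rule is stated
separately. The substitution spectrum keeps all 12 ordered ref→alt
classes — C→T and G→A are *not* collapsed to the pyrimidine strand,
because transition percentages are reported per strand in this setting.
With zero records the percentages are undefined (`NA`), never 0.

# Plasma biomarker

qPCR quantification uses the ΔΔCt model with the reference gene *RAD52*
and a healthy-PBMC calibrator assumed diploid:
$\mathrm{CN} = 2 \cdot (1+E)^{-\Delta\Delta C_t}$ with amplification
efficiency $E = 1$ (perfect doubling) by default. The underlying protocol
states only "normalized to healthy PBMC"; ΔΔCt is the standard
quantification consistent with that statement, and $E$ is exposed because
primer efficiencies are never exactly 1 in practice. Replicates are
averaged before ΔCt; replicate spreads above 0.5 cycles are flagged.
Non-detected targets report CN 0 with a flag.

The ratio is $\mathrm{CCND1} / \max(\mathrm{CDKN2A}, 0.05)$; the floor
keeps homozygous-deletion samples finite while preserving "very large"
semantics, and its use is flagged. The regression of ratio on
$\log_{10}(\mathrm{load})$ is ordinary least squares. The base-10
logarithm is not an assumption: with the published coefficients
(11.11, −36.93) only $\log_{10}$ reproduces the published worked example
(ratio ≈ 4.17 at 5000 copies/ml; the natural log would give ≈ 57.7).
Candidate classification uses a strict inequality at the cutoff
(default 4, the predicted ratio near 5000 copies/ml): a ratio exactly at
the cutoff is not a candidate, a documented choice where the source rule
gives no boundary semantics.

# Expression

RPKM is $10^9 c_{gs} / (N_s L_g)$. Genes are quantifiable with at least
10 reads in total across the samples of a comparison (the scope of the
10-read rule is unstated; totaling over the comparison is the most
permissive reading that still excludes unmeasurable genes). Fold change is
the ratio of mean RPKM after adding a one-read pseudocount to every cell.
The significance test is deliberately simple and self-contained: an exact
binomial test of the gene's treated count against the library-size split
for unreplicated 1-vs-1 designs, and Welch's t-test on
$\log_2(\mathrm{RPKM}+1)$ with replicates, instead of a dispersion-modeling
count framework — the calling rule being reproduced is "≥ 2-fold and
p < 0.05", with no multiple-testing correction by default (a BH option
exists). Exact DEG counts from real experiments are not reproducible from
a simple test; what is preserved, and tested, is the monotone relationship
between the number/size of planted effects and the number of DEG calls.

# Simulation layer

The generators define the study conditions the tests run under:

* **References/reads** — two chromosomes ("autosome", "chrX"), uppercase
  ACGT, default 20 kb total; divergence 0.1 between the human-like and
  mouse-like sequence; 100-bp error-free reads, contamination 0.2. Reads
  carry hidden origin labels for accuracy measurement.
* **Coverage** — Poisson counts with mean
  $\mathrm{depth} \cdot L_g/1000 \cdot \mathrm{CN}_g/\pi_g$ at depth 100
  over 200 genes (a negative-binomial option adds overdispersion).
  Poisson is the simplest model consistent with read-density semantics.
* **Variants** — substitution classes drawn from a configurable 12-class
  spectrum; coverage/VAF/MAF fields planted to fail each filter at
  configurable fractions, with exact bookkeeping.
* **Plasma cohorts** — loads log-uniform (default 5×10³–10⁶ copies/ml),
  ratio = 11.11·log₁₀(load) − 36.93 + N(0, 2), floored at 0.01; CDKN2A
  drawn from {2, 1, 0.05} with loss probability rising in load, CCND1
  defined as ratio × CDKN2A, RAD52 ≈ 2. The Normal residual model and its
  SD are assumptions (the source states none) and are exposed in the
  configuration. Default cohort size 22.
* **qPCR** — Ct values placed so the ΔΔCt estimator inverts them exactly
  at zero noise (round-trip identity), with optional per-replicate Ct
  noise.
* **Expression** — log-normal baseline means, Poisson counts, 3
  replicates per condition, planted fold changes.

All randomness flows from one integer seed with fixed per-generator
offsets, so any single output is reproducible in isolation and identical
configurations give byte-identical files.

What the simulations do **not** emulate: GC and mappability bias,
alignment artifacts, FFPE damage, subclonal heterogeneity, overdispersed
RNA counts (unless enabled), and primer-specific qPCR efficiencies.
Passing recovery tests therefore demonstrates correctness of the
estimators under their stated models, not robustness to every artifact of
real data.

# Reference cohort stand-ins

Two published record-level tables — the 282-variant somatic SNV list and
the 22-sample high-EBV-load plasma table — exist only as
non-machine-readable supplements. `synthetic_snv_table()` and
`synthetic_plasma_cohort()` rebuild *synthetic* stand-ins engineered to
reproduce their reported summary statistics (282 variants with per-tumor
counts in 34–99 and the C→T/G→A percentages; regression slope 11.11,
intercept −36.93, Pearson r = 0.576, 5/7 CDKN2A losses above 10⁵
copies/ml, mean CCND1 ≈ 22). The plasma construction is deterministic
linear algebra: the residual vector is made orthogonal to the design
matrix (so the OLS line is exact) and scaled to the residual variance
implied by r = 0.576; the residual shape is concentrated at high loads so
all ratios stay positive. Recomputing the statistics from these tables
validates the package's regression, correlation, spectrum and counting
code — it does not re-derive the original measurements.

# Problem sizes and numerical choices

The test and acceptance workloads use 200-gene exomes at depth 100,
5,000-read deconvolution sets, 50 plasma cohorts of n = 22, and
2,000-gene expression matrices with 3 replicates — sizes chosen so each
stochastic check has the power its tolerance needs (3-SD bands for
generator means, ±10% for slope recovery, MAE < 0.3 for copy number)
while the whole suite stays desk-scale. Floating-point outputs are
serialized with full precision; all test comparisons use explicit
tolerances, never string equality. Stochastic tests fix their seeds.

# Known limitations

* Copy-number estimation assumes a mostly copy-neutral genome for library
  normalization and male samples for the sex-chromosome baseline.
* The ambiguous read class is excluded rather than rescued; paired-end
  mate information is not used.
* The DEG test is not a dispersion-modeling framework and will be
  anticonservative for strongly overdispersed data.
* The qPCR model assumes a common amplification efficiency across targets
  and calibrator.
* Arm-level segmentation, GC correction, enrichment analysis and survival
  modeling are out of scope.
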