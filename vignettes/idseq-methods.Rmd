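---
title: "Models and methods behind idseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idseqr)
```

## The measurement model

Immuno-detection by sequencing (ID-seq) quantifies proteins and
phospho-proteins by sequencing DNA tags released from antibodies.  Each tag
carries a 10-nt antibody-dedicated barcode (BC1) and a 15-nt unique
molecular identifier (UMI); a well-specific barcode (BC2) is added by PCR,
and a constant anchor sequence marks the positions of all elements in the
read.  The signal for one antibody in one well is the number of *distinct*
UMIs observed — PCR copies of the same original tag share a UMI and are
collapsed, so the count approximates the number of antibody molecules that
bound and released a tag.

`idseqr` implements the full computational path: read parsing and
error-tolerant barcode matching, UMI deduplication, depth normalization, a
per-antibody negative-binomial (NB) differential model, and the screen-level
analytics used to aggregate hundreds of perturbations (kinase-inhibitor
probes) over a 70-antibody panel.

## Read parsing and barcode correction

A `read_layout()` records the segment order (default
`UMI(15) – ANCHOR – BC1(10) – BC2(10)`) so parsing is fixed-position
substring extraction, O(1) per read.  The default anchor and geometry are a
configurable convention, not a claim about any particular deposited data
set; assays differing in element order or lengths are described by their own
layout.  The anchor is verified with a configurable substitution budget
(default 2) summed over its occurrences.

Barcode matching returns the unique panel entry within Hamming distance
`tolerance` (default 1), rejecting ties at the minimal distance.  `N` and
any other non-ACGT character mismatch every base.  For `tolerance <= 1` the
implementation precomputes a dictionary of every barcode and its
single-substitution neighbourhood over `{A,C,G,T,N}` (ambiguous neighbours
map to no-match), reducing matching to one hash lookup per read; the
semantics are identical to an exhaustive Hamming scan, which remains the
reference implementation for larger tolerances and in the test suite.
`validate_panel()` enforces the safety condition for unambiguous correction,
minimum pairwise distance `>= 2*tolerance + 1`; under that condition a read
with at most `tolerance` substitutions can never be assigned to the wrong
antibody or well.

A *duplicate* is an exact repeat of the corrected (well, antibody, UMI)
triple; UMIs themselves are not error-collapsed, because the assay counts
distinct UMI sequences after duplicate removal.  Sequencing errors inside a
UMI therefore inflate counts slightly (roughly by the per-UMI error
probability); this is a known, documented bias of the counting rule rather
than a parsing artefact.

## Depth normalization

Per-well size factors use the median-of-ratios estimator: antibodies with a
zero count in any well are excluded from the geometric-mean reference
(optionally retained via `poscounts = TRUE` for sparse plates), and the
factors are rescaled to geometric mean 1 so that the model intercept remains
identifiable.  Factors enter the differential model as offsets; normalized
counts (`counts / factor`) are provided for QC and plotting only.

## The per-antibody differential model

For antibody *a* with counts \(y_{aw}\) over wells *w*, the model is

\[ y_{aw} \sim \mathrm{NB}(\mu_{aw}, \alpha_a), \qquad
   \log \mu_{aw} = \log s_w + x_w^\top \beta_a , \]

with \(s_w\) the size factor, \(x_w\) the treatment indicator plus fixed
blocking covariates (replicate, batch), and variance
\(\mu + \alpha\mu^2\).  Treatment significance is a likelihood-ratio test
of the full design against the blocks-only design, and each antibody's
score is the signed p-value, \(\mathrm{sign}(\hat\beta)\cdot(-\log_{10} p)\)
(p clipped at 1e-300).

Estimation details, all chosen for small plates:

* **Optimisation.** Coordinate ascent alternating IRLS for \(\beta\) with a
  one-dimensional search for \(\alpha\) on the log scale
  (`optimize`, bounds 1e-8–1e3), started from a Poisson-style fit;
  step-halving guards separation paths; relative log-likelihood tolerance
  1e-8, at most 100 outer iterations.  Convergence and the score norm are
  reported on every fit; all-zero rows return a degenerate flag with `NA`
  p-value instead of failing.
* **Dispersion.** Per-antibody maximum likelihood with a Cox–Reid
  adjustment (`-0.5 log det X'WX`) by default.  Plain ML underestimates
  \(\alpha\) badly at plate scale (n = 12 wells), which makes the LRT
  strongly anticonservative; the adjusted estimate restores honest test
  size.  The dispersion estimated under the full model is held fixed when
  the reduced model is refitted, so the test compares like with like.
* **Reference distribution.** `lrt()` defaults to the asymptotic
  chi-square.  `differential_table()` — the screen-scale path — instead
  refers the statistic to \(F(\mathrm{df}, n - p_{\mathrm{full}})\)
  (`small_sample = TRUE`).  In null simulations at n = 12 wells and
  dispersions 0.1–1, the chi-square reference rejected at 2–3% for a
  nominal 1% even with the Cox–Reid adjustment, while the F reference holds
  0.7–0.8%; both converge for large plates.  Blocking factors are fixed
  effects; a random-intercept formulation targets the same treatment
  contrast at screen scale, and the fixed-effect form keeps the
  likelihood-ratio machinery exact and fast.
* **Multiplicity.** Benjamini–Hochberg q-values across the antibody panel.

## Screen-level analytics

The per-probe, per-phenotype signed p-values form a probes × phenotypes
matrix.  `screen_pca()` mean-centres each phenotype (no variance scaling by
default — signed p-values already share a scale; `scale. = TRUE` is
available) and computes the SVD, fixing each component's sign so its
largest-magnitude loading is positive.  Missing entries must be imputed
explicitly (`impute_screen_matrix()`, phenotype-mean imputation); nothing is
imputed silently.  `annotate_pcs()` correlates phenotypes with the top
components and orders them by average-linkage clustering on correlation
distance, the standard way to read biological meaning into a component.
`decile_contrast()` compares the top against the bottom 10% of probes along
a chosen component with Welch t-tests per phenotype (zero-variance groups
with equal means give p = 1 by convention), BH-adjusted.

`assign_probe_sets()` assigns inhibitory probes to each kinase from a
probes × kinases %-inhibition matrix by a robust upper-tail outlier rule:
\(z = (x - \mathrm{median}) / (1.4826\,\mathrm{MAD})\) with normal tail
p < 0.01.  The rule is deliberately an interchangeable strategy — any
assignment that produces member lists can be slotted in.  Columns with zero
MAD fall back to a rank rule (probes above the median whose upper-tail
empirical fraction is at most alpha); all-constant columns give an empty
set with a warning.  Because the z-rule calibrates against a normal null,
its false-assignment rate is checked on Gaussian null columns; heavy- or
short-tailed inhibition distributions shift that rate, which is inherent to
any parametric outlier rule.

`gsea()` ranks probes by the component score (ties broken by probe id) and
computes the classic weighted Kolmogorov–Smirnov running-sum enrichment
score (weight exponent 1), evaluated only at member positions since the
running sum is piecewise linear between hits.  The null resamples member
labels.  Per-set permutation p-values (two-sided on |ES|) floor at
`1/(n_perm + 1)`, which BH cannot convert into set-level discoveries when
hundreds of sets are tested; the primary FDR therefore follows the
canonical GSEA recipe — sign-stratified normalisation of each ES by its
own set's mean same-sign permutation |ES| (NES), then FDR from the
permutation NES pooled across all sets, monotonised in |NES|.  BH on the
per-set p is still reported (`q_bh`).  10,000 permutations are recommended
for final set-level calls; 1,000 suffice for calibration checks.

`kinase_profiles()` summarises each probe set as the mean model estimate
per phenotype (s.e. = sd/sqrt(m), `NA` for singletons), and
`profile_cluster_compare()` k-means-clusters those profiles (best of 50
restarts under a fixed seed) and contrasts each kinase's member estimates
with a reference kinase phenotype-by-phenotype (Welch; a kinase against
itself reports p = 1).

## What the generators emulate

The simulators define the conditions under which the pipeline is validated;
all are pure functions of (parameters, seed) and serialise their truth
records.

* `simulate_fastq()` draws the per-cell number of distinct molecules, emits
  each `1 + Geometric(d)` times (memoryless PCR resampling; the expected
  duplicate fraction equals `d`), and applies independent substitution
  errors to the barcode segments only.  No indels, no quality scores, no
  optical duplicates, no PCR bias curves: barcodes are fixed-position and
  substitution-dominated, and those omissions keep every oracle analytic.
* `simulate_counts()` draws NB counts around log-normal antibody baselines
  (median ≈ 500 counts), log-uniform well depths (0.5–2×), optional
  replicate/batch log-normal effects, and planted log fold changes.
* `simulate_screen()` mirrors the published screen's geometry: 294 probes ×
  70 phenotypes × 225 kinases, two orthonormal phenotype axes with score
  s.d. 6 (a dominant signalling axis, ~30% of variance) and 2.5 (a
  differentiation axis, ~12%), entry noise s.d. 1.  A pool of 24
  differentiation-inducing probes carries a +10 shift on the second axis —
  responder probes separate discretely from the bulk, as strong
  differentiation inducers do — and each of 10 active kinases draws its 10
  true member probes from that shared pool, reproducing the
  polypharmacological overlap of inhibitor sets; inactive kinases draw
  members elsewhere.  Members receive high % inhibition (mean 85) against
  a background near 15.  The two eigenvalues are kept well separated
  because near-degenerate planted variances make the recovered components
  arbitrary rotations of the planted axes, which is a property of PCA, not
  of the screen.

What passing these simulations does *not* show: robustness to indel-bearing
reads, to antibody cross-reactivity, to non-NB count contamination
(e.g. well failures), or to inhibition matrices whose null columns are far
from symmetric.  Real screens should inspect the demux QC report and the
dispersion estimates before trusting downstream calls.

## A screen-shaped run in code

```{r screen-run, eval = FALSE}
scr <- simulate_screen(seed = 1)          # probes x phenotypes + inhibition
pca <- screen_pca(scr$values, k = 4)
ann <- annotate_pcs(scr$values, pca)      # which phenotypes define each PC
pc2 <- pca$scores[, 2]
ctr <- decile_contrast(scr$values, pc2)   # top vs bottom 10% of probes
sets <- assign_probe_sets(scr$inhibition, alpha = 0.01)
enr <- gsea(pc2, sets, n_perm = 10000, seed = 2)
prof <- kinase_profiles(scr$values, sets[enr$kinase[enr$q_value < 0.01]])
```

The same chain, driven from a YAML config with raw FASTQ input, is
`run_pipeline()`; `inst/cli/idseq.R` exposes it as shell subcommands.

## Validation problem sizes

The shipped checks run at the package's stated validation design: ~10^5
reads over a 70 × 96 plate for demultiplexing against a set-based oracle;
10^5 singly mutated barcodes for correction safety; 2,000 null simulations
per dispersion (0.1, 0.5, 1) at n = 12 wells for test calibration; 500
simulations at n = 48 wells for recovery of a planted ln 2 fold change; 500
random sets × 1,000 permutations for permutation-p uniformity and the full
294 × 225 screen at 10,000 permutations for planted-set recovery.

## Known limitations

* UMI errors are not collapsed (counting rule, see above).
* The NB model treats replicate and batch as fixed effects; designs where
  blocks should be treated as random draws with few levels are better
  served by a dedicated mixed-model fit.
* The outlier rule and the enrichment variant are pluggable conventions;
  alternative rules change set membership and therefore downstream calls.
* Probe polypharmacology is represented only through shared set membership;
  no deconvolution of probe–kinase attribution is attempted.
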