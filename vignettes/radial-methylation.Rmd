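---
title: "Radiation-induced DNA methylation in radial nuclear context: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiation-induced DNA methylation in radial nuclear context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialmeth)
```

# The problem

High-LET particles such as ⁵⁶Fe and ²⁸Si ions deposit dense ionization
tracks through the cell nucleus, while low-LET X-rays act diffusely
through radical chemistry. Both reshape DNA methylation, but the imprint
differs by particle: iron-like exposures tend to raise methylation and
the change persists, silicon-like and X-ray exposures tend to lower it
transiently. Whether a given CpG responds also depends on its spatial
context — how deep in the nucleus its chromosome sits, and what
chromatin marks surround it. `radialmeth` implements the full analysis
chain for this question and a synthetic-data generator that encodes the
qualitative biology as a generative model, so the chain can be validated
by planted-truth recovery.

# Differential methylation model

Beta values $\beta \in (0,1)$ (methylated intensity fraction) are
transformed to M values $M = \log_2(\beta/(1-\beta))$; M is the scale on
which effects and thresholds are defined, because it is unbounded and
approximately variance-stable. Exact 0/1 Beta values are clamped to
$\varepsilon = 10^{-6}$ with a warning.

For a comparison of focal group A against reference group B (each ≥ 2
replicates), every probe receives the two-group one-way ANOVA F
statistic on M values — identical to the squared pooled-variance t —
with Benjamini–Hochberg q values across probes. A probe is a DMP when

* $q < 0.05$,
* $|\mathrm{avDiff}| = |\bar M_A - \bar M_B| \ge 0.58$, and
* $|\Delta_{\mathrm{ctrl}}| = |\bar M_A - \bar M_{\mathrm{ctrl}}| \ge 0.58$,

where the control level is the per-probe mean M over **all** dose-zero
samples pooled across particle batches (they share culture, handling and
baseline methylation, so pooling maximizes the control sample size).
The three conditions are applied as one conjunction; their order does
not change the final set. Missing values are excluded pairwise, never
imputed — exclusion is conservative and keeps per-probe degrees of
freedom explicit. Probes with zero within-group variance are flagged
degenerate and receive the limiting p (0 when means differ, 1 when
identical). DMPs are sub-grouped by baseline state (hypo when control
M < 0, hyper otherwise; an exact 0 counts as hyper and is flagged) and
direction (up when $\Delta_{\mathrm{ctrl}} > 0$).

BH was chosen over Storey's q-value deliberately: it is deterministic,
assumption-light, and needs no density estimation; at the effect sizes
of interest the called set is insensitive to the choice.

## DMR construction

DMRs are built by distance chaining: per chromosome, passing DMPs are
sorted by position and consecutive probes join one region while the gap
is ≤ λ (default 1000 bp); chains of ≥ 2 probes become DMRs. This
replaces kernel-based region callers on purpose — the downstream
statistic is only the *fraction of DMPs inside DMRs*, and the
sensitivity analysis of interest ("does a larger bp limit change the
picture?") is natively a distance-semantics question. A DMR's mean
change is the unweighted mean of member $\Delta_{\mathrm{ctrl}}$; no
within-region weighting is attempted because region-level values are
only used descriptively.

## Permutation null for clustering

The clustering question — are DMPs packed together more than chance? —
is answered by permuting probe identifiers over the rows of the value
matrix: the multiset of measured profiles is untouched while genomic
coordinates are decoupled from values. The statistic is the in-DMR
fraction; the null repeats the identical pipeline on B permuted
datasets; the empirical p uses the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, so it is never 0
and is valid at finite B. The alternative is "greater" (observed
clustering exceeds the null). One exact algebraic shortcut is used:
because per-row statistics are invariant under row relabelling, the
probe-level tests are computed once and only coordinates are resampled;
a test verifies bit-level equivalence with the naive full recompute.
B defaults to 1000 (the study-scale choice); 200 is a practical fast
mode whose minimum attainable p is 1/201. One calibration subtlety worth
knowing: a layer-dependent effect magnitude concentrates detected DMPs
on the chromosomes whose territories sit at the favoured depths, which
is genuine chromosome-scale spatial structure — the test rightly picks
it up. A strict spatial null therefore requires a flat layer effect
profile as well as `clustered_fraction = 0`.

# Radial layering model

The Hi-C compartment score of the bin containing a probe proxies radial
depth: the higher the score, the deeper the probe. Layers are built by
ranking probes on `(score, chrom, pos)` and cutting the ranks into five
contiguous blocks of equal size (±1 probe): L1 holds the lowest scores
(periphery), L5 the highest (interior). Equal *occupancy* — the same
amount of DNA per layer — is the defining property, so the split is by
rank, not by score values, which would break under ties; the reported
layer boundaries are the empirical 0/20/40/60/80/100% score quantiles.
The tie-break key is fixed and documented for reproducibility. Probes
not covered by the track are dropped from spatial analyses (and
counted) but retained everywhere else. Quantiles are taken over probes,
not genomic bins, which is what makes "equal DNA per layer" hold after
the probe overlap.

Layer summaries are: the percentage of all DMPs per layer (sums to
100%), chromosome-normalized DMP frequency (DMPs ÷ probes per
chromosome, correcting array design bias), the per-layer ×
per-chromosome frequency matrix (cells with no probes are NA, never 0),
and the per-layer mean $|\Delta_{\mathrm{ctrl}}|$.

# Chromatin context

Histone peak sets are filtered to lengths in [300, 2000] bp (inclusive)
and a per-peak alignment score with a source-specific rule (`>= 10` or
`> 0`), mirroring the two kinds of score thresholds that real ChIP-seq
depositions carry. A probe carries a mark when its point lies inside
any peak (≥ 1 bp semantics everywhere; the half-open 0-based interval
convention is used throughout, so a probe whose 0-based position equals
a bin's `end` belongs to the next bin). The DMP-occurrence enrichment
ratio per layer is
$\frac{\text{DMPs in region} \cap \text{layer} / \text{all DMPs}}
      {\text{region probes in layer} / \text{all region probes}}$,
1 meaning DMPs distribute over layers exactly like the region class; a
zero denominator yields NA rather than 0 because "no region probes
here" is absence of evidence. Five regulatory classes are built from
TSS windows (halfwidth 2000 bp by default — the same genomic scale as
the shore definition; no canonical value exists, so it is a visible
parameter) partitioned by H3K4me3/H3K27ac overlap, plus H3K27ac peaks
outside all TSS windows and gene bodies as enhancers.

# Expression validation

Counts are TMM-normalized (`edgeR::calcNormFactors` — the field's
normalizer, with the upper-quartile reference rule) and expressed as
log2 CPM with a 0.5 pseudo-count on effective library sizes. The DE
gate at the first post-exposure timepoint uses a limma moderated t test
(`lmFit` + `eBayes`, mean–variance trend for counts) with BH, or
Bonferroni for microarray designs; microarray matrices are pre-filtered
to genes with median intensity ≥ 3. Moderation is a deliberate design
choice: with three replicates per group an unmoderated pooled t has 4
residual degrees of freedom and essentially no power after FDR control
(on the package's own synthetic counts it yields zero discoveries where
the moderated test recovers 95% of planted genes at 1% empirical FDR),
and empirical-Bayes variance shrinkage is exactly what the
edgeR/limma-style pipelines this module emulates provide. A NB-GLM
route is a possible extension, not implemented.

Gated genes get logFC-versus-control trajectories over the ordered
timepoints, an up/down class from the sign at the first timepoint,
per-class mean trajectories, and trend tests: ANOVA on the regression
gradient always, Mann–Kendall when ≥ 4 timepoints exist. Astronaut-style
single-replicate series are first grouped into five pseudo-replicated
groups of two consecutive timepoints via a shipped default pairing
(pre-flight control; early/late in-flight; early/late post-flight);
the pairing is configuration data, overridable, and a group size other
than two requires an explicit override flag. Whether the pre-flight
control really contains two samples is not decidable from the source
description; two is the default and the pairing table makes the
assumption explicit. Gated genes are mapped to nuclear layers through
their TSS for the per-layer mean |logFC| profile.

# Statistical utilities

* **Mann–Kendall**: $S = \sum_{i<j}\mathrm{sign}(x_j - x_i)$, tau-b.
  For n ≤ 9 without ties the p is exact, from the full tie-free null
  distribution of S (computed by the Mahonian inversion-count
  recurrence — an exact enumeration of all n! orderings without
  materializing them); otherwise the normal approximation with
  continuity and tie correction. A minimum of 4 points is enforced.
* **Chi-squared**: Pearson statistic without continuity correction
  (`stats::chisq.test(correct = FALSE)`); tables with a zero expected
  count are refused.
* **Slope ANOVA**: OLS slope with the F test of slope = 0; a constant
  response returns slope 0, F 0, p 1 by convention.
* **BH adjustment**: `stats::p.adjust(method = "BH")` behind a
  validating wrapper.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all generators derive
independent RNG streams from one seed, so identical config + seed gives
byte-identical outputs. Defaults, and what they emulate:

* 20,000 probes on 4 chromosomes of 5 Mb — a desk-scale stand-in for a
  485k-probe array; 3 replicates per condition, matching the
  three-replicate exposure design.
* Baseline Beta from a bimodal mixture (Beta(5,45) and Beta(45,5),
  modes ≈ 0.1/0.9) — the hypo/hyper bimodality of real arrays.
  Replicate noise is Gaussian on the M scale (sd 0.15), because M is
  where effects are thresholded.
* Particles: Fe-like (+1 direction, persistent), Si-like and X-like
  (−1, decaying with ratio 0.5 per timepoint) at |ΔM| = 1.5, 5% planted
  DMPs each — encoding the persistent-increase vs transient-decrease
  contrast.
* Layer effect profile (0.5, 0.8, 1.0, 0.8, 0.6): effects peak in the
  middle layer L3, the spatial signature the layer analysis should
  recover; set it flat for null tests.
* `clustered_fraction = 0.5`: half of each particle's true DMPs are
  packed into 1 kb windows, giving an in-DMR fraction of roughly half —
  the regime where the permutation test must reject; at 0 the test must
  calibrate.
* Hi-C track: 25 kb bins tiling every chromosome, per-chromosome mean
  shifts evenly spaced in [−1, 1] plus N(0, 0.5) noise — chromosome
  territories at distinct radial depths.
* Peaks: widths uniform in [300, 2000] bp; H3K9me3 placement
  probability decreases with bin score (peripheral heterochromatin),
  H3K27ac increases, the others are flat.
* Counts: NB with dispersion 0.1, lognormal baselines (median ≈ 100),
  library-size factors uniform in [0.5, 2]; 5% planted genes at
  |logFC| = 2, half up half down, persistent or geometrically decaying.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: probe-type chemistry differences and other
array artefacts, batch effects, correlated probe noise along the
genome, realistic CpG-island/gene geometry, cell-type mixtures, or any
physical track-structure of particle traversals. Recovery results
validate the pipeline's logic, not biological effect sizes.

# Numerical choices and degenerate inputs

* Intervals are 0-based half-open internally; manifest positions are
  1-based points (`pos − 1` at interval boundaries). BED round trips
  preserve the covered base set.
* CpG distance classes are inclusive on the lower class (2000 bp →
  Shore, 4000 bp → Shelf); the 3-level variant merges shores and
  shelves, as the fraction comparisons use.
* All-tied scores still fill five layers by rank (with a warning);
  empty layers and zero denominators are flagged NA, never silently 0.
* Beta/M round trips are exact to 1e−12 on (ε, 1−ε).
* Empirical p values use the add-one rule and are never 0.
* Problem sizes in the shipped tests and acceptance script (20-seed
  batches of 10k–20k-probe simulations, B = 200) were chosen so the
  whole validation runs in a few minutes on one core while keeping
  every Monte-Carlo margin comfortable.

# Known limitations

The DMR chaining is not a kernel smoother and reports no region-level
significance; the Hi-C score is taken as given (no eigenvector
computation from contact maps, no 3D coordinates, no physical radial
distances); the expression arm validates trends, not edgeR-equivalent
effect estimates; and the five-layer radial model is an ordinal
abstraction — layers hold equal DNA, not equal volume.
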