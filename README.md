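# radialmeth

Ionizing radiation — and especially the heavy, high-LET ions (⁵⁶Fe, ²⁸Si)
that dominate the health risk of galactic cosmic radiation — perturbs DNA
methylation. Whether a CpG site is hit, and how strongly, depends not only
on the beam but on where that site sits in the three-dimensional nucleus:
its radial depth, its chromatin state, and its regulatory context.
`radialmeth` is an R package for analysing exactly that question. It takes
a methylation array experiment (Beta values, probe manifest, sample
sheet), a Hi-C compartment-score track, histone ChIP-seq peak sets, gene
annotation and expression counts, and runs three linked analyses:

1. **Differential methylation.** Beta values are transformed to M values,
   `M = log2(β / (1 − β))`. For each comparison of irradiated conditions
   (e.g. Fe 1 Gy vs Si 1 Gy), every probe gets a two-group F test on M
   values; probes are called differentially methylated (DMPs) when
   `q < 0.05`, `|avDiff| ≥ 0.58` (mean M difference between groups) and
   `|ΔM vs control| ≥ 0.58`, with the control level defined as the mean M
   over all dose-zero samples pooled across particle batches. Passing DMPs
   are chained into regions (DMRs) when consecutive probes lie within
   λ = 1000 bp, and the fraction of DMPs inside DMRs is tested against a
   probe-label permutation null (B permutations, add-one empirical p) to
   ask whether induced changes cluster in the genome or scatter.

2. **Radial nuclear layering.** Probes are ranked by their Hi-C score
   (higher = deeper in the nucleus) and split at the 0/20/40/60/80/100%
   quantiles into five equal-DNA layers, L1 (periphery) to L5 (interior).
   Per-layer DMP frequencies, chromosome-normalized frequencies, mean
   |ΔM|, histone-mark distributions and the DMP-occurrence enrichment
   ratio `(DMPs in region ∩ layer / all DMPs) / (region probes in layer /
   all region probes)` quantify how radiation response varies with
   nuclear depth and chromatin context, including five regulatory-region
   classes built from TSS windows and H3K4me3/H3K27ac peaks.

3. **Expression persistence validation.** Counts are TMM-normalized,
   genes are gated on first-timepoint differential expression
   (moderated t, FDR < 0.05) and their logFC trajectories across later
   timepoints are classified up/down and tested for trend (regression
   ANOVA on the gradient, Mann–Kendall), asking whether early changes
   persist (iron-like exposures) or decay (silicon-like and X-ray).

Because the original array, Hi-C, ChIP-seq and expression datasets are
external accessions, the package ships a first-class synthetic-data
generator (`sim_config()`, `simulate_inputs()`) that emulates all six
input kinds — bimodal Beta baselines, three replicates per condition,
particle-specific persistent/decaying planted effects with an
L3-peaked layer profile, peripherally enriched H3K9me3 peaks,
negative-binomial count trajectories — together with the planted ground
truth, so every stage is testable by recovery.

## Worked example

```r
library(radialmeth)

cfg <- sim_config(seed = 11, layer_effect_profile = c(1, 1, 1, 1, 1))
sim <- simulate_inputs(cfg)
ex  <- as_m_scale(sim$experiment)

sm <- ex$samples
fe <- sm$sample_id[sm$particle == "Fe" & sm$dose_gy > 0 & sm$timepoint == "48h"]
si <- sm$sample_id[sm$particle == "Si" & sm$dose_gy > 0 & sm$timepoint == "48h"]

dmps <- call_dmps(ex, fe, si)          # per-probe tests + filters
sum(dmps$passes)
#> [1] 999

dmr <- build_dmrs(dmps, lambda = 1000)
dmr$fraction_inside
#> [1] 0.5305305

perm <- dmr_fraction_permutation_test(ex, fe, si, B = 200, seed = 99)
tidy(perm)
#> # A tibble: 1 x 7
#>   observed empirical_p     B tail    null_median null_min null_max
#>      <dbl>       <dbl> <dbl> <chr>         <dbl>    <dbl>    <dbl>
#> 1    0.531     0.00498   200 greater      0.0951   0.0631    0.132
```

999 of 20,000 probes pass the three filters (the configuration plants 5%
true DMPs at |ΔM| = 1.5; recovery here is 99.9% with zero false calls),
53% of them chain into DMRs, and that fraction exceeds all 200
permutation nulls (median 0.095), giving the minimum attainable empirical
p of 1/201 ≈ 0.005 — the planted clustering is real. Continue with
`build_layers()` / `layer_mean_abs_change()` for the radial profile
(`autoplot()` draws it), `overlap_probes()` / `dmp_enrichment_ratio()`
for chromatin context, and `de_gate()` / `logfc_trajectory()` for the
expression arm; `run_pipeline(cfg, "out/")` runs everything and writes
TSV tables plus a `summary.json`.

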