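# rhythmbiome

Circadian rhythmicity analysis of quantitative microbiome time series.

Fecal microbial communities oscillate over the 24-hour day. Deciding which
taxa are truly rhythmic, which rhythms are driven by a host circadian clock,
and how rhythm loss propagates to microbial metabolites requires a chain of
specialized statistics that this package implements end to end, for
microbiome researchers analyzing 16S amplicon time courses (and for method
development against a ground-truth simulator):

* **Rhythm detection** — fixed-period cosinor regression
  `y = M + A·cos(2π(t − φ)/24)` (mesor *M*, amplitude *A*, peak phase *φ*),
  two-harmonic regression, and the nonparametric **JTK_CYCLE** test built on
  an **exact Jonckheere–Terpstra null distribution** (convolution of
  Mann–Whitney counts; normal approximation only beyond n = 50), with
  Bonferroni-adjusted calls at p ≤ 0.05.
* **Differential rhythmicity** — per-group JTK followed by a **DODR-style
  harmonic interaction F-test** (H₀: equal rhythm coefficients between
  groups), classifying each taxon as `same`, `change`, `loss`, `gain`,
  `trend_loss`, `trend_gain` or `arrhythmic_both`.
* **Spike-in quantitative normalization** — 16S copies per gram via
  `Q = reads/spike_reads × spike_copies/mass`, plus sample QC (> 5000
  reads) and the mean-abundance > 0.1% / prevalence > 10% taxon filter.
* **Beta diversity** — generalized UniFrac (branch formula, α = 0.5
  default), PERMANOVA, PCoA, distance-to-reference-time curves, Procrustes
  comparison of ordinations.
* **Taxon–metabolite association** — Spearman correlation with the
  p ≤ 0.05 and |ρ| ≥ 0.5 report mask, restricted to clock-controlled taxa
  at ≥ 30% prevalence.
* **Synthetic study generator** — a two-group (control vs clock-deficient),
  6-subjects × 8-time-point repeated-measures design with known rhythmic
  fractions, a rhythmic total load, spike-in reads and coupled metabolites,
  returning the ground truth for recovery testing.

## Worked example

```r
library(rhythmbiome)

cfg  <- synth_config(n_taxa = 120, seed = 7)   # 2 groups x 6 mice x 8 time points
data <- generate_dataset(cfg)
rel  <- relative_abundance(data$counts)

calls <- rhythm_calls(rel, data$meta, "control")
s <- attr(calls, "summary")
sprintf("control: %d/%d taxa rhythmic (%.0f%%), carrying %.0f%% of abundance",
        s$n_rhythmic, s$n_taxa, 100 * s$fraction_rhythmic,
        100 * s$rhythmic_abundance_share)
#> "control: 73/120 taxa rhythmic (61%), carrying 75% of abundance"

cmp <- compare_rhythms(rel, data$meta, "control", "knockout")
attr(cmp, "summary")$category_counts
#>            same          change            loss            gain      trend_loss
#>              21               3              48               0               1
#>      trend_gain arrhythmic_both
#>               0              47
attr(cmp, "summary")$rhythmic_ratio_b_over_a
#> [1] 0.3287671
```

The generator planted 60% rhythmic taxa in the control group and retained a
third of them in the knockout; the pipeline recovers 61% rhythmic calls, a
knockout/control ratio of 0.33, and 48 `loss` taxa (rhythmic in control,
arrhythmic in knockout, confirmed by the DODR interaction test). The
strongest call:

```r
head(calls[order(calls$jtk_adj_p),
           c("taxon", "jtk_adj_p", "amplitude_jtk", "phase_h")], 1)
#>               taxon    jtk_adj_p amplitude_jtk  phase_h
#> zOTU_0031 zOTU_0031 4.220444e-16    0.04520946 4.013123
```

i.e. a relative-abundance rhythm of amplitude ≈ 0.045 peaking at ZT4.
A full run — normalization, rhythm calls, differential comparison,
GUniFrac/PERMANOVA/PCoA, metabolite correlations, with every table written
to disk and a manifest — is one call:

```r
bundle <- run_all(run_config(simulate = cfg, outdir = "run1", seed = 7))
```

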