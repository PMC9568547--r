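---
title: "Methods: circadian rhythm detection and comparison in quantitative microbiome time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rhythm detection and comparison in quantitative microbiome time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmbiome)
```

# The problem

Gut microbial communities in mice oscillate over the 24-h day: which taxa are
rhythmic, with what amplitude and peak phase, and which rhythms collapse when
a host circadian clock is disabled? Answering this from 16S amplicon time
series raises four methodological issues that this package addresses as one
coherent pipeline:

1. **Rhythm detection per taxon** must be robust to the skewed, heteroscedastic
   distribution of relative abundances — hence a rank-based test (JTK_CYCLE)
   alongside parametric cosinor regression.
2. **Relative versus quantitative analysis**: read fractions confound a taxon's
   own rhythm with rhythms of the total bacterial load. A spike-in standard of
   known copy number converts reads to 16S copies per gram, so both views can
   be compared.
3. **Differential rhythmicity** between a control and a clock-deficient group
   is a two-sample question about rhythm *parameters*, not merely two separate
   detection runs — hence a DODR-style interaction test layered on top of
   per-group calls.
4. **Community-level structure** (phylogenetic beta diversity over time,
   taxon–metabolite coupling) requires distances, ordination and correlation
   machinery that respects the compositional, phylogenetic nature of the data.

# Rhythm models

## Cosinor regression

For a fixed period $T = 24$ h the model is
$$y(t) = M + A\cos\!\left(\frac{2\pi (t-\varphi)}{T}\right) + \varepsilon,$$
with mesor $M$, amplitude $A \ge 0$ and peak phase $\varphi \in [0, T)$.
`fit_cosinor()` uses the standard linearization
$y = m + a\cos\omega t + b\sin\omega t$, giving $A = \sqrt{a^2+b^2}$ and
$\varphi = \tfrac{T}{2\pi}\operatorname{atan2}(b, a) \bmod T$. The p-value is
the F-test of the two rhythm coefficients against the intercept-only model.
Repeated measures are pooled: subjects sampled at the same time point are
treated as independent replicates. This mirrors the common practice of
fitting all replicates rather than per-time-point means; fitting means would
only change the F-test degrees of freedom, and the all-replicates fit is what
the per-sample data support. Constant series get $A = 0$, $p = 1$ by
convention (the F statistic is undefined there).

`fit_harmonic()` adds a second-harmonic (12-h) cosine pair and tests all four
rhythm coefficients jointly; it reduces exactly to the cosinor when the 12-h
amplitude is zero, which the tests verify.

## JTK_CYCLE with an exact Jonckheere–Terpstra null

For each lag $\varphi$ on a grid (one lag per sampling interval; 3-h sampling
gives 8 lags), observations are grouped by the distinct values of the
reference cosine $\cos(2\pi(t-\varphi)/T)$ and ordered by increasing
reference value. The Jonckheere–Terpstra statistic counts concordant minus
discordant between-group pairs; ties in $y$ contribute zero (tau-a
convention). Under exchangeability the statistic decomposes into a sum of
independent Mann–Whitney counts, so `jtk_null()` obtains the exact null pmf
by convolving Mann–Whitney count distributions — verified against complete
enumeration of all orderings for every design with $n \le 7$. Above a
configurable exact limit (default $n = 50$; the study design uses $n = 48$
per group and therefore stays exact) a normal approximation with continuity
correction takes over.

Two lags whose reference orderings are exact reversals describe the same
two-sided alternative, so the 8-lag grid collapses to 4 distinct
alternatives; the reported p-value is the minimal exact two-sided tail
multiplied by that alternative count (Bonferroni within the test, capped at
1). Because the exact null assumes no ties and ties score zero, the test is
conservative under ties — the flat-series simulations in the test suite show
an empirical size of about 2–4% at nominal 5%.

Per-taxon calls in `rhythm_calls()` follow the field's reporting convention:
JTK p-values are Bonferroni-adjusted across taxa and a taxon is *rhythmic*
when the adjusted p ≤ 0.05; the amplitude reported with the call is the
least-squares cosine amplitude constrained to the JTK best lag (the JTK
output itself is rank-based and has no natural amplitude), while the peak
phase is taken from the cosinor fit. Cosinor-based curve significance uses
the raw p ≤ 0.05.

## Differential rhythmicity (DODR) and the category table

`dodr_test()` fits the joint cosinor with a group indicator $g$:
$$y = \beta_0 + \beta_1 g + (a_0 + a_1 g)\cos\omega t + (b_0 + b_1 g)\sin\omega t$$
and tests $H_0: a_1 = b_1 = 0$ with an F-test; group-specific mesor shifts do
not trigger it. A robust variant (Huber M-estimation with a Wald F-type
statistic) is available because the differential-rhythmicity literature
offers both and heavy-tailed abundance residuals are common; the
least-squares F-test is the default as it is exactly calibrated in the
simulations.

`compare_rhythms()` combines per-group JTK calls (Bonferroni within group)
with the DODR test (Benjamini–Hochberg across taxa) into explicit categories:
both rhythmic → `change`/`same` by DODR; control-only rhythmic →
`loss`/`trend_loss`; knockout-only → `gain`/`trend_gain`; neither →
`arrhythmic_both`. Two deliberately open points were decided as follows and
are configurable: the multiplicity family for DODR is BH (the conventional
reading of "adjusted p" where no method is named; Bonferroni is a switch
away), and one-sided-rhythmic taxa without DODR support get an explicit
`trend_*` label rather than a silent `loss`/`gain` — ambiguity is surfaced,
not hidden. Mean-abundance differences are tested with the two-sided
Wilcoxon rank-sum test, BH-adjusted.

# Quantitative normalization

With a known quantity of artificial standard spiked into each weighed sample,
$$Q(s, i) = \frac{\text{reads}(s,i)}{\text{spike reads}(s)}
            \cdot \frac{\text{spike copies}(s)}{\text{mass}_g(s)}$$
estimates 16S copies per gram, valid *between* samples (no absolute cell
count is claimed). The identities that make this a normalization — invariance
to sequencing depth, inverse proportionality to spike reads, inverse
proportionality to sample mass — hold exactly by construction and are
asserted exactly in the tests. Sample QC keeps samples with bacterial read
sums strictly above 5000; the taxon filter keeps taxa with mean relative
abundance > 0.1% that are detected in > 10% of samples, computed on the
pooled analyzed dataset (prevalence counts strict positives, i.e. detection).

# Beta diversity and ordination

Generalized UniFrac is implemented directly from its branch-wise formula with
abundance-weighting exponent $\alpha$ (default 0.5, the moderated setting
recommended for the generalized form; $\alpha = 1$ reproduces normalized
weighted UniFrac, which the tests check against a hand-computed 5-leaf
oracle to $10^{-12}$). PERMANOVA is delegated to `vegan::adonis2` behind the
`permanova()` surface, with free permutation of sample labels by default
(matching common usage for this design) and pairwise mode under Bonferroni.
PCoA is classical metric scaling of the double-centered squared distances;
negative eigenvalues — expected for UniFrac-family distances — are dropped
with a warning. Beta-diversity time courses are quantified as each sample's
mean distance to the reference-time samples (ZT1 by default, self excluded),
then cosinor-fitted per group; the mean (not median) over reference samples
is used. Procrustes comparison of ordinations allows reflections by default
(the full orthogonal solution, as in `vegan`); a rotation-only variant with
a determinant correction is provided.

# Taxon–metabolite association

`select_clock_controlled()` picks taxa rhythmic in control but not knockout
(`loss` and `trend_loss`) with ≥ 30% prevalence. `spearman_matrix()` computes
Spearman's rho with midranks, the t-approximation p-value, BH adjustment over
the whole matrix, and the conventional report mask: raw p ≤ 0.05 *and*
|rho| ≥ 0.5. Both raw and adjusted p are emitted; the mask follows the
plotting rule because that is what the thresholded heatmaps in this
literature show. Missing metabolite values propagate via pairwise-complete
observations.

# The synthetic study generator

`generate_dataset()` emulates the study design the pipeline targets: two
groups (control, clock-deficient knockout) × 6 subjects × 8 time points on a
3-h grid over the 24-h day (96 samples), with subject identity persisting
across time points. Per taxon $i$, subject $m$, time $t$ the expected log
abundance is
$$\mu_i + u_m + A_i \cos\!\left(\frac{2\pi(t - \varphi_i)}{24}\right),$$
with $A_i = 0$ for taxa non-rhythmic in that group. Defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `n_taxa` | 580 | size of the filtered zOTU panel the analysis targets |
| `frac_rhythmic_control` | 0.60 | >60% of taxa rhythmic in intact hosts |
| `frac_retained_knockout` | 1/3 | two-thirds of rhythms lost without the intestinal clock |
| `amplitude_log_range` | 0.75–1.5 | log-scale amplitudes, ≈2–4.5× peak-to-trough |
| `noise_sd`, `subject_sd` | 0.30, 0.15 | residual and subject variation on the log scale |
| `phase_modes_h` | 6, 18 | bimodal day/night peak-phase distribution |
| `total_load_baseline` | 5×10⁹ /g | typical fecal 16S copy density |
| `total_load_amplitude` | 0.3 | rhythmic total load, so relative and quantitative views can disagree |
| `spike_copies` | 10⁸ | spike read share of ~30–50% against load × mass |
| `library_size_logmean` | log(10⁵) | HiSeq-scale per-sample depth |

The amplitude/noise ratio (minimum ≈ 2.2 after combining residual and
subject variation) was chosen once so that JTK at $n = 48$ with Bonferroni
correction across 580 taxa has high power for truly rhythmic taxa — the
regime the original study operates in, where the reported rhythmic fractions
are interpreted as close to the underlying truth. The knockout rhythmic set
is drawn as a subset of the control set, and retained taxa keep identical
amplitude and phase, so the `loss` category has an unambiguous ground truth.

Counts are drawn multinomially at a log-normal library size over the taxon
proportions plus one aggregate spike feature whose expected read share is
$\text{spike}/(\text{spike} + \text{load}\times\text{mass})$; a single
aggregate spike is simulated because a 12-standard panel is just a labeled
partition of the same reads. Metabolites are monotone (exponential-link)
transforms of a weighted coupled-taxon abundance plus Gaussian noise
calibrated to a target |Spearman| (default 0.7), coupled preferentially to
abundant clock-controlled taxa so the coupling survives count sampling.

**What the generator does not emulate** — and what passing recovery tests
therefore cannot show about real data: taxon–taxon ecological interactions
and phylogenetic signal in abundance (the tree is random relative to the
abundance model), overdispersion beyond log-normal subject/residual effects
(no Dirichlet-multinomial component), diet or light-condition effects,
sequencing artifacts (chimeras, denoising errors), and non-sinusoidal
waveforms. Rank-based detection is insensitive to the last point only up to
monotone shape changes.

# Numerical conventions and edge cases

* All log-scale quantities are natural logs; times are hours, folded modulo
  24 (the unfolded value is retained in `time_raw_h`).
* JTK ties: zero concordance contribution; tie-free exact null ⇒
  conservative p-values under ties. All-tied series: p = 1, tau = 0.
* Cosinor/harmonic on constant series: amplitude 0, p = 1.
* Permutation p-values are $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$,
  hence never below $1/(n_{perm}+1)$.
* Spearman on constant columns: reported missing (NA), never 0.
* Every stochastic stage of `run_all()` derives a recorded sub-seed from the
  master seed, so identical configs produce byte-identical output
  directories, and stages can be re-run in isolation.

# Validation problem sizes

The test suite validates the exact JT null by complete enumeration for all
120 group-size compositions with $n \le 7$; JTK size on 1000 flat series of
8×3 observations; cosinor phase RMSE over 500 noisy replicates at $n = 48$;
DODR calibration and power over 500 simulations each; recovery of the `loss`
set on the full default design (580 taxa, 96 samples per group-pair);
UniFrac against closed-form oracles on 5-leaf trees and bounds on random
30-taxa communities; and null-uniformity of PERMANOVA/Procrustes p-values
over 500 replicates at 199 permutations. Module tests use a 40-taxon version
of the same design.

# Known limitations

* The exact JT convolution assumes exchangeability within the analyzed
  group; autocorrelation within subjects across time points is ignored
  (pooled-replicates convention), which can make calls anti-conservative if
  subject-level autocorrelation is strong.
* The DODR F-test assumes homoscedastic Gaussian residuals; use
  `robust = TRUE` for heavy tails, at some cost in calibration exactness.
* Quantitative normalization assumes constant extraction/amplification
  efficiency between the spike and bacterial templates across samples, and
  performs no per-taxon 16S operon-count correction.
* PERMANOVA's free permutations do not respect the repeated-measures
  structure; treat small p-values on within-subject contrasts with care.
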