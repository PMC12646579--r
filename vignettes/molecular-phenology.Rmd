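---
title: "Comparative molecular phenology: models and methods"
author: "molphen package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative molecular phenology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Trees and other perennials re-organise their transcriptomes over the year:
genes tracking temperature and photoperiod rise and fall with annual or
half-annual rhythms, and the calendar position of each gene's expression
peak — its *molecular phenology* — can differ between related species that
flush leaves or flower at different times. `molphen` provides the full
analysis path from a seasonal RNA-seq count matrix sampled every few weeks
over about two years to:

1. normalized expression series per species, tissue and date (GeTMM),
2. per-gene rhythmicity calls with period and peak month,
3. cross-species peak-month comparisons, including a monthly
   *molecular phenology divergence index* D,
4. per-gene cross-species correlation of the seasonal profiles,
5. sample- and gene-level clustering overviews, and
6. pairwise dN/dS estimates for ortholog coding sequences, regressed on
   phase divergence or expression level.

A seeded synthetic-data generator emulates the sampling design
(four species in two genera, two tissues, roughly 27 four-weekly time
points, one to three individuals per species) with known ground truth, so
every stage is testable end to end.

# Preprocessing

Counts are converted to reads per kilobase (RPK); a gene is kept only when
its per-species mean RPK is at least 1 in every species (strict `< 1`
drops, so boundary genes stay). TMM scaling factors are then computed on
the RPK matrix — this combination is GeTMM, i.e. length correction before
library scaling — with the canonical trims (30% on M-values, 5% on
A-values) delegated to `edgeR::calcNormFactors`. Columns are expressed per
million, biological replicates are averaged within (species, tissue, date),
and values are transformed to `log2(mean + 1)`; the mean is taken before
the log. The fixed order *filter, then normalize* matters: TMM factors
change when the gene universe changes, and the pipeline documents and
tests that order rather than treating the two steps as interchangeable.

`variabilityRatio()` summarises how much larger between-gene variation is
than within-gene seasonal variation: per-gene coefficients of variation
sigma_i/mu_i on the log scale against the pooled sigma_g/mu_g, reported as
the ratio R. Both numerator and denominator are computed on the same (log)
scale; genes with zero mean are flagged and excluded.

# Rhythm detection

## The statistic

For a candidate period T (in time points) observations are assigned to
phase groups `g = ((index - 1) mod T) + 1`. A seasonal peak can fall
anywhere in phase, so the scan considers every cyclic rotation of the
group order together with every peak position inside it: the test statistic
is the Mack–Wolfe umbrella sum of pairwise Mann–Whitney counts, ascending
towards the peak group and descending after it, with ties contributing
0.5. Candidates whose pair masks coincide are de-duplicated, and the
per-gene p-value is Bonferroni-corrected by the number of distinct
candidates. Defaults scan periods 12 ± 11 time points (floored at 2,
capped at series length − 1) with no restriction on the peak position,
matching a two-year four-weekly design.

## The exact null

Under the no-tie null the umbrella statistic decomposes into mutually
independent Mann–Whitney components: the Jonckheere–Terpstra parts of the
rising and falling arms *excluding* the peak group, plus one Mann–Whitney
term of all non-peak observations against the peak group. (The two arms
share the peak group and are therefore dependent as written; factoring the
peak group into the final term restores independence. The test suite
verifies the decomposition against exhaustive enumeration of every group
configuration up to n = 8.) The null pmf is the convolution of these
component distributions, cached by component multiset; beyond a
configurable total-n cap (default 40) a normal approximation with the
exact mean and variance and a continuity correction is used. Tied data are
scored with midranks and flagged; their p-values come from the no-tie
null, which is slightly conservative, and `permutationOracle()` provides a
tie-robust check (per candidate, or for the whole scan's minimum-p
statistic — the latter is necessarily below the Bonferroni-corrected p,
since candidates overlap).

## Multiple testing, calendar conversion, classification

Across genes, q-values use adaptive Benjamini–Hochberg: the number of true
nulls m0 is estimated by the lowest-slope rule
(S_i = (1 − p_(i))/(m + 1 − i), walked until the first decrease) and
replaces m in the step-up procedure; with m0 = m this is plain BH. Genes
with q below 0.01 are called rhythmic.

Periods convert to months as `T × interval / (365.25 / 12)` with the
sampling interval in days. For the peak month, the scan's phase group is
only resolved to one sampling interval (~1 month) and its first-occurrence
date drifts for candidate periods that do not divide the year; the
reported peak month therefore comes from the expression-weighted circular
mean phase of the whole series under the best-fitting period (weights
`x − min(x)`), which on simulated annual genes recovers the true peak
month within ±1 month for ~95% of detected genes versus ~85% for the raw
phase-group date. The scan's phase parameter is still reported as
`peak_index`. Periods classify as half-annual (T < 8 months), annual
(8 ≤ T ≤ 16) or long (T > 16).

Half-annual rhythms are intrinsically harder at a 28-day cadence: 6 months
is 6.52 time points, so the nearest integer periods (6 or 7) drift by more
than two phase groups across two years and smear the phase assignment.
Detection power for half-annual genes is accordingly much lower than for
annual genes; this is a property of any integer-period rank scan at this
design, not of the implementation.

# Phenology divergence

Peak-month differences use the circular distance on the 12-month ring
(range 0–6). For an ordered species pair (A reference) and month t,

    D(t) = #{genes: peak_A = t and delta_phi >= 2} / #{genes: peak_A = t}

over the genes annual-rhythmic in both species. The threshold counts a
difference of exactly 2 months as divergent (the index is also exposed
with other thresholds and is monotone in them); months with no reference
peaks have undefined D and are excluded from summaries rather than imputed
as 0. Both directions of every pair are emitted, labelled intra-genus or
inter-genera. `compareMonths()` treats pairs as blocks and months as
treatments: a Friedman rank test over the months with D defined in every
block, Nemenyi all-pairs post-hoc comparisons against the studentized
range distribution, and an insert-and-absorb compact letter display at
alpha = 0.05.

# Cross-species conservation

Series are aligned window-by-index (season position, not calendar date,
since genera may be sampled in different years), and each gene gets a
Pearson r and a mean absolute difference on the log scale; constant series
are flagged, not dropped. Genes stratify into four classes — annual
peaking in winter (December–February, by the reference species' peak),
annual peaking in the growing season, half-annual, and arrhythmic/other —
with per-class medians. Extreme genes are the top and bottom 5% of the
mean-r distribution, quantile-based with all ties included.

# Clustering overview

Rows are z-scaled with the sample (n − 1) SD, constant rows flagged and
zeroed. Hierarchical clustering uses Ward's minimum-variance criterion on
Euclidean distances (`ward.D2`); the cluster number is chosen where the
within-cluster sum of squares curve is farthest from the chord joining its
endpoints (a geometric elbow; a linear curve returns k = 1 with a flag).
PCA is a thin wrapper over `prcomp` with internal centering.

# Sequence divergence

dN and dS use Nei–Gojobori (1986) counting: per codon, each position
carries one site split by the fraction of its non-stop single-base mutants
that are synonymous (mutations to stops leave the denominator); site counts
are averaged over the two sequences; multi-difference codons average the
synonymous/nonsynonymous step counts over all minimal mutational pathways,
excluding pathways through stop codons; proportions are Jukes–Cantor
corrected, `d = -(3/4) ln(1 - 4p/3)`, undefined (and flagged saturated) at
p ≥ 3/4. omega = dN/dS is +Inf when dN > 0 with dS = 0, which the standard
filters then remove: omega ≥ 99, dS > 10, dS < 0.001, or dN < 0.0003, with
a per-rule removal report. Rate regressions are OLS of log2(rate) on the
predictor (phase divergence or mean expression) with a t-test on the
slope; non-positive rates are excluded from the log and counted. A
precomputed rates table (e.g. from a maximum-likelihood codon model) can
be fed directly to `filterDivergence()`/`regressRates()` in place of the
counting estimator.

# The synthetic generator

`simulateDataset()` draws negative-binomial counts whose log2 mean is
`log2(depth * baseline) + A * cos(2 pi (t - peak) / P)` for rhythmic genes
(P = 12 or 6 months) and flat otherwise. Defaults and the reasons for
them:

* **Category mixture** 35% annual / 5% half-annual / 60% arrhythmic —
  consistent with seasonal transcriptomes of temperate evergreens, where
  roughly 40–50% of expressed genes test rhythmic and the large majority
  of those are annual. The mixture also interacts with normalization: a
  synchronized winter-locked block larger than the 30% M-trim would leak a
  shared scaling wobble into every gene (see *Limitations*).
* **Phase structure**: a `winterLockFraction` (default 0.8 in the recovery
  studies) of annual genes shares one peak month across species drawn from
  December–February; the rest draw a species-common growing-season base
  month (March–November) plus independent per-species offsets
  `round(N(0, growingPhaseSdMonths))`, default SD 2 months. Tissues share
  a gene's phase.
* **Noise**: NB dispersion 0.1 (variance `mu + 0.1 mu^2`), amplitude 1.5
  on the log2 scale, expected library depth 2e6 — moderate-depth bulk
  RNA-seq territory.
* **Design**: 27 time points, 28 days apart, from mid-April; species
  `Qglauca, Qacuta, Ledulis, Lglaber` with 3/3/1/3 individuals; gene
  lengths log-uniform on [300, 10000] bp so RPK and GeTMM are exercised
  nontrivially; per-gene baselines log-normal (sdlog 1.2).

`simulateCdsPairs()` writes gap- and stop-free codon alignments in which
synonymous and nonsynonymous single-base substitutions are placed per
codon at rates derived by inverting the Jukes–Cantor map at the target dS
and omega; NG86 on its output recovers the targets to within a few
percent at moderate divergence.

What the generator does **not** emulate: read-level artifacts (mapping,
GC, length biases beyond the RPK unit), tissue-specific phases, amplitude
and dispersion heterogeneity across genes, non-sinusoidal waveforms, and
the real species' actual phenological dates. Passing recovery tests on
this generator therefore demonstrates the statistical machinery, not
biological claims about real genes.

# Problem sizes and numerical choices

The test-suite and acceptance studies use sizes chosen to make the
properties statistically crisp while keeping a full run in minutes on one
core: 2000 genes for null FDR, 1000 genes (half annual) for recovery, 800
genes x 4 species x 27 time points for the end-to-end winter-lock and
correlation-ordering studies (20 and 10 seeded replicates), 300 simulated
ortholog pairs for the NG86 recovery, and 20000 permutations for the
null-distribution cross-check. Other numerical conventions: midrank 0.5
for ties; exact null up to n = 40, normal approximation with continuity
correction beyond; q-values clipped to [0, 1] and monotone in p-rank;
quantile-based extreme selection includes all tied genes; divergence
months with empty denominators are NA, never 0.

# Limitations

* TMM-family normalization assumes a majority of stably expressed genes.
  When a large synchronized block (more than the M-trim fraction) rises
  together — e.g. extreme winter locking with a high rhythmic fraction —
  a residual seasonal scaling wobble leaks into all genes, inflating
  cross-species correlations of arrhythmic genes and blurring phase
  estimates. This is a property of the normalization shared with any
  TMM-based analysis of strongly seasonal transcriptomes.
* Half-annual detection power is limited by the integer-period scan at a
  four-weekly cadence (see above).
* The exact null assumes no ties; tied series are flagged and their
  p-values are conservative.
* The Bonferroni correction over overlapping scan candidates is
  conservative by construction; FDR control in the null simulations is
  comfortably below the nominal level.
* NG86 counting underestimates rates at high divergence relative to
  maximum-likelihood codon models; the saturation flag and the dS/omega
  filters bound the usable range, and externally computed rates can be
  substituted.
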