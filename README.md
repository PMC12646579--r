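# molphen — comparative molecular phenology of seasonal transcriptomes

`molphen` analyses *molecular phenology*: genome-wide expression dynamics
measured under naturally fluctuating seasonal conditions, compared across
related species. It is aimed at researchers with bulk RNA-seq count
matrices sampled repeatedly (e.g. every four weeks for two years) from
several species and tissues, who want to know which genes are seasonally
rhythmic, when they peak, and how conserved that timing is between
species.

## What it computes

Starting from a gene × sample count matrix with gene lengths and sample
metadata (species, tissue, individual, date):

* **GeTMM normalization** — reads per kilobase (RPK), a per-species
  low-expression filter (mean RPK < 1 drops a gene), TMM scaling factors
  computed on RPK (via edgeR), per-million scaling, replicate averaging
  and `log2(x + 1)`.
* **Rhythm detection** — a rank-based scan over candidate periods
  T ∈ {2, …, 23} time points and all cyclic peak placements, scored by the
  Mack–Wolfe umbrella statistic

      U = Σ_{i<j≤peak} U_ij + Σ_{peak≤i<j} U_ji ,

  the sum of pairwise Mann–Whitney counts ascending to the peak phase
  group and descending after it. p-values come from the exact null
  distribution (an independent convolution of the statistic's
  Mann–Whitney components), Bonferroni-corrected over distinct
  candidates, with adaptive Benjamini–Hochberg q-values across genes;
  genes with q < 0.01 are rhythmic, classified half-annual (T < 8
  months), annual (8–16) or long (> 16), each with a calendar peak month
  φ.
* **Phenology divergence** — circular peak-month differences
  Δφ = min(|φ_A − φ_B|, 12 − |φ_A − φ_B|), 12 × 12 peak-comparison
  matrices, and the molecular phenology divergence index per reference
  month t,

      D(t) = #{genes: φ_A = t, Δφ ≥ 2} / #{genes: φ_A = t},

  profiled monthly over all ordered species pairs with a Friedman +
  Nemenyi compact-letter comparison across months.
* **Expression conservation** — per-gene cross-species Pearson r and mean
  absolute difference on index-aligned windows, stratified by rhythm
  class, with top/bottom 5% extreme-gene selection.
* **Clustering overview** — row z-scaling, Ward (`ward.D2`) hierarchical
  clustering with a within-cluster-sum-of-squares elbow, and PCA.
* **Sequence divergence** — Nei–Gojobori (NG86) counting estimates of dN,
  dS and ω = dN/dS with Jukes–Cantor correction for codon-aligned
  ortholog pairs, the standard outlier filters (ω ≥ 99, dS > 10,
  dS < 0.001, dN < 0.0003), and OLS regressions of log2 rates on Δφ or
  mean expression.
* **Synthetic data** — a seeded generator emulating a 4-species ×
  2-tissue × 27-time-point four-weekly design with negative-binomial
  counts, known rhythm categories, winter-locked versus
  growing-season-divergent phases, and codon-alignment pairs with
  controlled dN/dS — the ground truth behind the test suite.

## Worked example

```r
library(molphen)

cfg <- simConfig(nGenes = 300, tissues = "bud",
                 speciesNames = c("Qglauca", "Ledulis"),
                 replicates = c(Qglauca = 1L, Ledulis = 1L),
                 seed = 7)
sim <- simulateDataset(cfg)
sim$dataset
#> PhenologyExperiment: 300 genes x 54 samples
#>   species: Qglauca, Ledulis
#>   tissues: bud
#>   dates:   2021-04-15 to 2023-04-13

res <- runPipeline(sim$dataset, verbose = FALSE)
head(res$rhythm$Qglauca_bud[, c("gene_id", "q", "period_months",
                                "peak_month", "category")], 4)
#>   gene_id            q period_months peak_month   category
#> 1  g00001 6.500000e-01            NA         NA arrhythmic
#> 2  g00002 2.066757e-05      11.95893         12     annual
#> 3  g00003 6.500000e-01            NA         NA arrhythmic
#> 4  g00004 6.500000e-01            NA         NA arrhythmic

s <- res$profileSummary
subset(s, grouping == "all" & month %in% c(1, 7),
       select = c(month, mean_D, n_pairs))
#>   month mean_D n_pairs
#> 1     1   0.05       2
#> 7     7   0.55       2
```

Gene `g00002` is called annual (q ≈ 2 × 10⁻⁵) with a period of ~12.0
months peaking in December. The divergence profile shows the winter
constraint built into the simulation: in January only 5% of genes peaking
then in the reference species have shifted by two or more months in the
other species, against 55% in July — seasonal peak timing is conserved in
winter and diverges in the growing season.

## Layout

* `R/` — implementation (S4 classes `PhenologyExperiment`, `SimConfig`,
  `RhythmScanParams`; camelCase exported functions per stage).
* `tests/testthat/` — unit, property and end-to-end recovery tests.
* `vignettes/molecular-phenology.Rmd` — the methods vignette: models,
  assumptions, parameter meanings, numerical choices, limitations.
* `scripts/acceptance.R` — the reproduction script described above.
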