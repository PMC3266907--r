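# delimtherm

Species delimitation on ultrametric gene trees and thermal-tolerance range
analysis, in one tested R package.

Molecular surveys of morphologically plastic organisms — the motivating
system is tropical brown algae (*Dictyota*) sequenced for a plastid
marker — routinely find that one "widespread species" is a complex of
pseudocryptic lineages, and that once lineages are properly delimited,
their geographic ranges track their thermal tolerance. `delimtherm`
implements both halves of that workflow:

* **Delimitation.** A mixed Yule–coalescent threshold model on a rooted
  ultrametric gene tree: branching deeper than a threshold depth *T*
  (substitutions/site from the tips) follows a diversification process
  with rate λ₁·n^p₁; branching shallower than *T* follows per-cluster
  coalescent processes with rate λ₂·Σⱼ[nⱼ(nⱼ−1)]^p₂. Maximum likelihood
  over *T* and the rate parameters yields the entity count *N* (clusters
  of tips + singletons), a 2-log-likelihood confidence set, and a
  likelihood-ratio test against a single-process null,
  LR = 2(L − L₀) ~ χ²(3). Single- and multiple-threshold variants are
  provided.
* **Distances.** Haplotype collapsing and uncorrected p-distances with
  pairwise deletion, summarized within and among delimited species.
* **Thermal ranges.** Occurrence records intersected with min/mean/max
  SST rasters (ESRI ASCII grids, nodata-aware nearest-cell search for
  coastal records); per species: latitudinal/longitudinal range and the
  *maximum thermal tolerance range* = largest per-record max SST −
  smallest per-record min SST.
* **Association.** OLS of log₁₀(range size) on the tolerance range, with
  R², slope and a t-based p-value.
* **Synthetic data.** Seeded generators for all inputs (Yule-between /
  coalescent-within trees, JC69 alignments, gradient SST rasters,
  niche-confined occurrences), so everything is testable offline.

## Worked example

```r
library(delimtherm)

# a synthetic world: 10 species, 5 samples each, well-separated depth scales
sim <- simulate_gmyc_tree(k = 10, m = 5, s = 10, seed = 42)
fit <- fit_single_threshold(sim$tree)
fit
#> GMYC single threshold fit
#>   T (depth from tips): 0.000978499
#>   entities N: 10 (clusters 10, singletons 0), CI 10-10
#>   L0 = 423.3577, L = 432.1124, LR = 17.5095, p = 0.000555 (chi-sq, 3 df)
head(fit$entities, 3)
#>          tip entity    type
#> 1 SP005_T005      1 cluster
#> 2 SP005_T004      1 cluster
#> 3 SP005_T001      1 cluster
```

The fitted threshold (here ≈ 8×10⁻⁴ substitutions/site) separates the ten
simulated species exactly; `N` counts delimited entities and the CI is the
range of `N` over all scanned thresholds within 2 log-likelihood units of
the optimum. The LR test compares against the single-process null
(see the methods vignette for why its p-value should be read
descriptively).

The thermal half, on the packaged ten-species summary table:

```r
tab <- dictyota_thermal_summary()
tolerance_range_regression(tab, axis = "lon")
#> lon range vs max thermal tolerance range: n = 10, R^2 = 0.827, p = 0.000262
#>   log10(range) = -0.2125 + 0.1199 * max_range_C
```

Species tolerating a wider span of sea-surface temperatures occupy wider
longitudinal ranges (R² ≈ 0.83 across the ten published *Dictyota*
lineages).

End-to-end, from files:

```r
w <- simulate_world(seed = 1, dir = "world")   # writes newick/FASTA/CSV/.asc
cfg <- pipeline_config(tree = w$paths$tree, alignment = w$paths$alignment,
                       occurrences = w$paths$occurrences,
                       sst_min = w$paths$sst_min, sst_mean = w$paths$sst_mean,
                       sst_max = w$paths$sst_max, out_dir = "out", seed = 1)
report <- run_pipeline(cfg)   # delimit -> distances -> thermal -> associate
```

`run_pipeline()` writes per-stage CSV/JSON outputs and a `report.json`
with the headline numbers (N, CI, LR, p, per-axis R²); identical config
and seed give identical outputs. A command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "delimtherm")`.

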