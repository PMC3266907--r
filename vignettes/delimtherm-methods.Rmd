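---
title: "Species delimitation and thermal tolerance with delimtherm"
author: "delimtherm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delimitation and thermal tolerance with delimtherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delimtherm)
```

## What the package does

`delimtherm` implements two linked analyses for molecular biodiversity
surveys of marine organisms (its motivating system is tropical brown algae
sampled for a plastid marker):

1. **Species delimitation** on a rooted ultrametric gene tree by a mixed
   Yule-coalescent threshold model: branching deeper than a threshold depth
   `T` (measured from the tips, in substitutions/site) is attributed to an
   interspecific diversification process, branching shallower than `T` to
   within-species coalescent processes. The maximum-likelihood `T` cuts the
   tree into *entities* — clusters of tips that coalesce below the
   threshold, plus singleton tips — which are the putative species. A
   likelihood-ratio test compares the threshold model against a
   single-process null, and a confidence set collects every scanned
   configuration within 2 log-likelihood units of the optimum.

2. **Thermal-range analysis**: occurrence records are intersected with
   min/mean/max sea-surface-temperature (SST) climatology rasters; each
   species gets its latitudinal and longitudinal range and a *maximum
   thermal tolerance range* — the largest per-record maximum SST minus the
   smallest per-record minimum SST. Log-transformed range size is then
   regressed on that tolerance statistic.

A seeded synthetic-data module generates every input (trees, alignments,
rasters, occurrences) with the statistical structure the analyses assume,
so the whole pipeline is testable offline.

## The branching models

Let the tree's branching events have depths $d_1 > d_2 > \dots$ (tips at
depth 0) and cut the timeline into intervals at every event. The **null
model** applies one rate law to interval $i$:

$$b_i = \lambda\, n_i^{\,p},$$

where $n_i$ is the number of lineages present in the interval (the count
after the event that opens it). Each event-terminated interval of duration
$x_i$ contributes $\log b_i - b_i x_i$ to the log-likelihood; the final,
event-free interval contributes only its survival term $-b_i x_i$. With
$p = 1$ this is a Yule process and the maximum-likelihood rate has the
closed form $\hat\lambda = E / \sum_i n_i x_i$ with $E$ the number of
scored events — used as an oracle in the unit tests.

The **threshold model** additionally cuts the timeline (without an event)
at the threshold `T` and applies

$$b = \lambda_1\, n_{\mathrm{div}}^{\,p_1} +
      \lambda_2 \sum_j \left[n_j (n_j - 1)\right]^{p_2},$$

where $n_{\mathrm{div}}$ counts lineage segments still in the
diversification phase (deeper than their governing threshold) and $n_j$
counts lineages in cluster $j$. With $p_2 = 1$ the cluster term is
proportional to the number of lineage pairs, the neutral-coalescent rate.
The test statistic is $LR = 2(L_{\mathrm{model}} - L_0)$, referred to a
$\chi^2$ distribution with 3 degrees of freedom (the conventional
parameter count of the threshold model).

### Interval conventions (and why they matter)

The likelihood above is not fully specified until three conventions are
fixed; all three are deliberate, documented choices here:

* **Events are scored with the interval they terminate.** The rate factor
  for an event at depth $d$ uses the lineage counts of the interval on its
  root side. This yields the standard Yule estimator for the null model.
* **Within a cluster, an interval carries the lineage count established by
  the next cluster event below it.** The stretch from the threshold down
  to a cluster's first (deepest) event carries the pair rate
  $\lambda_2 \cdot 2 \cdot 1$, matching the standard coalescent's
  attribution of the deepest merger to two lineages; the stretch above the
  cluster's $k$-th event (counting from the tips) carries the
  post-event count; and the fully coalesced tail below a cluster's last
  event is dead (count 1, rate 0). Singleton branch segments below their
  threshold contribute nothing — there is nothing left to coalesce. An
  alternative, mirror-image convention (tip count at the threshold,
  decrementing toward the tips) is consistent with the same two- and
  three-tip worked examples but places the hottest coalescent rate on the
  long, event-free separation gap between the species and coalescent
  depth scales; in simulation it systematically splits one extra entity
  off at the optimum, which is why it was rejected.
* **The all-diversification candidate is `T = 0`,** at which the threshold
  model reduces *exactly* to the null (every tip a singleton, every
  segment diversification). Because this candidate is always scanned, the
  maximized threshold likelihood can never fall below the fitted null and
  the likelihood ratio is non-negative by construction.

### Threshold candidates

Between two consecutive event depths, moving `T` changes only exposure
terms, so at fixed parameters the log-likelihood is linear in `T` and,
after profiling over the parameters, convex: its supremum over a gap sits
at a gap *endpoint*, not in the middle. The scan therefore evaluates three
candidates per gap — at 98%, 50% and 2% of the gap above the shallower
event — plus one candidate above the root (one all-tip cluster) and
`T = 0`. Midpoint-only scanning loses several log-likelihood units on
trees with well-separated species and coalescent depth scales and
systematically overestimates the entity count by one; the small offset
from the gap boundaries keeps a rate switch from coinciding exactly with
an event (where the likelihood has a singular spike). The reported
threshold is the best candidate's actual depth.

### Optimization

The single-threshold likelihood separates: below `T` there are no
diversification segments and above `T` no active clusters, so the
diversification part $(\lambda_1, p_1)$ and the coalescent part
$(\lambda_2, p_2)$ are maximized independently. Given an exponent, the
rate scale is available in closed form, so each part reduces to a 1-D
profile likelihood over $p \in [-3, 5]$, maximized by a deterministic
33-point pre-grid followed by golden-section refinement (tolerance
$10^{-9}$). The profile of the diversification part is concave (log of a
positively weighted power sum), so this is exact; the coalescent profile
is handled by the same grid-plus-refinement. Rate scales are bounded in
$[10^{-8}, 10^6]$ and estimates at a bound are flagged. Heterogeneous
(multiple-threshold) configurations can mix both processes within an
interval; those are fitted by L-BFGS-B on
$(\log\lambda_1, p_1, \log\lambda_2, p_2)$ from five fixed starting
points. Everything is deterministic: identical inputs give identical
fits.

### Multiple thresholds

The multiple-threshold search is greedy and deterministic, seeded at the
single-threshold optimum: for every current cluster (visited deepest stem
first) it proposes moving that cluster's local threshold one candidate
position deeper (bounded by the cluster's stem parent) or shallower
(re-clustering the cluster's subtree at the new local threshold), refits
every proposal, and accepts the best strictly improving one until a local
optimum or the move budget `max_iter` is reached. The multiple-threshold
likelihood is therefore never below the single-threshold one. Its
confidence interval is taken over every configuration evaluated during
the search, which is a narrower (and typically more conservative) set
than the single-threshold scan.

### Calibration of the likelihood-ratio test

The $\chi^2(3)$ reference is approximate, and the package's own
calibration study (200 pure-Yule trees of 50 tips, no species structure;
re-run by `scripts/acceptance.R`) shows it is strongly anticonservative:
the nominal 5% test rejects in roughly half or more of structureless
trees. Two structural reasons: the alternative's likelihood is maximized
over $\approx 3(E-1)$ threshold candidates that the 3-df reference does
not account for, and the threshold model has near-singular density spikes
when a candidate sits just above a branching event. This behaviour is a
known property of this family of delimitation tests, not a fitting
failure — the entity count, its confidence set and the recovery behaviour
are unaffected. The significance test should be read as a descriptive
index, not a calibrated error rate; users needing calibrated significance
should bootstrap the null (out of scope here).

## Distances

Uncorrected p-distances use pairwise deletion: for each pair, only sites
where *both* symbols are an unambiguous `A/C/G/T` are compared (gaps, `N`
and IUPAC ambiguity codes are excluded pair by pair), the standard
behaviour of the distance tools used in the source literature. Haplotype
collapsing is exact string identity after normalization (uppercase,
`U -> T`). The intraspecific 95th percentile uses the
linear-interpolation quantile (R type 7), a documented choice since "95%
of the values" admits several conventions.

## Thermal summaries

SST layers are ESRI ASCII grids, cell-center registered, row 1
northernmost; a cell is valid only if all three layers have data there,
and `min <= mean <= max` is enforced at read time. Extraction takes the
containing cell's values; coastal records routinely fall on land cells of
marine grids, so a nodata hit searches the Chebyshev neighbourhood within
`radius` cells (default 2) for the nearest valid cell by center distance,
ties broken in row-major order. The longitudinal range is the raw
`max - min` span on $[-180, 180]$ by default (consistent with published
spans exceeding 300 degrees); a `circular_lon` option computes the
minimal covering arc instead. Records with identical coordinates are
kept; the maximum thermal tolerance range uses record-level extremes,
which is why it is never smaller than the difference of the per-species
mean max and mean min SST.

The association step regresses $\log_{10}(\text{range})$ on the maximum
thermal tolerance range; $R^2$ is invariant to the log base, so the base
only affects the slope's units. Species with non-positive range are
excluded (their log is undefined) rather than floored. On the packaged
ten-species Dictyota summary table the longitudinal regression gives
$R^2 \approx 0.827$; the latitudinal one gives $\approx 0.77$ from the
rounded table, a known discrepancy with the value computed from
unrounded per-record data, so only the longitudinal value is treated as
exactly reproducible.

## The synthetic world

`simulate_gmyc_tree()` draws a Yule species tree conditioned on `k` tips
(rate `lambda`, default 20 per substitutions/site — giving species-tree
depths of a few hundredths, the scale of a plastid marker) and grafts a
Kingman coalescent of `m` samples (scale `theta`, default 0.005) onto
each tip. Within-species subtrees are rescaled so the deepest coalescence
is exactly the shallowest species divergence divided by the separation
factor `s`; `s = 10` gives cleanly delimitable species, `s` near 1 hard
cases. Because of this rescaling the simulated problem is determined by
`(k, m, s)` up to an overall scale. `simulate_sequences()` runs JC69
along the tree (via phangorn). `simulate_sst_raster()` builds
$\mathrm{mean}(\phi) = T_{eq} - \Delta T (|\phi|/90)^2$ with seasonal
amplitude $A(\phi) = A_0 |\phi|/90$ (defaults 28, 30 and 12 °C — an
equator of 28 °C, polar means near -2 °C and a 12 °C peak seasonal
swing), Gaussian cell noise applied to the mean and amplitude before the
layers are formed (so `min <= mean <= max` holds by construction), and
rectangular land masks as nodata. `simulate_occurrences()` samples cell
centers uniformly from the cells whose `[min, max]` SST lies inside a
species' thermal niche. `simulate_world()` ties these together with
niche envelopes of graded latitude reach, so tolerant species have both
wider thermal ranges and wider geographic ranges — the qualitative
association the analysis is designed to detect.

What the generator does *not* emulate: rate variation among lineages and
sites, recombination or migration between species, spatially correlated
or coastline-shaped habitat, sampling bias in occurrence records, and
raster error. Passing tests on synthetic worlds therefore demonstrate
correctness of the computations and identifiability under the model's own
assumptions, not robustness to violations of them.

## Study designs used by the automated checks

The packaged checks use: 50 recovery trees (10 species × 5 samples,
separation 10), 200 calibration trees (50 tips), 6 small trees for the
brute-force oracle comparison, 20 synthetic worlds of 8 species × 30
records for the association sign, and a 10 000-site alignment for the JC
expectation. These sizes give binomial standard errors of a few percent
on the reported rates while keeping a full run in minutes on one CPU.

## Known limitations

* The likelihood-ratio significance test is anticonservative (see above).
* The entity count is weakly biased upward when within-species sampling
  is sparse or uneven — a known property of threshold delimitation.
* The multiple-threshold search is greedy; it cannot merge clusters that
  the single-threshold start separated, and it reaches only a local
  optimum.
* Thresholds are reported at scan candidates, so `T` is resolved only up
  to the candidate spacing within its gap.
* Rasters are handled in plain latitude/longitude (WGS84); no projection,
  no area weighting.
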