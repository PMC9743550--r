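---
title: "Divisive K-means with local feature adaptation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive K-means with local feature adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mass spectrometry imaging produces one spectrum per pixel, with thousands
of peak abundances per spectrum. Molecularly distinct tissue regions are
nested — tissue types contain subtypes — and the features that distinguish
subtypes inside one region are typically flat everywhere else. A single
global feature-engineering pass therefore privileges the dominant,
top-level contrasts and discards exactly the nuances a hierarchical
analysis is after.

`divikr` implements a divisive (deglomerative) answer: recurse over
regions, and *inside every region* re-derive the feature space from that
region's data alone before deciding whether and how to split it. Three
exchangeable components make up one recursion step.

**1. GMM-based feature filtering.** For the current region we compute, per
feature, the log10 mean abundance (globally, once) and the log10 abundance
variance (locally, at each node). Each statistic's empirical distribution
is decomposed into a 1-D Gaussian mixture, fitted by EM for 1–10
components with the count chosen by minimal BIC ($-2\log L + p\log n$;
ties towards fewer components). Components holding fewer than 1 % of the
features under maximum-posterior assignment are treated as numerical
artefacts, discarded, and the weights renormalised. The crossing points of
adjacent weighted component densities become thresholds: the abundance
model's *first* crossing separates the low-abundance noise floor (removed,
once, at the root); the variance model's *topmost* crossing keeps only the
locally most variable features, stepping down to lower crossings whenever
fewer than `minFeatureFraction` of the pool would survive, and falling
back to the top `minFeatureFraction` quantile when no crossing satisfies
the bound. Zero-mean and zero-variance features carry a `-Inf` sentinel on
the log scale, never enter the mixture fit, and are always removed.

**2. The stop rule.** Whether a region holds any structure at all is
decided by a two-trial GAP comparison. For a subsample of the region,
$W_k$ is the total within-cluster dispersion under the configured metric,
and $gap(k) = \mathrm{mean}_b \log W^{*}_{k,b} - \log W_k$, where the $B$
reference datasets are drawn uniformly within the subsample's per-feature
bounds and clustered by the identical deterministic pipeline. The
subsample votes "homogeneous" when $gap(1) \ge gap(2)$; the verdict is a
strict majority over `nSubsamples` votes, and a tie counts as
heterogeneous (splitting then still has to survive the k-selection). The
plain comparison is used, without the one-standard-error correction —
repeated subsampling already averages the reference noise, and the vote
aggregates it.

**3. Clustering and k-selection.** K-means under correlation distance
(1 − Pearson; scale-invariant, the natural choice for spectra) or
Euclidean distance. Initialisation is deterministic: the region is
compressed by a KD-tree (median split on the widest-spread dimension,
leaves capped at `kdtreeLeafFraction` of the region) into weighted boxes;
seed 1 is the box centroid at `seedPercentile` of the weighted CDF of
distances from the data centroid; seed 2 repeats from seed 1; each later
seed is taken at the same percentile of the Euclidean orthogonal distance
to the affine span of the existing seeds (a line through two seeds is not
defined under correlation distance, so the subspace geometry is Euclidean
in the filtered space; distances for seeds 1–2 use the configured metric).
The number of clusters sweeps 2…`maxK`; each candidate partition is fit on
the full node and scored by a centroid-based approximate Dunn index —
minimum pairwise centroid distance over the maximum of twice the mean
member-to-centroid distance — estimated as a mean over subsamples, with
ties towards the smaller k. This keeps every model-selection quantity
$O(nk)$: the pipeline never forms an observation-by-observation distance
matrix, which the `divikCounters()` instrumentation asserts.

## Parameters that matter

| parameter | unit | 2-D preset (`oscc`) | 3-D preset (`kidney3d`) |
|---|---|---|---|
| `distance` | — | correlation | correlation |
| `maxK` | clusters/level | 10 | 10 |
| `minClusterSize` | observations | 200 | 200 |
| `maxLeafSizeStop` | observations | — | 50,000 |
| `minFeatureFraction` | fraction of pool | 0.01 | 0.005 |
| `kdtreeLeafFraction` | fraction of node | 0.01 | 0.001 |
| `seedPercentile` | percentile | 99 | 95 |
| `nSubsamples` × `subsampleSize` | — | 10 × 1000 | 10 × 5000 |

The presets carry the two published experimental parameterisations; the
3-D preset replaces the minimum-cluster rule with a leaf-size stop
(regions of 50,000 spectra or fewer are not split further). `rngSeed`
drives every stochastic step — subsampling and GAP reference draws — via
derived per-node streams, so identical input, configuration and seed
reproduce the identical tree byte for byte.

Defaults chosen where no published value exists: up to 10 GMM components
(the scale of the per-level cluster cap); 10 GAP reference sets; maximum
recursion depth 20 (a guard against adversarial inputs, never reached on
realistic data); K-means stops on unchanged labels or 300 iterations.

## Numerical choices and degenerate inputs

* Crossing points are located by bracketed root finding (`uniroot`) on the
  log-density difference between the two component means; when the
  difference does not change sign there (strongly overlapping components),
  the midpoint of the means is used and a message emitted.
* The EM engine is `mclust`'s deterministic model-based hierarchical
  initialisation with unequal-variance 1-D models. Determinism here is
  what makes whole-tree reproducibility possible; restarting EM from
  random points would trade that away for negligible likelihood gains on
  these one-dimensional problems.
* Constant observation vectors have no defined correlation; their distance
  to everything is set to 2 (maximally dissimilar).
* A cluster emptied during a Lloyd iteration is repaired by reseeding it
  at the observation farthest from its assigned centroid (at most k
  repairs per iteration), so returned partitions never contain empty
  clusters.
* Weighted percentiles use the nearest-rank rule; ties resolve to the
  lowest box index. If all candidate boxes lie in the span of the seeds
  found so far (subspace distances below 1e-12), seeding falls back to
  the distance-to-nearest-seed CDF under the configured metric.
* $\log W$ is guarded as $\log(W + 10^{-12})$ when a partition reaches
  zero dispersion.
* Ranks use average-rank tie handling, reproducing fractional ranks such
  as 2.5 or 19.5 in the published tables.

## Design choices where the design was open

* **Variance filtering is recomputed from the root-surviving pool at every
  node**, not nested inside the parent's mask: a feature flat at the
  parent level may be exactly what separates the children, and local
  re-adaptation is the point of the method. The abundance filter, by
  contrast, is a *global* noise-floor cut and runs only once.
* **Claim resolution in label normalisation** enumerates the Cartesian
  product of candidate regions over multi-claimed clusters (capped at
  100,000 scenarios with a warning) and keeps the scenario maximising the
  adjusted Rand index. Greedy Dice acceptance is "keep iff Dice strictly
  increases"; the test suite bounds its regret against the exhaustive
  subset optimum.
* **Adjusted Rand everywhere**: where the published record shows both a
  "Rand index" narrative and "Adjusted Rand" table headers, the tables are
  taken as the quantitative record.
* **EXIMS is consumed, never computed**: the spatial structure score
  enters as a supplied number already rescaled to [0, 1] (bound at 1.0 for
  degenerate single-cluster maps).

## What the synthetic generator emulates — and what it does not

`generateHierarchy()` plants a hierarchy into log-normal abundances:
per-feature base levels `N(baseLogMean, featureMeanSd)` (default 2, 0.1),
observation noise `N(0, logSd)` on the log10 scale (default 0.2, about
58 % intensity CV), and per split a disjoint block of informative features
shifted by ±`effect` log10 units per child. Three generator-level design
choices deserve explanation:

* **Balanced sign codes.** Sibling shift patterns are drawn to differ
  pairwise on 40–60 % of the split's features. Unconstrained random
  patterns occasionally produce sibling pairs agreeing on nearly all
  features — planted "clusters" that are near-duplicates no method could
  (or should) tell apart.
* **Depth attenuation** (default 0.6 per level). Deeper splits apply
  proportionally smaller shifts. Equal-amplitude nested splits do not
  produce a hierarchy at all: geometrically they are a flat set of
  equidistant blocks, and a divisive method legitimately segments them in
  one level. Attenuation encodes the biology the fixture stands for —
  intra-tissue heterogeneity is subordinate to tissue-type heterogeneity.
* **No planted noise floor.** The hierarchy fixture's uninformative
  features sit at the same abundance scale as the informative ones, so
  recovery experiments run with `applyGlobalAbundanceFilter = FALSE`: the
  global filter exists to strip a low-abundance instrument noise floor,
  which this fixture deliberately lacks. The filter's own behaviour is
  validated separately on `generateNoiseFloor()`, which plants exactly
  such a floor (a low "noise" mode of per-feature means, default 3 log
  units below the signal mode).

Passing recovery tests on these fixtures therefore demonstrates that the
recursion, filtering, stop rule and seeding interact correctly under
log-normal abundances with block-structured means. They do not
demonstrate robustness to isotope envelopes, spatial autocorrelation,
batch effects, heteroscedastic instrument noise, or feature correlations
within a tissue type — none of which the generator models.

## Problem sizes in the shipped experiments

The test suite exercises structure recovery on a 5000 × 500 two-level
hierarchy (three top-level groups of 2000/2000/1000, the middle one split
1000/1000; 25 informative features per split, 1.0 log-unit effects), vote
error rates on forty 500 × 20 blob fixtures, and scalability on a
100,000 × 500 two-cluster matrix under the 3-D preset, where the
instrumentation confirms that GAP and Dunn evaluations never exceed the
5000-observation subsample and no all-pairs distance matrix is formed.

## Known limitations

* The approximate Dunn criterion, being centroid-based, discriminates
  weakly between merging and keeping well-separated groups under the
  bounded correlation metric; with diffuse clusters the 2-vs-3 decision
  at a node can be close. The exact Dunn index is intentionally not used
  (it is quadratic); tests assert rank agreement (Spearman ≥ 0.8) between
  the two on small fixtures.
* The GAP homogeneity rule compares k = 1 against k = 2 only; a region
  whose best split is three-way but whose two-way projection looks
  homogeneous would be left unsplit. This two-trial design is what keeps
  the stop rule subsample-cheap.
* Scenario enumeration in label normalisation is exponential in the
  number of multi-claimed clusters; the 100,000-scenario cap trades
  optimality for boundedness in pathological cases.
* `readMatrix()` supports delimited text and a simple binary container;
  no claim of compatibility with any vendor or archive format is made.
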