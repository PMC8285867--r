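---
title: "Designing cluster-based sampling strata from district health indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cluster-based sampling strata from district health indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataminer)
```

## The problem

National health surveys with small budgets cannot afford one stratum per
administrative region. When a country has hundreds of districts grouped
into dozens of provinces, sampling from every province is wasteful if many
of them look alike in the quantities the survey cares about. `strataminer`
implements an alternative: *let the data define the strata*. Districts are
described by a panel of numeric indicators covering health-service demand,
structure and outcomes (a "DSO" panel: hospitalization rates, insurance
coverage, bed and physician densities, cause-specific mortality
probabilities, and so on), and clustering finds a small number of
internally homogeneous groups of districts. Each cluster becomes a
stratum; one representative unit per stratum is then enough, and the gain
over simple random sampling (SRS) is quantified by simulation.

The workflow is:

1. **Clusterability** — is there any cluster structure at all? (Hopkins
   statistic)
2. **Clustering** — a Gaussian mixture model with BIC selection ("MCM")
   and complete-linkage hierarchical clustering with a majority-vote k
   ("HCM"), run side by side.
3. **Validation** — internal compactness/separation indices and
   leave-one-column-out stability indices for each candidate clustering.
4. **Profiling** — a decision tree turns the chosen clusters into
   human-readable threshold rules on raw-scale indicators.
5. **Design products** — provinces are assigned to clusters, a medoid
   province per cluster is proposed as the sampling site, and a
   Monte-Carlo simulation estimates the variance reduction over SRS.

## Data model and standardization

An `indicator_table` couples unit ids, province ids, populations, and a
units-by-indicators matrix with per-indicator metadata. Indicators can be
native to the district or to the province; province-native values are
broadcast to the province's districts, and missing district-native cells
fall back to the province value when one is supplied
(`broadcast_province_values()`). This mirrors the common situation where
some registries only report at the provincial level.

All distance-based stages (Hopkins, both clusterings, the validity
indices, medoid selection) operate on **standardized** columns
(`(x - mean)/sd`, sample sd with denominator `n - 1`): the panel mixes
scales from blood-pressure means (~130) to death probabilities (~0.01),
and unstandardized Euclidean distance would be dominated by whichever
column happens to have the largest units. Standardization is on by default
and can be disabled for data already on a common scale. Constant columns
cannot be scaled and are mapped to zero with a warning. Two stages
deliberately use the **raw** scale: the profiling tree (so that rule
thresholds like "stroke mortality < 0.008" are interpretable) and the
efficiency simulation (which estimates population-weighted means in the
indicator's own units).

## Clusterability: the Hopkins statistic

`hopkins_statistic()` draws `m` artificial points uniformly from the
per-dimension bounding box of the data and `m` real points without
replacement, and compares nearest-neighbour distances:
`H = sum(u^p) / (sum(u^p) + sum(w^p))`. Under spatial randomness the two
kinds of distances are exchangeable and `H` concentrates near 0.5; under
clustering, artificial points tend to fall in empty space (`u` large) and
`H` rises towards 1. The conventional rule treats `H > 0.5` as
clusterable. Defaults: `m = max(10, 0.1 n)` and exponent `p = 1` (the
classical form); `p = d` is available because the literature contains both
variants. Both the probe subset and the uniform draws are governed by an
explicit seed.

## Model-based clustering (MCM)

Districts are modelled as draws from a finite mixture of `K` multivariate
Gaussians. Six covariance parameterizations are supported, from spherical
equal-volume (`EII`) to fully unconstrained (`VVV`), so the model family
can adapt cluster shape to the data rather than forcing spherical groups.
Fitting is ordinary EM; the number of free parameters is
`(K - 1) + Kd + (covariance parameters)`, and model selection maximizes

```
BIC = 2 log L - n_params log n
```

(the larger-is-better sign convention: the largest BIC wins). `select_gmm()`
scans `K = 1..12` across all six families by default and returns the hard
partition of the winner plus the full BIC table. Numerical choices:

* **Initialization** is a deterministic Ward-linkage partition cut at `K`
  (computed once and reused across the scan), so fits are reproducible by
  construction; random restarts (seeded) are used only after a component
  collapses (mixing weight below `1/(10n)`).
* **Convergence**: relative log-likelihood change below `1e-6`, at most
  500 iterations; non-converged fits are returned flagged, and excluded
  from selection.
* **Regularization**: every covariance receives a ridge of `1e-6` times
  the mean column variance on its diagonal, bounding the smallest
  eigenvalue away from zero without an eigendecomposition per iteration.
* **Ties** in BIC (within `1e-9`) break to the smaller `K`, then to the
  simpler family, favouring parsimony.
* The EM inner loop is compiled (RcppArmadillo); an R-level density
  evaluator is kept alongside and the two are cross-checked against an
  independent mixture implementation in the tests.

## Hierarchical clustering (HCM) and the k-vote

`complete_linkage()` agglomerates with the complete (maximum) linkage on
Euclidean distances, and `cut_tree()` undoes the last `K - 1` merges.
Because a dendrogram does not choose `K` by itself, `propose_k()` computes
eight internal indices on the cuts over `k = 2..10` and lets each propose
one `k`; the winner is the mode, with ties to the smallest `k`. The fixed
ensemble is: Calinski–Harabasz, mean silhouette, Dunn, Davies–Bouldin,
C-index, McClain–Rao, Ball–Hall, Hartigan. This is a deliberately small,
versioned stand-in for the many-indices majority vote popular in the
hierarchical-clustering literature: the majority decision on separable
data is what matters, not the index census. Two index-specific choices
deserve note: the Ball–Hall criterion is scored by the second difference
of `WSS(k)/k` using flanking cuts *inside* the candidate range (a
one-cluster "clustering" is not a candidate, and including it makes the
index degenerate because the total sum of squares dominates), and the
Hartigan rule proposes the smallest `k` with statistic at most 10, which
requires one cut above the range. Indices whose value is undefined on
every cut (e.g. needing within-cluster variance on singleton-only cuts)
abstain with a message.

## Validity: internal and stability indices

For any candidate partition the package reports three internal indices —
within-cluster sum of squares (compactness), mean silhouette width
(`(b - a)/max(a, b)` per unit, in [-1, 1]; singletons score 0), and the
Dunn index (minimum between-cluster point distance over maximum cluster
diameter) — and four stability indices. Stability removes one indicator
column at a time, re-clusters with the same method and `K`, and compares
with the full-data partition: APN (average proportion of a unit's original
cluster mates it loses), AD (average cross-distance between the old and
new cluster of a unit), ADM (distance between the old and new cluster
centroids), and FOM (root mean within-cluster variance of the deleted
column under the reduced-data partition). Smaller is more stable. AD and
ADM are evaluated in full-data coordinates, matching the stability-
validation literature these measures come from; FOM is reported in its
plain form, with the `sqrt(n/(n - K))` adjustment behind a flag. For
mixture clusterings the covariance family is held fixed at the full-data
winner while refitting reduced data, isolating column-deletion stability
from model-selection noise. An all-singleton partition has zero diameter,
so the Dunn index returns `Inf` with a warning rather than failing.

The pipeline compares three configurations side by side — the mixture at
its BIC-selected `K`, the hierarchical cut at the voted `k`, and the
hierarchical cut at the mixture's `K` — and picks the configuration
winning the majority of the seven indices (ties favour the mixture). The
rule is explicit and overridable: on real survey-design projects this
decision typically also passes through expert review of the resulting
strata, which no automated rule can replace.

## Cluster profiling

`fit_tree()` grows a classification tree (Gini impurity, splits at
midpoints between adjacent distinct values, no pruning or surrogates;
depth at most 6 and at least 5 units per leaf by default) on the
raw-scale indicators against the cluster labels, via `rpart` with
`cp = 0`. `extract_rules()` converts every leaf into a partitioning rule —
a conjunction of `<` / `>=` threshold conditions with the leaf's majority
cluster and its coverage counts — and `rank_features()` normalizes the
Gini importance so the indicators that actually discriminate the strata
can be ranked. Applying the rule set reproduces the tree's predictions
exactly; with the defaults, an 8-cluster solution typically yields on the
order of ten rules. The tree is a description of the clustering, not a
predictive product, which is why no cross-validated pruning is offered.

## Design products and the efficiency simulation

Provinces are assigned to the cluster holding both the majority of their
districts and the largest share of their district population; when the
two criteria disagree, population decides and the province is flagged
(`assign_provinces()`). Each cluster's representative is its **medoid
province** — the province minimizing total distance to its same-cluster
peers, where a province is represented by the population-weighted mean of
its districts' standardized indicators; exact ties break to the smaller
province id.

`simulate_efficiency()` compares two designs over `B = 1000` replicates
(by default): the stratified design draws one district uniformly at
random per cluster; SRS draws the same number of districts without
replacement from all districts. Both estimate each indicator by the
population-weighted mean of the selected districts (weights proportional
to the selected districts' populations only, so both designs target the
same functional). Efficiency per indicator is
`Var_SRS / Var_cluster` across replicates (sample variances, denominator
`B - 1`): above 1 means the stratified design is more precise. An
indicator that is constant within clusters under equal populations makes
the cluster-design estimate identical in every replicate; its efficiency
is reported as `NA` with a `degenerate` flag instead of an infinity.
Population-weighted within-cluster selection is available behind a flag;
the default is uniform. The province assignment and medoid products are
deliberately *not* part of the variance simulation — they are the
deterministic reporting layer of the design, while the simulation
operates at the district level.

## The synthetic-data generator

Real district panels of this kind are typically restricted, so the
package ships a generator that emulates their structure with known ground
truth: `K` latent Gaussian clusters (spherical, diagonal or full
covariance), multinomial cluster sizes, provinces formed as
contiguous-by-cluster blocks with a 20% impurity reassignment so
provinces straddle clusters (exercising the majority/population conflict
in province assignment), and log-normal district populations
(`meanlog = log(1e5)`, `sdlog = 0.7`: median near 100,000 persons with a
realistic heavy tail). Defaults mirror a national panel: 413 districts,
31 provinces, 20 indicators.

The `separation` knob is the pairwise distance between cluster means in
units of the within-cluster standard deviation. Three geometry choices
make this knob honest under the package's own standardization step:

* means sit at the vertices of a regular simplex, so *every* pairwise
  distance equals `separation` (a 1-D lattice is used when `K > d`);
* the simplex is randomly rotated (seeded) and then *diagonal-equalized*
  by pairwise plane rotations so each column carries exactly the same
  between-cluster variance — otherwise column-wise standardization would
  shrink precisely the signal-bearing columns and silently dilute the
  knob (with an axis-aligned simplex, a nominal separation of 6 drops to
  an effective ~3.8 after standardization);
* the whole table is scaled so columns have unit total variance in
  expectation, making standardization a near-identity on generator
  output.

With these choices, separation ≥ 4 and spherical covariance put the data
in a regime where the Bayes-optimal mislabeling rate is a few percent and
any reasonable method at the correct `K` recovers the truth with adjusted
Rand index above 0.9.

What the generator does **not** emulate: the marginal distributions of
real indicator panels (skewness, bounded supports, discreteness), spatial
autocorrelation between neighbouring districts, and measurement error
correlated within data sources. Passing tests on generator output
therefore demonstrate that the machinery is correct and calibrated, not
that any particular real panel is clusterable.

## Problem sizes and reproducibility

The test-suite and acceptance studies use the generator's default scale
(413 units, 20 indicators) for the recovery and calibration studies —
20 seeds for the BIC-selection study, 50 for Hopkins calibration, 10 for
the k-vote and efficiency studies — and smaller instances (n ≤ 200) where
the property under test does not depend on scale; brute-force oracle
comparisons run on 200 random instances with n ≤ 12 and d ≤ 3, where
exhaustive evaluation of the definitions is exact. Every stochastic
component (generator, Hopkins probes, EM restarts, simulation draws)
takes an explicit seed, and the pipeline writes a manifest of output
checksums: identical input, configuration and seed give bit-identical
artifacts.

## Known limitations

* Stability indices re-cluster the data once per column; for mixture
  clusterings on wide panels this is the most expensive step of the
  pipeline.
* The k-vote ensemble is 8 indices, not a full index census; individual
  indices (notably McClain–Rao, whose raw value decreases almost
  monotonically in `k`) can defect from the majority on noisy data.
* Province assignment is a reporting convention on top of a district
  clustering; no spatial contiguity or travel-cost constraint is imposed
  on the strata.
* The efficiency simulation ignores finite-population corrections and
  within-district sampling stages; it compares first-stage designs only.
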