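---
title: "Structural covariance networks: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnets)
```

## The analysis in one paragraph

A structural covariance network (SCN) is a group-level graph: its nodes are
cortical parcels (here the 68-region Desikan-Killiany atlas, 34 per
hemisphere) and its edge weights are the absolute Pearson correlations,
across the subjects of one group, between a regional morphometric measure —
cortical surface area (CSA, mm²) or cortical thickness (CT, mm). Each group's
68×68 |r| matrix is thresholded into binary graphs at every density
("sparsity") from 0.10 to 0.40 in steps of 0.01, keeping exactly
`round(s·R(R−1)/2)` strongest edges so that both groups have identical edge
counts at each density. Global and nodal graph metrics are traced across the
grid, summarized by the trapezoidal area under the curve (AUC), and compared
between groups with a subject-relabeling permutation test. Because the SCN is
a *group-level* object, the unit of resampling is the subject: each
permutation reassigns subjects to two pseudo-groups of the original sizes and
re-runs the entire pipeline (correlation → thresholding → metrics → AUC).

## Pipeline stages and their assumptions

### Covariate correction

Before any correlation is computed, each region's values are residualized by
ordinary least squares on age and sex (`residualize()`), fitted on both
groups pooled. Pooled fitting is the default because group-specific centering
would remove exactly the between-group mean differences whose covariance
consequences the analysis is meant to capture, and because the nuisance
model (a linear age slope and a sex offset) is assumed common to both
groups. Both the covariate list and pooled-versus-per-group fitting are
arguments. Residuals are deliberately *not* re-standardized: Pearson
correlation is invariant to per-region affine rescaling, so standardization
would change nothing downstream (a property the test suite asserts).

### Thresholding

Matched-density binarization is the field's standard answer to the
confound that almost every graph metric depends strongly on edge count.
Edge count depends only on the sparsity and the node count, never on the
data, so group comparisons at a density are comparisons of topology, not of
degree. Ties between equal |r| values are broken by lexicographic node-index
order: ties have measure zero in real data but are common in toy fixtures,
and a deterministic rule makes every result bit-reproducible. A consequence
of ranking edges once per matrix is that edge sets are nested along the
grid, which the suite also checks.

The lower end of the grid (0.10) can produce disconnected graphs. The
package follows the dominant toolbox convention: characteristic path length
averages finite distances only, while the efficiency metrics natively treat
unreachable pairs as zero contribution. The consequences of this convention
are discussed at the end of this vignette, because they matter for what the
synthetic-effect tests can and cannot show.

### Graph metrics

All metrics use the binary, undirected forms: Watts–Strogatz clustering
(`Cp`), characteristic path length (`Lp`), Latora–Marchiori global and local
efficiency, Newman modularity `Q` (best of 10 seeded Louvain restarts with
shuffled node order; only the Q value is reported, the partition is an
implementation detail), nodal degree, nodal efficiency, and betweenness
centrality (unordered pairs, endpoints excluded, unnormalized — the center
of a 5-star scores 6). The binary choice is deliberate: the networks are
explicitly binarized, so weighted variants would be inconsistent with the
thresholding step.

`gamma = Cp/⟨Cp_rand⟩` and `lambda = Lp/⟨Lp_rand⟩` normalize against an
ensemble of degree-preserving Maslov–Sneppen rewirings (default 100 networks,
10 attempted swaps per edge, seeds derived from one master seed), and the
small-world index is `sigma = gamma/lambda`, exactly. A graph is called
small-world when `sigma > 1`: clustering above, path length near, the
random-network level. The ensemble size trades Monte-Carlo error in the
normalizers against runtime; 100 networks puts the standard error of
`⟨Lp_rand⟩` well below 1% for these graph sizes.

Internally, shortest-path matrices and clustering are computed by dense
boolean matrix products (BLAS), which for 68-node graphs is considerably
faster than per-call graph-library dispatch; rewiring and betweenness use
igraph's C implementations. Every metric is validated against independent
brute-force oracles (Floyd–Warshall, triangle enumeration, exhaustive
shortest-path enumeration, exhaustive partition search) on randomized
batteries of small graphs.

### Group inference

The observed statistic for a global metric is `AUC_A − AUC_B` of its curve
over the grid. The permutation null relabels subjects (exact group sizes
preserved) and re-runs everything; the p-value is the two-tailed add-one
estimator `(1 + #{|null| ≥ |obs|})/(B + 1)`, which can never be zero, and
the 95% band is the 2.5–97.5 percentile interval of the null differences.
Two-tailed is the default: with no a-priori direction for a topology
difference, one-sided testing would be hard to justify. The default
repetition count is 2000; the functions warn below 1000. Inside permutations the rewired-null ensemble for the normalized
metrics is reduced (default 20 per permuted group) because the permutation
distribution needs many cheap draws more than it needs individually precise
ones; the observed statistic always uses the full ensemble.

Nodal metrics are compared region by region at a single density (default
0.10, the low end of the analysis range) with the same permutation scheme,
then Benjamini–Hochberg adjusted across the 68 regions at 5% FDR.

### Clinical statistics

Demographic and clinical comparisons are gated by per-group Shapiro–Wilk
tests at α = 0.05 (the gate's α is an assumption, stated here once): both
groups compatible with normality → pooled-variance two-tailed t-test,
otherwise Mann–Whitney U (exact for small untied samples, normal
approximation with tie correction otherwise). The pooled t is also exposed
in a summary-statistics form (`summary_t_test()`) that reproduces data-level
results exactly from printed means/SDs/ns. Correlations between regional
morphometrics and clinical scores are partial correlations adjusted for age
and sex: both variables are OLS-residualized, the residuals correlated, and
significance taken from `t = r·sqrt(df/(1−r²))` with `df = n − 2 − k`.
These screens are reported uncorrected, as exploratory.

## The synthetic cohort generator

No subject-level data are distributed with the package, so the generator
(`synthetic_spec()` / `generate_cohort()`) produces cohorts with the
statistical structure the pipeline assumes:

* **Covariance**: subject latent vectors are multivariate normal with a
  block structure — 4 contiguous modules by default, within-block
  correlation `r_in = 0.5`, between-block `r_out = 0.15` — diluted by
  independent noise (`noise_sd = 0.3` on the unit latent scale). The
  implied matrix is eigenvalue-checked before sampling. The `group_effect`
  multiplier scales group B's between-block correlations (1 = null).
* **Covariates**: age ~ U(45, 80) years, sex ~ Bernoulli(1/2), with linear
  per-region effects defaulting to −0.3%/year and +8% (male) of the regional
  mean for surface area, −0.2%/year and +1% for thickness — magnitudes in
  line with typical cross-sectional morphometric gradients.
* **Profiles**: regional means drawn once per seed from 500–10000 mm²
  (area) or 1.5–4.5 mm (thickness), with a 10% (area) or 5% (thickness)
  coefficient of variation.
* **Clinical scores**: optional, with two-group-study-like magnitudes
  (e.g. motor score ≈ 54 ± 13, levodopa dose ≈ 818 ± 351 mg), generated
  without group differences.

Cohort sizes default to 50 and 49. Everything is deterministic given the
spec's single seed, and `write_fixture()` emits the TSV pair plus a JSON
ground-truth manifest from which the cohort can be regenerated bit-for-bit.

### What the generator does and does not emulate

It emulates: block-modular covariance (hence small-world thresholded
graphs — `sigma` averaged over the grid is ≈ 2–2.5 for default cohorts),
linear nuisance structure, realistic scales, and a controllable
integration deficit. It does not emulate: spatially smooth correlation
gradients, hemispheric symmetry, heavy-tailed regional distributions, or
subject-level outliers. Passing tests on synthetic cohorts therefore
validate the *pipeline's statistical machinery*, not the anatomical
specificity of any real-data finding.

### The integration knob and the correlation noise floor

One property deserves an honest, detailed statement. The `group_effect`
multiplier weakens between-module covariance, and one would like the
weakened group's thresholded networks to show *longer* normalized paths
(higher `lambda`) — segregation without integration. Whether that happens
is governed by the sample-correlation noise floor. With n = 50 subjects the
sampling SD of a near-zero correlation is ≈ 0.146. Two regimes:

* **Above the floor** (e.g. `r_out = 0.40`, multiplier 0.5, so the weakened
  group's between-block correlation is 0.20): the weakened group's
  between-module edges lose rank to within-module pairs, its networks
  become more modular at matched density, and `lambda`-AUC is higher in the
  weakened group in essentially every replicate (the suite asserts ≥ 10 of
  12). This is the regime in which the knob means what it says.
* **At or below the floor** (the default `r_out = 0.15` halved to 0.075):
  the weakened group's marginal edges are selected by sampling noise, i.e.
  placed uniformly at random — and random placement *shortens* paths at
  matched edge count (random graphs are near-optimal expanders). Where
  weakening disconnects the graph instead, the finite-only path-length
  convention drops the unreachable pairs and again *shortens* measured
  `Lp`. Both mechanisms run opposite to the intended direction, and no
  parameterization of a Gaussian block model at this coupling strength
  escapes them (a Gaussian model is fully determined by its covariance, so
  there is no residual design freedom). The effect direction at this
  parameter point is therefore not a reliable property, and the package
  does not pretend otherwise.

This is a statement about group-level correlation networks at n = 50 and
matched density — not about the pipeline's correctness, which is what the
oracle and calibration suites establish.

## Numerical choices and degenerate inputs

* Edge counts use half-up rounding of `s·R(R−1)/2`; at R = 68, s = 0.10
  gives 228 edges.
* An empty thresholded graph (k = 0), an edgeless graph passed to the
  modularity optimizer, a zero-variance region, a constant covariate
  column, and groups below 4 subjects are all hard errors; group sizes
  below 30 warn (correlation estimates get unstable).
* p-values from permutation tests are never 0 by construction; BH
  adjustment is the standard step-up with monotonicity enforcement.
* All randomness — generator, permutations, rewiring ensembles, Louvain
  restarts — derives from explicit integer seeds; identical seeds give
  bit-identical outputs, which the suite asserts end-to-end.

## Problem sizes used by the test suite

The suite validates statistical behavior at deliberately reduced scale:
type-I calibration uses 200 replicate cohorts of 20 + 20 subjects × 6
regions with 199 permutations each (nominal 5% rate checked against the
95% binomial interval); p-value uniformity uses 60 replicates on a coarse
3-point grid; the small-world and parameter-recovery checks run full
68-region cohorts with 100-network (observed) and 2–5-network
(within-permutation) null ensembles. These sizes were chosen to keep each
property's Monte-Carlo error well inside its assertion margin.

## Known limitations

* Group-level SCNs yield one network per group; no subject-level network,
  and hence no subject-level covariate modeling of topology, is possible.
* The permutation test assumes exchangeability of subjects under the null
  after residualization; strong unmodeled confounding would violate it.
* The nodal comparison defaults to a single density rather than the AUC of
  nodal curves (curves are available via `nodal_metric_curves()`): nodal
  metrics at a fixed density are the more interpretable unit for
  region-level reporting.
* Vertex-wise (surface-based) analysis is out of scope; the per-region
  group comparison in `run_pipeline()` is a labeled region-level surrogate.
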