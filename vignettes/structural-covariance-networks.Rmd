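---
title: "Group-level structural covariance network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level structural covariance network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
```

## The model

A structural covariance network treats brain regions as nodes and the
across-subject correlation of a morphometric measure — here, regional
gray-matter volume — as the evidence for an edge. The quantity is inherently
group-level: a single subject has one volume per region, so the Pearson
correlation r_ij between regions i and j only exists across a cohort. The
pipeline is:

1. **Confound regression.** For each region, volume is regressed on an
   intercept, age and total brain volume (OLS); the residuals replace the
   raw values. Shared age and head-size effects otherwise inflate every
   inter-regional correlation.
2. **Association matrix.** R with entries r_ij = Pearson correlation of
   residual volumes across subjects; diagonal set to 0.
3. **Binarization at matched density.** Comparing groups at a fixed
   correlation threshold would give networks of different edge counts, so
   instead each group's R is thresholded to the same network density
   D = E / (N(N-1)/2): the E = round(D·N(N-1)/2) largest signed
   correlations become edges of an undirected, unweighted graph. Two
   regimes are analyzed: the *minimum full-connectivity density* (the
   smallest density at which every group's graph is one connected
   component) and a sweep over a density grid.
4. **Graph metrics.** Clustering coefficient C (segregation),
   characteristic path length L (integration), and their ratios to a
   degree-matched random null: gamma = C/C_rand, lambda = L/L_rand, and the
   small-world index sigma = gamma/lambda. Nodal betweenness centrality and
   degree describe regional roles; a node whose betweenness is at least 2
   population SDs above the network mean is a hub.
5. **Inference.** Overall correlation strength is compared by Fisher
   r-to-z transforming each group's N(N-1)/2 upper-triangle values and
   applying a pooled two-sample t-test. Network measures, which have no
   subject-level distribution, are compared by permutation: subjects'
   residual rows are reassigned to two groups of the original sizes, the
   networks rebuilt, and the measure difference recomputed, giving a null
   distribution for the observed difference at each density.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| density grid | 0.05–0.50 step 0.01 | fraction of possible edges | spans from very sparse to clearly non-small-world; below ~0.05 a 90-node graph fragments badly, above 0.5 the graph is near-random |
| repetitions | 1000 | label permutations | the classical choice; the add-one p floor is 1/1001 |
| ensemble_size | 20 | rewired graphs per network | stabilizes C_rand and L_rand to about 1–2% relative error at N = 90, D ≈ 0.18 |
| iterations_per_edge | 10 | swap attempts per edge | standard Maslov–Sneppen mixing heuristic |
| path_length_mode | component | — | see "Numerical choices" |
| hub rule | mean + 2 SD of betweenness | — | population SD over all N nodes; no hubs when SD = 0 |

## The synthetic cohort generator

No volumetric cohort ships with the package, so `generate_cohort()` stands
in. It emulates the statistical object the pipeline consumes — a
subjects × ROI matrix whose inter-regional correlation structure differs
between groups — not images or anatomy:

* The confound-free component of each subject's ROI vector is multivariate
  normal with a **block-constant correlation matrix**: `n_modules` planted
  modules (equal sizes, remainder appended to the last), correlation
  `r_within` inside a module and `r_between` across modules, common
  marginal SD `noise_sd`. This is the simplest positive-definite structure
  whose clustering coefficient responds monotonically to `r_within`; with
  `0 <= r_between < r_within < 1` the matrix is provably positive definite
  (it is a nonnegative sum of PSD block terms plus `(1-r_within)·I`), so
  the PD guard in `cohort_spec()` is defensive.
* Confounds enter additively: age uniform on 43–67 years (a realistic
  mid-life study range), TBV normal around 1200 mL (SD 110), with per-ROI
  coefficients `beta_age = -0.05` (mild age-related atrophy) and
  `beta_tbv = 0.01` volume units per mL. Against `noise_sd = 1` these give
  confound-attributable spreads of order one unit — visible but not
  dominant, as in volumetric data.
* Defaults `r_within_A = 0.6`, `r_within_B = 0.3`, `r_between = 0.1`,
  6 modules over 90 ROIs state the planted group contrast: group A more
  strongly clustered within modules, marginal variances matched. Volumes
  are real-valued with no positivity truncation — truncation would distort
  the planted covariance, and the pipeline works on signed residuals
  anyway.

What the generator does **not** emulate: spatially structured atrophy,
hemispheric symmetry of correlations, heavy-tailed volume distributions,
site effects, or any subject-level network property. A green simulation
test therefore establishes that the pipeline recovers planted covariance
topology under Gaussian sampling — not that it would detect any particular
clinical effect.

## Numerical choices

* **Thresholding.** E = round(D·N(N-1)/2); symmetric rounding keeps the
  density grid uniform. Edges are the top-E *signed* correlations (not
  absolute values). Ties at the cutoff are broken by (row, column)
  lexicographic order — irrelevant for continuous data, deterministic for
  constructed fixtures. When the cutoff correlation is ≤ 0 the graph is
  still built but a warning notes that negative correlations entered.
* **Minimum full-connectivity density.** Per association matrix this is a
  percolation point: edges are added in the same deterministic
  decreasing-correlation order under a union-find structure until the graph
  first connects; the answer is the maximum percolation density over
  groups. A single sorted pass is simpler than binary search at the same
  O(E log E) cost and yields the exact percolation edge count; tests verify
  it against a brute-force scan over all edge counts for N ≤ 12.
* **Path length below full connectivity.** The average shortest path is
  undefined across components. Default `component` averages over
  same-component pairs only, which reproduces the qualitative behavior that
  fragmenting networks' normalized path length rises sharply near the
  percolation density; `harmonic` (reciprocal of global efficiency) is
  offered as an alternative. Neither is asserted to be what any particular
  study used — published analyses rarely say.
* **Permutation p and null interval.** p is two-tailed from the percentile
  position of the observed difference: p = min(1, 2·min(p_lower, p_upper))
  with the add-one correction, so p ≥ 1/(repetitions+1) and exact zeros are
  impossible. The reported 95% null interval is the pair of order
  statistics [d_(K+1), d_(R-K)], K = ceiling(0.025(R+1)) − 2, chosen so
  that "p < 0.05" and "observed difference outside the interval" are
  *exactly* equivalent — an absolute-value p rule cannot guarantee that for
  asymmetric nulls. No multiple-comparison correction is applied across
  ROIs or densities; pointwise uncorrected significance is the field's
  reporting convention for density sweeps, and correction is left to the
  caller.
* **Permutation pathway and confounds.** Residuals are computed once on
  the observed groups and their rows are then permuted. This mirrors
  permuting "calculated residual volumes" and avoids refitting confound
  models per permutation; it also settles the pooled-versus-per-group
  fitting question for inference (the permuted quantity is fixed). For
  network *construction*, per-group fitting is the default, with
  `pooled_confound_fit = TRUE` available since the choice is genuinely
  open.
* **Null-model ensembles.** Degree-preserving double-edge-swap rewiring.
  Graphs admitting no legal swap (triangles, stars, complete graphs) come
  back as copies with a warning; a star's ensemble then has C_rand = 0 and
  `small_worldness()` refuses the degenerate normalization. Ensemble
  member m is drawn under seed `seed + m`, so ensembles are reproducible
  and extensible. For ensemble-based measures inside the permutation test,
  each repetition uses a fresh ensemble under a per-repetition seed
  (`seed + repetition`), keeping the whole run deterministic.
* **Nodal null references.** The nodal comparison reports two distinctly
  labeled references: the permutation null (could the difference arise from
  labels alone?) and the mean over rewired ensembles of each observed graph
  (how would this node behave in a degree-matched random graph?). They
  answer different questions and are kept separate.

## Acceptance-test design

The suite's simulation criteria state their worlds up front: null
calibration uses 500 cohorts generated with identical specs for both groups
(within-module correlation 0.6, n = 35/group) and expects the clustering
test's rejection rate at the minimum full-connectivity density to fall in
[0.03, 0.07] with 200 permutations; effect recovery uses 100 cohorts at the
generator's stated 0.6-vs-0.3 contrast and expects the clustering
difference to reject in at least 80% of datasets while the path-length
rejection rate stays approximately nominal, operationalized *before
measurement* as at most 0.15. Monte-Carlo sizes follow the stated designs;
permutation counts are reduced from 1000 to 200 there to keep the suite
inside its time budget, which widens the p-value granularity but not the
tests' validity.

One caveat the suite itself exposes: a block-constant covariance contrast
at matched density cannot change clustering *without* changing path
length. The stronger-module group spends its fixed edge budget inside
near-clique modules connected by few bridges, which lengthens inter-module
geodesics, so the path-length permutation test also rejects under the
planted contrast (the criterion's path-length clause is accordingly red,
by measurement, not hidden). Reproducing an empirical "clustering differs,
path length does not" pattern would require a generative model in which
between-module connectivity is preserved while within-module coherence
drops — a property of particular datasets, not of this generator's stated
world.

## Known limitations

* Group-level only: no subject-level network measures exist in this
  framework, so no brain–behavior correlation is possible downstream.
* Binary, undirected graphs only; no weighted, partial-correlation, or
  covariance-regularized variants.
* The permutation test assumes exchangeability of residual rows under the
  null; strong group differences in covariate *distributions* (not handled
  by linear adjustment) would violate it.
* Fisher-z values of the N(N-1)/2 correlations are treated as independent
  observations in the strength t-test, as is conventional; they are not
  actually independent, so that p-value is descriptive rather than exact.
* `sigma` for sparse, fragmenting graphs is sensitive to the path-length
  convention; compare groups only at densities where both graphs are
  connected if this matters.
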