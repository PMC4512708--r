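---
title: "Weighted functional connectome analysis with fconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted functional connectome analysis with fconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fconn)
```

## The problem

Functional connectomics treats the brain as a weighted network: atlas
regions of interest (ROIs) are nodes, and the zero-lag Pearson correlation
between two regions' fMRI time series is the weight of the edge joining
them. `fconn` implements the full analysis chain from per-subject ROI time
series to group-level network statements: network construction and
thresholding, nodal elimination, weighted graph metrics normalized against
degree- and weight-preserving random networks, consensus community
detection, hub classification, and permutation inference for paired
condition contrasts. A synthetic-data module generates multi-subject
panels with known ground truth so that every stage of the pipeline is
testable end to end without any imaging data.

## Network construction

`correlation_graph()` computes the pairwise Pearson correlations of a
`roi_panel()` and clamps negative entries to zero. Correlation matrices of
task and rest fMRI typically carry only a negligible number of negative
entries once nuisance signals are regressed out (and no global-signal
regression is applied anywhere in this package, since that step is what
manufactures spurious negative correlations); clamping rather than
dropping keeps the matrix shape stable, and the clamp count is recorded on
the returned `weighted_graph` so it is never silent.

**Density thresholding.** The density (or cost) of a graph is the number
of realized edges over `N(N-1)/2`. `threshold_to_density()` keeps the
`floor(target * N(N-1)/2)` strongest edges with their weights unchanged.
Ties at the cut weight are broken by lexicographic node-pair order: this
makes thresholding deterministic and makes the edge sets of an increasing
`density_schedule()` exactly nested, which the tests assert.

**Nodal elimination.** `eliminate_nodes()` reproduces a two-stage
downsizing driven by a reference condition: the across-subject mean
reference matrix is thresholded to 50% density, and nodes retaining fewer
links than 5% of `N - 1` are dropped. The spec of this procedure leaves
open whether the 50% thresholding is per subject or aggregate; we operate
on the aggregate mean matrix, because a single removal set applied to all
conditions implies an aggregate decision, and both thresholds are exposed
as arguments. `random_network_control()` repeats the elimination on
weight-shuffled surrogates with the same number of nonzero entries and
compares degree-distribution summaries before and after downsizing, the
standard sanity check that the elimination does not erase topological
structure.

**Group averaging.** `group_average()` keeps an edge if it is present in
at least `min_presence` of the subjects (default 1, an intersection rule)
and assigns it the mean weight across all subjects. The presence fraction
is exposed because the appropriate consensus rule depends on how
consistently edges rank across subjects; for the synthetic generator
below, whose cross-subject edge-rank consistency is lower than that of
real data, `run_pipeline()` defaults to a majority rule
(`min_presence = 0.5`).

## Graph metrics and null normalization

Per node, `degree_strength()` returns the degree `k_i` (incident edge
count) and strength `s_i` (incident weight sum), each min-max normalized
to [0, 1]; a constant vector normalizes to all ones with a warning, since
there is no ordering to preserve. `clustering_coefficient()` implements
the geometric-mean (Onnela) weighted clustering coefficient on weights
scaled by the network maximum; `global_efficiency()` is the mean inverse
shortest-path length with edge lengths `1/w` (the conventional transform
for correlation weights — note that path metrics on correlation networks
mix direct and indirect coupling and should be read with caution; metric
reports carry this caveat).

Raw clustering and efficiency are not comparable across networks with
different weight distributions, so `metric_report()` normalizes both
against the mean over a `null_ensemble()` of (by default) 100 random
graphs that preserve the degree sequence exactly (Maslov–Sneppen pair
rewiring, ten attempted swaps per edge) and the weight multiset exactly.
Weights are re-laid onto the rewired topology by iterative rank matching
against the original nodal strengths — the strongest remaining weight goes
to the edge whose endpoints have the largest residual strength targets,
with residuals refreshed every 5% of assignments — which preserves nodal
strengths to within a few percent (the ensemble reports its mean relative
strength error). Complete graphs admit no degree-preserving rewiring; the
ensemble then falls back to weight shuffling, with a warning.

The small-world index is `sigma = C_norm * E_norm`, the ratio of
normalized clustering to inverse normalized efficiency. Two identities pin
the scale: a graph normalized against itself has `sigma = 1` exactly, and
a ring lattice with a few shortcuts — the canonical small-world
construction — scores `sigma > 1` against its own null ensemble.

## Community structure

`modularity_score()` is Newman's weighted modularity
`Q = sum_m [W_m/W - (S_m/2W)^2]`. `kl_refine()` maximizes it with a
Kernighan–Lin-style heuristic from an initial partition (conventionally
the all-singleton state): stochastic sweeps move single nodes to the
module with the largest positive gain; when no positive move exists the
search tries the best pairwise module merge, and then Kernighan–Lin
tunneling passes in which every node is forced to move once (steepest
first, then a few randomized orders) and the pass reverts to the best
intermediate state. Only positive-gain outcomes are ever accepted, so the
refined modularity never falls below the initial value and termination is
guaranteed. On all graphs small enough for exhaustive search over
partitions, multi-restart refinement (`restarts = 8`) reaches the global
maximum in at least 95% of seeded runs — the tests measure this against a
brute-force enumeration oracle.

Because the heuristic is stochastic, `consensus_partition()` chains 100
refinements, each seeded by its predecessor, with every chain step
canonicalized so that node #1 anchors module 1 and module ids count up in
order of first appearance. The final affiliation gives each node the
module id it received most often across the chain, with ties resolved in
favor of the earliest iteration. The modal rule is our operationalization
of "the average partition over iterations"; the per-iteration chain is
returned so users can apply co-classification consensus instead if they
prefer.

Partitions are compared with `partition_similarity()`, the normalized
mutual information `2 I(a;b) / (H(a) + H(b))` in natural logarithms (the
base cancels). Identical partitions score 1; by convention two
single-module partitions score 1 and a zero-entropy partition against a
structured one scores 0. Field usage sometimes calls this quantity a
partition *distance*, but larger values always mean more similar.

## Hubs and roles

A node is a hub when its degree or strength is at least one sample
standard deviation above the network mean; the rule is affine-invariant.
For figures and tables, min-max-normalized values are banded into
0.9–1.0, 0.7–0.89, 0.4–0.69 and <0.4, the ≥0.7 band being the
conventional "top 30%" reporting range, and `shared_distinct()` compares
that band across two networks. `participation_coefficient()` measures how
a node's connectivity spreads over modules
(`pc_i = 1 - sum_m (kappa_im/s_i)^2`, strength-weighted by default with an
edge-count mode for sensitivity checks); its maximum in an `m`-module
network is `1 - 1/m`, and `classify_hub_roles()` labels hubs within 10% of
that maximum as connectors (linking communities) and the rest as
provincial hubs (serving their own community).

## Permutation inference

`paired_permutation_tmax()` contrasts two conditions measured on the same
subjects, one value per node. Per-node paired t statistics are referred to
the permutation distribution of the *maximum* absolute statistic across
nodes, built by flipping each subject's difference vector as a whole —
joint flips preserve the spatial correlation the max-statistic correction
relies on. This controls family-wise error at the nominal level without
assuming independence across nodes. With `n` subjects the full `2^n`
sign-flip distribution is enumerated whenever it fits the permutation
budget; otherwise flips are sampled and the add-one estimator
`(1 + b)/(n_perm + 1)` keeps p values strictly positive. The tests verify
calibration directly: 500 null replicates at 14 subjects × 150 nodes put
the simulated family-wise error inside [0.03, 0.07] at a nominal 0.05.
`group_consistency_check()` is the unpaired variant over per-node time
series summary features (mean and SD), used to confirm that two cohorts
can be pooled.

## The synthetic generator

`simulation_spec()` defines a factor model for ROI time series: each node
loads `sqrt(rho_b)` on a global latent, `sqrt(rho_w - rho_b)` on its
module's latent, and hubs load an extra `hub_cross_loading` on every other
module's latent; independent noise tops each signal up to unit variance.
All latents and noise are AR(1) with coefficient 0.3, giving fMRI-like
temporal autocorrelation while leaving the cross-correlation structure
untouched (every node series is then exactly AR(1)). The implied
population correlation matrix is available in closed form from
`population_correlation()` and is nonnegative by construction, matching
the near-absence of negative correlations in cleaned fMRI connectivity
data.

Defaults mirror a realistic resting/task fMRI study: 150 nodes in 5
modules, 14 subjects, 150 time points, `rho_w = 0.6`, `rho_b = 0.15`, two
hubs per module with cross-loading 0.15, and a task condition that
multiplies hub loadings by 1.25 — emulating the characteristic "strength
rises, degree barely moves" hub shift between rest and task. Two defaults
deserve comment:

* `rho_b = 0.15` rather than something nearer zero: clamping negative
  sample correlations biases near-zero edges upward in across-subject mean
  graphs (`E[max(0, N(0, s))] ≈ 0.4 s`), so the ordinary between-module
  edge cloud must sit clearly above that bias for planted "weak" nodes
  (all loadings attenuated to 2%) to separate cleanly under the
  elimination rule. With 14 subjects this reproduces a clean 212 → 150
  reduction in the tests.
* `condition_gain = 1.25`: at this gain the hub strength shift is reliably
  detected by the paired max-statistic contrast at 14 subjects, as in the
  study design the generator emulates; the gain is validated against the
  unit-variance budget at construction time.

What the generator does *not* emulate: hemodynamics, scanner noise and
motion artifacts, heterogeneous per-edge weight distributions within a
block, negative population correlations, and spatial autocorrelation of
parcels. Passing recovery tests therefore demonstrate the pipeline's
correctness on block-modular correlation structure, not robustness to
every feature of real fMRI.

`recovery_benchmark()` runs simulation → correlation → thresholding →
consensus communities → hubs → paired contrast and reports the NMI between
planted and recovered partitions, the fraction of planted hubs reaching
the 0.7 strength band, and whether the planted condition effect is
detected. At the strong-signal conditions used in the tests (60 nodes, 4
modules, `rho_w = 0.6`, `rho_b = 0.05`, 150 time points) recovery is
essentially exact (NMI ≥ 0.9). The benchmark computes communities on the
across-subject *mean* correlation network thresholded to 60% density and
the condition contrast on per-subject networks at a common 60% density;
per-subject thresholding at higher densities is not generally feasible for
clamped correlation graphs at `rho_b = 0.05`, whose density is only ~0.70.

## The end-to-end pipeline

`run_pipeline()` wires the stages together from a configuration list or
YAML file: build per-subject networks per condition, derive the keep-list
from the reference condition, reduce all conditions identically, threshold
each subject to a common density (default 0.80, inside the typical
per-subject 77–86% band), group-average (majority presence rule by
default, see above), threshold the group network to the analysis density
(default 0.60, the usual minimum of the group density range, where
comparative analyses concentrate), and then compute metric reports (100
nulls), consensus partitions (100 iterations), hub tables, pairwise
partition NMIs and the paired strength contrast. Every stochastic stage
derives its seed from the configuration seed, so a rerun with the same
configuration is bitwise identical; `pipeline_summary()` serializes the
result to JSON.

```{r, eval = FALSE}
res <- run_pipeline(list(
  seed = 1,
  simulate = list(n_nodes = 212, n_subjects = 14, n_time = 150,
                  weak_nodes = 151:212),
  reference_condition = "task"))
pipeline_summary(res)
```

## Numerical choices and degenerate inputs

* Symmetry: matrices are symmetrized by averaging below a relative
  tolerance of 1e-8 and rejected beyond it.
* Edge counts at a target density use `floor`; ties at the cut break by
  lexicographic node pair.
* Normalized metrics divide by the null-ensemble mean; ensemble size and
  seed are recorded in every report.
* Degenerate min-max normalization (constant vector) maps to 1 with a
  warning; nodes of degree < 2 have clustering 0; isolated nodes have
  participation 0; zero-variance difference vectors get t = 0 with a
  warning.
* Problem sizes in the test-suite fixtures (≤ 212 nodes, ≤ 14 subjects,
  ensembles of 10–100, 500 calibration replicates × 1,000 permutations)
  are desk-scale choices that keep the full suite under half a minute
  while still exercising every guarantee at the study's natural
  dimensions.

## Known limitations

Path-based metrics on correlation networks remain interpretively
ambiguous; the KL heuristic guarantees local, not global, modularity
optima (hence consensus and multi-restart); strength preservation in the
null ensemble is approximate (a few percent error, reported); the modal
consensus rule can in principle mix module labels across structurally
different chain partitions, though canonical anchoring makes this rare in
practice; and the generator's homogeneous block weights understate the
weight heterogeneity of real connectomes, which is why the pipeline's
group-averaging default is a majority rather than intersection rule.
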