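# fconn

Weighted functional connectome construction and graph-theoretical analysis
in R.

`fconn` is for researchers who turn multi-subject ROI (region-of-interest)
fMRI time series — or precomputed correlation matrices — into group-level
network statements: how segregated and integrated a functional network is,
where its hubs sit, how its community structure reorganizes between
conditions, and which nodal changes survive family-wise error control.

## What it computes

Starting from per-subject panels `X ∈ R^{T×N}` (T time points, N ROIs):

* **Networks.** Edge weights `w_ij = max(0, cor(x_i, x_j))` (negative
  correlations are clamped, with a recorded count); density-based
  thresholding that keeps the strongest edges; reference-driven nodal
  elimination (threshold the mean reference network to 50% density, drop
  nodes with degree below 5% of `N−1`, apply the same keep-list to every
  condition); group averaging with a presence rule.
* **Metrics.** Degree `k_i`, strength `s_i` (min–max normalized), Onnela
  weighted clustering `c_i` (geometric mean of max-scaled triangle
  weights), global efficiency `E_glob` (mean inverse shortest path length
  on lengths `1/w`). Global clustering `C` and `E_glob` are normalized
  against 100 degree-, weight- and (approximately) strength-preserving
  random networks, and combined into the small-world index
  `σ = C_norm · E_norm` (> 1 ⇒ small-world organization).
* **Communities.** Newman modularity `Q` maximized by Kernighan–Lin-style
  iterative refinement from a singleton start, chained 100 times into a
  consensus affiliation anchored at node #1; partitions compared by
  normalized mutual information `2I/(H1+H2)`.
* **Hubs.** Hub = value ≥ mean + 1 SD; banding of normalized values
  (0.9–1.0 / 0.7–0.89 / 0.4–0.69 / <0.4); participation coefficient
  `pc_i = 1 − Σ_m (κ_im/s_i)²`; hubs with `pc` within 10% of the maximum
  `1 − 1/m` are connectors, below it provincial.
* **Inference.** Paired permutation tests with `T_max` family-wise error
  correction (joint sign flips of subject difference vectors; exact
  enumeration when `2^n` fits the budget).
* **Synthetic data.** A factor-model generator with planted modules, hubs,
  weak nodes and a task-vs-rest hub coupling gain, with the implied
  population correlation matrix available in closed form — the whole
  pipeline is testable without any imaging data.

See `vignettes/fconn-methods.Rmd` for the model details and design
decisions.

## Worked example

Simulate an 8-subject, two-condition study with 4 planted modules and 8
planted hubs, then analyze one subject's task network:

```r
library(fconn)
spec   <- simulation_spec(n_nodes = 60, n_subjects = 8, n_time = 150,
                          n_modules = 4)
panels <- simulate_panel(spec, seed = 7)
g <- threshold_to_density(correlation_graph(panels[["S01.task"]]), 0.6)
g
#> <weighted_graph> 60 nodes, 1062 edges, density 0.600

metric_report(g, nulls = 50, seed = 11)
#> <metric_report> density 0.600: C = 0.3218 (norm 1.1890),
#>   E_glob = 0.3391 (norm 0.8369), sigma = 0.9950

cons <- consensus_partition(g, iterations = 50, seed = 11)
cons
#> <node_partition> 60 nodes in 4 modules
partition_similarity(cons, spec$planted_partition)
#> [1] 1

ht <- hub_table(g, "strength", partition = cons)
head(ht[order(-ht$normalized), ], 5)
#>       node   metric value normalized     band is_hub    pc       role
#> 16 ROI_016 strength  23.5      1.000  0.9-1.0   TRUE 0.706  connector
#> 17 ROI_017 strength  23.3      0.988  0.9-1.0   TRUE 0.705  connector
#> 1  ROI_001 strength  22.9      0.959  0.9-1.0   TRUE 0.687  connector
#> 47 ROI_047 strength  22.7      0.945  0.9-1.0   TRUE 0.685  connector
#> 46 ROI_046 strength  21.8      0.875 0.7-0.89   TRUE 0.673 provincial
```

Reading this: at 60% connection density the network clusters 19% above its
random-network ensemble (`C_norm = 1.19`) while keeping near-random
efficiency; the consensus over 50 seeded refinements recovers the 4
planted modules exactly (NMI = 1); the strongest nodes are the planted
hubs, and their participation coefficients (max `1 − 1/4 = 0.75`,
connector cut `0.675`) split them into connectors linking modules and a
provincial hub serving its own.

`run_pipeline()` runs the whole chain (build → eliminate → threshold →
average → metrics → communities → hubs → contrast) from one configuration
list or YAML file and writes matrices, partitions, hub tables and a
summary JSON.

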