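# spatialcoherence

Topology-based quality control and denoising for spatial networks, aimed at
the DNA barcode networks produced by sequencing-based microscopy (DNA
microscopy, molecular pixelation and related chemistries). In these assays,
barcoded molecular entities (polonies, pixels) link to nearby entities, and
the resulting proximity graph is all that is recorded — the experiment has
no ground-truth image to validate against. This package measures how
*spatially coherent* such a graph is, i.e. how consistently its
shortest-path metric behaves like distances on a low-dimensional physical
space, using topology alone, and uses that score to drive edge filtering.

## The three diagnostics

For a connected graph with `N` nodes, mean degree `⟨k⟩` and shortest-path
distances `d′`:

- **Network dimension `D′`.** The number of nodes within BFS radius `r′` of
  a central origin grows as `N(r′) ∝ r′^D′` when the network fills a
  `D′`-dimensional space. Per origin (origins are the top-closeness nodes:
  top 1%, clamped to [10, 100]), the log–log ball-growth curve is fitted
  over the sliding window of depths with the best `R²`; the slopes are
  pooled by their mean. Shortcut (false) edges inflate `D′`; sparsification
  deflates it.
- **Spatial constant `S`.** `S = ⟨d′⟩ (⟨k⟩/N)^{1/D}` — the network analogue
  of the mean-line-segment constant of a Euclidean region (for a disk
  `⟨d⟩ ≈ 0.9 r`, giving `0.9/√π ≈ 0.508`). Computed on BFS subgraphs of
  growing depth, it stays flat across scales for coherent networks and
  falls with depth when shortcuts compress long paths.
- **Spectral scores.** Double-center the squared shortest-path matrix,
  `G = −½ J D′² J`, and examine the spectrum of `G`: the variance
  contribution `C_D = Σ_{i≤D} λ_i / Σ_j λ_j` and the spectral gap
  `Δλ = 1 − λ_{D+1}/λ_D`. Both are 1 exactly when the distances come from
  genuine `D`-dimensional Euclidean coordinates and fall as the metric
  departs from that.

Edge denoising ranks edges by confidence — raw interaction weight, or the
number of indirect simple paths of length `L = 3` around each edge — and
picks the retention fraction `τ*` that maximises `C_D` of the filtered
graph by golden-section search on `τ ∈ [0, 1]`.

## Worked example

```r
library(spatialcoherence)

net <- generate_network(n = 1500, k = 6, seed = 42)  # KNN graph on a disk
fit <- spatial_coherence(net, dim = 2, seed = 1)
fit
#> Spatial coherence (D = 2) of a graph with 1500 nodes, 5297 edges
#>   variance contribution C_D : 0.9846
#>   spectral gap           dl : 0.9370
#>   network dimension      D' : 1.900 (sd 0.072)
#>   spatial constant        S : 1.2233 at full depth (range 1.1368-1.2721)
```

A clean proximity network scores as coherent: `C_D` and `Δλ` near 1,
dimension near the physical 2, stable spatial constant. Now inject 15%
false edges (barcode collisions joining distant regions) and denoise:

```r
noisy <- add_false_edges(net, 0.15, seed = 7)
spatial_coherence(noisy$graph, dim = 2, seed = 1)
#>   variance contribution C_D : 0.1703
#>   spectral gap           dl : 0.1025
#>   network dimension      D' : 3.057 (sd 0.074)
#>   spatial constant        S : 0.5762 at full depth (range 0.5762-1.0151)

rk <- score_by_indirect_paths(noisy$graph, L = 3)
fr <- optimize_filter(noisy$graph, rk, dim = 2)
fr
#> Coherence-driven edge filter
#>   ranking: indirect_path
#>   tau* = 0.6525  (kept 3975 edges, removed 2117)
#>   S0 = 0.1703 -> S(tau*) = 0.9881  (delta S = +0.8178)
#>   12 objective evaluations

evaluate_filter(noisy$record, fr$removed)
#> precision    recall        f1
#> 0.3736419 0.9949686 0.5432692
```

All three diagnostics collapse under noise; the indirect-path filter,
guided only by the coherence score, restores `C_D` to 0.99 and removes
99.5% of the injected false edges (at the cost of some true edges — the
precision/recall trade-off of harsh filtering).

A command-line front end over the same functions ships in
`inst/scripts/spatialcoherence` (`generate`, `perturb`, `measure`,
`filter`, `convert`).

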