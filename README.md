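# nichemix

Continuous membership, borders, gradients and heterogeneity for
spatial-omics tissue organization.

## What problem this solves

Single-cell spatial-omics pipelines (CODEX and other multiplexed imaging
platforms) annotate every segmented cell with discrete hierarchical
organization labels — cellular neighborhoods, communities, tissue units.
Hard labels hide what happens *between* units: border zones, graded
transitions, and context-dependent reorganization. `nichemix` turns the
discrete annotations into per-cell membership probabilities and builds
quantitative tissue-architecture metrics on top of them. It is aimed at
computational biologists analyzing segmented cell tables with coordinates,
cell types and neighborhood-style annotations.

The core model: each cell gets a composition window — counts of each
lower-level label among its k nearest neighbors within the same region
(k = 10 over cell types at the neighborhood scale, k = 100 over
neighborhood labels at the community scale, k = 300 over community labels
at the tissue-unit scale). Each annotated unit *n* becomes a
diagonal-covariance Gaussian centroid (per-feature sample mean μₙₜ and
standard deviation σₙₜ, floored at ε = 10⁻⁶), and cell *i*'s membership is
the softmax over units of

    ℓᵢₙ = Σₜ log φ(xᵢₜ; μₙₜ, σₙₜ)

From the probability vectors the package derives:

* **Border cells** — cells at/above a probability threshold (default
  0.25) for more than one unit (Cᵢ > 1), with threshold sweeps and
  interface cell-type enrichment `E_t = log2(p_border / p_single)`.
* **Interaction networks** — unit graphs weighted by co-membership counts
  and by the symmetric geometric mean `w_AB = √(P(B|A) · P(A|B))`.
* **Transition gradients** — probability-weighted log-ratio scores
  `S = log((P₁+ε)/(P₂+ε)) · max(P₁,P₂)`, equal-width score bins, ordered
  transition clusters (weighted percentile score `W_c = Σ (N_cb/N_c)·2^rank(b)`),
  steepness = mean |second discrete derivative| of ordered cluster mean
  scores, and local gradient fields normalized per intercellular step
  `G = |∇S| · d_NN`.
* **Context heterogeneity** — centroids refit per context,
  `ΔP = P_context − P_global`, heterogeneity index `H_c = Σₙ |mean ΔP|`,
  patient aggregation, compositional enrichment with 1% / two-fold
  annotation filters, and Shannon entropy.
* **Cluster-number recommendation** — a k-means sweep scored by the
  harmonic composite of normalized fit (mean assigned log-likelihood) and
  confidence (mean assigned probability), selected on the earliest stable
  plateau between the two curve elbows.
* **Synthetic tissue** — a seeded generator (stripes, rings, blobs;
  logistic interfaces; context shifts) with ground-truth labels, so every
  stage is testable without downloads.

## Worked example

```r
library(nichemix)

# a two-stripe synthetic tissue with a one-cell-spacing logistic interface
spec <- tissue_spec("striped", n_cells = 6000, n_domains = 2,
                    interface_width = 0.66, aspect = 0.25, seed = 1)
tb <- generate_tissue(spec)
M  <- soft_membership(tb, level = "neighborhood", k = 20)
b  <- classify_borders(M, threshold = 0.25)
g  <- build_graph(b)
tp <- transition_profile(tb, M, c("N1", "N2"), seed = 0)
```

which prints:

```
<membership_matrix> 6000 cells x 2 units
  mean assigned probability 0.998
<border_set> threshold 0.25: 13 / 6000 cells are border cells
  node_a node_b count_weight geomean_weight
1     N1     N2           13              1
<transition_profile> N1 vs N2: 6000 cells in transition
  steepness 10.94, max curvature 16.1, mean G 0.7327
```

Reading the numbers: assignment is near-certain away from the interface
(mean assigned probability 0.998); the 13 border cells all lie on the
single N1/N2 interface (`distance_to_interface(tb)` confirms 100% are
within two nearest-neighbor spacings of the true boundary), and since
every border cell is co-positive for the only two units, the
geometric-mean edge weight is 1. The steepness of 10.9 says the ordered
transition clusters change score abruptly — this is a sharp interface; a
20-fold wider interface yields steepness below 1.

Real data enters the same way via `load_cell_table("cells.csv", schema = ...)`
or `read_h5ad_cell_table("cells.h5ad", ...)`, followed by the identical
calls. A thin CLI (`exec/nichemix`) wraps validation, simulation and the
staged pipeline (`run_pipeline()`), which writes CSV artifacts plus a JSON
manifest that reproduces the run byte-for-byte.

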