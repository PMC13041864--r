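---
title: "Continuous niche membership: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous niche membership: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemix)
```

## The problem

Spatial-omics pipelines for segmented single cells typically end in a hard
assignment: every cell belongs to exactly one cellular neighborhood (CN),
one community, one tissue unit. Hard labels erase exactly the information
that matters at the places where biology happens — interfaces between
organizational units, graded transitions inside them, and reorganization
across disease states. `nichemix` converts discrete hierarchical
annotations into continuous multi-membership probabilities and derives
border, network, gradient, heterogeneity and resolution-selection metrics
from them.

## The membership model

For each cell $i$ we build a composition window: the counts of each
lower-level label among its $k$ nearest neighbors (Euclidean distance,
within the same tissue region, the index cell excluded). At the CN scale
the window counts cell types with $k = 10$; at the community scale it
counts CN labels with $k = 100$; at the tissue-unit scale, community labels
with $k = 300$. These defaults follow the established hierarchical
neighborhood workflow for multiplexed imaging data; windows never cross
region boundaries, and an optional `max_radius` truncates windows in sparse
tissue (off by default, since no universally sensible radius exists).

Each annotated unit $n$ is summarized by a *centroid*: the per-feature
sample mean $\mu_{n,t}$ and sample standard deviation $\sigma_{n,t}$
(denominator $n-1$) of the windows of the cells annotated to it, with
every $\sigma$ floored at $\varepsilon = 10^{-6}$ so that zero-variance
features and singleton units stay well defined. The centroid defines a
diagonal-covariance Gaussian; the log-likelihood of cell $i$ under unit
$n$ is

$$\ell_{i,n} = \sum_t \log \phi(x_{i,t};\, \mu_{n,t},\, \sigma_{n,t}),$$

and memberships are the row-wise softmax of $\ell$, computed with
max-subtraction so no underflow or overflow occurs. The softmax implies
uniform mixture weights: we deliberately add no abundance prior, so a
cell's probabilities compare how well its *surroundings* match each unit,
not how common the units are. Centroids are annotation-conditioned, never
EM-refit: the model quantifies graded membership relative to the given
annotation rather than re-deriving one. Hierarchy levels are fit
independently. Features are raw counts; optional row-proportion
normalization is a flag on the caller's side (divide windows by their row
sums before fitting) but raw counts are the default because the centroid
statistics are defined on counts.

Ties in the window search at rank $k$ are broken by ascending `cell_id`,
which makes windows — and everything downstream — independent of row
order.

## Borders and interaction networks

A cell is *positive* for a unit when its probability is at or above a
threshold (default 0.25, inclusive — the two printed conventions in the
field differ between "at least" and "exceeding"; we use $\geq$ everywhere
and expose it as a flag). Cells positive for more than one unit
($C_i > 1$) are border cells. Each border cell contributes every unordered
pair of its co-positive units to the interaction graph; the count weight
of an edge is the number of contributing cells, and the geometric-mean
weight combines the two conditional co-occurrence probabilities among
border cells, $w_{AB} = \sqrt{P(B\mid A)\,P(A\mid B)}$, which is symmetric
by construction. Interface enrichment compares cell-type proportions in
the both-positive group against each single-positive group with a
pseudocount (default $10^{-4}$) added to both proportions.

## Gradients and steepness

For a chosen unit pair the per-cell transition coordinate is the
probability-weighted log-ratio
$S_i = \log\frac{P_i(A)+\varepsilon}{P_i(B)+\varepsilon}\cdot\max(P_i(A),P_i(B))$
with $\varepsilon = 10^{-9}$, computed on cells argmax-assigned to the
pair. Scores are discretized into $K = 5$ equal-width bins (top bin
closed); each cell's 20 nearest in-pair neighbors yield a bin-count
vector; seeded k-means partitions the vectors into 5 transition clusters,
ordered by the size-normalized weighted percentile score
$W_c = \sum_b (N_{c,b}/N_c)\, 2^{\mathrm{rank}(b)}$ with ranks $1\ldots K$
ascending. We read the weight as the power $2^{\mathrm{rank}}$ rather than
the product $2\cdot\mathrm{rank}$ — the power is strictly
order-preserving and both readings give identical orderings on monotone
bin profiles; the linear variant is available behind a flag.

Steepness is the mean *absolute* second discrete derivative of the
ordered cluster mean scores, and max-curvature the largest absolute one.
The signed mean telescopes to
$(D^{(1)}_{\mathrm{last}} - D^{(1)}_{\mathrm{first}})/(K-2)$ and is
therefore not a curvature summary (it is kept behind a flag for
diagnostics).

The local gradient fits, for each cell, the no-intercept plane
$\Delta S = \beta_x \Delta x + \beta_y \Delta y$ over its 20 nearest
scored neighbors — no intercept because all deltas are taken relative to
the focal cell, so the plane passes through the origin by construction.
$G_i = |\nabla S_i|\cdot d_{NN}$ rescales the magnitude by the region's
mean nearest-neighbor spacing, making it the expected score change per
intercellular step and hence scale-free.

One summary deserves care. The spatial mean of $|\nabla S|$ over *all*
pair cells is essentially the total score variation divided by the area,
so it is the same for a razor-sharp and a diffuse interface — it cannot
discriminate them. The discriminating summary is the mean $G$ over the
*transition zone*, which we define parameter-free as the cells in the
interior score bins (the two extreme bins hold the saturated plateaus of
either unit). `transition_profile()` reports this as
`mean_G_transition`, alongside the plain per-region mean and median.

## Context heterogeneity

For a context $c$ (a disease state, a patient, one region), centroids are
refit on the context's cells only — windows are *not* recomputed, because
a cell's spatial surroundings are what they are regardless of how the
cohort is partitioned — and
$\Delta P_{i,n}(c) = P_c(n\mid i) - P_{global}(n\mid i)$. Each cell's
deltas sum to zero; the context heterogeneity index is
$H_c = \sum_n |\bar{\Delta P}_n(c)|$, summed over regions per patient when
patient-level summaries are wanted. Units absent from a context are
dropped from its model with a warning and get `NA` deltas. Compositional
enrichment within a unit, $E_{t,n}(c) = \log_2 (p_{t,n}(c)/p_{t,n})$, is
evaluated exactly when both proportions are positive and with a
pseudocount (flagged) when one is zero — an unconditional pseudocount
would distort the exact two-fold values the annotation filter
($|E| \geq 1$ and context abundance $> 1\%$) keys on. Entropy uses the
natural log by default, base 2 behind a flag.

## Cluster-number selection

Sweeping k-means over cluster numbers $n$, each clustering is scored by
the mean assigned-cluster log-likelihood $\bar L(n)$ (fit) and the mean
assigned probability $\bar P(n)$ (confidence; exactly 1 at $n = 1$).
Both are min-max normalized *over the swept range* — changing the range
changes the normalized curves, which is why the range is recorded in every
output — and combined into the harmonic composite
$S(n) = 2L_nP_n/(L_n+P_n)$. Elbows are located on the raw curves by the
maximum perpendicular distance to the endpoint chord (the kneedle
construction; note the argmax is invariant to per-axis rescaling). The
selected resolution is the smallest $n$ between the two elbows whose
composite slope (central finite difference, one-sided at the ends) is at
most 0.005 and whose composite is at least 90% of the in-range maximum;
if none qualifies the in-range argmax is returned, flagged. k-means is
seeded with `n_init` restarts (default 10) for reproducibility.

On synthetic tissues we consistently observe the *fit* elbow at the
generative cluster number and the *confidence* elbow later — the reverse
order from noisy real data, where confidence collapses early. The reason
is structural: in clean synthetic data, k-means below the truth merges
whole units (leaving every cell confident), and above the truth splits
units into near-identical halves (a steady confidence decline with no
early knee). Selection is therefore constrained to the interval between
the two elbows whichever way they are ordered, and the recovery claim we
test is that the selected $n$ lands within $[G-2, G+3]$ of the generative
$G$.

## The synthetic-tissue generator

`tissue_spec()`/`generate_tissue()` define the package's study conditions:

* **Geometry.** Square (or `aspect`-elongated) regions at unit cell
  density — the region side is $\sqrt{n_{cells}}$, cells sit on a
  jittered grid (45% jitter), so $d_{NN} \approx 0.66$ and no two cells
  coincide. Domains are parallel stripes, concentric rings, or Voronoi
  patches of grid-jittered centers; compositions mix across interfaces
  with logistic weights of signed distance over `interface_width`.
* **Compositions.** Signature-block defaults: types split evenly into one
  block per domain, own block up-weighted by `contrast` (default 8), at
  least 12 types. This mirrors multiplexed-imaging datasets, where each
  niche is enriched for a handful of marker cell types over a shared
  background of 10–50 types, and it keeps window counts informative
  rather than concentrating all signal in one type. A vector `contrast`
  yields units of heterogeneous distinctness.
* **Scale choices in the tests.** Stripe experiments use 10k (borders) or
  6k (networks, gradients) cells with `aspect = 0.25` — an elongated
  region lengthens the interface at constant density, which stabilizes
  border statistics; windows use $k = 20$ there so the window radius
  ($\approx 2.5\,d_{NN}$) resolves the interface band at unit density.
  Heterogeneity cohorts use four contexts of 5k cells at `contrast = 2`:
  a deliberately soft regime, because saturated probabilities make
  $\Delta P$ vanish except at borders, whereas real cohorts live in the
  soft regime. Resolution experiments use ~650 cells per domain. These
  sizes are the package's study conditions, chosen to finish a full test
  run on a laptop-class single core in minutes.
* **What the generator does not emulate.** Marker intensities, segmentation
  errors, holes and vessels, anisotropic cell packing, within-domain
  composition drift, and 3-D structure. Passing tests therefore show the
  estimators behave correctly under controlled truth; they do not certify
  performance on any particular real dataset.

`generate_context_cohort()` builds multi-context cohorts from a shared
spec with seeded per-context realizations and targeted absolute shifts of
one type's proportion within one domain (other types rescaled
proportionally).

## Numerical choices and degenerate inputs

* Softmax via log-sum-exp with max subtraction; probabilities sum to 1
  within $10^{-9}$ by construction.
* $\sigma$ floor $10^{-6}$ applied to the standard deviation (not the
  variance), also for singleton units.
* Equal-width bin edges $e_j = S_{min} + (j/K)(S_{max}-S_{min})$;
  half-open $[e_j, e_{j+1})$ except the closed top bin; constant scores
  are a hard error (no meaningful bins exist).
* Local gradient: closed-form 2×2 normal equations; when the neighbor
  geometry is collinear the determinant test fails and a minimum-norm
  SVD solution is used and flagged.
* k-means ties and empty-cluster pathologies are avoided by seeded
  restarts; distance ties in windows break by `cell_id`.
* All randomness is seeded through function arguments; the RNG state of
  the calling session is saved and restored.

## Known limitations

* Diagonal covariance ignores feature correlations within units; strongly
  correlated type abundances make the likelihoods overconfident.
* The membership probabilities of well-separated annotations saturate, so
  border statistics on extremely clean data rest on few cells.
* Min-max normalization in the resolution sweep makes $L_n$, $P_n$ and
  $S(n)$ range-dependent; compare sweeps only over identical ranges.
* The h5ad reader covers the standard on-disk layout for `obs` columns
  and an `obsm` spatial matrix; exotic encodings are out of scope.
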