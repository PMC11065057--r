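---
title: "Traffic maps of the brain: the USFC model and its implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traffic maps of the brain: the USFC model and its implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usfc)
```

## The model

Structural connectivity (SC) gives the brain's road system: an undirected,
FA-weighted graph over atlas regions.  Functional connectivity (FC) gives the
traffic demand: a signed Pearson-correlation matrix over the same regions.
The unified structural-functional connectivity (USFC) model assumes route
choice is economical — travellers between two regions take the structural
route that minimises total cost, where the cost of one step between adjacent
regions is the Euclidean distance between their centroids divided by the
strength of the direct structural connection:

$$EP(i, j) \;=\; \min_{\text{routes } i \to j} \sum_{k}
  \frac{D(node_k, node_{k+1})}{SC(node_k, node_{k+1})},$$

with routes limited to at most four steps.  A step over an absent structural
edge (SC = 0) has infinite cost and is inadmissible.  Accumulating, for every
routed region pair, the magnitude of its FC value onto each structural edge
of its optimal route yields the USFC matrix: a per-edge traffic load,
weighted by both the number of routes using the segment and the strength of
the functional connections they serve.

Assumptions worth making explicit:

* **Static routing.** Costs depend only on distance and SC; current traffic
  does not reroute anyone (no congestion feedback).
* **One route per pair.** Only the minimising route carries the pair's load;
  near-optimal alternatives carry nothing.
* **Magnitude semantics.** The default accumulation uses `|FC|`: traffic is
  a magnitude, and letting positive and negative flows cancel (available as
  `mode = "signed"`) would contradict the load metaphor.  Both modes are
  implemented because the aggregation convention for signed FC is not
  uniquely determined by the model.

## Pipeline stages and their parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `max_steps` | 4 | edges | hop limit of the route search |
| `fc_policy` | `auto` | — | route masked-significant pairs if a mask exists, else all nonzero-FC pairs |
| `mode` | `absolute` | — | accumulate `|FC|` or signed FC |
| `alpha` | 0.05 | — | BH-FDR level for edge and network tests |
| `consistency_threshold` | 0.5 | fraction | strict lower bound on modal-route support |
| `fence_k` | 1.5 | — | IQR multiplier of the upper outlier fence |
| `top_k` | 10 | edges | size of the heavy-pathway ranking |
| `normalize` | `max` | — | per-matrix normalisation before cross-type metric comparisons |

A "step" is one edge, so a 4-step route has at most three intermediate
regions.  Each step's distance is the Euclidean distance between that step's
two endpoints, not the end-to-end distance of the pair being routed.

**Search algorithm.** The route search is a hop-layered Bellman–Ford
relaxation, exact by construction: optimal substructure holds only per hop
count, so the state is best-cost-per-(node, hops).  Because all edge costs
are strictly positive, the minimum over walks of at most `max_steps` edges
is attained by a simple path, which makes the layered walk relaxation exact
for simple paths as well.  An exhaustive simple-path enumerator
(`brute_force_pathway()`, guarded at N ≤ 14) serves as an independent oracle;
the test suite checks exact agreement of costs (1e-9) and tie-broken
sequences on hundreds of random graphs.

**Tie handling.** Costs within 1e-9 are treated as tied; ties are broken by
fewer steps, then by the lexicographically smallest node-index sequence.
Real-valued costs make ties essentially impossible outside constructed
fixtures, but the deterministic rule keeps the search, the oracle and
serialized outputs reproducible.

**Group statistics.** Edges nonzero in at least one subject are tested with
a one-sample t-test against zero and BH correction across tested edges only
— structural non-edges never dilute the correction.  An edge with zero
variance and nonzero mean (a constant positive load) is assigned p = 0: a
constant nonzero load is maximal evidence against the zero null, and
excluding such edges would silently drop the strongest signals.

**Outliers.** Regional load is the row sum of a symmetric matrix.  Quartiles
use linear interpolation between order statistics (R's default type 7), and
only the upper fence `q3 + 1.5 IQR` is screened: the question is which
regions carry exceptionally heavy traffic, and a two-sided rule would flag
half the brain whenever loads are skewed.

**Step-stratified coupling.** Routes are grouped by the exact node sequence;
a pair is "consistent" when one sequence is shared by strictly more than
half the cohort (ties between modal sequences drop the pair with a warning).
Identity by step count alone is available behind `match = "steps"` since
sequence-exact matching is the stricter of the two defensible readings.  The
group FC of a pair is its subject-mean FC; classification into the positive
or negative group happens after this averaging (group-average-then-classify),
and exact zeros are excluded.  Route-mean SC is evaluated on the
subject-averaged SC matrix; averaging route-mean SC per subject instead
gives the same value because the route's edge set is fixed.  Spearman's rho
uses average ranks for ties; its two-sided p-value is computed by full
permutation enumeration for groups smaller than 10 (small 3-step groups need
exactness) and by the t approximation otherwise.

**Graph metrics.** Shortest-path metrics need a weight-to-distance
convention the connectivity matrices do not carry; we use length = 1/weight,
the standard choice for connectivity-strength matrices.  FC enters as
`|FC|` because lengths must be nonnegative.  Efficiency (global, nodal,
local), betweenness centrality (normalised by `(N-1)(N-2)/2`), and
modularity come from igraph's weighted implementations; community detection
is deterministic greedy agglomeration (fast-greedy), chosen over stochastic
multi-restart algorithms because reproducibility of the analysis surface
matters more here than marginal Q gains.  When greedy merging ends on a
partition with Q < 0 (possible on near-tie graphs), the trivial
single-community partition (Q = 0 exactly) is returned instead, so reported
Q is never worse than no partition at all.  "Nodal modularity" is each
node's additive contribution
$q_i = \sum_{j \in c(i)} (w_{ij} - s_i s_j / 2W)/(2W)$, which sums exactly
to Q.  Before cross-type comparisons each matrix is normalised (default:
divided by its maximum); USFC, SC and FC live on different scales and raw
comparisons would measure scale, not topology.  `normalize = "none"`
reproduces the naive comparison.

## What the synthetic cohort emulates

Every analysis stage is testable without imaging data because the generator
plants known structure:

* **Geometry.** 90 regions inside a 140 × 180 × 120 mm ellipsoid.  Networks
  are spatially contiguous clusters whose centres tile the
  anterior-posterior axis in stratified bands, mimicking the gross
  anterior-posterior layout of cortical systems; centroids keep a minimum
  mutual separation of 12 mm, as centres of mass of a real parcellation do.
* **A midline corridor.** The backbone regions (default: the 12 regions of
  network 1) lie on an anterior-to-posterior midline chain whose consecutive
  edges carry SC = 0.9, well above every other tract.  Because the chain is
  collinear, multi-step chain routes are nearly distance-optimal, so the
  corridor attracts through-traffic — the property the top-10 pathway
  ranking is expected to recover.
* **Sparse modular SC.** Support is chosen by distance-decayed random
  scores, boosted within networks; every region gets guaranteed "ramp"
  edges to its two nearest backbone nodes (so corridor traffic enters
  locally instead of funnelling through a few mega-gateways); tracts between
  two ordinary networks are weaker (weights ≈ 0.12–0.5) than within-network
  ones (≈ 0.2–0.8), echoing the weaker FA of long association fibres.
  Total density is held at `sc_density` (default 0.15).
* **Route-linked FC.** Group-mean FC is a monotone transform of the cheapest
  route on the group-mean SC: positive pairs get
  `0.85 exp(-cost/60)`, so short strong routes carry high FC.  Designated
  network pairs (default: all pairs (i, j) with 2 ≤ i < j and i + j odd)
  get negative FC `-(0.05 + 0.7 · routeSC) exp(-cost/150)` — stronger routes
  carry stronger negative FC, the anti-correlation the coupling analysis
  must detect.  Each negative block keeps its ten shortest direct tracts in
  the SC support, with weights spanning the full strength range, so 1-step
  negative routes exist and the planted SC-FC relation is identifiable
  against distance variation.
* **Cohort noise.** Subjects are the group mean plus Gaussian noise
  (SD 0.05), re-symmetrised and clipped (SC to [0, 1], FC to [-1, 1],
  diagonals zeroed).  SC noise perturbs supported edges only: perturbing
  true zeros would make every subject's structural support near-complete and
  destroy the sparse-support semantics (USFC support within SC support,
  backbone present in every subject).  Clipping after noise, rather than
  truncated resampling, is simplicity — boundary mass is negligible at
  SD 0.05.

One RNG stream is seeded per cohort; draws occur in a documented order
(support scores, edge weights, then per-subject SC and FC noise in subject
order), so identical configurations reproduce bit-identical cohorts.

**What it does not emulate.** No BOLD time series (FC is drawn directly), no
hemispheric symmetry or homotopic connections, no measurement floor effects,
no subject-level structural variability beyond i.i.d. edge noise, and no
relationship between noise across SC and FC.  Passing tests therefore show
that the pipeline recovers planted statistical structure of this kind — not
that it would reproduce any particular empirical dataset's values.

## Problem sizes and numerical choices in the test suite

The suite runs the full default cohort (90 regions, 20 subjects, seeds 1–5)
for the recovery checks, exhaustive-oracle comparisons on 200 random graphs
of up to 12 nodes, conservation checks on 50 random cohorts, and determinism
checks on a 24-region, 3-subject pipeline run — sizes chosen so the whole
suite completes in a few minutes on one core while still exercising every
code path at the default study dimensions.  Symmetry validation uses an
absolute tolerance of 1e-9 and rejects asymmetric input rather than
symmetrising it; malformed data should fail loudly.  Matrix files are
written with 15 significant digits, so write/read round-trips are exact to
1e-12.

## Known limitations

* Routing is static; the model's own framing concedes that "real-time"
  (dynamic FC) rerouting is out of scope.
* One-step structural connections derived from probabilistic tractography
  may bundle several white-matter tracts; the model cannot distinguish them.
* The FDR family contains only edges observed nonzero in at least one
  subject; with very small cohorts this family is itself noisy.
* The exact permutation test enumerates up to 9! orderings; groups of 10 or
  more fall back to the t approximation, which is slightly liberal for
  heavy-tied data.
* `compare_metrics` normalises per matrix (default max); comparisons under
  `none` reflect scale differences between USFC, SC and FC and should be
  interpreted accordingly.
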