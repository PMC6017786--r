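---
title: "Scoring and solving the secondary-structure topology problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and solving the secondary-structure topology problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomatch)
```

## The model

A sub-nanometer cryo-EM volume shows where the secondary structure elements
(SSEs) of a protein are, but not which part of the sequence each one is.
topomatch matches the ordered sequence segments `SQ_1 … SQ_M` (helices and
strands annotated on the chain) to the unordered sticks `D_1 … D_N`
detected in the volume, assigning each stick one segment and one direction.
We assume `M_x ≥ N_x` per SSE type: detection misses elements, so some
segments may go unassigned, but every stick must be explained.

The search space is organised as a weighted directed layered graph. A node
`(i, j, t)` is the assignment of segment `i` to stick `j` in direction `t`
(with `t = 0` the chain runs from the stick's `p0` endpoint to `p1`).
Nodes exist only for type-compatible pairs, so there are at most
`2 M_H N_H + 2 M_β N_β` of them plus START and END. An edge
`(i,j,t) → (i′,j′,t′)` says "the next assigned segment after `i` is `i′`,
on stick `j′`": it requires `i′ > i`, `j′ ≠ j`, a bounded number of skipped
segments, and the loop-span feasibility rule

\[
\mathrm{vLength}(j,j') \le \mathrm{sLength}(i,i') = (\mathrm{Loop}_{aa}(i,i') + 1) \times 3.8\ \text{Å},
\]

where `Loop_aa` counts the residues strictly between the two segments on
the chain (skipped segments' residues included) and 3.8 Å is the Cα–Cα
step. `vLength` is the distance from the *exit* endpoint of `(j,t)` to the
*entry* endpoint of `(j′,t′)`. The direction-aware endpoint convention is a
design choice this package makes explicit: nodes exist per direction, so
the loop must depart from the end the chain actually leaves. An
endpoint-agnostic minimum-distance variant is available behind
`v_length(..., direction_aware = FALSE)` for comparison.

A valid topology is a START→END path that visits each column (stick)
exactly once with strictly increasing rows. The baseline edge weight is the
slack `W_Eucl = sLength − vLength ≥ 0`.

## Solving: exact best-K enumeration

The solver works on the expanded state DAG over `(node, used-column mask)`,
in which *every* path is a valid topology by construction. A backward
dynamic program computes the exact cost-to-go `h(state)`; complexity is the
usual subset-DP bound `O(Δ² N² 2^N)` with `Δ = M − N + 1`. Best-first
enumeration with priority `g + h` then emits complete paths in exactly
nondecreasing total cost. This replaces a Yen-style deviation scheme: on a
DAG with exact completion costs the two enumerate the same set in the same
order, and best-first search needs no spur-path revalidation.

Two numerical rules make ranks deterministic:

* equal-cost paths are ordered lexicographically by their `(i, j, t)`
  triples;
* costs within `1e-9` of each other are treated as equal before that rule
  applies, so mathematically tied topologies (e.g. the exact chain-reversal
  of a symmetric bundle) are ordered by the lexicographic rule rather than
  by floating-point summation order. Scores differing by less than `1e-9`
  carry no physical information at Å scale.

The column bitmask bounds the practical stick count at about 24; the
benchmark problems (N ≤ 22) fit, and the test suite exercises N ≤ 7.
`enumerate_all()` is a deliberately independent depth-first enumeration
used as the test oracle; it shares only the graph construction with the
solver.

## Skeleton scoring

The skeleton of the volume (computed externally; an input here) records
connectivity between SSEs. Scoring proceeds exactly in these stages, all
parameters in Å:

1. **SSE removal** — foreground voxels within 2.5 of a stick axis are
   cleared (the removal step is standard; the radius is this package's
   choice, about one voxel beyond the axis).
2. **Reduction** — greedy clustering with growth radius 2.0: clusters start
   at a random unassigned voxel and absorb the nearest unassigned voxel
   within 2.0 of the running centroid, recomputing the centroid each time.
   The partition depends on the seed, which is therefore a required,
   logged argument.
3. **Graph** — centroids are linked when some voxel of one cluster lies
   within 3.0 of some voxel of the other; edge weight is the
   centroid–centroid distance.
4. **Clique merging** — maximal cliques of size ≥ 3 (Bron–Kerbosch, via
   igraph) mark crowded regions and are each replaced by one node at the
   geometric centre of all member voxels. Cliques are processed in
   decreasing size; nodes already absorbed are excluded from later cliques
   (the overlap policy; ties between equal-sized cliques break on the
   smallest member id).
5. **Gap bridging** — trace ends (nodes with at most one neighbour;
   a fully orphaned fragment counts as an end) within 10.0 of each other
   are joined. Bridging adds edges only, so it can never shorten a pair
   already connected by a cheaper route.
6. **Anchors** — for each stick endpoint the nearest graph node is marked.

`W_trace` for an edge is the best `|path cost − sLength|` over simple
anchor-to-anchor paths found by depth-first search, `∞` if none is found.
The DFS is bounded (path cost ≤ `sLength` + 20 Å slack, ≤ 60 nodes per
path) because unrestricted simple-path enumeration explodes on noisy
skeletons; both limits are configurable. Anchor pairs are queried in a
canonical order so that both orientations of the same connection get the
bit-identical cost. The final skeleton weight is

\[ W_{sk} = \min(W_{Eucl} + e,\ W_{trace}) \]

with `e = 15` Å by default — the penalty for a missing trace, on the order
of one loop span; the combination rule is fixed, the value of `e` is a
package default and configurable.

## Geometry scoring

For two consecutive SSEs, `V1` and `V3` run along the elements and `V2`
along the connecting loop. The dihedral `φ ∈ (−180°, 180°]` is the signed
angle between the projections of `V1` and `V3` onto the plane perpendicular
to `V2`, right-handed about `V2`, with −180° canonicalised to +180°;
`η = θ1 + θ2 ∈ [0°, 360°]` sums the two SSE–loop angles. Across large loop
surveys the two are approximately independent and normal, giving the score

\[ f(\varphi, \eta) = A \exp\left(-\tfrac12 (x - \Lambda)^T \Sigma^{-1} (x - \Lambda)\right) \]

with fitted parameters Λ = (−4.501, 203.207)° and
Σ = diag(5581.972, 2103.773)°². `A` defaults to 1, making `f` a
dimensionless value in (0, 1]; mixing it with Å-valued skeleton weights in
the combined schemes is a unit mismatch inherited from the scheme
definitions, and `A` is configurable to rebalance them. When geometry
stands alone the package uses the weight `A − f` rather than `f` itself:
the solver minimises, so high-probability packings must get *small*
weights. This standalone transform is this package's resolution of an
ambiguity in the scheme list and is flagged as such.

On graph edges (no backbone exists yet) the vectors come from stick
endpoints, direction-aware. Degenerate geometry — coincident exit/entry
points, or an axis parallel to the loop vector — yields `f = 0`: no
geometric support, never an error, because a graph edge must always get a
weight.

## Energy scoring

Each node's SSE model is built from ideal geometry — a helix of rise
1.5 Å/residue, twist 100°, radius 2.3 Å, or a pleated strand of rise
3.3 Å/residue with the pleat width set so consecutive Cα are 3.8 Å apart —
rigidly placed on the stick (axial rescaling clamped at ±20% with a
warning) with a side-chain centre along the local outward normal at a
per-residue-type distance. Two residues are in contact when their
side-chain centres are within the cutoff (default 6.5 Å for all pairs);
the pair energy is a Lennard-Jones-style repulsion `(3.5/r)^12` minus
Gaussian wells (default: one well at 5.5 Å, depth 1, width 1 Å):

\[ E(r) = (3.5/r)^{12} - \textstyle\sum_k d_k \exp\!\left(-\frac{(r - r_k)^2}{2\sigma_k^2}\right) \]

`W_e` sums the inter-model contact energies plus both models' internal
contacts (sequence separation ≥ 2, so bonded neighbours are excluded);
everything else in the protein is ignored. With no inter-model contact the
edge weight falls back to the constant `e` (default 0, neutral). The
original potential's pair-specific cutoffs, well parameters and side-chain
radii live in an external parameterisation that is not reprinted here;
they are pluggable configuration with the defaults above, and no attempt
is made to tune them — the energy scheme is known to be the weakest and is
kept as a faithful procedural skeleton with exchangeable parameters.

## The synthetic generator: what it emulates and what it does not

`make_bundle()` builds the study conditions for the desk-scale experiments:

* serpentine SSE placement with 13 Å axis spacing — loose packing, chosen
  so the skeleton's 10 Å gap-bridging rule does not fuse the trimmed ends
  of adjacent loops through empty space;
* helices of 11–15 residues, strands of 6–9, so element axes are long
  enough that removal does not leave both ends of one element's adjoining
  loops within bridging range of each other;
* loops of 3–5 residues whose polyline contour equals the stretched span
  `(loop_aa + 1) × 3.8` times a uniform factor in [1.0, 1.2] — skeleton
  traces follow the meandering backbone and are rarely shorter than it,
  often a little longer. The extra length over the straight gap is coiled
  as a corkscrew along the gap: constant, gentle curvature (no hairpins
  for the 2 Å clustering to collapse) and coil pitch above the 3 Å
  linking cutoff, so the rasterized trace measures close to its nominal
  contour;
* terminal tails: short (8 Å) traces beyond the first and last element,
  as real chain termini leave in a skeleton; they give the free stick
  ends distinct anchors;
* `corrupt_skeleton()` cuts spheres (gap diameter ≤ `gap_len`) and adds
  random straight spurs, seeded.

These fixtures *do not* emulate: density-derived detection errors in stick
endpoints, β-sheet lateral packing (strands here pack like isolated
elements), skeleton thickness/branching noise beyond explicit spurs, or
chain breaks. Passing the recovery tests therefore shows that the scoring
and solver behave correctly on clean and mildly corrupted connectivity
evidence — not that detection noise on real volumes is handled, which is
exactly where the published benchmark shows the skeleton scheme failing.

The angle sampler draws i.i.d. from the fitted bivariate normal, which is
by construction the regime where `fit_params()` must recover the
parameters; it validates the estimator, not the normality assumption.

## Numerical choices and degenerate inputs

* Sticks with coincident endpoints are rejected at extraction (a 3-residue
  segment's two end triangles are the same atoms — such sticks cannot
  carry a direction).
* Loop residue counts use sequential chain positions, not author
  numbering, so numbering gaps do not inflate spans.
* `count_topologies()` treats the per-type factors symmetrically
  (`C(M_x, N_x) · N_x! · 2^{N_x}` for each type); this is verified against
  brute-force enumeration for every type-count tuple with `M ≤ 6`.
* The clique-merge example of two triangles sharing a node yields three
  nodes under the stated overlap policy (one merged triangle, two
  survivors); the policy, not a node-count target, is the contract.
* All randomness (cluster seeding, fixture generation, corruption) flows
  from explicit seed arguments; pipelines log every tunable.

## Problem sizes used by the test suite

The suite runs 200 random solver-oracle problems at N ≤ 5, the full
topology-count sweep at M ≤ 6, and 100 seeded end-to-end bundles
(N ∈ 2–5, with and without 8 Å gaps); these sizes exercise every code
path — larger N changes only the constant in the subset-DP bound, not the
logic.

## Known limitations

* Strand sticks are treated like helix sticks geometrically; sheet-level
  constraints (neighbouring strand order within a sheet) are not modelled.
* The energy module's ideal placement plus centroid side chains shifts
  absolute energies relative to rotamer-packed models; only the procedure
  and its contracts are preserved.
* The bitmask DP is exponential in N; beyond ~24 sticks a different
  state encoding would be needed.
* Scheme combination mixes units (Å, probability, energy); per-component
  scales are exposed (`A`, well depths, `e` penalties) but default to the
  published combination rules.
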