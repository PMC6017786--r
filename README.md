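# topomatch

Secondary-structure topology determination for cryo-EM de novo modeling.

At sub-nanometer resolution (5–10 Å) a cryo-EM volume does not resolve the
protein backbone, but the positions and orientations of the major secondary
structure elements (SSEs) are detectable as *sticks* — line segments with two
endpoints (SSEs-V). Sequence-based annotation or prediction gives the same
SSEs in chain order (*segments*, SSEs-S) but with no spatial information.
Before any backbone can be built, the two views must be reconciled: which
segment sits on which stick, and in which direction does the chain run
through it? This is the **topology problem**, and it is combinatorially
explosive — with `M_H` helix segments on `N_H` helix sticks and `M_β` strand
segments on `N_β` strand sticks there are

```
C(M_H, N_H) · N_H! · 2^N_H  ×  C(M_β, N_β) · N_β! · 2^N_β
```

candidate topologies. topomatch reimplements the DP-TOSS approach: the
candidates are the paths of a weighted directed layered graph over
assignment nodes `(i, j, t)` (segment `i` on stick `j` in direction
`t ∈ {0,1}`), edges are pruned by the loop-span feasibility rule

```
vLength(j, j′)  ≤  sLength(i, i′) = (Loop#aa(i, i′) + 1) × 3.8 Å
```

(a loop of `n` residues cannot stretch farther than `(n+1)` Cα–Cα steps),
and the best-K valid paths — each stick used exactly once, rows increasing —
are enumerated in exact score order by a subset dynamic program with
K-shortest-path enumeration. Edge weights come from six scoring schemes:

| scheme   | edge weight                     |
|----------|---------------------------------|
| `sk`     | `Wsk = min(W_Eucl + e, W_trace)` — skeleton-trace fit |
| `sk+g`   | `Wsk − f(φ, η)`                 |
| `sk+g+e` | `Wsk − f(φ, η) + We`            |
| `sk+e`   | `Wsk + We`                      |
| `g`      | `A − f(φ, η)`                   |
| `g+e`    | `(A − f(φ, η)) + We`            |

where `W_trace` is the best mismatch between a skeleton trace length and the
expected loop span, `f(φ, η) = A·exp(−½ (x−Λ)ᵀ Σ⁻¹ (x−Λ))` is a bivariate
normal score of the packing dihedral φ and packing-angle sum η = θ₁ + θ₂
(fitted mean `Λ = (−4.501, 203.207)` degrees, diagonal covariance
`(5581.972, 2103.773)` deg²), and `We` is a multi-well pairwise contact
energy between ideal-geometry SSE models.

The package also ships a synthetic fixture generator (toy helix/strand
bundles with known topology, rasterized loop skeletons with controllable
gaps and spurs, packing-angle samples), so the whole pipeline runs and is
tested at desk scale with no external data.

## Worked example

Generate a 4-helix bundle with known topology, build its skeleton graph,
score edges with the skeleton scheme and rank topologies:

```r
library(topomatch)

b     <- make_bundle(n_helices = 4, n_strands = 0, seed = 42)
grid  <- rasterize_skeleton(b)                         # voxelized loop skeleton
skelg <- skeleton_graph(grid, b$sticks, rng_seed = 42) # reduce, merge, bridge, anchor
g     <- build_graph(b$segments, b$sticks, b$chain)    # layered topology graph
g     <- compute_skeleton_scores(g, skelg)             # Wsk per edge
ranking <- k_best(apply_scheme(g, "sk"), K = 10)

ranking[1:4, c("rank", "total_score", "assignment")]
#>   rank total_score                          assignment
#> 1    1       26.41 SQ1->D1+ SQ2->D2+ SQ3->D3+ SQ4->D4+
#> 2    2       26.41 SQ1->D4- SQ2->D3- SQ3->D2- SQ4->D1-
#> 3    3       32.26 SQ1->D4- SQ2->D3- SQ3->D2- SQ4->D1+
#> 4    4       33.13 SQ1->D4- SQ2->D3- SQ3->D2+ SQ4->D1-

rank_of_truth(ranking, b$truth)
#> [1] 1
```

The top topology assigns each sequence segment `SQ_i` to detected stick
`D_j` with a direction (`+` = the stick's `p0 → p1` end order); its score is
the summed edge weight, here the skeleton-trace mismatch in Å. Rank 2 is
the chain reversal — an exact score tie, as it must be for a bundle whose
loop traces are symmetric; ties are broken lexicographically, so ranks are
deterministic. Out of `count_topologies(4, 4) = 384` candidates, only the
feasible ones are ever visited.

`tidy()`, `glance()` and `autoplot()` work on the ranking; the packaged
benchmark rank table reproduces the published summary fractions:

```r
summary_fraction(benchmark_ranks(), "sk", 35)
#> [1] 0.68
```

A thin command-line wrapper is installed at
`system.file("cli", "topomatch.R", package = "topomatch")` with
`fixtures`, `solve` and `summarize` subcommands.

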