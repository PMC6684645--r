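---
title: "Ranking binary node metadata by the dyadic effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking binary node metadata by the dyadic effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadnet)
```

## The model

An undirected simple graph with `n` nodes and `m` edges carries a
binary attribute `c` flagging `n1` nodes. Each edge, together with its
endpoints' labels, is a *dyad* of type (1–1), (1–0) or (0–0); the
counts `m11`, `m10`, `m00` partition `m`. If the `n1` flags were placed
uniformly at random, the expected counts would be
`m̄11 = C(n1, 2) δ` and `m̄10 = n1 n0 δ`, with `δ = 2m / (n(n−1))` the
density. Dyadicity `D = m11 / m̄11` and heterophilicity `H = m10 / m̄10`
measure the observed departure: `D > 1` indicates same-label clustering,
`H < 1` avoidance of mixed edges.

`D` and `H` alone are not comparable across attributes because the set
of values each can reach depends on `n1` and on the degree sequence.
With the degrees sorted non-increasing, let `H(k)` be the first `k`
entries (the head) and `T(k)` the last `k` (the tail); ties within
equal degrees are irrelevant since only the degree multiset enters.
The realizable counts obey

* `m11 ≤ min(m, C(n1,2), ⌈Σ_{i∈H(n1)} min(d_i, n1−1) / 2⌉)` — no more
  edges among flagged nodes than the network has, than a flagged clique
  holds, or than the highest-degree `n1` nodes can emit internally;
* `m10 ≤ min(m, n1 n0, min(Σ_{i∈H(n1)} min(d_i, n0),
  Σ_{i∈H(n0)} min(d_i, n1)))` — analogous caps for mixed edges under
  either head/tail split;
* `m11 ≥ max(0, ⌊(Σ_{i∈T(n1)} d_i − Σ_{i∈H(n0)} d_i) / 2⌋)` — degree
  that the lowest-degree flagged nodes cannot discharge onto unflagged
  partners must be absorbed internally;
* `m10 ≥ max(1, Σ_{i∈T(n1)} d_i − n1(n1−1))` for `0 < n1 < n` — even a
  flagged clique leaks leftover degree as mixed edges, and a connected
  graph always has at least one.

The `m00` bounds follow by swapping the roles of the labels
(`m00_bounds()` is the `m11` bound at `n0`). Dividing the bounds by the
expectations yields the rectangle `[Hmin, Hmax] × [Dmin, Dmax]`
containing every realizable `(H, D)`, with the pivot `(1, 1)` always
inside.

## The relevance score

The pivot divides the rectangle into four regions: I
heterophobic-dyadic (`H < 1 < D`), II heterophilic-dyadic, III
heterophilic-antidyadic, IV heterophobic-antidyadic. In each region the
most extreme admissible configuration is the region's outer corner, and
the vector from the pivot to that corner is the region's diagonal. An
observed attribute at `(H, D)` defines `v = (H − 1, D − 1)`; its
relevance is the projection of `v` onto the diagonal `u`, normalized by
the diagonal length:

$$ r = \frac{p(v)}{\lVert u \rVert} = \frac{v \cdot u}{u \cdot u} \in [0, 1]. $$

`r = 0` at the pivot (indistinguishable from random), `r = 1` at the
corner (as extreme as the degree sequence permits), and `r = t` along
`pivot + t·u`. Because the same normalization applies in every region
and for every `n1`, scores of different attributes are directly
comparable, which is what makes the ranking meaningful. The projection
is taken in raw `(H, D)` coordinates, exactly as the space is
constructed; no per-axis rescaling is applied even when `Dmax` greatly
exceeds `Hmax`. Rescaling would change the ranking and has no
principled normalizer, so the anisotropy of the rectangle is treated as
part of the geometry being measured.

Three conventions are fixed here because the construction leaves them
open, and each is a genuine design decision of this package:

* **Boundary assignment.** A point with `H = 1` (but `D ≠ 1`) joins the
  heterophilic side (regions II/III); `D = 1` joins the dyadic side
  (I/II). Any fixed convention works; this one makes classification
  deterministic and total.
* **Mean ties in binarization.** `binarize_mean()` flags values
  *strictly* greater than the mean: over-performers are those above
  average, and a value exactly at the mean is not above it. With
  continuous indices ties are measure-zero; with discrete data the
  choice is conservative (smaller `n1`).
* **Degenerate attributes.** For `n1 ∈ {0, 1, n−1, n}` one of the
  expectations or bound widths collapses, so `rank_metadata()` excludes
  such attributes with a logged message rather than assigning `r = 0`
  — an undefined score is not a zero score. (`permutation_test()`
  accepts `n1 = n − 1`, where `D` and `H` themselves are still
  defined.)

## Significance and redundancy

The permutation null reshuffles the label vector uniformly among all
placements with the same `n1`; edges are never rewired, because the
question is whether *this* assignment is special on *this* network.
`p_r` is the fraction of `K` reshuffles (default `K = 1000`) whose
relevance reaches the observed one. `p_D` and `p_H` are one-sided in
the direction of the observed departure — for a dyadic observation
(`D ≥ 1`), `p_D` counts reshuffles with `D` at least as large; for a
heterophobic one (`H ≤ 1`), `p_H` counts reshuffles with `H` at most as
small; the other regions mirror this. Proportions are unsmoothed (a
reshuffle set that never reaches the observed value reports exactly 0)
and ties count as qualifying, the conservative choice. One reshuffle
set per attribute serves all three p-values, so they are comparable
within a row. The same seed always reproduces the same result, and the
caller's RNG stream is left untouched.

Redundancy between two attributes is the cosine similarity of their 0/1
label vectors, taken over the same node set in a fixed (sorted) node
order: 1 for identical assignments, 0 for disjoint ones. Identical
assignments necessarily have identical dyad counts and hence identical
relevance; the converse fails, which is exactly why `rr_table()` pairs
each couple's redundancy with both relevances — relevant-but-different
assignments and similar-but-differently-relevant assignments are the
interesting corners of that table.

## The exact phase diagram as oracle

For small networks, `enumerate_configurations()` visits all
`choose(n, n1)` label placements (in lexicographic order over sorted
node ids) and tallies the degeneracy of every realizable `(m10, m11)`
cell. Three identities make this the package's internal oracle, checked
by `verify_against_bounds()` in exact integer arithmetic:

* the degeneracies sum to `choose(n, n1)`;
* the degeneracy-weighted mean of `m11` equals `m̄11` exactly (and
  `m10` likewise), since `E[m11] = m · n1(n1−1) / (n(n−1))`;
* every realizable cell lies inside the bound rectangle.

The enumerator refuses jobs above a configurable cap (default 2×10⁶
subsets) with the exact count in the error message, rather than
truncating silently — a partial phase diagram is not a phase diagram.
The test suite runs the oracle across 50 random graphs with `n ≤ 12`
at every `n1`, and against the 43-node toy (123,410 subsets), where the
exact upper tail of `D` has probability `1/123410` and the Monte-Carlo
p-value must agree within binomial error.

## Synthetic data: what it does and does not emulate

The generators produce the study conditions used throughout the tests:

* `rich_club_toy()` — a fixed 43-node, 45-edge network whose four
  flagged nodes form a clique and hold the four highest degrees, with
  dyad counts `(6, 37, 2)`, hence `D ≈ 20.07` and `H ≈ 4.76`. The toy
  is defined by its dyad counts, which fully determine `D` and `H`;
  among count splits compatible with the published rounded values,
  `m10 = 37` is used (`H = 4.76` rounds to 4.8, whereas `m10 = 38`
  would give 4.89). The reconstruction's mixing coefficient is −0.66.
* `counts_constrained_graph()` — seeded sampling of edges within each
  dyad class, realizing prescribed `(m11, m10, m00)` exactly; used to
  plant rich-club-like annotations (e.g. a flagged 5-clique on 20
  nodes with `m11 = 10, m10 = 10, m00 = 20`).
* `random_annotated_graph()` — Erdős–Rényi `G(n, m)` with a uniform
  flagged subset; the 25-node, 32-edge configuration with `n1 = 5` (or
  15) is the reference setting for phase-diagram and calibration runs.

These fixtures exercise the combinatorics fully, but they are
homogeneous-degree random graphs plus planted cliques: they do not
reproduce the heavy-tailed degree distributions, clustering or
community structure of real interactomes or trade networks. Passing
tests therefore certify the correctness of the counting, bounds,
geometry and null distribution — not that any particular real-world
attribute will be relevant.

## Numerical and scale choices

All counts and bounds are exact integers (with the stated ceil/floor);
expectations and scores are double precision, and `relevance()` clamps
its output to `[0, 1]` against rounding at the corners. Reports round
`D`, `H`, `r` to 2 decimals and p-values to 3 for display only. The
test suite keeps problem sizes at desk scale — graphs of 5–43 nodes,
enumerations up to 123,410 subsets, permutation runs of 500–4000
draws, 200-replicate calibration — which the package's own oracle
identities make sufficient: the quantities checked are exact
combinatorial identities, not asymptotics. The calibration check
(Kolmogorov–Smirnov distance of `p_r` from uniform below 0.1 at 200
replicates, `K = 500`) uses the 25-node reference graph, where the
discreteness of the `(m10, m11)` grid leaves a modal cell mass of about
0.055, small enough for near-uniformity.

## Limitations

The method is restricted to binary metadata; numeric attributes must be
dichotomized, and the mean threshold is only appropriate for reasonably
homogeneous distributions (for fat-tailed metadata a quantile- or
class-based split should be preferred upstream). The score is a single
global number: it cannot localize *which* nodes drive the correlation
(the degree–betweenness table is offered as a follow-up lens). Weighted
and directed dyads are out of scope, as are degree-preserving edge
rewiring nulls — the null model here reshuffles labels, not topology.
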