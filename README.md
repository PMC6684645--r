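# dyadnet

Networks rarely come as bare topology: nodes carry metadata — protein
functional classes in an interactome, economic indices of countries in a
trade network, group membership in a social graph. When many such
attributes are available, the practical question is which of them
actually correlate with the observed wiring, and how strongly, so that
analysis can be prioritized. `dyadnet` answers this for **binary** node
metadata (or numeric metadata dichotomized at their mean) on undirected
simple graphs, and ranks competing attributes on a common `[0, 1]`
scale.

## The method

A binary attribute splits the `n` nodes into `n1` flagged and
`n0 = n − n1` unflagged nodes, and types every edge as a (1–1), (1–0)
or (0–0) **dyad**, with counts `m11 + m10 + m00 = m`. Under uniformly
random placement of the `n1` flags the expected counts are

    m̄11 = C(n1, 2) · δ,   m̄10 = n1 · n0 · δ,   δ = 2m / (n(n − 1))

and the departure from randomness is summarized by **dyadicity** and
**heterophilicity**:

    D = m11 / m̄11,   H = m10 / m̄10.

`D > 1` means flagged nodes link to each other more than chance allows;
`H < 1` means they avoid mixed edges. Both counts are further confined
by exact combinatorial bounds derived from the degree sequence (head
and tail partitions of the sorted degrees), so every attribute lives in
a rectangle `[Hmin, Hmax] × [Dmin, Dmax]` around the pivot
`(H, D) = (1, 1)`. The **relevance score** of an attribute is the
projection of the vector from the pivot to the observed `(H, D)` onto
the diagonal of its quadrant, normalized by the diagonal length:
`r ∈ [0, 1]`, with `r = 0` for a perfectly random-looking assignment and
`r = 1` for the most extreme configuration the degree sequence admits.
Because the score only needs `(n, m, n1, m11, m10)` and the degree
sequence, it costs a handful of algebraic operations per attribute and
scales to networks of any size.

Around the score, the package provides:

- **permutation significance** (`permutation_test()`): p-values for `D`,
  `H` and `r` from label reshuffling that preserves `n1`;
- **redundancy** (`cosine_similarity()`, `rr_table()`): cosine overlap
  between label vectors, pairing each couple's redundancy with both
  members' relevance (the Redundancy–Relevance diagram in tabular form);
- an **exact phase diagram** (`enumerate_configurations()`): the full
  `(m10, m11)` degeneracy map for small networks, which doubles as a
  brute-force oracle for the bounds and expectations;
- deterministic **synthetic fixtures** (`rich_club_toy()`,
  `counts_constrained_graph()`, `random_annotated_graph()`) and a thin
  command-line front end (`inst/cli/dyadnet`).

## Worked example

The bundled rich-club toy network has 43 nodes and 45 edges; its four
flagged nodes form a clique and hold the four highest degrees. The
attribute is strongly *dis*assortative (`r ≈ −0.66` by the mixing
coefficient), yet the dyadic effect reveals a tightly interconnected
flagged core:

```r
library(dyadnet)
toy <- rich_club_toy()
count_dyads(toy$graph, toy$annotation)
#> <dyad_counts: m11 = 6, m10 = 37, m00 = 2 (m = 45)>
dyadicity_heterophilicity(count_dyads(toy$graph, toy$annotation),
                          expected_counts(43, 45, 4))
#> <hd_metrics: D = 20.07, H = 4.76>
```

`D ≈ 20` says the flagged clique holds twenty times more internal edges
than a random placement of 4 flags would produce; `H ≈ 4.8` says mixed
edges are also five-fold enriched — the signature of a rich club, which
the single assortativity number cannot distinguish from plain
disassortative mixing. The full pipeline, from files to a ranked report
with permutation p-values:

```r
analyze_metadata("toy_edges.txt", "toy_meta.csv", binarize = FALSE,
                 permutations = 200, seed = 1)
#>   attribute n1        D        H region         r p_D p_H p_r
#> 1 rich_club  4 20.06667 4.759402     II 0.9931149   0   0   0
```

The same report from the shell:

```sh
Rscript inst/cli/dyadnet analyze toy_edges.txt toy_meta.csv \
    --permutations 200 --seed 1
#> # dyadnet analyze: K = 200, seed = 1
#> attribute  n1  D      H     r     p_D    p_H    p_r
#> rich_club  4   20.07  4.76  0.99  0.000  0.000  0.000
```

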