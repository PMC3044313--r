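# cswo — Closest String with Outliers

Exact solvers for the **Closest String with Outliers (CSWO)** problem.
Given *n* strings *s₁, …, sₙ*, each of length *ℓ* over an alphabet Σ, a
Hamming radius *d* and an outlier budget *k*, find a **center string** *s*
and a subset *S\** of at least *n\* = n − k* input strings such that
*d(s, t) ≤ d* for every *t ∈ S\**; the excluded strings (at most *k*) are
the **outliers**.

The classic closest-string model — every input string must lie within
*d* of the center — underlies universal PCR primer design, probe and
antisense design, consensus of protein families and motif recognition.
It is robust to oversampling but brittle to contamination: a single aberrant
sequence forces *d* up for the whole set. CSWO keeps *d* small by letting up
to *k* strings be set aside, and reports *which* ones — so a solution is
both a consensus and an outlier diagnosis. This package is for anyone who
needs that computation at desk scale (primer/probe candidate sets, curated
motif collections, small consensus panels) and for people studying the
problem itself.

## What is inside

* **Branching solver** (`solve_branching`, the default in `cswo_solve`) —
  a bounded search tree, fixed-parameter in *(d, k)*: at each node, pick a
  string farther than *d* from the current candidate center; either declare
  it an outlier (budget *k* decreases) or move the candidate toward it at
  one of *d + 1* mismatch positions (budget Δd decreases). Per start the
  tree has at most 2^(k+d)·(d+1)^d + 1 nodes; the solver restarts from each
  of the first min(k + 1, n) strings, which makes it complete.
* **Exhaustive enumeration** (`enumerate_centers`) — scans every center in
  the cross-product of per-column occurring symbols (a lossless restriction
  of Σ^ℓ) and returns a coverage-maximizing center.
* **Subset + integer program** (`solve_subset_ilp`) — enumerates inlier
  subsets of size *n\** in lexicographic order and solves each closest-string
  subproblem exactly through its 0/1 position-symbol formulation.
* **Optimization wrappers** (`minimize_d`, `minimize_k`) — smallest feasible
  radius for fixed *k*, or smallest outlier budget for fixed *d*.
* **CLIQUE → CSWO reduction** (`reduce_clique`, `decode_center`) — the
  constructive hardness gadget: a graph has a *t*-clique iff its reduced
  string instance (ℓ = t, d = t − 2, one gadget string per position pair and
  edge) is feasible; feasible centers decode back to cliques.
* **Generators** (`generate_planted`, `generate_random_instance`,
  `random_graph`) — seeded instances with known ground truth.
* **I/O and CLI** — FASTA (single-character alphabets) and a tokenized
  format (arbitrary alphabets), edge-list graphs, and a `cswo` command-line
  tool (`inst/cli/cswo`) with `solve`, `reduce`, `generate` and `verify`
  subcommands.

## Worked example

Five primer candidates, one of them contaminant. Allowing a single outlier
(`k = 1`) at radius `d = 1`:

```r
library(cswo)
primers <- c(p1 = "ACGTACGT", p2 = "ACGAACGT", p3 = "ACGTACGA",
             p4 = "TTGCGGAA", p5 = "ACGTTCGT")
inst <- cswo_instance(primers, d = 1, k = 1)
summary(cswo_solve(inst))
#> CSWO solution (branching)
#>   center:  A C G T A C G T
#>   inliers: 4 string(s): 1, 2, 3, 5
#>   outliers: 4
#>   search: 2 node(s) visited (1 outlier, 0 position branches)
```

The consensus `ACGTACGT` covers four primers within one mismatch and flags
`p4` as the outlier. Without the outlier budget the radius would have to
grow to cover `TTGCGGAA`; `cswo_solve(inst, k = 1, minimize = "d")` confirms
`d = 1` is already optimal for `k = 1`.

The hardness gadget, on the 4-vertex example graph with edges
(1,2), (1,3), (1,4), (2,3) and clique size `t = 3`:

```r
g <- cswo_graph(4, rbind(c(1,2), c(1,3), c(1,4), c(2,3)))
red <- reduce_clique(g, t = 3)          # 12 strings, l = 3, d = 1, n* = 3
sol <- enumerate_centers(red$instance)
sol
#> CSWO solution (enumerate)
#>   center:  v1 v2 v3
#>   inliers: 3 string(s): 1, 6, 12
#>   outliers: 2, 3, 4, 5, 7, 8, 9, 10, 11
decode_center(sol, red$map)
#> [1] 1 2 3
```

The best center covers exactly 3 gadget strings — the three encoding the
edges of the triangle {v1, v2, v3}, the graph's only 3-clique.

From a shell, the same solve:

```sh
Rscript inst/cli/cswo reduce --graph inst/extdata/example_graph.txt -t 3 --out gadget.txt
Rscript inst/cli/cswo solve --in gadget.txt --algorithm enumerate
```

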