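---
title: "Closest string with outliers: models, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closest string with outliers: models, solvers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cswo)
```

## The model

Closest string asks, for $n$ strings of common length $\ell$ over an
alphabet $\Sigma$ and a radius $d$, whether some *center* string lies within
Hamming distance $d$ of every input. The model is the standard abstraction
for consensus tasks — degenerate primer design, probe design, motif
recognition — and is robust to oversampling: adding copies of a string never
changes the answer. It is, however, brittle to contamination. One aberrant
string forces $d$ up for the entire set, which defeats applications where a
small radius is the point (a primer's degeneracy budget, for instance).

Closest string *with outliers* (CSWO) adds a budget $k$: find a center $s$
and a subset $S^*$ of at least $n^* = n - k$ inputs with
$d(s, t) \le d$ for all $t \in S^*$. A solution is simultaneously a
consensus for the bulk of the data and an identification of the at most $k$
strings that do not fit. Both decision parameters have optimization
versions: minimize $d$ at fixed $k$, or minimize $k$ at fixed $d$
(`minimize_d()`, `minimize_k()`).

Throughout the package symbols are opaque tokens, not characters. DNA and
protein instances use one-character tokens and can travel through FASTA;
the hardness gadgets below need one symbol per graph vertex plus one fresh
symbol per gadget string, which only the tokenized format can express.
String identity is positional: duplicated inputs are distinct members, so
oversampled data behaves as in the unweighted model. Ids and positions are
1-based everywhere, matching R convention and the package's user-facing
reports.

Degenerate parameter values are legal and resolved by convention rather
than rejected: $d \ge \ell$ makes every string an inlier, and $k \ge n$
makes the instance trivially feasible (the first string is returned as
center, with whatever it happens to cover as inliers, so the returned
object still satisfies the full solution contract).

## The bounded search tree solver

`solve_branching()` is fixed-parameter in $(d, k)$. A node carries the
active string set, a candidate center $x$, and two budgets: $\Delta d$
(candidate positions that may still change) and $k_\mathrm{rem}$ (strings
that may still be discarded). The recursion:

1. If $\Delta d < 0$ or $k_\mathrm{rem} < 0$, fail.
2. Pick the active string $s_i$ with $d(x, s_i) > d$; if none exists, $x$
   is a center for the active set — succeed.
3. Branch A: declare $s_i$ an outlier — recurse on the active set minus
   $s_i$ with $k_\mathrm{rem} - 1$.
4. Branch B (only if A fails): $s_i$ is an inlier, so the final center
   agrees with $s_i$ on at least one of any $d + 1$ positions where $x$
   and $s_i$ disagree. For each of the **first** $d + 1$ mismatch
   positions $p$ in increasing order, set $x[p] \leftarrow s_i[p]$ and
   recurse with $\Delta d - 1$.

Per start the tree has at most $2^{k+d}(d+1)^d + 1$ nodes: each level
consumes one unit of one budget, the outlier-vs-position guess contributes
the $2^{k+d}$ factor and the position choice the $(d+1)^d$ factor. The
node counter (`stats$nodes_per_start`) counts iterations that pass the
step-1 guard; a call that fails the guard is its parent's failed guess,
not a tree node. The validation suite asserts the bound on every solved
instance with $d, k \le 3$.

### Completeness and the multi-start repair

Starting only from $x = s_1$ is incomplete. Witness:
$S = \{A^{10}, T^{10}, T^{10}\}$, $d = 0$, $k = 1$. The only feasible
center is $T^{10}$ with $s_1$ the outlier, but from $s_1$ the position
budget $\Delta d = 0$ cannot bridge ten mismatches, and the outlier branch
can discard only one string. The per-step correctness argument needs the
start candidate to be within $d$ of the final center's inlier set's
perspective — which $s_1$ need not be when it is itself an outlier.

The repair: in any feasible solution at most $k$ strings are outliers, so
among $s_1, \dots, s_{\min(k+1, n)}$ at least one is an inlier, and an
inlier start is within $d$ of its solution's center — exactly what the
bounded-search-tree argument requires. `solve_branching()` therefore runs
the recursion from each of the first $\min(k+1, n)$ strings and returns the
first success. Cost: a multiplicative factor $\le k + 1$; completeness is
verified against exhaustive enumeration on a complete sweep of small binary
instances.

### Tie-breaking

Three choices the recursion leaves open are fixed for determinism: the
violating string is the one with the smallest id; the $d+1$ positions are
the first $d+1$ mismatches in increasing order (at least $d+1$ exist, since
$d(x, s_i) > d$); branches run outlier-first, then positions in increasing
order. Each position branch starts from the candidate *as it was on entry
to the node* — a cumulative mutation across the $d+1$ branches would change
several positions per single $\Delta d$ decrement and break the budget
argument.

## Exact baselines

Two independent solvers serve as user-facing alternatives and as oracles
for each other in the test suite.

**Exhaustive enumeration** (`enumerate_centers()`). When $\Sigma$ and
$\ell$ are small, all $|\Sigma|^\ell$ centers can be checked. The package
restricts each column to the symbols actually occurring there: replacing a
center symbol at position $p$ by an occurring one never decreases coverage
(a non-occurring symbol matches zero strings at $p$), so the restricted
maximum equals the unrestricted one — this losslessness is itself tested
against an unrestricted brute force on tiny instances. Enumeration order is
lexicographic (leftmost column most significant, symbols in first-occurrence
order) and ties go to the first maximizer, so results are deterministic.
Candidates are processed in vectorized batches of 65,536; the default cap of
$2 \times 10^6$ candidates (`max_centers`, config key
`enumerate.max_centers`) turns an oversized request into an explicit error
naming the product size. A `stop_at` coverage level allows early exit when
only the feasibility verdict is needed; the verdict is unaffected.

**Subset enumeration + 0/1 program** (`solve_subset_ilp()`). Enumerate the
$\binom{n}{n^*}$ inlier subsets in lexicographic id order (deterministic:
the first feasible subset is returned) and solve each closest-string
subproblem exactly. The subproblem is the direct position–symbol 0/1
program: indicators $x_{p,a}$ for each position $p$ and occurring symbol
$a$, one symbol per column, and $\sum_p (1 - x_{p, s_i[p]}) \le d$ per
string. `closest_string_ilp()` solves it by depth-first branch and bound
over columns, pruning any partial assignment in which some string already
exceeds $d$ mismatches. This direct formulation was chosen over the
column-type formulation with a constant number of variables from the
fixed-parameter literature: at desk scale the direct program is exact,
simpler, and its search is genuinely different from plain cross-product
enumeration, which is what makes the three-solver agreement test
informative. The subset cap defaults to $10^5$ (`subset.max_subsets`).

## The CLIQUE gadget

`reduce_clique(g, t)` implements the constructive reduction that makes CSWO
with unbounded alphabets hard: a graph $G = (V, E)$ has a clique of size
$t$ iff the reduced instance is feasible. For every position pair
$1 \le i < j \le t$ and every edge $e_m = (v_r, v_s)$, $r < s$, emit the
length-$t$ string with $v_r$ at position $i$, $v_s$ at position $j$ and a
symbol $c_{i,j,m}$ unique to that string everywhere else; set $d = t - 2$
and $n^* = t(t-1)/2$. A center covering $n^*$ strings can afford no $c$
symbol (each occurs in a single string — pigeonhole), so it spells out $t$
vertex symbols, and covering a string of pair $(i, j)$ forces an edge
between the vertices at positions $i$ and $j$: feasible centers decode to
cliques (`decode_center()`, `is_clique()`).

Reading notes on the construction, fixed once and used consistently: the
padding run after position $j$ has length $t - j$, so every gadget string
has length exactly $t$ (the worked 4-vertex example and the "every string
has length $t$" property both force this); position pairs range over
$i < j$ only, giving $t(t-1)/2 \cdot |E|$ strings (12 for the example
graph); edges are indexed in lexicographic $(r, s)$ order; symbols are
spelled `v<r>` and `c_<i>_<j>_<m>` with underscores so multi-digit indices
stay unambiguous. `t <= 2` and edgeless graphs are rejected — the
construction is degenerate there.

The validation suite closes the loop in both directions: planted-clique
graphs reduce to feasible instances whose solved centers decode to cliques,
and across **all** 1,093 graphs on 3–5 vertices (every nonempty edge
subset), reduced-instance feasibility coincides exactly with the presence
of a triangle ($t = 3$).

## Generators

`generate_planted(n, l, d, k, alphabet, seed, outlier_margin = 1)` emulates
the model's motivating scenario: an unknown consensus with near-copies plus
a few contaminants. It draws a uniform center, gives each of the $n - k$
inliers a uniform number (0..$d$) of distinct flipped positions — not
always $d$, so instances exercise slack — and places each outlier at
distance exactly $d + \mathrm{outlier\_margin}$. The margin (default 1,
the smallest value that separates the classes) makes the inlier/outlier
boundary sharp and testable: outliers are never accidentally coverable by
the planted center. Ids are shuffled so outliers are not positionally
last. The random stream is consumed in a fixed order (center, id shuffle,
strings in id order), so adding parameters later cannot silently reshuffle
existing fixtures; every generator restores the caller's RNG state.

What planted instances do *not* emulate: indels, phylogenetic correlation
among the inliers, composition bias, or motif-style background sequence.
Passing tests on planted data therefore demonstrate solver correctness on
the Hamming-ball geometry the model actually defines — not robustness to
alignment error or to evolutionary structure, which are outside the model.

`generate_random_instance()` draws i.i.d. uniform symbols (pairwise
distances concentrate around $\mathrm{Binomial}(\ell, 1 - 1/|\Sigma|)$,
which the suite checks) and feeds the oracle-equivalence fuzzing.
`random_graph()` is Erdős–Rényi with an optional planted clique.

## Validation scale

The suite's problem sizes, chosen as comfortable desk scale for exact
methods: the complete three-solver agreement sweep covers **all** 45,450
(instance, $d$, $k$) combinations of binary instances with $n \le 4$,
$\ell \le 3$, $d, k \le 2$; fuzzing adds 500 seeded DNA instances with
$n \le 8$, $\ell \le 10$; the search-tree bound is asserted on 300 further
instances with $d, k \le 3$; planted recovery runs 200 seeded instances
with $n \le 12$, $\ell \le 12$, $d, k \le 3$ (feasible on 100% of them);
the reduction equivalence enumerates all 1,093 small graphs. The whole
suite runs in well under a minute on one CPU.

## Known limitations

* Everything is exponential in something — that is inherent (the problem is
  NP-complete even for binary alphabets with $k = 0$, and W[1]-hard in
  $\ell$, $d$, $n^*$ for unbounded alphabets, which is what the gadget
  construction witnesses). The branching solver scales with $2^{k+d}$, the
  baselines with $|\Sigma|^\ell$ and $\binom{n}{n^*}$; caps turn runaway
  requests into errors rather than hangs.
* Hamming distance only: no indels, no weighted positions, equal lengths
  required. The closest *substring* variant is out of scope.
* `minimize_d`/`minimize_k` scan linearly from 0. Feasibility is monotone,
  so this is exact; it also yields a witness at every probed value, and at
  desk scale the saving from binary search is irrelevant.
* The subset solver's lexicographic "first feasible subset" is a canonical
  choice among possibly many feasible subsets, not a statement that the
  returned subset is special.
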