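---
title: "Consensus outlines: method, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus outlines: method, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloutline)
```

## The problem

A phylogenetic study rarely ends with one tree. Gene-by-gene analyses,
bootstrap replicates and Bayesian posterior samples all produce a *profile*
of m unrooted trees on the same n taxa, and the trees typically disagree.
A consensus tree (strict, majority, greedy) summarises what the trees share
but hides the disagreement; a consensus network at threshold p displays
conflicting splits but can explode into a non-planar tangle of
high-dimensional boxes when p is small.

The consensus *outline* sits between the two. It selects a **circular**
subset of the input splits — a split set for which some circular ordering of
the taxa makes every split an arc — and draws it as a single closed,
outer-labeled planar polygon with exactly two parallel edges per split:
2|S| nodes and 2|S| edges, never more than O(n²) of either, regardless of
how much conflict the input carries.

## The selection procedure

Write S(T) for the split encoding of a tree T (one split per edge, weighted
by branch length). Fix a reference taxon x₀ (the package defaults to the
lexicographically smallest label) and, for any split S, let S̄ be the side
that avoids x₀.

1. Pool S_H = ⋃ᵢ S(Tᵢ). The support of a split is the number of trees
   containing it (`tree_count`), or the sum of the edge-support labels over
   those trees (`edge_support`); its aggregate weight is the mean of its
   branch lengths over the containing trees.
2. Sort the splits by decreasing support.
3. Offer each split's cluster S̄ to a PQ-tree. The PQ-tree maintains the set
   of all linear orderings of the taxa in which every previously accepted
   cluster is consecutive; a cluster is accepted exactly when it can join
   that family. Accepted split → kept; rejected → discarded.
4. Extract a linear ordering Z from the PQ-tree; closing it into a cycle
   makes every kept split an arc.
5. Lay out the outline polygon from the kept splits and Z.

The kept set is circular by construction, so step 5 can never fail.

The `weightRetention()` statistic reports how much signal survives: each
split contributes, per containing tree, its branch length divided by the
tree's total length; retention is the kept-to-total ratio of these
contributions, as a percentage. 100% means every input split was kept.

## Pinned tie-breaks

Greedy procedures are sensitive to ordering, so every free choice is fixed:

* Sort order is support descending, then mean weight descending, then the
  canonical key (sorted taxon indices of S̄) ascending. Identical inputs
  therefore always give identical outputs, byte for byte.
* The taxon index space is the lexicographically sorted label vector, fixed
  once per profile.
* PQ-tree extraction visits P-node children in ascending order of smallest
  descendant taxon and reads each Q node in the direction that puts the
  smaller taxon first.

The *set* of accepted splits does not depend on the choice of x₀: a family
of clusters all avoiding x₀ has a consecutive arrangement exactly when the
corresponding splits are jointly circular, which is a property of the splits
alone. (Only the processing order could differ via the canonical-key
tie-break; with continuous weights, ties essentially never reach that level.
The suite checks the invariance explicitly on seeded profiles, all n
choices of x₀ each.)

## The PQ-tree

The implementation uses the classic template reduction (the P- and Q-node
patterns), written recursively over an immutable node structure: a
reduction either returns the updated pertinent subtree or fails, and a
failed insertion simply discards the partial copy, leaving the visible tree
untouched. No amortised-complexity machinery is attempted — one insertion
costs O(n) to O(n log n) here, which for the intended profile sizes
(hundreds of trees, tens of taxa) is far below a second in total. The
contract is frontier semantics, and the test suite verifies the decisions
against a brute-force oracle that enumerates all n! orderings for n ≤ 7,
over hundreds of random insertion sequences.

## Outline geometry

With Z rotated so that x₀ sits at position 1, each kept split's cluster is
an interval [p, q] of positions 2..n. Taxon positions get equally spaced
angles αᵢ = 2π(i−1)/n (x₀ at angle 0) and split S gets direction
θ_S = (α_p + α_q)/2 with length equal to its support, mean weight or summed
weight (`scaleMode`). The boundary is traced by walking the taxa in order:
in the gap after position i, the walk crosses every split whose interval
opens at i+1 (displacement +v_S) and every split whose interval closes at i
(−v_S), processing the crossings of one gap in ascending θ_S.

Every split contributes +v_S and −v_S exactly once, so the polygon closes
exactly in exact arithmetic; the implementation asserts closure to 1e-9.
Equal-angle spacing and the mean-endpoint-angle rule are conventions chosen
for determinism and simplicity; correctness is defined by the structural
invariants (closure, two equal antiparallel edges per split, node count =
edge count = 2|S|, no boundary self-intersection), all of which are tested
on random circular systems, not by pixel agreement with any other program.
Should the ascending-θ within-gap rule ever produce a self-intersection on
valid circular input, that input should be kept as a failing fixture rather
than patched around; none has appeared across the seeded families tested.

Zero-length splits (support or weight 0 under the chosen scale) are allowed
and produce degenerate edges, with a message.

## Thresholds and support modes

* **Majority** keeps splits in *strictly more than* half the trees
  (`fraction` ≥ 0.5 is enforced; below one half compatibility is no longer
  guaranteed and the network method is the right tool).
* **Network** keeps splits in *at least* p·m trees, 0 < p ≤ 1. Nothing
  guarantees the selection is circular; the package exports such selections
  as splits and only draws them when they happen to be circular.
* Strict and majority membership always count *trees*, even when
  `edge_support` ordering is in use: summed edge supports have no natural
  denominator, so in `edge_support` mode the network threshold is read as an
  absolute summed-support cutoff rather than a fraction. This ambiguity is
  surfaced in the interface rather than hidden behind a guessed
  normalisation.
* Trivial splits (singleton sides) are retained by every method; they are
  compatible with everything and every drawn object should display all taxa.
* Retention is always computed from branch-length proportions, regardless
  of the support mode used for ordering.

## Input handling

Trees are parsed with ape (multi-tree Newick and Nexus TREES blocks,
translate tables included). Rooted trees are unrooted on read — the method
is defined on unrooted trees — with the two root-edge lengths summed, and
support carried across the merge by matching splits. Fully numeric
internal-node labels are read as the support of the edge above the node
(the de-facto Newick dialect for bootstrap values); other labels are
ignored with a warning. Missing branch lengths default to 1 with a warning,
so purely topological bootstrap profiles remain usable. Multifurcations are
accepted as-is; the split encoding handles them naturally.

## What the generators emulate — and what they do not

`makeProfile()` produces the three regimes the method is aimed at:

* `yule_identical` — a degenerate posterior: m copies of one random tree.
* `nni_mixture` — two (or more) topologies one rearrangement apart in fixed
  proportions, edge lengths resampled independently per tree
  (exponential with mean 1 by default). This is the cleanest model of a
  genuine conflicting signal: the swapped splits appear with supports
  exactly proportional to the mixture fractions.
* `bootstrap_like` — a base topology perturbed, per tree, by a
  binomially-distributed number of random NNIs (default rate 0.05 per
  internal edge), mimicking the scatter of bootstrap replicates.

Random trees come from sequential random leaf attachment with exponential
branch lengths. Real profiles differ in ways these generators do not
attempt: rearrangements beyond NNI, correlated branch lengths, rogue taxa,
non-uniform tree shapes. Passing tests therefore demonstrate the
correctness of the algebra, the PQ-tree and the geometry under controlled
conflict — not that any biological conclusion follows from a particular
outline.

## Problem sizes used by the test suite

The suite runs the permutation oracle on n ≤ 7 (200 sequences), the
identity-profile check at n = 30, m = 50, the monotonicity/circularity
sweep over 50 profiles with n ≤ 15 and m ≤ 100, geometry checks at n ≤ 10,
and the x₀-invariance sweep over 20 profiles with every choice of x₀.
These sizes exercise every code path at the scale the algorithm is designed
for while keeping the whole suite around a minute; the algorithm itself is
O(mn²) and handles the profile sizes of typical multi-gene or posterior
analyses directly.

## Known limitations

* General (non-circular) split networks are not drawn; network selections
  with small p are export-only unless circular.
* Greedy selection remains order-sensitive in principle: a strongly
  supported split can be rejected because of earlier acceptances, and a
  weakly supported one can slip in. Scaling edges by support
  (`scaleMode = "support"`) makes the latter visible.
* Nexus support is limited to TREES blocks on input and the SPLITS dialect
  described in `?writeSplitsNexus` on output; CHARACTERS/DATA blocks are
  out of scope.
* The Nexus TREES reader does not recover internal-node support labels;
  use Newick input when `edge_support` mode matters.
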