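# phyloutline

Summarising a profile of phylogenetic trees — gene trees, bootstrap
replicates, a Bayesian posterior sample — usually means choosing between a
consensus *tree*, which hides all disagreement, and a consensus *network*,
which can blow up into an unreadable non-planar tangle. `phyloutline`
implements the middle ground: the **phylogenetic consensus outline**, a
greedy, PQ-tree-guided selection of a *circular* subset of the input splits,
drawn as a single closed, outer-labeled planar polygon in which every split
contributes exactly two parallel edges. Conflicting groupings stay visible,
but the drawing never needs more than 2|S| ≤ n(n−1) nodes and edges.

## The method in brief

For trees T₁…Tₘ on taxa X (|X| = n), pool the split encodings
S_H = ⋃ᵢ S(Tᵢ), where each edge of a tree induces the split A|B of the two
taxon sets it separates, weighted by branch length. Fix a reference taxon
x₀ and write S̄ for the side of a split avoiding x₀. Then:

1. support(S) = number of trees containing S (or the sum of its edge
   support labels);
2. visit the splits in order of decreasing support and offer each S̄ to a
   PQ-tree, which accepts a cluster exactly when some linear ordering of X
   makes it and all previously accepted clusters consecutive;
3. keep the accepted splits S_P, extract an ordering Z from the PQ-tree,
   and draw the outline of (S_P, Z).

Because the accepted clusters are consistent with a common ordering, S_P is
circular and the outline always exists. The package also provides strict,
majority and greedy consensus trees and threshold consensus-network split
selection (support ≥ p·m) for comparison, plus a **weight retention**
statistic: the percentage of length-normalised input split weight carried
by the output, per split and tree ω_T(S)/L(T), 100% meaning nothing was
discarded.

## Worked example

Build a profile with a known conflict — 70 trees of one topology, 30 of a
topology one NNI away — and summarise it:

```r
library(phyloutline)

profile <- makeProfile(n = 10, m = 100, model = "nni_mixture",
                       mixtureFractions = c(0.7, 0.3), seed = 42)
profile
#> Tree profile: m = 100 trees on n = 10 taxa

res <- consensusOutline(profile)
res
#> Consensus (outline): 18 of 18 input splits kept from m = 100 trees
#>   weight retention: 100.0%
#>   circular ordering: t01 t02 t10 t03 t06 t08 t07 t04 t05 t09

sort(unique(extractProfileSplits(profile)$treeCount))
#> [1]  30  70 100

maj <- majorityConsensus(profile)
sprintf("majority keeps %d splits, retention %.1f%%", nSplits(maj$splits), maj$retention)
#> "majority keeps 17 splits, retention 98.3%"

ol <- computeOutline(res$splits, res$ordering, scaleMode = "support")
ol
#> Phylogenetic outline: 36 nodes and 36 edges for 18 splits on 10 taxa
renderSVG(ol, "outline.svg")
```

The two rival splits carry supports 70 and 30; the majority tree keeps only
the 70-split (17 of 18 splits, 98.3% retention), while the outline keeps
both alternatives (retention 100%) and draws the conflict as a band of
parallelograms in the polygon. Results are deterministic: sorting,
tie-breaks and the PQ-tree traversal are all pinned, so identical inputs
give byte-identical outputs.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/consout.R", package="phyloutline"))')" \
  run --input trees.nwk --method outline --out-nexus out.nex --out-svg out.svg
```

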