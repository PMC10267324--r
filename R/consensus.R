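## Consensus computations on a tree profile.
##
## All methods share one deterministic processing order -- support
## descending, mean weight descending, canonical key ascending -- so that
## tie-breaks are pinned (the greedy selections are order-sensitive).
## Trivial splits are retained by every method: they are compatible with
## everything and every displayed object must carry all taxa.

.consensusResult <- function(splits, ordering, method, threshold, retention,
                             supportMode, nInput, m) {
  structure(list(splits = splits, ordering = ordering, method = method,
                 threshold = threshold, retention = retention,
                 supportMode = supportMode, nInputSplits = nInput, m = m),
            class = "consensusResult")
}

#' @export
print.consensusResult <- function(x, ...) {
  cat("Consensus (", x$method, "): ", nSplits(x$splits), " of ",
      x$nInputSplits, " input splits kept from m = ", x$m, " trees\n", sep = "")
  if (!is.null(x$threshold)) cat("  threshold:", x$threshold, "\n")
  cat(sprintf("  weight retention: %.1f%%\n", x$retention))
  if (!is.null(x$ordering))
    cat("  circular ordering:",
        paste(x$splits$taxa[x$ordering], collapse = " "), "\n")
  invisible(x)
}

#' Consensus outline split selection
#'
#' The core greedy procedure: pool all input splits, sort them by decreasing
#' support, and offer each split's x0-avoiding part to a PQ-tree; a split is
#' kept exactly when the PQ-tree accepts its cluster, i.e. when the kept set
#' stays consistent with some linear ordering of the taxa. The result is a
#' circular split system together with the ordering extracted from the
#' PQ-tree, ready to be drawn as a planar outline.
#'
#' @param profile a [treeProfile()].
#' @param supportMode `"tree_count"` (number of trees containing a split) or
#'   `"edge_support"` (sum of the edge-support labels over those trees).
#' @param x0 reference taxon: index into the sorted taxon labels, or a
#'   label. The accepted split set does not depend on this choice (only the
#'   stored canonical forms do).
#' @return a `consensusResult` with elements `splits`, `ordering`,
#'   `retention` (percentage of length-normalised input split weight kept).
#' @export
consensusOutline <- function(profile, supportMode = c("tree_count", "edge_support"),
                             x0 = 1L) {
  supportMode <- match.arg(supportMode)
  x0 <- .resolveX0(profile, x0)
  if (nTaxa(profile) < 3L) stop("need at least 3 taxa")
  S <- extractProfileSplits(profile, supportMode, x0)
  ord <- .splitOrder(S)
  pq <- pqNew(length(S$taxa))
  keep <- logical(nSplits(S))
  for (j in ord) keep[j] <- pqAccept(pq, S$parts[[j]])
  Z <- pqExtractOrdering(pq)
  kept <- S[keep]
  .consensusResult(kept, Z, "outline", NULL,
                   weightRetention(S, kept, profile), supportMode,
                   nSplits(S), nTrees(profile))
}

#' Majority consensus
#'
#' Keeps the splits present in more than `fraction` of the input trees
#' (strictly more than half by default); such a set is always pairwise
#' compatible, i.e. a tree.
#'
#' @inheritParams consensusOutline
#' @param fraction threshold in \[0.5, 1): a split is kept iff its tree
#'   count exceeds `fraction * m`. For thresholds below one half use
#'   [consensusNetworkSplits()].
#' @return a `consensusResult` (no ordering).
#' @export
majorityConsensus <- function(profile, supportMode = c("tree_count", "edge_support"),
                              fraction = 0.5, x0 = 1L) {
  supportMode <- match.arg(supportMode)
  x0 <- .resolveX0(profile, x0)
  if (fraction < 0.5)
    stop("fraction below 0.5 can give incompatible splits; use consensusNetworkSplits()")
  S <- extractProfileSplits(profile, supportMode, x0)
  m <- nTrees(profile)
  keep <- S$treeCount > fraction * m | isTrivialSplit(S)
  kept <- S[keep]
  .consensusResult(kept, NULL, "majority", fraction,
                   weightRetention(S, kept, profile), supportMode, nSplits(S), m)
}

#' Strict consensus
#'
#' Keeps only the splits present in every input tree.
#'
#' @inheritParams consensusOutline
#' @return a `consensusResult` (no ordering).
#' @export
strictConsensus <- function(profile, x0 = 1L) {
  x0 <- .resolveX0(profile, x0)
  S <- extractProfileSplits(profile, "tree_count", x0)
  m <- nTrees(profile)
  kept <- S[S$treeCount == m]
  .consensusResult(kept, NULL, "strict", NULL,
                   weightRetention(S, kept, profile), "tree_count", nSplits(S), m)
}

#' Greedy consensus
#'
#' Iterates the input splits in decreasing-support order and keeps each one
#' that is compatible with everything kept so far; the result is always a
#' tree-compatible superset of the majority splits.
#'
#' @inheritParams consensusOutline
#' @return a `consensusResult` (no ordering).
#' @export
greedyConsensus <- function(profile, supportMode = c("tree_count", "edge_support"),
                            x0 = 1L) {
  supportMode <- match.arg(supportMode)
  x0 <- .resolveX0(profile, x0)
  S <- extractProfileSplits(profile, supportMode, x0)
  ord <- .splitOrder(S)
  keep <- logical(nSplits(S))
  keptIdx <- integer(0)
  for (j in ord) {
    ok <- all(vapply(keptIdx, function(i)
      .partsCompatible(S$parts[[i]], S$parts[[j]]), logical(1)))
    if (ok) { keep[j] <- TRUE; keptIdx <- c(keptIdx, j) }
  }
  kept <- S[keep]
  .consensusResult(kept, NULL, "greedy", NULL,
                   weightRetention(S, kept, profile), supportMode,
                   nSplits(S), nTrees(profile))
}

#' Consensus-network split selection
#'
#' Keeps all splits present in at least `p * m` of the input trees (plus the
#' trivial splits). No compatibility or circularity is guaranteed: for small
#' `p` the set may only be displayable as a general split network, which is
#' out of this package's drawing scope -- an ordering is attached only when
#' the selected set happens to be circular.
#'
#' @inheritParams consensusOutline
#' @param p threshold in (0, 1\] (`tree_count` mode). In `edge_support` mode
#'   there is no natural denominator for summed supports, so `p` is read as
#'   an absolute summed-support cutoff instead.
#' @return a `consensusResult`; `$ordering` is `NULL` unless the selection
#'   is circular.
#' @export
consensusNetworkSplits <- function(profile, p,
                                   supportMode = c("tree_count", "edge_support"),
                                   x0 = 1L) {
  supportMode <- match.arg(supportMode)
  x0 <- .resolveX0(profile, x0)
  S <- extractProfileSplits(profile, supportMode, x0)
  m <- nTrees(profile)
  if (supportMode == "tree_count") {
    if (p <= 0 || p > 1) stop("threshold p must be in (0, 1]")
    keep <- S$treeCount >= p * m | isTrivialSplit(S)
  } else {
    keep <- S$support >= p | isTrivialSplit(S)
  }
  kept <- S[keep]
  Z <- .circularOrderingOf(kept)
  .consensusResult(kept, Z, "network", p,
                   weightRetention(S, kept, profile), supportMode, nSplits(S), m)
}

## Try to certify a split system as circular: offer every part to a fresh
## PQ-tree (a jointly consistent family is accepted in any order). Returns
## the extracted ordering, or NULL if some part is rejected.
.circularOrderingOf <- function(S) {
  pq <- pqNew(length(S$taxa))
  for (p in S$parts) if (!pqAccept(pq, p)) return(NULL)
  pqExtractOrdering(pq)
}

.resolveX0 <- function(profile, x0) {
  if (is.character(x0)) {
    i <- match(x0, profile$taxa)
    if (is.na(i)) stop("unknown reference taxon: ", x0)
    return(i)
  }
  x0 <- as.integer(x0)
  if (x0 < 1L || x0 > nTaxa(profile)) stop("x0 index out of range")
  x0
}
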