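## Split systems.
##
## A split A|B of the taxon set X is stored by its canonical part: the side
## that does NOT contain the fixed reference taxon x0, as a sorted vector of
## taxon indices. Keying splits this way makes lookup exact and pins every
## tie-break. Each split carries an aggregate weight (mean branch length over
## the trees containing it), a support value, the tree-occurrence count, and
## the per-tree weight list needed for the weight-retention statistic.

#' Construct a split system
#'
#' @param taxa character vector of taxon labels (defines index space 1..n).
#' @param parts list of integer vectors: canonical split parts (sorted taxon
#'   indices, excluding `x0`).
#' @param weight aggregate split weights (mean branch length).
#' @param support split supports (tree counts or summed edge supports).
#' @param treeCount integer occurrence counts (defaults to `support`).
#' @param occTrees,occWeights per-split lists: indices of the trees
#'   containing the split and the split's branch length in each.
#' @param x0 index of the reference taxon (default 1, the lexicographically
#'   smallest label).
#' @return an object of class `splitSystem`.
#' @export
splitSystem <- function(taxa, parts = list(), weight = numeric(),
                        support = numeric(), treeCount = NULL,
                        occTrees = NULL, occWeights = NULL, x0 = 1L) {
  n <- length(taxa)
  x0 <- as.integer(x0)
  stopifnot(n >= 1L, x0 >= 1L, x0 <= n)
  parts <- lapply(parts, function(p) sort(as.integer(p)))
  k <- length(parts)
  if (length(weight) == 0L) weight <- rep(0, k)
  if (length(support) == 0L) support <- rep(0, k)
  if (is.null(treeCount)) treeCount <- as.integer(round(support))
  for (p in parts) {
    if (length(p) == 0L || length(p) >= n)
      stop("split part must be a proper non-empty subset of the taxa")
    if (x0 %in% p) stop("canonical split part must not contain x0")
    if (any(p < 1L) || any(p > n)) stop("taxon index out of range in split part")
  }
  if (any(weight < 0) || any(support < 0))
    stop("split weights and supports must be non-negative")
  obj <- structure(list(taxa = taxa, x0 = x0, parts = parts,
                        weight = as.numeric(weight),
                        support = as.numeric(support),
                        treeCount = as.integer(treeCount),
                        occTrees = occTrees, occWeights = occWeights),
                   class = "splitSystem")
  if (anyDuplicated(splitKeys(obj)))
    stop("duplicate split (same canonical key) in split system")
  obj
}

#' Canonical keys of the splits in a system
#'
#' With `canonical = FALSE` the key is the stored x0-avoiding part; with
#' `canonical = TRUE` the part is re-normalised to avoid taxon index 1, which
#' makes key sets comparable across systems built with different `x0`.
#'
#' @param x a `splitSystem`.
#' @param canonical normalise keys to avoid taxon 1 regardless of `x0`.
#' @return character vector of keys.
#' @export
splitKeys <- function(x, canonical = FALSE) {
  n <- length(x$taxa)
  parts <- x$parts
  if (canonical && length(parts)) {
    all <- seq_len(n)
    parts <- lapply(parts, function(p) if (1L %in% p) setdiff(all, p) else p)
  }
  vapply(parts, paste, character(1), collapse = " ")
}

#' @export
print.splitSystem <- function(x, ...) {
  cat("Split system:", length(x$parts), "splits on", length(x$taxa),
      "taxa (x0 =", x$taxa[x$x0], ")\n")
  if (length(x$parts)) {
    ns <- min(length(x$parts), 6L)
    for (j in seq_len(ns))
      cat(sprintf("  {%s}  weight %.4g  support %.4g\n",
                  paste(x$taxa[x$parts[[j]]], collapse = ","),
                  x$weight[j], x$support[j]))
    if (length(x$parts) > ns) cat("  ...\n")
  }
  invisible(x)
}

#' Number of splits
#' @param x a `splitSystem`.
#' @export
nSplits <- function(x) length(x$parts)

#' Subset a split system
#' @param x a `splitSystem`.
#' @param i index vector (integer or logical) over the splits.
#' @param ... unused.
#' @export
`[.splitSystem` <- function(x, i, ...) {
  splitSystem(x$taxa, x$parts[i], x$weight[i], x$support[i], x$treeCount[i],
              if (!is.null(x$occTrees)) x$occTrees[i],
              if (!is.null(x$occWeights)) x$occWeights[i], x$x0)
}

#' Is a split trivial (a singleton on either side)?
#' @param x a `splitSystem`.
#' @return logical vector.
#' @export
isTrivialSplit <- function(x) {
  n <- length(x$taxa)
  vapply(x$parts, function(p) length(p) == 1L || length(p) == n - 1L, logical(1))
}

#' Split encoding of a tree
#'
#' Every edge of an unrooted tree induces the split of the two taxon sets it
#' separates; the weight of the split is the edge length and its support is
#' the edge support label (1 when absent).
#'
#' @param phy a normalised `phylo` (as stored inside a [treeProfile()]).
#' @param taxa the profile's taxon label vector.
#' @param x0 reference taxon index.
#' @return a `splitSystem` with one split per edge.
#' @export
splitEncoding <- function(phy, taxa, x0 = 1L) {
  n <- length(taxa)
  tipIdx <- match(phy$tip.label, taxa)
  if (anyNA(tipIdx)) stop("tree has tips outside the taxon set")
  sets <- .edgeTipSets(phy)
  all <- seq_len(n)
  parts <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    p <- sort(tipIdx[sets[[k]]])
    if (x0 %in% p) p <- setdiff(all, p)
    parts[[k]] <- p
  }
  sup <- phy$edge.support
  if (is.null(sup)) sup <- rep(NA_real_, length(sets))
  splitSystem(taxa, parts, weight = phy$edge.length,
              support = ifelse(is.na(sup), 1, sup),
              treeCount = rep(1L, length(parts)), x0 = x0)
}

#' Pool the splits of a whole profile
#'
#' Takes the union of the split encodings of all trees. Per split, the
#' support is either the number of trees containing it (`"tree_count"`) or
#' the sum of the corresponding edge-support values over those trees
#' (`"edge_support"`); the aggregate weight is the arithmetic mean of the
#' split's branch lengths over the trees containing it. The per-tree weight
#' list is retained for [weightRetention()].
#'
#' @param profile a [treeProfile()].
#' @param supportMode `"tree_count"` or `"edge_support"`.
#' @param x0 reference taxon index.
#' @return a `splitSystem`.
#' @export
extractProfileSplits <- function(profile,
                                 supportMode = c("tree_count", "edge_support"),
                                 x0 = 1L) {
  supportMode <- match.arg(supportMode)
  stopifnot(inherits(profile, "treeProfile"))
  taxa <- profile$taxa
  if (supportMode == "edge_support") {
    for (i in seq_along(profile$trees))
      if (all(is.na(profile$trees[[i]]$edge.support)))
        stop("edge_support requested but tree ", i, " carries no support labels")
  }
  idx <- new.env(hash = TRUE, parent = emptyenv())
  parts <- list(); occT <- list(); occW <- list(); occS <- list()
  for (i in seq_along(profile$trees)) {
    phy <- profile$trees[[i]]
    enc <- splitEncoding(phy, taxa, x0)
    keys <- splitKeys(enc)
    rawSup <- phy$edge.support
    if (is.null(rawSup)) rawSup <- rep(NA_real_, nSplits(enc))
    for (k in seq_along(keys)) {
      j <- idx[[keys[k]]]
      if (is.null(j)) {
        j <- length(parts) + 1L
        idx[[keys[k]]] <- j
        parts[[j]] <- enc$parts[[k]]
        occT[[j]] <- integer(0); occW[[j]] <- numeric(0); occS[[j]] <- numeric(0)
      }
      occT[[j]] <- c(occT[[j]], i)
      occW[[j]] <- c(occW[[j]], enc$weight[k])
      occS[[j]] <- c(occS[[j]], rawSup[k])
    }
  }
  treeCount <- vapply(occT, length, integer(1))
  weight <- vapply(occW, mean, numeric(1))
  support <- if (supportMode == "tree_count") as.numeric(treeCount)
             else vapply(occS, function(s) sum(s, na.rm = TRUE), numeric(1))
  splitSystem(taxa, parts, weight, support, treeCount, occT, occW, x0)
}

## Compatibility of two canonical parts (both avoiding the same x0):
## compatible iff disjoint or nested. (The two co-parts both contain x0, so
## of the four part intersections only these three can be empty.)
.partsCompatible <- function(pa, pb) {
  i <- length(intersect(pa, pb))
  i == 0L || i == length(pa) || i == length(pb)
}

#' Are two splits of a system compatible?
#'
#' Two splits are compatible iff at least one of the four pairwise
#' intersections of their parts is empty; a pairwise-compatible split set is
#' exactly the split encoding of some tree.
#'
#' @param x a `splitSystem`.
#' @param i,j split indices.
#' @return logical scalar.
#' @export
areCompatible <- function(x, i, j) {
  stopifnot(inherits(x, "splitSystem"))
  .partsCompatible(x$parts[[i]], x$parts[[j]])
}

#' Is a split system circular with respect to an ordering?
#'
#' After rotating the ordering so that the reference taxon x0 sits first,
#' every canonical part must occupy a contiguous block of positions 2..n.
#'
#' @param x a `splitSystem`.
#' @param ordering integer permutation of 1..n (a `CircularOrdering`).
#' @return logical scalar.
#' @export
isCircular <- function(x, ordering) {
  n <- length(x$taxa)
  ordering <- as.integer(ordering)
  if (length(ordering) != n || !setequal(ordering, seq_len(n)))
    stop("ordering must be a permutation of 1..", n)
  r <- which(ordering == x$x0)
  ordering <- c(ordering[r:n], ordering[seq_len(r - 1L)])
  pos <- integer(n); pos[ordering] <- seq_len(n)
  for (p in x$parts) {
    pr <- range(pos[p])
    if (pr[2] - pr[1] + 1L != length(p)) return(FALSE)
  }
  TRUE
}

#' Weight-retention statistic
#'
#' For each split and each tree containing it, the split contributes its
#' branch length in that tree divided by the tree's total length. Retention
#' is the contribution sum over the kept splits as a percentage of the sum
#' over all input splits; 100 means every input split is in the output.
#'
#' @param allSplits the full profile split system (from
#'   [extractProfileSplits()], carrying per-tree weights).
#' @param keptSplits the selected subset (matched by canonical key).
#' @param profile the originating [treeProfile()] (supplies tree lengths).
#' @return a percentage in \[0, 100\].
#' @export
weightRetention <- function(allSplits, keptSplits, profile) {
  stopifnot(inherits(allSplits, "splitSystem"), inherits(keptSplits, "splitSystem"),
            inherits(profile, "treeProfile"))
  if (is.null(allSplits$occTrees))
    stop("allSplits must carry per-tree weights (use extractProfileSplits)")
  L <- vapply(profile$trees, function(p) sum(p$edge.length), numeric(1))
  if (any(L <= 0))
    stop("undefined normalization: tree ", which(L <= 0)[1], " has total length 0")
  keysAll <- splitKeys(allSplits, canonical = TRUE)
  keysKept <- splitKeys(keptSplits, canonical = TRUE)
  if (!all(keysKept %in% keysAll))
    stop("keptSplits is not a subset of allSplits")
  contrib <- vapply(seq_along(allSplits$parts), function(j)
    sum(allSplits$occWeights[[j]] / L[allSplits$occTrees[[j]]]), numeric(1))
  denom <- sum(contrib)
  if (denom == 0) return(0)
  100 * sum(contrib[keysAll %in% keysKept]) / denom
}

## Deterministic processing order for the greedy loops: support descending,
## then mean weight descending, then canonical key ascending (taxon indices
## zero-padded so string order equals lexicographic index order).
.splitOrder <- function(x) {
  w <- max(4L, nchar(as.character(length(x$taxa))))
  lex <- vapply(x$parts, function(p)
    paste(formatC(p, width = w, flag = "0"), collapse = " "), character(1))
  order(-x$support, -x$weight, lex)
}
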