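## PQ-tree over the taxa 1..n.
##
## The tree maintains exactly the set of linear orderings of the taxa in
## which every accepted cluster is consecutive (its frontier): children of a
## P node may be permuted freely, a Q node may be read forward or in
## reverse. Insertion uses the classic template reduction (the P2-P6 / Q2-Q3
## patterns), written recursively over an immutable nested-list tree: a
## rejected insertion simply discards the partial copy, so the visible tree
## is untouched -- the behaviour the greedy consensus loop relies on.
##
## Nodes: list(type = "L", taxon = i) | list(type = "P"|"Q", children = ...).
## The handle returned by pqNew() is an environment so that pqAccept() can
## update in place and still return a plain logical.

#' Create a universal PQ-tree
#'
#' The fresh tree has a single P root over all taxa and therefore accepts
#' every linear ordering of 1..n.
#'
#' @param n number of taxa (or a character vector of labels, whose length is
#'   used).
#' @return a `pqTree` handle.
#' @export
pqNew <- function(n) {
  if (is.character(n)) n <- length(n)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  leaves <- lapply(seq_len(n), function(i) list(type = "L", taxon = i))
  root <- if (n == 1L) leaves[[1L]] else list(type = "P", children = leaves)
  e <- new.env(parent = emptyenv())
  e$n <- n
  e$root <- root
  e$accepted <- list()
  class(e) <- "pqTree"
  e
}

#' Offer a cluster to a PQ-tree
#'
#' The cluster is accepted iff some linear ordering consistent with all
#' previously accepted clusters also makes it consecutive; on acceptance the
#' tree is updated, on rejection it is left exactly as it was. Clusters of
#' size at most 1, or equal to the whole taxon set, are accepted without
#' structural change.
#'
#' @param pq a `pqTree` handle.
#' @param cluster integer vector of taxon indices.
#' @return `TRUE` (accepted, tree updated) or `FALSE` (rejected, tree
#'   unchanged).
#' @export
pqAccept <- function(pq, cluster) {
  stopifnot(inherits(pq, "pqTree"))
  cluster <- unique(as.integer(cluster))
  if (length(cluster) && (min(cluster) < 1L || max(cluster) > pq$n))
    stop("cluster contains unknown taxon index")
  if (length(cluster) <= 1L || length(cluster) == pq$n) {
    pq$accepted <- c(pq$accepted, list(sort(cluster)))
    return(TRUE)
  }
  inS <- rep(FALSE, pq$n)
  inS[cluster] <- TRUE
  newRoot <- .pqReduceFrom(pq$root, inS, length(cluster))
  if (is.null(newRoot)) return(FALSE)
  pq$root <- .pqNormalize(newRoot)
  pq$accepted <- c(pq$accepted, list(sort(cluster)))
  TRUE
}

#' Accepted clusters of a PQ-tree
#' @param pq a `pqTree` handle.
#' @return list of sorted integer vectors, in acceptance order.
#' @export
pqAccepted <- function(pq) pq$accepted

#' Extract the canonical linear ordering from a PQ-tree
#'
#' A deterministic member of the frontier: children of P nodes are visited
#' in ascending order of their smallest descendant taxon; a Q node is read
#' forward or in reverse, whichever puts the smaller taxon first. Every
#' accepted cluster is consecutive in the result.
#'
#' @param pq a `pqTree` handle.
#' @return integer permutation of 1..n.
#' @export
pqExtractOrdering <- function(pq) {
  stopifnot(inherits(pq, "pqTree"))
  .canonSeq(pq$root)
}

.canonSeq <- function(node) {
  if (node$type == "L") return(node$taxon)
  seqs <- lapply(node$children, .canonSeq)
  if (node$type == "P") {
    unlist(seqs[order(vapply(seqs, min, integer(1)))])
  } else {
    a <- unlist(seqs)
    if (a[1L] <= a[length(a)]) a else rev(a)
  }
}

#' Bracket serialization of a PQ-tree (for debugging and tests)
#'
#' P nodes print as `P(...)` with children in canonical order, Q nodes as
#' `Q[...]` in stored order (canonical orientation), leaves as their taxon
#' index.
#'
#' @param pq a `pqTree` handle.
#' @return character scalar.
#' @export
pqFormat <- function(pq) .fmtNode(pq$root)

.fmtNode <- function(node) {
  if (node$type == "L") return(as.character(node$taxon))
  parts <- vapply(node$children, .fmtNode, character(1))
  if (node$type == "P")
    paste0("P(", paste(sort(parts), collapse = ","), ")")
  else {
    if (parts[1L] > parts[length(parts)]) parts <- rev(parts)
    paste0("Q[", paste(parts, collapse = ","), "]")
  }
}

#' @export
print.pqTree <- function(x, ...) {
  cat("PQ-tree on", x$n, "taxa,", length(x$accepted), "accepted clusters\n")
  cat(" ", pqFormat(x), "\n")
  invisible(x)
}

## ---- reduction internals ----------------------------------------------

.countS <- function(node, inS) {
  if (node$type == "L") return(as.integer(inS[node$taxon]))
  sum(vapply(node$children, .countS, integer(1), inS = inS))
}

## Descend to the pertinent root (the deepest node whose subtree contains
## the whole cluster), reduce there; NULL signals rejection.
.pqReduceFrom <- function(node, inS, sz) {
  if (node$type != "L") {
    cnts <- vapply(node$children, .countS, integer(1), inS = inS)
    i <- which(cnts == sz)
    if (length(i) == 1L) {
      sub <- .pqReduceFrom(node$children[[i]], inS, sz)
      if (is.null(sub)) return(NULL)
      node$children[[i]] <- sub
      return(node)
    }
  }
  r <- .reduceNode(node, inS, isRoot = TRUE)
  if (is.null(r)) NULL else r$node
}

## Group a list of nodes under a fresh P node (identity for a single node).
.groupP <- function(nodes) {
  if (length(nodes) == 0L) return(NULL)
  if (length(nodes) == 1L) return(nodes[[1L]])
  list(type = "P", children = nodes)
}

.mkQ <- function(children) {
  if (length(children) == 1L) return(children[[1L]])
  list(type = "Q", children = children)
}

## Recursive template reduction. Returns NULL on failure, else
## list(status = "empty" | "full" | "partial", node = <updated node>).
## A "partial" node is a Q whose children run empty-side first, full-side
## last. At the pertinent root (isRoot = TRUE) the returned status is not
## meaningful beyond success.
.reduceNode <- function(node, inS, isRoot = FALSE) {
  if (node$type == "L") {
    return(list(status = if (inS[node$taxon]) "full" else "empty", node = node))
  }
  kids <- vector("list", length(node$children))
  st <- character(length(node$children))
  for (i in seq_along(node$children)) {
    r <- .reduceNode(node$children[[i]], inS, isRoot = FALSE)
    if (is.null(r)) return(NULL)
    kids[[i]] <- r$node
    st[i] <- r$status
  }
  node$children <- kids
  if (all(st == "empty")) return(list(status = "empty", node = node))
  if (all(st == "full")) return(list(status = "full", node = node))
  if (node$type == "P") .reduceP(node, kids, st, isRoot)
  else .reduceQ(node, kids, st, isRoot)
}

.reduceP <- function(node, kids, st, isRoot) {
  E <- kids[st == "empty"]
  F <- kids[st == "full"]
  Pp <- kids[st == "partial"]
  fullGroup <- .groupP(F)
  if (isRoot) {
    if (length(Pp) > 2L) return(NULL)
    if (length(Pp) == 0L) {
      ## template P2: gather the full children under one new child
      node$children <- c(E, list(fullGroup))
      return(list(status = "full", node = node))
    }
    qk <- Pp[[1L]]$children
    if (!is.null(fullGroup)) qk <- c(qk, list(fullGroup))
    if (length(Pp) == 2L) qk <- c(qk, rev(Pp[[2L]]$children))  ## P6
    qn <- .mkQ(qk)                                             ## P4 / P6
    if (length(E) == 0L) node <- qn
    else node$children <- c(E, list(qn))
    return(list(status = "partial", node = node))
  }
  ## not the pertinent root: at most one partial child; the node becomes a
  ## partial Q with empties at the head and fulls at the tail (P3 / P5)
  if (length(Pp) > 1L) return(NULL)
  qk <- list()
  eg <- .groupP(E)
  if (!is.null(eg)) qk <- c(qk, list(eg))
  if (length(Pp) == 1L) qk <- c(qk, Pp[[1L]]$children)
  if (!is.null(fullGroup)) qk <- c(qk, list(fullGroup))
  list(status = "partial", node = .mkQ(qk))
}

.reduceQ <- function(node, kids, st, isRoot) {
  k <- length(kids)
  ne <- which(st != "empty")
  if (max(ne) - min(ne) + 1L != length(ne)) return(NULL)  # block not contiguous
  inner <- st[ne]
  li <- length(inner)
  if (any(inner[-c(1L, li)] == "partial")) return(NULL)   # partial inside block
  np <- sum(inner == "partial")
  if (isRoot) {
    if (np > 2L) return(NULL)
    block <- list()
    for (j in seq_along(ne)) {
      ch <- kids[[ne[j]]]
      if (inner[j] == "partial") {
        ## left-end partial keeps its empty side facing left; a right-end
        ## partial is reversed so its full side faces the full run
        block <- c(block, if (j == 1L) ch$children else rev(ch$children))
      } else block <- c(block, list(ch))
    }
    node$children <- c(kids[seq_len(min(ne) - 1L)], block,
                       if (max(ne) < k) kids[seq(max(ne) + 1L, k)])
    return(list(status = "full", node = node))
  }
  ## non-root: after possibly reversing, the pattern must read E* P? F*
  if (np > 1L) return(NULL)
  valid <- function(ss) {
    runs <- rle(ss)$values
    paste(runs, collapse = ".") %in%
      c("empty.full", "empty.partial", "partial.full", "empty.partial.full")
  }
  if (valid(st)) {
    ord <- seq_len(k)
  } else if (valid(rev(st))) {
    ord <- rev(seq_len(k))
  } else return(NULL)
  flat <- list()
  for (i in ord) {
    if (st[i] == "partial") flat <- c(flat, kids[[i]]$children)
    else flat <- c(flat, list(kids[[i]]))
  }
  list(status = "partial", node = .mkQ(flat))
}

## Splice out single-child internal nodes; a Q with two children is the
## same constraint as a P with two children.
.pqNormalize <- function(node) {
  if (node$type == "L") return(node)
  node$children <- lapply(node$children, .pqNormalize)
  if (length(node$children) == 1L) return(node$children[[1L]])
  if (node$type == "Q" && length(node$children) == 2L) node$type <- "P"
  node
}
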