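## Seeded synthetic data: random unrooted binary trees, nearest-neighbour
## interchanges, and profile generators that emulate the typical inputs of a
## consensus analysis (identical posterior samples, two-topology mixtures,
## bootstrap-like profiles with sporadic rearrangements).

## Run expr under a temporary RNG state so generators are reproducible per
## seed without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random unrooted binary tree
#'
#' Built by sequential random leaf attachment: starting from the star on
#' three taxa, each further leaf subdivides a uniformly chosen existing
#' edge. Taxon labels are `t01..tn` (zero-padded, so lexicographic order
#' equals numeric order).
#'
#' @param n number of taxa (>= 3).
#' @param edgeLengthLaw `"exponential"` (rate `1/meanLength`) or `"unit"`.
#' @param meanLength mean branch length for the exponential law.
#' @param seed integer seed; identical seeds give identical trees.
#' @return a normalised `phylo` with `edge.support` (all `NA`).
#' @export
randomTree <- function(n, edgeLengthLaw = c("exponential", "unit"),
                       meanLength = 1, seed = NULL) {
  edgeLengthLaw <- match.arg(edgeLengthLaw)
  n <- as.integer(n)
  stopifnot(n >= 3L)
  .withSeed(seed, {
    ## nodes: 1..n leaves, negative ids for internal; edge list of pairs
    edges <- list(c(-1L, 1L), c(-1L, 2L), c(-1L, 3L))
    nextInt <- -2L
    for (k in seq_len(n)[-(1:3)]) {
      e <- sample.int(length(edges), 1L)
      ab <- edges[[e]]
      w <- nextInt; nextInt <- nextInt - 1L
      edges[[e]] <- c(ab[1L], w)
      edges <- c(edges, list(c(w, ab[2L])), list(c(w, k)))
    }
    wdt <- max(2L, nchar(as.character(n)))
    labs <- sprintf(paste0("t%0", wdt, "d"), seq_len(n))
    adj <- list()
    for (e in edges) {
      a <- as.character(e[1L]); b <- as.character(e[2L])
      adj[[a]] <- c(adj[[a]], e[2L]); adj[[b]] <- c(adj[[b]], e[1L])
    }
    lens <- if (edgeLengthLaw == "unit") rep(1, length(edges))
            else rexp(length(edges), rate = 1 / meanLength)
    key <- function(a, b) paste(min(a, b), max(a, b))
    lenMap <- structure(as.list(lens),
                        names = vapply(edges, function(e) key(e[1], e[2]), ""))
    nwk <- local({
      rec <- function(node, parent) {
        nb <- setdiff(adj[[as.character(node)]], parent)
        if (node > 0L) return(labs[node])
        paste0("(", paste(vapply(nb, function(ch) paste0(
          rec(ch, node), ":",
          format(lenMap[[key(node, ch)]], digits = 15)), character(1)),
          collapse = ","), ")")
      }
      paste0(rec(-1L, NA), ";")
    })
    .normalizeTree(ape::read.tree(text = nwk))
  })
}

#' Apply one nearest-neighbour interchange
#'
#' Around the chosen internal edge, one of the two subtrees on the far side
#' is exchanged with one subtree on the near side, replacing exactly one
#' non-trivial split of the encoding by an incompatible one. The inverse of
#' an NNI is an NNI at the same edge.
#'
#' @param phy a binary `phylo` (as from [randomTree()]).
#' @param whichEdge index into the tree's internal edges (edge-matrix
#'   order); random under `seed` when `NULL`.
#' @param swap 1 or 2: which of the two NNI neighbours to take; random
#'   under `seed` when `NULL`.
#' @param seed integer seed used when `whichEdge`/`swap` are unset.
#' @return the rearranged `phylo` (branch lengths travel with their
#'   subtrees).
#' @export
nniNeighbour <- function(phy, whichEdge = NULL, swap = NULL, seed = NULL) {
  nt <- length(phy$tip.label)
  internal <- which(phy$edge[, 2L] > nt)
  ## exclude edges whose child has fewer than 2 children (shouldn't occur)
  if (!length(internal)) stop("tree has no internal edge (star or n < 4)")
  .withSeed(seed, {
    if (is.null(whichEdge)) whichEdge <- sample.int(length(internal), 1L)
    if (is.null(swap)) swap <- sample.int(2L, 1L)
    if (whichEdge < 1L || whichEdge > length(internal))
      stop("whichEdge out of range: tree has ", length(internal),
           " internal edges (a pendant edge cannot be rearranged)")
    swap <- as.integer(swap)
    stopifnot(swap %in% 1:2)
    row <- internal[whichEdge]
    u <- phy$edge[row, 1L]; v <- phy$edge[row, 2L]
    vKids <- which(phy$edge[, 1L] == v)
    if (length(vKids) != 2L) stop("NNI requires a binary tree")
    uKids <- setdiff(which(phy$edge[, 1L] == u), row)
    if (!length(uKids)) stop("NNI requires a binary tree")
    aRow <- uKids[1L]
    cRow <- vKids[swap]
    phy$edge[aRow, 1L] <- v
    phy$edge[cRow, 1L] <- u
    ## rebuild a clean phylo (edge order, node numbering) via Newick
    phy2 <- phy
    phy2$edge.support <- NULL
    o <- ape::reorder.phylo(phy2, "cladewise", index.only = TRUE)
    phy2$edge <- phy2$edge[o, , drop = FALSE]
    phy2$edge.length <- phy2$edge.length[o]
    out <- .normalizeTree(ape::read.tree(text = ape::write.tree(phy2)))
    out
  })
}

#' Generate a profile of trees under a simple conflict model
#'
#' * `yule_identical`: `m` copies of one random tree -- no conflict; every
#'   consensus method returns the full encoding.
#' * `nni_mixture`: two topologies one NNI apart, replicated according to
#'   `mixtureFractions`, with edge lengths independently resampled per tree;
#'   the two swapped splits end up with supports `round(fractions * m)`.
#' * `bootstrap_like`: a base topology with, per tree, a small
#'   binomially-distributed number of random NNIs (rate `nniRate` per
#'   internal edge) and resampled lengths.
#'
#' @param n number of taxa (>= 4).
#' @param m number of trees (>= 1).
#' @param model one of `"yule_identical"`, `"nni_mixture"`,
#'   `"bootstrap_like"`.
#' @param mixtureFractions positive fractions summing to 1 (mixture model).
#' @param edgeLengthLaw,meanLength see [randomTree()].
#' @param nniRate per-internal-edge NNI probability (bootstrap model).
#' @param seed integer seed; the whole profile is reproducible from it.
#' @return a [treeProfile()].
#' @export
makeProfile <- function(n, m,
                        model = c("yule_identical", "nni_mixture", "bootstrap_like"),
                        mixtureFractions = c(0.7, 0.3),
                        edgeLengthLaw = c("exponential", "unit"),
                        meanLength = 1, nniRate = 0.05, seed = NULL) {
  model <- match.arg(model)
  edgeLengthLaw <- match.arg(edgeLengthLaw)
  stopifnot(n >= 4L, m >= 1L)
  if (model == "nni_mixture") {
    if (any(mixtureFractions <= 0) || abs(sum(mixtureFractions) - 1) > 1e-12)
      stop("mixtureFractions must be positive and sum to 1")
  }
  .withSeed(seed, {
    base <- randomTree(n, edgeLengthLaw, meanLength)
    resample <- function(phy) {
      if (edgeLengthLaw == "exponential")
        phy$edge.length <- rexp(length(phy$edge.length), rate = 1 / meanLength)
      phy
    }
    trees <- switch(model,
      yule_identical = rep(list(base), m),
      nni_mixture = {
        counts <- diff(c(0L, round(cumsum(mixtureFractions) * m)))
        tops0 <- vector("list", length(counts))
        tops0[[1L]] <- base
        for (z in seq_len(length(counts) - 1L))
          tops0[[z + 1L]] <- nniNeighbour(
            tops0[[z]],
            whichEdge = sample.int(sum(tops0[[z]]$edge[, 2] > n), 1L),
            swap = sample.int(2L, 1L))
        tops <- rep(tops0, times = counts)
        lapply(tops, resample)
      },
      bootstrap_like = lapply(seq_len(m), function(i) {
        t <- base
        nInt <- sum(t$edge[, 2] > n)
        k <- rbinom(1L, nInt, nniRate)
        for (z in seq_len(k)) t <- nniNeighbour(t)
        resample(t)
      }))
    treeProfile(trees)
  })
}
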