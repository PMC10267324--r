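## Tree profiles: a set of m unrooted trees sharing one taxon set.
##
## Trees are stored as ape "phylo" objects carrying an extra numeric vector
## `edge.support` (aligned with rows of $edge, NA where no support is known).
## The taxon index space is the lexicographically sorted label vector; it is
## fixed once per profile so that canonical split keys, sort orders and
## tie-breaks are deterministic.

#' Assemble a tree profile from a list of trees
#'
#' @param trees a list of `phylo` objects (or a `multiPhylo`), all on the
#'   same leaf-label set.
#' @return an object of class `treeProfile`: a list with elements `taxa`
#'   (sorted character vector of labels) and `trees` (normalised `phylo`
#'   objects, unrooted, with `edge.support`).
#' @export
treeProfile <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  attr(trees, "TipLabel") <- NULL
  if (length(trees) < 1L) stop("profile error: need at least one tree")
  labs <- sort(trees[[1L]]$tip.label)
  if (anyDuplicated(labs)) stop("profile error: duplicate taxon labels: ",
                                paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (length(labs) < 3L)
    stop("profile error: need at least 3 taxa, got ", length(labs))
  for (i in seq_along(trees)) {
    li <- sort(trees[[i]]$tip.label)
    if (!identical(li, labs)) {
      d <- c(setdiff(li, labs), setdiff(labs, li))
      stop("profile error: tree ", i, " has a different taxon set; ",
           "symmetric difference: ", paste(sort(unique(d)), collapse = ", "))
    }
  }
  trees <- lapply(trees, .normalizeTree)
  structure(list(taxa = labs, trees = trees), class = "treeProfile")
}

#' Read a profile of trees from Newick or Nexus
#'
#' Trees are unrooted on read (a degree-2 root is suppressed and its two
#' incident edge lengths summed), fully numeric internal-node labels are
#' interpreted as support of the edge above that node, and missing branch
#' lengths default to 1 (with a warning).
#'
#' @param file path to a file, or `NULL` when `text` is given.
#' @param text character scalar holding the file content.
#' @param format `"auto"` (detect a leading `#NEXUS`), `"newick"` or
#'   `"nexus"`.
#' @return a [treeProfile()].
#' @export
readTreeProfile <- function(file = NULL, text = NULL,
                            format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (is.null(file)) stop("give either 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (format == "auto")
    format <- if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) "nexus" else "newick"
  trees <- if (format == "nexus") {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    tryCatch(ape::read.nexus(tf, force.multi = TRUE),
             error = function(e) stop("Nexus parse error: ", conditionMessage(e),
                                      call. = FALSE))
  } else {
    tryCatch(ape::read.tree(text = text, keep.multi = TRUE),
             error = function(e) stop("Newick parse error: ", conditionMessage(e),
                                      call. = FALSE))
  }
  if (is.null(trees)) stop("Newick parse error: no tree found in input")
  treeProfile(trees)
}

## Normalise one tree: default missing lengths, harvest numeric node labels
## as per-edge support, unroot / collapse degree-2 nodes, and attach
## `edge.support`. Support is carried across the unrooting via split keys
## (the two edges at a degree-2 root induce the same split).
.normalizeTree <- function(phy) {
  nt <- length(phy$tip.label)
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 1", call. = FALSE)
    phy$edge.length <- rep(1, nrow(phy$edge))
  } else if (anyNA(phy$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 1", call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 1
  }
  if (any(phy$edge.length < 0))
    stop("profile error: negative branch length in input tree")
  supMap <- .supportBySplit(phy)
  phy2 <- phy
  if (ape::is.rooted(phy2)) phy2 <- ape::unroot(phy2)
  phy2 <- ape::collapse.singles(phy2)
  phy2$node.label <- NULL
  sets <- .edgeTipSets(phy2)
  lab <- phy2$tip.label
  es <- rep(NA_real_, nrow(phy2$edge))
  if (length(supMap)) {
    for (k in seq_along(es)) {
      key <- .labelKey(lab[sets[[k]]], lab)
      v <- supMap[[key]]
      if (!is.null(v)) es[k] <- v
    }
  }
  phy2$edge.support <- es
  phy2
}

## Map canonical split key (over tip labels) -> numeric support, from the
## internal-node labels of a (possibly rooted) tree. Non-numeric labels are
## ignored with a warning; duplicate keys (degree-2 chains) keep the maximum.
.supportBySplit <- function(phy) {
  nl <- phy$node.label
  out <- list()
  if (is.null(nl)) return(out)
  nt <- length(phy$tip.label)
  sets <- .edgeTipSets(phy)
  bad <- FALSE
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2L]
    if (child <= nt) next
    labk <- nl[child - nt]
    if (is.na(labk) || !nzchar(labk)) next
    v <- suppressWarnings(as.numeric(labk))
    if (is.na(v)) { bad <- TRUE; next }
    key <- .labelKey(phy$tip.label[sets[[k]]], phy$tip.label)
    out[[key]] <- max(out[[key]], v)
  }
  if (bad)
    warning("non-numeric internal node labels ignored (not usable as support)",
            call. = FALSE)
  out
}

## Canonical key of a tip-label subset: the side avoiding the
## lexicographically smallest label, sorted and pasted.
.labelKey <- function(part, allLabs) {
  ref <- min(allLabs)
  if (ref %in% part) part <- setdiff(allLabs, part)
  paste(sort(part), collapse = "\r")
}

## For every edge row k, the sorted tip indices (into phy$tip.label) on the
## child side of the edge.
.edgeTipSets <- function(phy) {
  nt <- length(phy$tip.label)
  ne <- nrow(phy$edge)
  childEdges <- split(seq_len(ne), phy$edge[, 1L])
  sets <- vector("list", nt + phy$Nnode)
  rec <- function(node) {
    if (node <= nt) return(node)
    out <- integer(0)
    for (k in childEdges[[as.character(node)]]) {
      v <- phy$edge[k, 2L]
      sets[[v]] <<- rec(v)
      out <- c(out, sets[[v]])
    }
    sort(out)
  }
  root <- nt + 1L
  sets[[root]] <- rec(root)
  lapply(seq_len(ne), function(k) sort(sets[[phy$edge[k, 2L]]]))
}

#' Number of trees and taxa in a profile
#' @param x a `treeProfile`.
#' @return `nTrees`: the number of trees m; `nTaxa`: the number of taxa n.
#' @export
nTrees <- function(x) length(x$trees)

#' @rdname nTrees
#' @export
nTaxa <- function(x) length(x$taxa)

#' @export
print.treeProfile <- function(x, ...) {
  cat("Tree profile: m =", nTrees(x), "trees on n =", nTaxa(x), "taxa\n")
  cat("Taxa:", paste(head(x$taxa, 8L), collapse = ", "),
      if (nTaxa(x) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Write a profile as multi-tree Newick
#'
#' @param x a `treeProfile`.
#' @param file output path.
#' @export
writeTreeProfile <- function(x, file) {
  stopifnot(inherits(x, "treeProfile"))
  txt <- vapply(x$trees, function(p) ape::write.tree(p), character(1))
  writeLines(txt, file)
  invisible(NULL)
}
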