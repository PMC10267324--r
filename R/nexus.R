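## SplitsTree-style Nexus interchange for split systems, and writing a
## pairwise-compatible split system as the unique unrooted tree it encodes.

#' Write a split system as a Nexus SPLITS block
#'
#' Emits a TAXA block plus a SPLITS block in the SplitsTree dialect:
#' DIMENSIONS, FORMAT (weights and confidences on), an optional CYCLE line
#' (1-based taxon indices of a circular ordering), and MATRIX lines of the
#' form `id weight confidence member-indices,` where the members are the
#' canonical (x0-avoiding) split part. [readSplitsNexus()] reproduces the
#' system exactly.
#'
#' @param splits a `splitSystem`.
#' @param file output path.
#' @param ordering optional integer circular ordering to record as CYCLE.
#' @export
writeSplitsNexus <- function(splits, file, ordering = NULL) {
  stopifnot(inherits(splits, "splitSystem"))
  n <- length(splits$taxa)
  k <- nSplits(splits)
  out <- c("#NEXUS", "",
           "BEGIN TAXA;",
           sprintf("DIMENSIONS ntax=%d;", n),
           "TAXLABELS",
           paste0("\t'", splits$taxa, "'"),
           ";", "END;", "",
           "BEGIN SPLITS;",
           sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, k),
           "FORMAT labels=no weights=yes confidences=yes;")
  if (!is.null(ordering)) {
    ordering <- as.integer(ordering)
    if (!setequal(ordering, seq_len(n)))
      stop("ordering must be a permutation of 1..", n)
    out <- c(out, paste0("CYCLE ", paste(ordering, collapse = " "), ";"))
  }
  out <- c(out, "MATRIX")
  for (j in seq_len(k))
    out <- c(out, sprintf("%d %.17g %.17g %s,", j,
                          splits$weight[j], splits$support[j],
                          paste(splits$parts[[j]], collapse = " ")))
  out <- c(out, ";", "END;")
  writeLines(out, file)
  invisible(NULL)
}

#' Read a Nexus SPLITS block written by [writeSplitsNexus()]
#'
#' @param file input path.
#' @param x0 reference taxon index for canonical storage.
#' @return a list with `splits` (a `splitSystem`) and `ordering` (integer
#'   CYCLE, or `NULL`).
#' @export
readSplitsNexus <- function(file, x0 = 1L) {
  ln <- trimws(readLines(file, warn = FALSE))
  if (!grepl("^#NEXUS", ln[1], ignore.case = TRUE))
    stop("not a Nexus file: ", file)
  grab <- function(block) {
    i0 <- grep(paste0("^BEGIN\\s+", block, "\\s*;"), ln, ignore.case = TRUE)
    if (!length(i0)) stop("no ", block, " block in ", file)
    i1 <- grep("^END\\s*;", ln, ignore.case = TRUE)
    i1 <- i1[i1 > i0[1]][1]
    ln[(i0[1] + 1L):(i1 - 1L)]
  }
  tb <- grab("TAXA")
  j0 <- grep("^TAXLABELS", tb, ignore.case = TRUE)
  j1 <- which(tb == ";")
  j1 <- j1[j1 > j0][1]
  taxa <- gsub("^'|'$", "", tb[(j0 + 1L):(j1 - 1L)])
  sb <- grab("SPLITS")
  cyc <- grep("^CYCLE", sb, ignore.case = TRUE)
  ordering <- NULL
  if (length(cyc))
    ordering <- as.integer(strsplit(trimws(sub(";.*$", "", sub("^CYCLE", "", sb[cyc[1]], ignore.case = TRUE))), "\\s+")[[1]])
  m0 <- grep("^MATRIX", sb, ignore.case = TRUE)[1]
  m1 <- which(sb == ";")
  m1 <- m1[m1 > m0][1]
  parts <- list(); weight <- numeric(); support <- numeric()
  rows <- if (m1 > m0 + 1L) sb[seq(m0 + 1L, m1 - 1L)] else character(0)
  rows <- rows[nzchar(rows)]
  for (r in rows) {
    f <- strsplit(sub(",\\s*$", "", r), "\\s+")[[1]]
    weight <- c(weight, as.numeric(f[2]))
    support <- c(support, as.numeric(f[3]))
    parts <- c(parts, list(as.integer(f[-(1:3)])))
  }
  list(splits = splitSystem(taxa, parts, weight, support, x0 = x0),
       ordering = ordering)
}

#' Write a pairwise-compatible split system as a Newick tree
#'
#' A pairwise-compatible split system is the split encoding of exactly one
#' unrooted tree; this reconstructs that tree (adding any missing trivial
#' splits as zero-length pendant edges) and writes it as Newick with branch
#' lengths taken from the split weights, or from the supports.
#'
#' @param splits a `splitSystem` whose splits are pairwise compatible.
#' @param file output path, or `NULL` to return the Newick string.
#' @param lengths `"weight"` or `"support"`: what to write as branch
#'   lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
writeTreeNewick <- function(splits, file = NULL, lengths = c("weight", "support")) {
  lengths <- match.arg(lengths)
  stopifnot(inherits(splits, "splitSystem"))
  k <- nSplits(splits)
  for (i in seq_len(max(0L, k - 1L))) for (j in seq(i + 1L, k))
    if (!.partsCompatible(splits$parts[[i]], splits$parts[[j]]))
      stop("incompatible split pair: {",
           paste(splits$taxa[splits$parts[[i]]], collapse = ","), "} vs {",
           paste(splits$taxa[splits$parts[[j]]], collapse = ","), "}")
  n <- length(splits$taxa)
  len <- if (lengths == "weight") splits$weight else splits$support
  ## pendant edge length per taxon (0 when the trivial split is absent)
  pend <- rep(0, n)
  nontriv <- list(); ntLen <- numeric()
  for (j in seq_len(k)) {
    p <- splits$parts[[j]]
    if (length(p) == 1L) pend[p] <- len[j]
    else if (length(p) == n - 1L) pend[setdiff(seq_len(n), p)] <- len[j]
    else { nontriv <- c(nontriv, list(p)); ntLen <- c(ntLen, len[j]) }
  }
  ## compatible parts avoiding x0 form a laminar family: nest by containment
  o <- order(-vapply(nontriv, length, integer(1)))
  nontriv <- nontriv[o]; ntLen <- ntLen[o]
  nodeFor <- function(members, length0) {
    ## children: maximal nested parts, then bare taxa not covered by any
    inner <- which(vapply(nontriv, function(q)
      length(q) < length(members) && all(q %in% members), logical(1)))
    used <- integer(0); childStr <- character(0)
    for (ix in inner) {
      q <- nontriv[[ix]]
      if (any(q %in% used)) next   # not maximal: nested inside a sibling
      childStr <- c(childStr, nodeFor(q, ntLen[ix]))
      used <- c(used, q)
    }
    bare <- setdiff(members, used)
    childStr <- c(childStr, sprintf("%s:%s", .quoteNewick(splits$taxa[bare]),
                                    format(pend[bare], digits = 15)))
    body <- paste0("(", paste(childStr, collapse = ","), ")")
    if (is.na(length0)) body
    else paste0(body, ":", format(length0, digits = 15))
  }
  nwk <- paste0(nodeFor(seq_len(n), NA_real_), ";")
  if (is.null(file)) return(nwk)
  writeLines(nwk, file)
  invisible(nwk)
}

.quoteNewick <- function(labs) {
  need <- grepl("[ ()\\[\\]:;,']", labs)
  ifelse(need, paste0("'", gsub("'", "''", labs), "'"), labs)
}
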