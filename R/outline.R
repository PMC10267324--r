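## Phylogenetic outline: a circular split system drawn as one closed,
## outer-labeled planar polygon. With the ordering rotated so that x0 sits
## at position 1, every canonical split part is an interval [p, q] of
## positions 2..n. Taxon positions get equally spaced angles on the circle
## (x0 at angle 0) and a split's edge direction is the mean of its interval
## endpoints' angles. Walking the taxa in order, the boundary crosses each
## split twice: +v when its interval opens, -v when it closes, so the
## polygon closes exactly and every split contributes two equal-length
## antiparallel edges.

#' Compute the outline polygon of a circular split system
#'
#' @param splits a `splitSystem` that is circular with respect to
#'   `ordering` (this is checked).
#' @param ordering integer permutation of 1..n, e.g. from a
#'   [consensusOutline()] result.
#' @param scaleMode edge length per split: `"support"`, `"mean_weight"`
#'   (mean branch length over the containing trees) or `"sum_weight"`
#'   (summed branch length).
#' @return an object of class `outline`: list with `points` (closed
#'   coordinate matrix, last row equals the first), `edges` (data frame
#'   `from`, `to`, `split`), `taxonAnchor` (point index per taxon),
#'   `ordering`, `splits`, `scaleMode`.
#' @export
computeOutline <- function(splits, ordering,
                           scaleMode = c("support", "mean_weight", "sum_weight")) {
  scaleMode <- match.arg(scaleMode)
  stopifnot(inherits(splits, "splitSystem"))
  if (!isCircular(splits, ordering))
    stop("split system is not circular with respect to the given ordering")
  n <- length(splits$taxa)
  r <- which(ordering == splits$x0)
  ord <- c(ordering[r:n], ordering[seq_len(r - 1L)])
  pos <- integer(n); pos[ord] <- seq_len(n)
  k <- nSplits(splits)
  len <- switch(scaleMode,
    support = splits$support,
    mean_weight = splits$weight,
    sum_weight = vapply(seq_len(k), function(j)
      if (!is.null(splits$occWeights)) sum(splits$occWeights[[j]])
      else splits$weight[j] * max(1, splits$treeCount[j]), numeric(1)))
  if (any(len == 0))
    message("outline: ", sum(len == 0), " zero-length split(s) give degenerate edges")
  p <- vapply(splits$parts, function(s) min(pos[s]), integer(1))
  q <- vapply(splits$parts, function(s) max(pos[s]), integer(1))
  alpha <- 2 * pi * (seq_len(n) - 1L) / n
  theta <- (alpha[p] + alpha[q]) / 2
  vx <- len * cos(theta); vy <- len * sin(theta)

  pts <- matrix(0, nrow = 2L * k + 1L, ncol = 2L)
  edges <- data.frame(from = integer(2L * k), to = integer(2L * k),
                      split = integer(2L * k))
  anchor <- integer(n)
  anchor[ord[1L]] <- 1L
  cur <- c(0, 0); ip <- 1L; ie <- 0L
  for (g in seq_len(n)) {          # gap after position g
    opening <- which(p == g + 1L)  # crossed outward: +v
    closing <- which(q == g)       # crossed back: -v
    ev <- c(opening, closing)
    sgn <- c(rep(1, length(opening)), rep(-1, length(closing)))
    o <- order(theta[ev])
    for (t in o) {
      j <- ev[t]
      cur <- cur + sgn[t] * c(vx[j], vy[j])
      ip <- ip + 1L
      pts[ip, ] <- cur
      ie <- ie + 1L
      edges$from[ie] <- ip - 1L; edges$to[ie] <- ip; edges$split[ie] <- j
    }
    if (g < n) anchor[ord[g + 1L]] <- ip
  }
  if (max(abs(cur)) > 1e-9 * max(1, max(abs(pts))))
    stop("outline walk failed to close (numerical inconsistency)")
  structure(list(points = pts, edges = edges, taxonAnchor = anchor,
                 ordering = ord, splits = splits, scaleMode = scaleMode),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  k <- nSplits(x$splits)
  cat("Phylogenetic outline:", 2L * k, "nodes and", 2L * k, "edges for",
      k, "splits on", length(x$splits$taxa), "taxa\n")
  cat("  scale:", x$scaleMode, "\n")
  invisible(x)
}

#' Render an outline as SVG
#'
#' Writes a standards-conforming SVG 1.1 document: one closed path for the
#' polygon boundary and one text label per taxon, offset outward along the
#' taxon's angular direction. Output is byte-deterministic for a given
#' outline and options.
#'
#' @param outline an [computeOutline()] result.
#' @param file output path.
#' @param width canvas width in pixels (height follows the aspect ratio).
#' @param fontSize label font size in pixels.
#' @param strokeBySupport scale per-edge stroke width by split support.
#' @export
renderSVG <- function(outline, file, width = 600, fontSize = 11,
                      strokeBySupport = FALSE) {
  stopifnot(inherits(outline, "outline"))
  pts <- outline$points
  n <- length(outline$splits$taxa)
  span <- apply(pts, 2, range)
  sz <- pmax(span[2, ] - span[1, ], 1e-12)
  margin <- 0.14 * max(sz)
  scale <- (width - 2) / (max(sz) + 2 * margin)
  tx <- function(x) (x - span[1, 1] + margin) * scale + 1
  ty <- function(y) (span[2, 2] - y + margin) * scale + 1   # flip y
  W <- fmt((max(sz) + 2 * margin) * scale + 2)
  H <- W
  d <- paste0("M ", fmt(tx(pts[1, 1])), " ", fmt(ty(pts[1, 2])), " ",
              paste(paste("L", fmt(tx(pts[-1, 1])), fmt(ty(pts[-1, 2]))),
                    collapse = " "), " Z")
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">",
            W, H, W, H))
  if (strokeBySupport) {
    e <- outline$edges
    sup <- outline$splits$support
    wmax <- max(sup, 1e-12)
    for (i in seq_len(nrow(e))) {
      sw <- 0.5 + 2.5 * sup[e$split[i]] / wmax
      lines <- c(lines, sprintf(
        "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\" stroke-width=\"%s\"/>",
        fmt(tx(pts[e$from[i], 1])), fmt(ty(pts[e$from[i], 2])),
        fmt(tx(pts[e$to[i], 1])), fmt(ty(pts[e$to[i], 2])), fmt(sw)))
    }
  } else {
    lines <- c(lines, sprintf(
      "<path d=\"%s\" fill=\"none\" stroke=\"black\" stroke-width=\"1\"/>", d))
  }
  alpha <- 2 * pi * (seq_len(n) - 1L) / n
  off <- 0.05 * max(sz)
  for (i in seq_len(n)) {
    tax <- outline$ordering[i]
    pt <- pts[outline$taxonAnchor[tax], ]
    lx <- pt[1] + off * cos(alpha[i])
    ly <- pt[2] + off * sin(alpha[i])
    anchorAttr <- if (cos(alpha[i]) < -1e-9) "end" else "start"
    lines <- c(lines, sprintf(
      "<text x=\"%s\" y=\"%s\" font-family=\"Helvetica\" font-size=\"%s\" text-anchor=\"%s\">%s</text>",
      fmt(tx(lx)), fmt(ty(ly)), fmt(fontSize), anchorAttr,
      .xmlEscape(outline$splits$taxa[tax])))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, file)
  invisible(NULL)
}

fmt <- function(x) sprintf("%.4f", x)

.xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}
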