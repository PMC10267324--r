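# Independent oracles and small generators used across the suite.
# The permutation oracle decides cluster consecutiveness by enumerating all
# n! linear orderings; it never touches the PQ-tree implementation.

permAll <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permAll(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) out <- rbind(out, cbind(i, sub + (sub >= i)))
  out
}

# rows of P (orderings) in which the cluster is consecutive
rowsConsecutive <- function(P, cluster) {
  n <- ncol(P)
  L <- matrix(P %in% cluster, nrow(P))
  C <- col(L)
  mx <- max.col(L * C, ties.method = "last")
  mn <- max.col(L * ((n + 1L) - C), ties.method = "first")
  (mx - mn + 1L) == length(cluster)
}

# enumerate the frontier of a PQ-tree (all leaf orderings it represents)
pqFrontier <- function(pq) {
  cart <- function(lists) {
    out <- list(integer(0))
    for (opts in lists)
      out <- unlist(lapply(out, function(pre)
        lapply(opts, function(s) c(pre, s))), recursive = FALSE)
    out
  }
  permsOf <- function(k) {
    if (k == 1L) return(list(1L))
    m <- permAll(k)
    lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  rec <- function(node) {
    if (node$type == "L") return(list(node$taxon))
    fr <- lapply(node$children, rec)
    if (node$type == "P") {
      out <- list()
      for (p in permsOf(length(fr))) out <- c(out, cart(fr[p]))
      out
    } else {
      fwd <- cart(fr)
      c(fwd, lapply(fwd, rev))
    }
  }
  unique(rec(pq$root))
}

# proper-crossing test for two closed segments (shared endpoints allowed)
segmentsCross <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  t > 1e-9 && t < 1 - 1e-9 && s > 1e-9 && s < 1 - 1e-9
}

outlineIsSimple <- function(ol) {
  P <- ol$points
  ne <- nrow(ol$edges)
  for (i in seq_len(ne - 1L)) {
    for (j in seq(i + 1L, ne)) {
      if (j == i + 1L || (i == 1L && j == ne)) next  # adjacent may touch
      if (segmentsCross(P[i, ], P[i + 1L, ], P[j, ], P[j + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

# a random circular split system: random ordering, distinct intervals of
# positions 2..n as canonical parts, x0 = 1
randomCircularSystem <- function(n, nsplits, seed) {
  set.seed(seed)
  taxa <- sprintf("s%02d", seq_len(n))
  z <- c(1L, 1L + sample.int(n - 1L))
  iv <- unique(t(apply(cbind(sample(2:n, nsplits, TRUE),
                             sample(2:n, nsplits, TRUE)), 1, sort)))
  parts <- lapply(seq_len(nrow(iv)), function(i) sort(z[iv[i, 1]:iv[i, 2]]))
  keys <- vapply(parts, paste, "", collapse = " ")
  keep <- !duplicated(keys) & vapply(parts, length, 1L) < n
  parts <- parts[keep]
  sys <- splitSystem(taxa, parts, weight = runif(length(parts), 0.2, 2),
                     support = sample.int(50, length(parts), TRUE), x0 = 1L)
  list(splits = sys, ordering = z)
}

quartetProfile <- function() {
  readTreeProfile(text = paste(
    "((a:1,b:1):1,(c:1,d:1):1);",
    "((a:1,b:1):1,(c:1,d:1):1);",
    "((a:1,c:1):1,(b:1,d:1):1);", sep = "\n"))
}
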