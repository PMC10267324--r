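## End-to-end pipeline: read a profile, run one consensus method, write the
## requested artifacts. Output files are written to a temporary sibling and
## atomically renamed, so a failure never leaves a partial file behind.

#' Run a consensus analysis on a tree file
#'
#' @param input path to a multi-tree Newick file or a Nexus TREES block.
#' @param method `"outline"`, `"majority"`, `"strict"`, `"greedy"` or
#'   `"network"`.
#' @param p network threshold in (0, 1\]; required iff `method = "network"`.
#' @param supportMode `"tree_count"` or `"edge_support"`.
#' @param scaleMode edge scaling for the outline drawing: `"support"`,
#'   `"mean_weight"` or `"sum_weight"`.
#' @param x0 reference taxon label or index (default: lexicographically
#'   smallest label).
#' @param outNexus,outNewick,outSvg optional output paths: the selected
#'   splits as a Nexus SPLITS block (with CYCLE when an ordering exists),
#'   the consensus tree as Newick (compatible split sets only), and the
#'   outline drawing as SVG (circular split sets only).
#' @param quiet suppress the log lines.
#' @return the `consensusResult`, invisibly.
#' @export
runConsensus <- function(input,
                         method = c("outline", "majority", "strict", "greedy", "network"),
                         p = NULL,
                         supportMode = c("tree_count", "edge_support"),
                         scaleMode = c("support", "mean_weight", "sum_weight"),
                         x0 = 1L, outNexus = NULL, outNewick = NULL,
                         outSvg = NULL, quiet = FALSE) {
  method <- match.arg(method)
  supportMode <- match.arg(supportMode)
  scaleMode <- match.arg(scaleMode)
  if (method == "network" && is.null(p))
    stop("method 'network' needs a threshold p", call. = FALSE)
  profile <- readTreeProfile(input)
  say <- function(...) if (!quiet) message(...)
  say("profile: n = ", nTaxa(profile), " taxa, m = ", nTrees(profile), " trees")
  res <- switch(method,
    outline  = consensusOutline(profile, supportMode, x0),
    majority = majorityConsensus(profile, supportMode, x0 = x0),
    strict   = strictConsensus(profile, x0),
    greedy   = greedyConsensus(profile, supportMode, x0),
    network  = consensusNetworkSplits(profile, p, supportMode, x0))
  say(method, ": kept ", nSplits(res$splits), " of ", res$nInputSplits,
      " input splits; retention ", sprintf("%.1f%%", res$retention))
  if (!is.null(outNexus))
    .atomically(outNexus, function(tmp)
      writeSplitsNexus(res$splits, tmp, ordering = res$ordering))
  if (!is.null(outNewick)) {
    ok <- tryCatch({
      .atomically(outNewick, function(tmp) writeTreeNewick(res$splits, tmp))
      TRUE
    }, error = function(e) { say("Newick skipped: ", conditionMessage(e)); FALSE })
  }
  if (!is.null(outSvg)) {
    if (is.null(res$ordering)) {
      say("SVG skipped: the selected splits are not circular; ",
          "exported splits only (general split-network drawing is not supported)")
    } else {
      ol <- computeOutline(res$splits, res$ordering, scaleMode)
      say("outline: ", nrow(ol$edges), " nodes and ", nrow(ol$edges), " edges")
      .atomically(outSvg, function(tmp) renderSVG(ol, tmp))
    }
  }
  invisible(res)
}

.atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(NULL)
}
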