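#' Parse a rooted ultrametric tree from newick text
#'
#' Reads a newick string (or a file containing one), validates that the tree
#' is rooted, has non-negative branch lengths on all non-root edges, and is
#' ultrametric (all root-to-tip path lengths equal) within a relative
#' tolerance. Polytomies are resolved deterministically into binary nodes
#' joined by zero-length branches, children taken in input order, because the
#' branching-rate models assume binary branching events.
#'
#' Depths are measured back from the tips (present = 0), so the threshold of
#' a delimitation model is directly comparable to "genetic distance from the
#' branch tips" in substitutions per site.
#'
#' @param text a newick string. Use [read_ultrametric()] for files.
#' @param epsilon relative ultrametricity tolerance: the maximum allowed
#'   deviation of any root-to-tip path from the tree depth, as a fraction of
#'   the tree depth. Default `1e-6`.
#' @param force_ultrametric if `TRUE`, a non-ultrametric tree is accepted and
#'   node depths are taken as the mean root-to-tip distance minus the
#'   root-to-node distance, with tip depths rescaled to 0.
#' @return an object of class `c("ultratree", "phylo")`: an [ape] tree with
#'   an added `node_depth` attribute giving, for every node id, its depth
#'   (distance to its descendant tips; 0 for all tips).
#' @seealso [branching_schedule()], [write_newick()]
#' @export
parse_newick <- function(text, epsilon = 1e-6, force_ultrametric = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick: could not parse tree text", call. = FALSE)
  }
  as_ultrametric(tr, epsilon = epsilon, force_ultrametric = force_ultrametric)
}

#' Read a rooted ultrametric tree from a newick file
#'
#' @param file path to a newick file.
#' @inheritParams parse_newick
#' @return see [parse_newick()].
#' @export
read_ultrametric <- function(file, epsilon = 1e-6, force_ultrametric = FALSE) {
  if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""),
               epsilon = epsilon, force_ultrametric = force_ultrametric)
}

#' Validate a phylo object as a rooted ultrametric tree
#'
#' @param tree a `phylo` object.
#' @inheritParams parse_newick
#' @return an `ultratree` (see [parse_newick()]).
#' @export
as_ultrametric <- function(tree, epsilon = 1e-6, force_ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    # deterministic resolution: children in input order, zero-length
    # branches; a basal trichotomy is treated as a root polytomy
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("tree must have at least 2 tips", call. = FALSE)

  h <- ape::node.depth.edgelength(tree)  # distance from root to each node
  tip_h <- h[seq_len(n_tip)]
  depth <- max(tip_h)
  if (depth <= 0) stop("tree has zero depth", call. = FALSE)
  dev <- max(abs(tip_h - depth))
  if (dev > epsilon * depth && !force_ultrametric) {
    stop(sprintf(
      "tree is not ultrametric: max tip-depth deviation %.3g exceeds %.3g (= %g * depth); set force_ultrametric = TRUE to rescale",
      dev, epsilon * depth, epsilon), call. = FALSE)
  }
  if (force_ultrametric) {
    node_depth <- mean(tip_h) - h
    node_depth[seq_len(n_tip)] <- 0
    node_depth <- pmax(node_depth, 0)
  } else {
    node_depth <- depth - h
    node_depth[seq_len(n_tip)] <- 0
  }
  attr(tree, "node_depth") <- node_depth
  class(tree) <- unique(c("ultratree", class(tree)))
  tree
}

#' Node depths of an ultrametric tree
#'
#' Depth is the distance from a node to any of its descendant tips; tips are
#' at depth 0 and the root at the tree depth.
#'
#' @param tree an `ultratree` (or a `phylo`, which is validated first).
#' @return numeric vector indexed by node id (tips `1..n`, then internals).
#' @export
node_depths <- function(tree) {
  nd <- attr(tree, "node_depth")
  if (is.null(nd)) {
    tree <- as_ultrametric(tree)
    nd <- attr(tree, "node_depth")
  }
  nd
}

#' Tree depth (root depth) of an ultrametric tree
#' @param tree an `ultratree`.
#' @return the root-to-tip distance in the tree's branch-length units.
#' @export
tree_depth <- function(tree) {
  max(node_depths(tree))
}

# Merge event depths closer than `tol` into single multi-lineage events.
# Returns data.frame(depth, mult) sorted deepest first.
merge_event_depths <- function(depths, tol = 1e-10) {
  d <- sort(depths, decreasing = TRUE)
  grp <- cumsum(c(TRUE, diff(d) < -tol))
  data.frame(
    depth = as.numeric(tapply(d, grp, max)),
    mult  = as.integer(tapply(d, grp, length))
  )
}

#' Branching-event schedule of an ultrametric tree
#'
#' Derives the sequence of branching-event depths (deepest first) and the
#' inter-event intervals with their lineage counts, the sufficient statistics
#' of the single-process branching-rate model. The lineage count of an
#' interval is the number of lineages present after the event that opens it
#' (so a binary tree with n tips yields counts 2, 3, ..., n). Simultaneous
#' events (depth difference below `merge_tol`) are merged into one
#' multi-lineage increment and the zero-length interval between them is
#' skipped.
#'
#' @param tree an `ultratree`.
#' @param merge_tol absolute depth tolerance below which events are merged.
#' @return a list of class `branching_schedule` with elements
#'   \describe{
#'     \item{events}{data.frame `depth`, `mult` (merged lineage increments),
#'       deepest first}
#'     \item{intervals}{data.frame `start`, `end`, `x` (duration), `n`
#'       (lineage count), `event` (does the interval end in an event?),
#'       `mult` (number of merged events ending it, 0 for the last)}
#'     \item{depth}{root depth}
#'   }
#' @export
branching_schedule <- function(tree, merge_tol = 1e-10) {
  tree <- if (inherits(tree, "ultratree")) tree else as_ultrametric(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("schedule requires at least 2 tips", call. = FALSE)
  nd <- node_depths(tree)
  internal <- nd[(n_tip + 1L):length(nd)]
  ev <- merge_event_depths(internal, tol = merge_tol)
  E <- nrow(ev)
  # lineage count after each event group
  n_after <- 1L + cumsum(ev$mult)
  ends <- c(ev$depth[-1L], 0)
  intervals <- data.frame(
    start = ev$depth,
    end   = ends,
    x     = ev$depth - ends,
    n     = n_after,
    event = c(rep(TRUE, E - 1L), FALSE),
    mult  = c(ev$mult[-1L], 0L)
  )
  # drop zero-length intervals (possible only with merged events at end = 0)
  intervals <- intervals[intervals$x > 0 | intervals$event, , drop = FALSE]
  out <- list(events = ev, intervals = intervals, depth = ev$depth[1L])
  class(out) <- "branching_schedule"
  out
}

#' Serialize an ultrametric tree to newick
#'
#' Round-trip safe: parsing the output reproduces topology, labels and node
#' depths (within numerical precision of the decimal representation).
#'
#' @param tree an `ultratree` or `phylo`.
#' @param digits number of significant digits for branch lengths.
#' @return a newick string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}
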