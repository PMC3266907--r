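# Threshold-based partitioning of an ultrametric tree into diversification
# nodes and coalescent clusters/singletons (the delimited entities).

# Build a partition object from explicit cluster roots and singleton tips.
# clusters: list of list(root = node id, T = local threshold depth)
# singletons: data.frame(tip = node id, T = threshold depth)
build_partition <- function(tree, clusters, singletons) {
  nd <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cluster_of <- rep(NA_integer_, n_node)
  cl_out <- vector("list", length(clusters))
  if (length(clusters)) {
    for (i in seq_along(clusters)) {
      root <- clusters[[i]]$root
      tips <- phangorn::Descendants(tree, root, type = "tips")[[1]]
      all_desc <- c(root, phangorn::Descendants(tree, root, type = "all"))
      internal <- all_desc[all_desc > n_tip]
      cl_out[[i]] <- list(
        root = root,
        T = clusters[[i]]$T,
        tips = sort(tips),
        events = sort(nd[internal], decreasing = TRUE)
      )
      cluster_of[all_desc] <- i
    }
  }
  if (is.null(singletons)) {
    singletons <- data.frame(tip = integer(0), T = numeric(0))
  }
  n_entities <- length(cl_out) + nrow(singletons)
  structure(
    list(tree = tree, clusters = cl_out, singletons = singletons,
         cluster_of = cluster_of, n_entities = n_entities),
    class = "gmyc_partition"
  )
}

#' Classify tree nodes against a threshold depth
#'
#' Nodes deeper than the threshold `T` belong to the diversification
#' (interspecific) phase; nodes at depth below `T` belong to the coalescent
#' (intraspecific) phase. A branch crossing `T` whose subtree contains at
#' least one node shallower than `T` defines a cluster of its tips; a branch
#' crossing `T` with no internal node below it yields a singleton tip. A
#' threshold deeper than the root yields a single all-tip cluster (one
#' entity); a threshold below every internal node makes every tip a
#' singleton.
#'
#' @param tree an `ultratree` (see [parse_newick()]).
#' @param T threshold depth from the tips, in the tree's branch-length units
#'   (substitutions/site for a molecular clock tree). Must be non-negative.
#' @return an object of class `gmyc_partition` with elements `clusters`
#'   (each with `root`, `T`, `tips`, `events`), `singletons` (data.frame
#'   `tip`, `T`) and `n_entities`. Use [entity_table()] for a per-tip view.
#' @export
classify_nodes <- function(tree, T) {
  tree <- if (inherits(tree, "ultratree")) tree else as_ultrametric(tree)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0) {
    stop("threshold T must be a single non-negative number", call. = FALSE)
  }
  nd <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internal_ids <- (n_tip + 1L):(n_tip + tree$Nnode)
  coal <- nd[internal_ids] < T
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent[root] <- 0L

  # cluster roots: coalescent internal nodes whose parent is diversification
  # (or which are the tree root itself)
  is_coal <- rep(FALSE, n_tip + tree$Nnode)
  is_coal[internal_ids] <- coal
  parent_coal <- rep(FALSE, length(internal_ids))
  has_par <- parent[internal_ids] > 0L
  parent_coal[has_par] <- is_coal[parent[internal_ids][has_par]]
  cl_roots <- internal_ids[coal & (internal_ids == root | !parent_coal)]
  clusters <- lapply(cl_roots, function(r) list(root = r, T = T))

  # singleton tips: tips whose parent node is diversification
  sing_tips <- which(!is_coal[parent[seq_len(n_tip)]])
  # tips inside clusters are not singletons (parent coalescent) by the above
  singletons <- data.frame(tip = sing_tips, T = rep(T, length(sing_tips)))
  build_partition(tree, clusters, singletons)
}

# Re-cluster the subtree rooted at `node` with local threshold `T_local`,
# returning list(clusters = ..., singletons = ...) specs relative to the
# whole tree.
recluster_subtree <- function(tree, node, T_local) {
  nd <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  sub_nodes <- c(node, phangorn::Descendants(tree, node, type = "all"))
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  in_sub <- rep(FALSE, n_tip + tree$Nnode)
  in_sub[sub_nodes] <- TRUE
  is_coal <- rep(FALSE, n_tip + tree$Nnode)
  internals <- sub_nodes[sub_nodes > n_tip]
  is_coal[internals] <- nd[internals] < T_local
  par_coal <- rep(FALSE, length(internals))
  has_par <- parent[internals] > 0L
  par_coal[has_par] <- is_coal[parent[internals][has_par]]
  cl_roots <- internals[is_coal[internals] & (internals == node | !par_coal)]
  sub_tips <- sub_nodes[sub_nodes <= n_tip]
  sing <- sub_tips[!is_coal[parent[sub_tips]]]
  list(
    clusters = lapply(cl_roots, function(r) list(root = r, T = T_local)),
    singletons = if (length(sing))
      data.frame(tip = sing, T = rep(T_local, length(sing)))
    else data.frame(tip = integer(0), T = numeric(0))
  )
}

#' Per-tip entity membership of a partition
#'
#' @param partition a `gmyc_partition` (from [classify_nodes()] or a fitted
#'   model's `partition` element).
#' @return data.frame with columns `tip` (label), `entity` (integer id) and
#'   `type` (`"cluster"` or `"singleton"`). Entities are numbered clusters
#'   first, in order of decreasing stem depth, then singletons.
#' @export
entity_table <- function(partition) {
  stopifnot(inherits(partition, "gmyc_partition"))
  tree <- partition$tree
  rows <- list()
  eid <- 0L
  for (cl in partition$clusters) {
    eid <- eid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      tip = tree$tip.label[cl$tips], entity = eid, type = "cluster"
    )
  }
  if (nrow(partition$singletons)) {
    for (tp in partition$singletons$tip) {
      eid <- eid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        tip = tree$tip.label[tp], entity = eid, type = "singleton"
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$tip, tree$tip.label)), , drop = FALSE]
}

#' @export
print.gmyc_partition <- function(x, ...) {
  cat("GMYC partition:", length(x$clusters), "cluster(s),",
      nrow(x$singletons), "singleton(s),", x$n_entities, "entities\n")
  invisible(x)
}
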