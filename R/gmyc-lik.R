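# Mixed Yule-coalescent likelihood machinery.
#
# The tree's timeline runs from the root depth down to 0 (the tips). It is
# cut at every branching event and additionally (without an event) at every
# threshold. During a sub-interval the total branching rate is
#
#   b = lambda1 * n_div^p1 + lambda2 * sum_j [n_j (n_j - 1)]^p2
#
# where n_div counts lineages still in the diversification phase (segments
# deeper than their governing threshold) and n_j is the lineage count of
# cluster j. Within a cluster the count during a sub-interval is the
# forward lineage count after the next cluster event below it (so the
# stretch from the threshold down to the cluster's first event carries
# count 2, the pre-final stretch carries the tip count, and the fully
# coalesced tail below the cluster's last event carries count 1, i.e. rate
# 0) -- the attribution of the standard coalescent, in which the deepest
# merger involves two lineages. Singleton branch segments below their
# threshold contribute nothing (there is nothing left to coalesce). Every
# event-terminated sub-interval contributes log(b) - b*x (log(b) once per
# merged simultaneous event), event-free sub-intervals contribute -b*x.
#
# This interval convention reduces exactly to the single-process null model
# when the threshold is at depth 0 (every segment diversification), which is
# what guarantees a non-negative likelihood-ratio statistic.

# Precompute the likelihood's sufficient structure for one partition.
gmyc_interval_data <- function(partition, merge_tol = 1e-10) {
  tree <- partition$tree
  nd <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  internal <- nd[(n_tip + 1L):length(nd)]
  ev <- merge_event_depths(internal, tol = merge_tol)
  root_depth <- ev$depth[1L]

  thr <- c(vapply(partition$clusters, `[[`, numeric(1), "T"),
           partition$singletons$T)
  thr <- thr[thr > merge_tol & thr < root_depth - merge_tol]
  cuts <- sort(unique(c(ev$depth, thr)), decreasing = TRUE)
  # drop cut depths indistinguishable from an event depth
  keep <- c(TRUE, diff(cuts) < -merge_tol)
  cuts <- cuts[keep]
  bounds <- c(cuts, 0)

  parent_d <- nd[tree$edge[, 1L]]
  child_d <- nd[tree$edge[, 2L]]
  child_id <- tree$edge[, 2L]
  cluster_of_child <- partition$cluster_of[child_id]
  sing_T <- rep(NA_real_, n_tip)
  if (nrow(partition$singletons)) {
    sing_T[partition$singletons$tip] <- partition$singletons$T
  }
  cl_T <- vapply(partition$clusters, `[[`, numeric(1), "T")
  cl_events <- lapply(partition$clusters, `[[`, "events")

  n_sub <- length(bounds) - 1L
  x <- A <- evmult <- numeric(n_sub)
  pidx <- integer(0)
  pairs <- numeric(0)
  for (i in seq_len(n_sub)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    x[i] <- a - b
    m <- (a + b) / 2
    crossing <- parent_d > m & child_d < m
    cid <- cluster_of_child[crossing]
    ch <- child_id[crossing]
    # diversification segments: not governed by any cluster/singleton
    # threshold, or still deeper than it
    gov_T <- ifelse(!is.na(cid), cl_T[ifelse(is.na(cid), 1L, cid)],
                    ifelse(ch <= n_tip, sing_T[pmax(ch, 1L)], NA_real_))
    A[i] <- sum(is.na(gov_T) | m > gov_T)
    # active clusters: threshold above m; count = forward lineage count
    # after the next cluster event below m (1, i.e. rate 0, once the
    # cluster has fully coalesced)
    if (length(cl_T)) {
      act <- which(cl_T > m)
      for (j in act) {
        if (!any(cl_events[[j]] < m)) next  # fully coalesced: dead
        nj <- 2L + sum(cl_events[[j]] > m)
        pidx <- c(pidx, i)
        pairs <- c(pairs, nj * (nj - 1L))
      }
    }
    # terminating event (sub-interval ending at an event depth)
    if (b > 0) {
      hit <- which(abs(ev$depth - b) <= merge_tol)
      if (length(hit)) evmult[i] <- ev$mult[hit[1L]]
    }
  }
  # skip zero-length event-free sub-intervals
  keep <- x > merge_tol | evmult > 0
  remap <- cumsum(keep)
  dat <- list(
    x = x[keep], A = A[keep], evmult = evmult[keep],
    pidx = remap[pidx][keep[pidx]], pairs = pairs[keep[pidx]],
    n_sub = sum(keep)
  )
  dat$ev_sub <- which(dat$evmult > 0)
  has_pair <- rep(FALSE, dat$n_sub)
  has_pair[dat$pidx] <- TRUE
  dat$has_pair <- has_pair
  # separable: no sub-interval mixes diversification and coalescent terms
  dat$separable <- !any(dat$A > 0 & has_pair)
  dat
}

# Coalescent statistic per sub-interval: C_i(p2) = sum_j pairs_ij^p2
coal_stat <- function(dat, p2) {
  cs <- numeric(dat$n_sub)
  if (length(dat$pairs)) {
    v <- dat$pairs^p2
    agg <- rowsum(v, dat$pidx)
    cs[as.integer(rownames(agg))] <- agg[, 1L]
  }
  cs
}

# Core evaluator. Absent components may be passed as NA and are treated as 0.
gmyc_loglik_eval <- function(dat, lambda1, p1, lambda2, p2) {
  rdiv <- numeric(dat$n_sub)
  if (!is.na(lambda1) && any(dat$A > 0)) {
    pos <- dat$A > 0
    rdiv[pos] <- lambda1 * dat$A[pos]^p1
  }
  rcoal <- if (!is.na(lambda2) && length(dat$pairs)) {
    lambda2 * coal_stat(dat, p2)
  } else numeric(dat$n_sub)
  b <- rdiv + rcoal
  ev <- dat$ev_sub
  if (any(b[ev] <= 0)) return(-Inf)
  sum(dat$evmult[ev] * log(b[ev])) - sum(b * dat$x)
}

#' Log-likelihood of the single-process null branching model
#'
#' The null model applies one rate law `b_i = lambda * n_i^p` to every
#' inter-event interval of the branching schedule; each event-terminated
#' interval contributes `log(b_i) - b_i * x_i` and the event-free terminal
#' interval contributes only its survival term `-b_i * x_i`.
#'
#' @param schedule a [branching_schedule()].
#' @param lambda branching-rate scale (> 0), per branch-length unit.
#' @param p rate exponent (dimensionless).
#' @return the log-likelihood.
#' @export
loglik_null <- function(schedule, lambda, p) {
  stopifnot(inherits(schedule, "branching_schedule"))
  if (!is.numeric(lambda) || lambda <= 0) {
    stop("lambda must be positive", call. = FALSE)
  }
  iv <- schedule$intervals
  b <- lambda * iv$n^p
  sum(iv$mult * log(b)) - sum(b * iv$x)
}

#' Log-likelihood of the mixed Yule-coalescent model for a partition
#'
#' Evaluates the threshold model under the interval convention documented in
#' the package vignette: the timeline is additionally cut (without an event)
#' at each threshold; during a sub-interval the rate is
#' `lambda1 * n_div^p1 + lambda2 * sum_j [n_j(n_j-1)]^p2`; singletons and
#' one-lineage clusters contribute zero to the coalescent term.
#'
#' @param partition a `gmyc_partition` (see [classify_nodes()]).
#' @param params list with `lambda1`, `p1`, `lambda2`, `p2`. A component
#'   irrelevant to the partition (e.g. `lambda2` when there is no cluster)
#'   may be `NA`.
#' @return the log-likelihood; `-Inf` if an event-terminated interval has
#'   zero rate (an inconsistent assignment/parameter combination).
#' @export
loglik_gmyc <- function(partition, params) {
  stopifnot(inherits(partition, "gmyc_partition"))
  dat <- gmyc_interval_data(partition)
  if (!is.na(params$lambda1) && params$lambda1 <= 0 && any(dat$A > 0)) {
    stop("lambda1 must be positive", call. = FALSE)
  }
  gmyc_loglik_eval(dat, params$lambda1, params$p1, params$lambda2, params$p2)
}
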