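# Independent brute-force oracle for the single-threshold mixed model with
# both exponents fixed at 1. Everything is recomputed from first principles
# (ape node heights, direct edge-crossing counts, dense lambda grids with
# one refinement pass); only the documented threshold-candidate rule (three
# points per inter-event gap plus the extremes) is shared with the package,
# since the threshold discretization is part of the model definition.

oracle_loglik_T <- function(tree, T, lam_grid) {
  n <- length(tree$tip.label)
  h <- ape::node.depth.edgelength(tree)
  depth <- max(h[seq_len(n)])
  d <- depth - h
  d[seq_len(n)] <- 0
  internal <- d[(n + 1):length(d)]

  par_d <- d[tree$edge[, 1]]
  ch_d <- d[tree$edge[, 2]]
  ch <- tree$edge[, 2]

  # clusters: internal nodes below T whose parent is above T (or the root)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  is_int <- (n + 1):(n + tree$Nnode)
  par_above <- vapply(is_int, function(v) {
    parent[v] == 0 || d[parent[v]] > T
  }, logical(1))
  cl_roots <- is_int[d[is_int] < T & par_above]
  cl_members <- lapply(cl_roots, function(r) {
    nodes <- r
    frontier <- r
    while (length(frontier)) {
      kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
      nodes <- c(nodes, kids)
      frontier <- kids[kids > n]
    }
    nodes
  })
  cl_events <- lapply(cl_members, function(m) d[m[m > n]])

  bounds <- sort(unique(c(internal, if (T < max(internal)) T)),
                 decreasing = TRUE)
  bounds <- c(bounds, 0)
  n_sub <- length(bounds) - 1L

  div_ev_A <- c(); coal_ev_C <- c()
  SA <- 0; SC <- 0
  for (i in seq_len(n_sub)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    m <- (a + b) / 2
    x <- a - b
    A <- if (m > T) sum(par_d > m & ch_d < m) else 0L
    C <- 0
    if (m < T) {
      for (j in seq_along(cl_roots)) {
        ev <- cl_events[[j]]
        if (!any(ev < m)) next
        nj <- 2 + sum(ev > m)
        C <- C + nj * (nj - 1)
      }
    }
    SA <- SA + A * x
    SC <- SC + C * x
    if (b > 0 && any(abs(internal - b) < 1e-12)) {
      k <- sum(abs(internal - b) < 1e-12)
      if (b > T) div_ev_A <- c(div_ev_A, rep(A, k))
      else coal_ev_C <- c(coal_ev_C, rep(C, k))
    }
  }
  part_max <- function(ev_counts, S, grid) {
    if (!length(ev_counts)) return(-min(grid) * S)
    if (any(ev_counts == 0)) return(-Inf)
    vals <- length(ev_counts) * log(grid) + sum(log(ev_counts)) - grid * S
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    fine <- exp(seq(log(lo), log(hi), length.out = 200))
    max(length(ev_counts) * log(fine) + sum(log(ev_counts)) - fine * S)
  }
  part_max(div_ev_A, SA, lam_grid) + part_max(coal_ev_C, SC, lam_grid)
}

# Maximize over the candidate thresholds and a dense log-spaced lambda grid.
gmyc_grid_oracle <- function(tree) {
  n <- length(tree$tip.label)
  h <- ape::node.depth.edgelength(tree)
  depth <- max(h[seq_len(n)])
  d <- sort(unique(depth - h[(n + 1):length(h)]), decreasing = TRUE)
  cands <- d[1] * 1.05
  if (length(d) > 1) {
    for (i in seq_len(length(d) - 1)) {
      gap <- d[i] - d[i + 1]
      cands <- c(cands, d[i + 1] + c(0.98, 0.5, 0.02) * gap)
    }
  }
  cands <- sort(unique(c(cands, 0)), decreasing = TRUE)
  grid <- exp(seq(log(1e-8), log(1e6), length.out = 200))
  lls <- vapply(cands, function(T) oracle_loglik_T(tree, T, grid),
                numeric(1))
  list(loglik = max(lls), T = cands[which.max(lls)], scan = lls,
       candidates = cands)
}
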