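# Maximum-likelihood fitting of the null and mixed Yule-coalescent models.
#
# The single-threshold likelihood separates into a diversification part and
# a coalescent part (no sub-interval mixes the two processes), and within
# each part the rate scale lambda has a closed form given the exponent p, so
# each part is maximized by a 1-D profile likelihood over p (deterministic
# pre-grid + bounded golden-section refinement). Heterogeneous-threshold
# models can mix processes within a sub-interval; those are fitted by a
# bounded quasi-Newton search from five deterministic starting points.

default_lambda_bounds <- c(1e-8, 1e6)
default_p_bounds <- c(-3, 5)

clip <- function(v, b) min(max(v, b[1L]), b[2L])

# Profile-likelihood fit of b = lambda * n^p on intervals (x, n) with event
# weights w (merged multiplicities; 0 for event-free intervals).
fit_powerlaw_profile <- function(x, n, w, fix_p = NULL,
                                 p_bounds = default_p_bounds,
                                 lambda_bounds = default_lambda_bounds) {
  E <- sum(w)
  if (E == 0) {
    p_hat <- if (!is.null(fix_p)) fix_p else 1
    lam <- lambda_bounds[1L]
    return(list(lambda = lam, p = p_hat,
                loglik = -lam * sum(n^p_hat * x),
                boundary = TRUE, n_events = 0L))
  }
  cw <- sum(w * log(n))
  prof <- function(p) {
    S <- sum(n^p * x)
    lam <- clip(E / S, lambda_bounds)
    E * log(lam) + p * cw - lam * S
  }
  if (!is.null(fix_p)) {
    p_hat <- fix_p
  } else {
    grid <- seq(p_bounds[1L], p_bounds[2L], length.out = 33L)
    vals <- vapply(grid, prof, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    p_hat <- if (lo == hi) lo else
      stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
    # keep the better of grid point and refined point
    if (prof(grid[i]) > prof(p_hat)) p_hat <- grid[i]
  }
  S <- sum(n^p_hat * x)
  lam <- clip(E / S, lambda_bounds)
  list(lambda = lam, p = p_hat, loglik = prof(p_hat),
       boundary = lam <= lambda_bounds[1L] * (1 + 1e-9) ||
         lam >= lambda_bounds[2L] * (1 - 1e-9) ||
         (is.null(fix_p) && min(abs(p_hat - p_bounds)) < 1e-6),
       n_events = E)
}

# Profile-likelihood fit of the coalescent part of an interval structure:
# b = lambda2 * C_i(p2), C_i(p2) = sum_j pairs_ij^p2.
fit_coal_profile <- function(dat, fix_p = NULL,
                             p_bounds = default_p_bounds,
                             lambda_bounds = default_lambda_bounds) {
  ev <- dat$ev_sub[dat$has_pair[dat$ev_sub]]
  E <- sum(dat$evmult[ev])
  if (E == 0) {
    p_hat <- if (!is.null(fix_p)) fix_p else 1
    lam <- lambda_bounds[1L]
    Sx <- sum(coal_stat(dat, p_hat) * dat$x)
    return(list(lambda = lam, p = p_hat, loglik = -lam * Sx,
                boundary = TRUE, n_events = 0L))
  }
  prof <- function(p) {
    cs <- coal_stat(dat, p)
    Sx <- sum(cs * dat$x)
    lam <- clip(E / Sx, lambda_bounds)
    sum(dat$evmult[ev] * log(lam * cs[ev])) - lam * Sx
  }
  if (!is.null(fix_p)) {
    p_hat <- fix_p
  } else {
    grid <- seq(p_bounds[1L], p_bounds[2L], length.out = 33L)
    vals <- vapply(grid, prof, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    p_hat <- if (lo == hi) lo else
      stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
    if (vals[i] > prof(p_hat)) p_hat <- grid[i]
  }
  cs <- coal_stat(dat, p_hat)
  Sx <- sum(cs * dat$x)
  lam <- clip(E / Sx, lambda_bounds)
  list(lambda = lam, p = p_hat, loglik = prof(p_hat),
       boundary = lam <= lambda_bounds[1L] * (1 + 1e-9) ||
         lam >= lambda_bounds[2L] * (1 - 1e-9) ||
         (is.null(fix_p) && min(abs(p_hat - p_bounds)) < 1e-6),
       n_events = E)
}

# Bounded multi-start search for interval structures that mix the two
# processes within a sub-interval (heterogeneous thresholds).
fit_mixed <- function(dat, fix_p = NULL,
                      p_bounds = default_p_bounds,
                      lambda_bounds = default_lambda_bounds) {
  has_div <- any(dat$A > 0)
  has_coal <- length(dat$pairs) > 0
  # closed-form p = 1 seeds
  Ediv <- sum(dat$evmult[dat$ev_sub][dat$A[dat$ev_sub] > 0])
  Ecoal <- sum(dat$evmult[dat$ev_sub][dat$has_pair[dat$ev_sub]])
  Sdiv <- sum(dat$A * dat$x)
  Scoal <- sum(coal_stat(dat, 1) * dat$x)
  l1_0 <- clip(if (Sdiv > 0) max(Ediv, 0.5) / Sdiv else 1, lambda_bounds)
  l2_0 <- clip(if (Scoal > 0) max(Ecoal, 0.5) / Scoal else 1, lambda_bounds)

  free_p <- is.null(fix_p)
  p1_fix <- if (free_p) NA_real_ else fix_p[1L]
  p2_fix <- if (free_p) NA_real_ else fix_p[2L]

  unpack <- function(th) {
    i <- 0L
    l1 <- NA_real_; p1 <- p1_fix; l2 <- NA_real_; p2 <- p2_fix
    if (has_div) {
      l1 <- exp(th[i + 1L]); i <- i + 1L
      if (free_p) { p1 <- th[i + 1L]; i <- i + 1L }
    }
    if (has_coal) {
      l2 <- exp(th[i + 1L]); i <- i + 1L
      if (free_p) { p2 <- th[i + 1L]; i <- i + 1L }
    }
    list(l1 = l1, p1 = if (is.na(p1)) 1 else p1,
         l2 = l2, p2 = if (is.na(p2)) 1 else p2)
  }
  neg <- function(th) {
    q <- unpack(th)
    ll <- gmyc_loglik_eval(dat, q$l1, q$p1, q$l2, q$p2)
    if (!is.finite(ll)) 1e10 else -ll
  }
  mk_start <- function(m1, p1, m2, p2) {
    th <- c()
    if (has_div) th <- c(th, log(clip(l1_0 * m1, lambda_bounds)),
                         if (free_p) p1)
    if (has_coal) th <- c(th, log(clip(l2_0 * m2, lambda_bounds)),
                          if (free_p) p2)
    th
  }
  starts <- list(mk_start(1, 1, 1, 1), mk_start(1, 0, 1, 0),
                 mk_start(1, 2, 1, 2), mk_start(0.2, 1, 5, 1),
                 mk_start(5, 1, 0.2, 1))
  lb <- ub <- c()
  if (has_div) { lb <- c(lb, log(lambda_bounds[1L]), if (free_p) p_bounds[1L])
                 ub <- c(ub, log(lambda_bounds[2L]), if (free_p) p_bounds[2L]) }
  if (has_coal) { lb <- c(lb, log(lambda_bounds[1L]), if (free_p) p_bounds[1L])
                  ub <- c(ub, log(lambda_bounds[2L]), if (free_p) p_bounds[2L]) }
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, neg, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(factr = 1e4, maxit = 400L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixed-model optimization failed", call. = FALSE)
  q <- unpack(best$par)
  at_bound <- any(abs(best$par - lb) < 1e-6) || any(abs(best$par - ub) < 1e-6)
  list(params = list(lambda1 = q$l1, p1 = if (has_div) q$p1 else NA_real_,
                     lambda2 = q$l2, p2 = if (has_coal) q$p2 else NA_real_),
       loglik = -best$value, boundary = at_bound, converged = converged)
}

# Fit model parameters for a given partition (any threshold structure).
fit_partition <- function(partition, fix_p = NULL) {
  dat <- gmyc_interval_data(partition)
  bad <- dat$ev_sub[dat$A[dat$ev_sub] == 0 & !dat$has_pair[dat$ev_sub]]
  if (length(bad)) {
    stop("zero branching rate on an event-terminated interval: ",
         "assignment inconsistent with the tree", call. = FALSE)
  }
  if (dat$separable) {
    idx <- dat$A > 0
    has_div <- any(idx)
    has_coal <- length(dat$pairs) > 0
    ll <- 0
    l1 <- p1 <- l2 <- p2 <- NA_real_
    boundary <- FALSE
    if (has_div) {
      f <- fit_powerlaw_profile(dat$x[idx], dat$A[idx], dat$evmult[idx],
                                fix_p = if (!is.null(fix_p)) fix_p[1L])
      l1 <- f$lambda; p1 <- f$p; ll <- ll + f$loglik
      boundary <- boundary || f$boundary
    }
    if (has_coal) {
      f <- fit_coal_profile(dat, fix_p = if (!is.null(fix_p)) fix_p[2L])
      l2 <- f$lambda; p2 <- f$p; ll <- ll + f$loglik
      boundary <- boundary || f$boundary
    }
    list(params = list(lambda1 = l1, p1 = p1, lambda2 = l2, p2 = p2),
         loglik = ll, boundary = boundary, converged = TRUE)
  } else {
    fit_mixed(dat, fix_p = fix_p)
  }
}

#' Fit the single-process null branching model
#'
#' Maximum-likelihood estimation of `(lambda, p)` for the uniform rate law
#' `b_i = lambda * n_i^p` over the branching schedule, by profile likelihood
#' over `p` (with `lambda` in closed form given `p`). With `fix_p = 1` the
#' estimator reduces to the classic Yule form
#' `lambda = (number of scored events) / sum(n_i * x_i)`.
#'
#' @param schedule a [branching_schedule()].
#' @param fix_p optional fixed value for the exponent `p`.
#' @return a list of class `null_fit`: `lambda`, `p`, `loglik`, `boundary`.
#' @export
fit_null <- function(schedule, fix_p = NULL) {
  stopifnot(inherits(schedule, "branching_schedule"))
  iv <- schedule$intervals
  if (sum(iv$mult) == 0) {
    stop("degenerate schedule: no event-terminated interval", call. = FALSE)
  }
  f <- fit_powerlaw_profile(iv$x, iv$n, iv$mult, fix_p = fix_p)
  structure(list(lambda = f$lambda, p = f$p, loglik = f$loglik,
                 boundary = f$boundary), class = "null_fit")
}

#' Fit the mixed Yule-coalescent model at a fixed threshold
#'
#' @param tree an `ultratree`.
#' @param T threshold depth (see [classify_nodes()]).
#' @param fix_p optional pair `c(p1, p2)` of fixed exponents; `c(1, 1)`
#'   gives the pure Yule / neutral-coalescent rates used by the closed-form
#'   cross-checks.
#' @return list with `partition`, `params` (`lambda1`, `p1`, `lambda2`,
#'   `p2`; `NA` for a process absent from the partition), `loglik`,
#'   `boundary` and `converged` flags.
#' @export
fit_at_threshold <- function(tree, T, fix_p = NULL) {
  tree <- if (inherits(tree, "ultratree")) tree else as_ultrametric(tree)
  part <- classify_nodes(tree, T)
  out <- fit_partition(part, fix_p = fix_p)
  out$partition <- part
  out$T <- T
  out
}

#' Likelihood-ratio test of the threshold model against the null
#'
#' `LR = 2 * (L1 - L0)`, referred to a chi-square distribution with `df`
#' degrees of freedom (3 by the conventional parameter count of the
#' threshold model). A negative difference is floored at zero with a
#' warning.
#'
#' @param L0 null-model log-likelihood.
#' @param L1 threshold-model log-likelihood.
#' @param df degrees of freedom of the reference chi-square (default 3).
#' @return list with `LR`, `p_value` and `df`.
#' @export
lr_test <- function(L0, L1, df = 3) {
  LR <- 2 * (L1 - L0)
  if (LR < 0) {
    warning("L1 < L0: likelihood ratio floored at 0")
    LR <- 0
  }
  list(LR = LR, p_value = stats::pchisq(LR, df = df, lower.tail = FALSE),
       df = df)
}

#' Entity-count confidence set from a threshold scan
#'
#' The confidence set contains every scanned candidate whose log-likelihood
#' is within `delta` (default 2) units of the maximum; the confidence
#' interval on the entity count is the range of `N` over that set.
#'
#' @param scan data.frame with columns `loglik` and `N` (one row per
#'   evaluated candidate).
#' @param delta log-likelihood radius of the confidence set.
#' @return integer vector `c(N_min, N_max)`.
#' @export
entity_confidence <- function(scan, delta = 2) {
  if (!nrow(scan)) stop("empty scan", call. = FALSE)
  keep <- scan$loglik >= max(scan$loglik) - delta
  range(scan$N[keep])
}

# Candidate threshold depths: one above the root, three points per gap
# between consecutive distinct event depths (near both ends and the
# middle -- within a gap the profile log-likelihood is linear in T at fixed
# parameters, hence convex after profiling, so its supremum sits at a gap
# endpoint and midpoints alone can miss it by several units), and 0.
threshold_candidates <- function(event_depths, fracs = c(0.98, 0.5, 0.02)) {
  d <- event_depths
  cands <- d[1L] * 1.05
  if (length(d) > 1L) {
    for (i in seq_len(length(d) - 1L)) {
      cands <- c(cands, d[i + 1L] + fracs * (d[i] - d[i + 1L]))
    }
  }
  sort(unique(c(cands, 0)), decreasing = TRUE)
}

#' Single-threshold GMYC fit
#'
#' Scans candidate thresholds: one above the root (every tip in one
#' cluster); three per gap between consecutive distinct branching-event
#' depths (near the deep end, the middle and the shallow end -- the
#' within-gap likelihood peaks at a gap boundary, so end-of-gap candidates
#' are required to attain the optimum); and depth 0 (every tip a singleton,
#' which reduces the model exactly to the fitted null and so guarantees a
#' non-negative likelihood ratio). At each candidate the rate parameters
#' are fitted by maximum likelihood; the reported threshold is the best
#' candidate (ties broken deepest first).
#'
#' @param tree an `ultratree` with at least 3 tips.
#' @param fix_p optional pair `c(p1, p2)` fixing both exponents (the null
#'   model is then fitted with `p` fixed at `fix_p[1]`).
#' @return an object of class `gmyc_fit`: `model`, `threshold`, `params`,
#'   `partition`, `entities` (see [entity_table()]), `N`, `ci`, `L0`,
#'   `loglik`, `LR`, `p_value`, `scan`, `null`, `boundary`, `converged`.
#' @export
fit_single_threshold <- function(tree, fix_p = NULL) {
  tree <- if (inherits(tree, "ultratree")) tree else as_ultrametric(tree)
  if (length(tree$tip.label) < 3L) {
    stop("single-threshold fit requires at least 3 tips", call. = FALSE)
  }
  sched <- branching_schedule(tree)
  null <- fit_null(sched, fix_p = if (!is.null(fix_p)) fix_p[1L])
  candidates <- threshold_candidates(sched$events$depth)

  fits <- vector("list", length(candidates))
  scan <- data.frame(T = candidates, loglik = NA_real_, N = NA_integer_,
                     clusters = NA_integer_, singletons = NA_integer_)
  for (i in seq_along(candidates)) {
    f <- fit_at_threshold(tree, candidates[i], fix_p = fix_p)
    fits[[i]] <- f
    scan$loglik[i] <- f$loglik
    scan$N[i] <- f$partition$n_entities
    scan$clusters[i] <- length(f$partition$clusters)
    scan$singletons[i] <- nrow(f$partition$singletons)
  }
  best_i <- which.max(scan$loglik)  # candidates ordered deepest first
  best <- fits[[best_i]]
  lr <- lr_test(null$loglik, best$loglik)
  structure(list(
    model = "single",
    threshold = best$T,
    params = best$params,
    partition = best$partition,
    entities = entity_table(best$partition),
    N = best$partition$n_entities,
    ci = entity_confidence(scan),
    L0 = null$loglik,
    loglik = best$loglik,
    LR = lr$LR, p_value = lr$p_value, df = lr$df,
    scan = scan,
    null = null,
    boundary = best$boundary,
    converged = best$converged,
    fix_p = fix_p
  ), class = "gmyc_fit")
}

#' Multiple-threshold GMYC fit
#'
#' Greedy stepwise refinement seeded at the single-threshold optimum: at
#' each iteration, for every current cluster, moving its local threshold one
#' branching event deeper (bounded by the cluster's stem parent) or
#' shallower (re-clustering the cluster's subtree at the new local
#' threshold) is proposed; all proposals are refitted and the best strictly
#' improving one is accepted. The search stops at a local optimum or after
#' `max_iter` accepted moves, so the multiple-threshold likelihood is never
#' below the single-threshold one. Clusters are visited deepest stem first
#' and ties between equally good proposals are broken in that order.
#'
#' @param tree an `ultratree` with at least 3 tips.
#' @param max_iter maximum number of accepted moves.
#' @param fix_p optional pair `c(p1, p2)` of fixed exponents.
#' @param single an existing [fit_single_threshold()] result to seed from
#'   (refitted if `NULL`).
#' @return a `gmyc_fit` with `model = "multiple"`, `threshold` a vector of
#'   the distinct local thresholds in use, `iterations` the number of
#'   accepted moves and `max_iter_reached` a flag. The confidence interval
#'   is taken over every configuration evaluated during the search.
#' @export
fit_multiple_threshold <- function(tree, max_iter = 20L, fix_p = NULL,
                                   single = NULL) {
  tree <- if (inherits(tree, "ultratree")) tree else as_ultrametric(tree)
  if (is.null(single)) single <- fit_single_threshold(tree, fix_p = fix_p)
  nd <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  sched <- branching_schedule(tree)
  grid <- threshold_candidates(sched$events$depth)
  grid <- grid[grid < sched$depth]  # local thresholds live inside the tree

  part <- single$partition
  cur <- fit_partition(part, fix_p = fix_p)
  evaluated <- data.frame(loglik = cur$loglik, N = part$n_entities)

  iter <- 0L
  repeat {
    if (!length(part$clusters)) break
    ord <- order(vapply(part$clusters, function(cl) nd[cl$root],
                        numeric(1)), decreasing = TRUE)
    proposals <- list()
    for (ci in ord) {
      cl <- part$clusters[[ci]]
      cap <- if (cl$root == n_tip + 1L) Inf else nd[parent[cl$root]]
      deeper <- grid[grid > cl$T & grid < cap]
      shallower <- grid[grid < cl$T]
      for (g in c(if (length(deeper)) min(deeper),
                  if (length(shallower)) max(shallower))) {
        proposals[[length(proposals) + 1L]] <- list(cluster = ci, T_new = g)
      }
    }
    if (!length(proposals)) break
    best_prop <- NULL
    for (pr in proposals) {
      cl <- part$clusters[[pr$cluster]]
      if (pr$T_new > nd[cl$root]) {
        new_clusters <- lapply(part$clusters, function(z)
          list(root = z$root, T = z$T))
        new_clusters[[pr$cluster]]$T <- pr$T_new
        new_sing <- part$singletons
      } else {
        rec <- recluster_subtree(tree, cl$root, pr$T_new)
        new_clusters <- c(
          lapply(part$clusters[-pr$cluster], function(z)
            list(root = z$root, T = z$T)),
          rec$clusters)
        new_sing <- rbind(part$singletons, rec$singletons)
      }
      cand_part <- build_partition(tree, new_clusters, new_sing)
      fit <- tryCatch(fit_partition(cand_part, fix_p = fix_p),
                      error = function(e) NULL)
      if (is.null(fit)) next
      evaluated <- rbind(evaluated,
                         data.frame(loglik = fit$loglik,
                                    N = cand_part$n_entities))
      if (fit$loglik > cur$loglik + 1e-8 &&
          (is.null(best_prop) || fit$loglik > best_prop$loglik + 1e-12)) {
        best_prop <- list(part = cand_part, fit = fit,
                          loglik = fit$loglik)
      }
    }
    if (is.null(best_prop)) break
    part <- best_prop$part
    cur <- best_prop$fit
    iter <- iter + 1L
    if (iter >= max_iter) break
  }

  thresholds <- sort(unique(c(
    vapply(part$clusters, `[[`, numeric(1), "T"), part$singletons$T)),
    decreasing = TRUE)
  lr <- lr_test(single$L0, cur$loglik)
  structure(list(
    model = "multiple",
    threshold = thresholds,
    params = cur$params,
    partition = part,
    entities = entity_table(part),
    N = part$n_entities,
    ci = entity_confidence(evaluated),
    L0 = single$L0,
    loglik = cur$loglik,
    LR = lr$LR, p_value = lr$p_value, df = lr$df,
    scan = evaluated,
    null = single$null,
    single = single,
    iterations = iter,
    max_iter_reached = iter >= max_iter,
    boundary = cur$boundary,
    converged = cur$converged,
    fix_p = fix_p
  ), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC", x$model, "threshold fit\n")
  if (x$model == "single") {
    cat(sprintf("  T (depth from tips): %.6g\n", x$threshold))
  } else {
    cat(sprintf("  local thresholds: %s\n",
                paste(signif(x$threshold, 4), collapse = ", ")))
    cat(sprintf("  accepted moves: %d\n", x$iterations))
  }
  cat(sprintf("  entities N: %d (clusters %d, singletons %d), CI %d-%d\n",
              x$N, length(x$partition$clusters),
              nrow(x$partition$singletons), x$ci[1L], x$ci[2L]))
  cat(sprintf("  L0 = %.4f, L = %.4f, LR = %.4f, p = %.3g (chi-sq, %d df)\n",
              x$L0, x$loglik, x$LR, x$p_value, x$df))
  invisible(x)
}

#' Table-style summary of a GMYC fit
#'
#' @param fit a `gmyc_fit`.
#' @return a list with the headline quantities (`model`, `T`, `N`, `CI`,
#'   `L0`, `L_gmyc`, `LR`, `p_value`), suitable for JSON serialization.
#' @export
gmyc_summary <- function(fit) {
  stopifnot(inherits(fit, "gmyc_fit"))
  list(
    model = fit$model,
    T = if (fit$model == "single") fit$threshold else NA_real_,
    thresholds = fit$threshold,
    N = fit$N,
    CI = list(N_min = fit$ci[1L], N_max = fit$ci[2L]),
    L0 = fit$L0,
    L_gmyc = fit$loglik,
    LR = fit$LR,
    p_value = fit$p_value
  )
}
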