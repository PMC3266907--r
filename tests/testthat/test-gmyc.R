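toy3 <- function() parse_newick("((A:1,B:1):1,C:2);")

test_that("classify_nodes partitions tips as the threshold moves", {
  tr <- toy3()
  p <- classify_nodes(tr, 1.5)
  expect_equal(length(p$clusters), 1L)
  expect_equal(sort(tr$tip.label[p$clusters[[1]]$tips]), c("A", "B"))
  expect_equal(tr$tip.label[p$singletons$tip], "C")
  expect_equal(p$n_entities, 2L)

  expect_equal(classify_nodes(tr, 0.5)$n_entities, 3L)   # all singletons
  expect_equal(classify_nodes(tr, 2.5)$n_entities, 1L)   # one big cluster
  expect_equal(classify_nodes(tr, 0)$n_entities, 3L)
  expect_error(classify_nodes(tr, -1), "non-negative")
})

test_that("null log-likelihood and closed-form fit match hand computation", {
  s <- branching_schedule(toy3())
  expect_equal(loglik_null(s, 0.2, 1), log(0.4) - 1, tolerance = 1e-9)
  expect_equal(loglik_null(s, 0.2, 1), -1.9163, tolerance = 1e-4)
  expect_equal(loglik_null(s, 1, 0), -2, tolerance = 1e-12)
  expect_error(loglik_null(s, 0, 1), "positive")
  # lambda -> 0 diverges
  expect_lt(loglik_null(s, 1e-12, 1), -20)

  f <- fit_null(s, fix_p = 1)
  expect_equal(f$lambda, 0.2, tolerance = 1e-12)
  expect_equal(f$loglik, log(0.4) - 1, tolerance = 1e-9)

  s2 <- branching_schedule(parse_newick("(A:1,B:1);"))
  expect_error(fit_null(s2), "no event-terminated")
})

test_that("null fit recovers the Yule rate on simulated trees", {
  ok <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    tr <- ape::rphylo(100, birth = 1, death = 0)
    f <- fit_null(branching_schedule(tr), fix_p = 1)
    if (abs(f$lambda - 1) < 0.2) ok <- ok + 1L
  }
  expect_gte(ok, 7L)
})

test_that("mixed-model log-likelihood matches the worked 3-tip example", {
  p <- classify_nodes(toy3(), 1.5)
  ll <- loglik_gmyc(p, list(lambda1 = 1, p1 = 1, lambda2 = 1, p2 = 1))
  expect_equal(ll, log(2) - 2, tolerance = 1e-9)
})

test_that("an all-diversification assignment reduces to the null model", {
  sim <- simulate_gmyc_tree(4, 3, seed = 2)
  s <- branching_schedule(sim$tree)
  for (pars in list(c(0.5, 1), c(2, 0.3))) {
    p0 <- classify_nodes(sim$tree, 0)
    ll <- loglik_gmyc(p0, list(lambda1 = pars[1], p1 = pars[2],
                               lambda2 = NA, p2 = NA))
    expect_equal(ll, loglik_null(s, pars[1], pars[2]), tolerance = 1e-9)
  }
})

test_that("lambda2 -> 0 with a coalescent event present diverges", {
  p <- classify_nodes(toy3(), 1.5)
  ll <- loglik_gmyc(p, list(lambda1 = 1, p1 = 1, lambda2 = 1e-300, p2 = 1))
  expect_lt(ll, -600)
})

test_that("fit_at_threshold reproduces the boundary maximization example", {
  f <- fit_at_threshold(toy3(), 1.5, fix_p = c(1, 1))
  expect_equal(f$loglik, log(2) - 1, tolerance = 1e-6)
  expect_equal(f$params$lambda2, 1, tolerance = 1e-6)
  expect_lte(f$params$lambda1, 1e-7)  # no diversification event below T
  expect_true(f$boundary)

  # determinism
  f2 <- fit_at_threshold(toy3(), 1.5, fix_p = c(1, 1))
  expect_identical(f, f2)
})

test_that("threshold fits are nested above the null on every tested tree", {
  for (seed in 1:8) {
    sim <- simulate_gmyc_tree(sample(2:8, 1), sample(2:5, 1), seed = seed)
    fit <- fit_single_threshold(sim$tree)
    expect_gte(fit$LR, 0)
    expect_gte(fit$loglik, fit$null$loglik - 1e-9)
  }
})

test_that("the likelihood-ratio test matches the published arithmetic", {
  t1 <- lr_test(1649.088, 1671.926)
  expect_equal(t1$LR, 45.676, tolerance = 1e-9)
  expect_equal(t1$LR, 45.67581, tolerance = 0.01 / 45.67581)
  expect_lt(t1$p_value, 0.001)

  t2 <- lr_test(1649.088, 1674.306)
  expect_equal(t2$LR, 50.43415, tolerance = 0.01 / 50.43415)
  expect_lt(t2$p_value, 0.001)

  expect_equal(lr_test(10, 10), list(LR = 0, p_value = 1, df = 3))
  expect_warning(t3 <- lr_test(10, 9), "floored")
  expect_equal(t3$LR, 0)
  # chi-square 3 df quantile: LR = 7.815 sits at p ~ 0.05
  expect_equal(lr_test(0, 7.815 / 2)$p_value, 0.05, tolerance = 1e-3)
})

test_that("entity confidence keeps candidates within 2 log-units", {
  scan <- data.frame(T = c(1, 2, 3), loglik = c(10, 9.5, 7.5),
                     N = c(5L, 4L, 8L))
  expect_equal(entity_confidence(scan), c(4L, 5L))
  expect_equal(entity_confidence(scan[1, , drop = FALSE]), c(5L, 5L))
  expect_error(entity_confidence(scan[0, ]), "empty")
})

test_that("single-threshold fit recovers deeply separated species", {
  sim <- simulate_gmyc_tree(10, 5, s = 10, seed = 42)
  fit <- fit_single_threshold(sim$tree)
  expect_equal(fit$N, 10L)
  expect_true(fit$ci[1] <= 10 && fit$ci[2] >= 10)
  # every true species maps to exactly one entity and vice versa
  tab <- table(sim$species[fit$entities$tip], fit$entities$entity)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_lt(fit$p_value, 0.05)
  # threshold sits between the coalescent and species depth scales
  nd <- node_depths(sim$tree)
  internal <- sort(nd[-(1:50)], decreasing = TRUE)
  expect_lt(fit$threshold, internal[9])
  expect_gt(fit$threshold, internal[10])
})

test_that("scan extremes give one entity above the root, all tips at zero", {
  sim <- simulate_gmyc_tree(4, 3, seed = 6)
  fit <- fit_single_threshold(sim$tree)
  sc <- fit$scan
  expect_equal(sc$N[1L], 1L)                 # deepest candidate: above root
  expect_equal(sc$N[nrow(sc)], 12L)          # T = 0: all singletons
  expect_equal(sc$loglik[nrow(sc)], fit$null$loglik, tolerance = 1e-6)
})

test_that("the scan optimum matches a brute-force grid on small trees", {
  # independent oracle: direct interval enumeration + dense parameter grid,
  # exponents fixed at 1
  for (seed in c(1, 2)) {
    sim <- simulate_gmyc_tree(3, 2, seed = seed)
    fit <- fit_single_threshold(sim$tree, fix_p = c(1, 1))
    oracle <- gmyc_grid_oracle(sim$tree)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-3)
  }
})

test_that("identical inputs give identical fits", {
  sim <- simulate_gmyc_tree(5, 3, seed = 4)
  f1 <- fit_single_threshold(sim$tree)
  f2 <- fit_single_threshold(sim$tree)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$threshold, f2$threshold)
  expect_identical(f1$params, f2$params)
})

test_that("multiple-threshold search never falls below the single fit", {
  sim <- simulate_gmyc_tree(6, 4, s = 10, seed = 9)
  single <- fit_single_threshold(sim$tree)
  multi <- fit_multiple_threshold(sim$tree, single = single)
  expect_gte(multi$loglik, single$loglik - 1e-9)
  expect_equal(multi$L0, single$L0)
  expect_gte(multi$LR, single$LR - 1e-9)
  expect_s3_class(multi, "gmyc_fit")
  expect_false(multi$max_iter_reached && multi$iterations == 0L)
})

test_that("heterogeneous coalescent depths reward a second threshold", {
  # two species groups whose within-species depths differ 8-fold: grafting
  # a deep-coalescence pair next to shallow species favours local thresholds
  txt <- paste0(
    "(((a1:0.004,a2:0.004):0.096,(b1:0.004,b2:0.004):0.096):0.1,",
    "((c1:0.032,c2:0.032):0.068,(d1:0.032,d2:0.032):0.068):0.1);")
  tr <- parse_newick(txt)
  single <- fit_single_threshold(tr)
  multi <- fit_multiple_threshold(tr, single = single)
  expect_gte(multi$loglik, single$loglik)
  if (multi$iterations > 0L) {
    expect_gt(multi$loglik, single$loglik)
    expect_gt(length(multi$threshold), 1L)
  }
})

test_that("at a multiple-threshold fixed point the single result is kept", {
  sim <- simulate_gmyc_tree(4, 4, s = 50, seed = 13)
  single <- fit_single_threshold(sim$tree)
  multi <- fit_multiple_threshold(sim$tree, single = single)
  expect_gte(multi$loglik, single$loglik - 1e-9)
  if (multi$iterations == 0L) {
    expect_equal(multi$N, single$N)
    expect_equal(multi$loglik, single$loglik, tolerance = 1e-8)
    expect_equal(sort(unique(multi$threshold)), single$threshold)
  }
})
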