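test_that("posterior draws require stochastic layers and a sane draw count", {
  fit <- smallFit()
  detModel <- fit$model
  detModel@config$dropout_p <- 0
  detModel@config$dropedge_p <- 0
  expect_error(posteriorDraws(detModel, fit$val, T = 5), "degenerate")
  expect_error(posteriorDraws(fit$model, fit$val, T = 1), "at least 2")
})

test_that("posterior draws are reproducible under a fixed seed", {
  fit <- smallFit()
  d1 <- posteriorDraws(fit$model, fit$val, T = 4, seed = 42)
  d2 <- posteriorDraws(fit$model, fit$val, T = 4, seed = 42)
  expect_identical(d1@draws, d2@draws)
  d3 <- posteriorDraws(fit$model, fit$val, T = 4, seed = 43)
  expect_false(identical(d1@draws, d3@draws))
  # every slice row-stochastic
  expect_true(all(abs(apply(d1@draws, c(1, 2), sum) - 1) < 1e-6))
})

test_that("draws collapse to determinism in the zero-stochasticity limit", {
  # dropout off; DropEdge has nothing to act on in an edgeless graph, so all
  # stochastic passes coincide
  fit <- smallFit()
  g <- fit$val
  grid <- data.frame(
    row = nodeCoords(g)[, 1], col = nodeCoords(g)[, 2], label = nodeLabels(g)
  )
  attr(grid, "classNames") <- classVocabulary(g)
  gEmpty <- assembleWSG(grid, nodeAttributes(g), matrix(integer(0), 0, 2))
  m2 <- fit$model
  m2@config$dropout_p <- 0
  dr <- posteriorDraws(m2, gEmpty, T = 3, seed = 1)
  expect_equal(dr@draws[1, , ], dr@draws[2, , ], tolerance = 1e-12)
  expect_equal(dr@draws[1, , ], dr@draws[3, , ], tolerance = 1e-12)
})

test_that("uncertainty scores match hand arithmetic", {
  # identical draws: zero variance, entropy of the single vector
  p <- c(0.7, 0.3)
  same <- array(rep(p, each = 3 * 1), c(3, 1, 2))
  sc <- uncertaintyScores(methods::new("PosteriorDraws", draws = same, seed = 1L))
  expect_equal(sc$variance, 0)
  expect_equal(sc$entropy, -sum(p * log(p)))

  # uniform mean over K = 8: maximum entropy log(8)
  u <- array(1 / 8, c(2, 1, 8))
  scU <- uncertaintyScores(methods::new("PosteriorDraws", draws = u, seed = 1L))
  expect_equal(scU$entropy, log(8))

  # three hand-written draws over K = 2
  d <- array(NA_real_, c(3, 1, 2))
  d[, 1, 1] <- c(0.9, 0.5, 0.7)
  d[, 1, 2] <- c(0.1, 0.5, 0.3)
  scH <- uncertaintyScores(methods::new("PosteriorDraws", draws = d, seed = 1L))
  expect_equal(scH$variance, mean(c(var(c(0.9, 0.5, 0.7)), var(c(0.1, 0.5, 0.3)))))
  expect_equal(scH$entropy, -(0.7 * log(0.7) + 0.3 * log(0.3)))
})

test_that("entropy respects its bounds on model draws", {
  fit <- smallFit()
  sc <- uncertaintyScores(posteriorDraws(fit$model, fit$val, T = 6, seed = 3))
  K <- length(classVocabulary(fit$val))
  expect_true(all(sc$entropy >= 0 & sc$entropy <= log(K)))
  expect_true(all(sc$variance >= 0))
})

test_that("interior nodes are less uncertain than boundary nodes", {
  fit <- smallFit()
  g <- fit$train
  sc <- uncertaintyScores(posteriorDraws(fit$model, g, T = 15, seed = 5))
  lab <- nodeLabels(g)
  e <- edgeList(g)
  boundary <- rep(FALSE, nodeCount(g))
  mixed <- lab[e[, 1]] != lab[e[, 2]]
  boundary[unique(c(e[mixed, 1], e[mixed, 2]))] <- TRUE
  expect_gte(sum(boundary), 20)
  expect_gte(sum(!boundary), 20)
  expect_lt(median(sc$entropy[!boundary]), median(sc$entropy[boundary]))
})

test_that("pruning and propagation follow the majority-vote contract", {
  # 5-node star: center pruned, four neighbors of class 2
  grid <- data.frame(
    row = c(1L, 0L, 2L, 1L, 1L), col = c(1L, 1L, 1L, 0L, 2L),
    label = c(1L, 2L, 2L, 2L, 2L)
  )
  attr(grid, "classNames") <- c("a", "b")
  edges <- cbind(rep(1L, 4), 2:5)
  g <- assembleWSG(grid, matrix(0, 5, 2), edges)
  scores <- list(entropy = c(1, 0, 0, 0, 0))
  refined <- pruneAndPropagate(g, nodeLabels(g), scores, pruneQuantile = 0.7)
  expect_equal(as.integer(refined), c(2L, 2L, 2L, 2L, 2L))
  expect_equal(attr(refined, "pruned"), c(TRUE, FALSE, FALSE, FALSE, FALSE))

  # constant entropy: strict quantile exceedance prunes nothing
  same <- pruneAndPropagate(g, nodeLabels(g), list(entropy = rep(0.5, 5)), 0.9)
  expect_equal(as.integer(same), nodeLabels(g))

  expect_error(pruneAndPropagate(g, nodeLabels(g), scores, 1.2), "\\(0, 1\\)")
})

test_that("unpruned nodes are never relabeled and stranded nodes fall back", {
  # two components: a triangle (labeled) and an isolated pruned node
  grid <- data.frame(
    row = c(0L, 0L, 1L, 5L), col = c(0L, 1L, 0L, 5L),
    label = c(1L, 1L, 2L, 2L)
  )
  attr(grid, "classNames") <- c("a", "b")
  g <- assembleWSG(grid, matrix(0, 4, 2), rbind(c(1, 2), c(1, 3), c(2, 3)))
  scores <- list(entropy = c(0, 0, 0.5, 1))
  expect_warning(
    refined <- pruneAndPropagate(g, nodeLabels(g), scores, pruneQuantile = 0.8),
    "no labeled neighbor"
  )
  expect_equal(as.integer(refined), c(1L, 1L, 2L, 2L)) # stranded keeps original
  # unpruned nodes untouched even under adversarial majorities
  scores2 <- list(entropy = c(0, 0, 1, 0))
  ref2 <- pruneAndPropagate(g, c(1L, 1L, 2L, 2L), scores2, pruneQuantile = 0.7)
  expect_equal(as.integer(ref2)[c(1, 2, 4)], c(1L, 1L, 2L))
  expect_equal(as.integer(ref2)[3], 1L) # pruned node adopts the majority
})

test_that("refinement under interior corruption recovers true labels", {
  set.seed(77)
  sl <- toySlide(seed = 61L, depth = 0.5, noiseSd = 1)
  g <- buildSlideGraph(sl, k = 8)
  truth <- nodeLabels(g)
  m <- nodeCount(g)
  e <- edgeList(g)
  boundary <- rep(FALSE, m)
  mixed <- truth[e[, 1]] != truth[e[, 2]]
  boundary[unique(c(e[mixed, 1], e[mixed, 2]))] <- TRUE
  interior <- which(!boundary)
  corrupt <- sample(interior, round(0.1 * m))
  noisy <- truth
  noisy[corrupt] <- ((truth[corrupt] + 1L) %% 8L) + 1L
  # oracle entropy: high exactly at corrupted nodes
  entropy <- runif(m, 0, 0.2)
  entropy[corrupt] <- runif(length(corrupt), 1.5, 2)
  refined <- suppressWarnings(
    pruneAndPropagate(g, noisy, list(entropy = entropy), pruneQuantile = 0.9)
  )
  expect_gt(
    weightedF1(as.integer(refined), truth, K = 8),
    weightedF1(noisy, truth, K = 8)
  )
})
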