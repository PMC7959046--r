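test_that("a linearly separable two-class slide is fitted to perfect training F1", {
  g <- separableGraph()
  cfg <- gatConfig(
    n_conv_layers = 2L, hidden_dim = 4L, attention_heads = 1L,
    dropedge_p = 0, dropout_p = 0, learning_rate = 5e-2,
    max_epochs = 40L, seed = 2L
  )
  fit <- fitNodeClassifier(list(g), list(g), cfg)
  expect_equal(max(fit@trainLog$valF1), 1.0)
  expect_equal(fit@selectedEpoch, which.max(fit@trainLog$valF1))
})

test_that("training is deterministic without stochastic layers", {
  g <- separableGraph()
  cfg <- gatConfig(
    n_conv_layers = 2L, hidden_dim = 4L, attention_heads = 1L,
    dropedge_p = 0, dropout_p = 0, learning_rate = 1e-2,
    max_epochs = 5L, seed = 3L
  )
  f1 <- fitNodeClassifier(list(g), list(g), cfg)
  f2 <- fitNodeClassifier(list(g), list(g), cfg)
  expect_identical(f1@trainLog$loss, f2@trainLog$loss)
})

test_that("predicted probabilities are normalized and reproducible", {
  fit <- smallFit()
  p <- predictProba(fit$model, fit$val)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predictProba(fit$model, fit$val))
})

test_that("isolated nodes use the defined empty-neighborhood aggregate", {
  fit <- smallFit()
  g <- fit$val
  grid <- data.frame(
    row = nodeCoords(g)[, 1], col = nodeCoords(g)[, 2],
    label = nodeLabels(g)
  )
  attr(grid, "classNames") <- classVocabulary(g)
  gEmpty <- assembleWSG(grid, nodeAttributes(g), matrix(integer(0), 0, 2))
  pAll <- predictProba(fit$model, gEmpty)
  # the zero-edge prediction of each node equals its singleton-graph prediction
  for (i in c(1L, 17L, 60L)) {
    gi <- data.frame(row = 0L, col = 0L, label = grid$label[i])
    attr(gi, "classNames") <- classVocabulary(g)
    g1 <- assembleWSG(gi, nodeAttributes(g)[i, , drop = FALSE], matrix(integer(0), 0, 2))
    expect_equal(unname(pAll[i, ]), unname(predictProba(fit$model, g1)[1, ]), tolerance = 1e-12)
  }
})

test_that("duplicated nodes with identical features and neighbors get identical rows", {
  fit <- smallFit()
  g <- fit$val
  grid <- data.frame(
    row = c(nodeCoords(g)[, 1], max(nodeCoords(g)[, 1]) + 5L),
    col = c(nodeCoords(g)[, 2], 0L),
    label = c(nodeLabels(g), nodeLabels(g)[1])
  )
  attr(grid, "classNames") <- classVocabulary(g)
  X <- rbind(nodeAttributes(g), nodeAttributes(g)[1, ])
  m <- nodeCount(g)
  e <- edgeList(g)
  # duplicate node m+1 copies node 1's neighborhood
  nb <- unique(c(e[e[, 1] == 1, 2], e[e[, 2] == 1, 1]))
  e2 <- rbind(e, cbind(nb, m + 1L))
  gDup <- assembleWSG(grid, X, e2)
  p <- predictProba(fit$model, gDup)
  expect_equal(p[1, ], p[m + 1L, ], tolerance = 1e-10)
})

test_that("predictions are permutation equivariant", {
  fit <- smallFit()
  g <- fit$val
  set.seed(9)
  perm <- sample(nodeCount(g))
  grid <- data.frame(
    row = nodeCoords(g)[perm, 1], col = nodeCoords(g)[perm, 2],
    label = nodeLabels(g)[perm]
  )
  attr(grid, "classNames") <- classVocabulary(g)
  e <- edgeList(g)
  inv <- order(perm) # original index -> new position
  ePerm <- cbind(inv[e[, 1]], inv[e[, 2]])
  gPerm <- assembleWSG(grid, nodeAttributes(g)[perm, ], ePerm)
  p0 <- predictProba(fit$model, g)
  p1 <- predictProba(fit$model, gPerm)
  expect_lt(max(abs(p1 - p0[perm, ])), 1e-5)
})

test_that("embeddings are deterministic and actually use graph context", {
  fit <- smallFit()
  g <- fit$val
  Z1 <- extractEmbeddings(fit$model, g)
  expect_identical(Z1, extractEmbeddings(fit$model, g))
  expect_equal(nrow(Z1), nodeCount(g))
  grid <- data.frame(
    row = nodeCoords(g)[, 1], col = nodeCoords(g)[, 2], label = nodeLabels(g)
  )
  attr(grid, "classNames") <- classVocabulary(g)
  gEmpty <- assembleWSG(grid, nodeAttributes(g), matrix(integer(0), 0, 2))
  Z0 <- extractEmbeddings(fit$model, gEmpty)
  expect_gt(max(abs(Z1 - Z0)), 1e-6)
})

test_that("contextualized embeddings separate classes better than raw features", {
  # representation quality on a slide the model was fitted to
  fit <- smallFit()
  g <- fit$train
  Z <- extractEmbeddings(fit$model, g)
  X <- nodeAttributes(g)
  sil <- function(M, lab) {
    D <- as.matrix(dist(M))
    s <- vapply(seq_len(nrow(M)), function(i) {
      a <- mean(D[i, lab == lab[i] & seq_len(nrow(M)) != i])
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(k) mean(D[i, lab == k]), 0))
      (b - a) / max(a, b)
    }, 0)
    mean(s, na.rm = TRUE)
  }
  lab <- nodeLabels(g)
  keep <- lab %in% which(tabulate(lab) >= 2)
  expect_gt(sil(Z[keep, ], lab[keep]), sil(X[keep, ], lab[keep]))
})

test_that("node metrics match hand-computed values", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  ev <- evaluateNodes(onehot, c(1, 2, 3, 1))
  expect_equal(ev$auroc, 1.0)
  expect_equal(ev$weightedF1, 1.0)

  unif <- matrix(0.5, 4, 2)
  expect_equal(suppressWarnings(macroAUROC(unif, c(1, 1, 2, 2))), 0.5)

  # fixed 6-node table, hand computation
  probs <- rbind(
    c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6),
    c(0.3, 0.7), c(0.2, 0.8), c(0.6, 0.4)
  )
  truth <- c(1, 1, 1, 2, 2, 2)
  # class-1 scores: pos {0.9,0.8,0.4} vs neg {0.3,0.2,0.6}: 8 of 9 pairs won
  expect_equal(aucFromScores(probs[, 1], truth == 1), 8 / 9)
  expect_equal(macroAUROC(probs, truth), 8 / 9)
  # predictions: 1,1,2,2,2,1 -> per-class: tp1=2 fp1=1 fn1=1; f1 = 2*2/(4+1+1)
  expect_equal(weightedF1(c(1, 1, 2, 2, 2, 1), truth), (3 * (2 / 3) + 3 * (2 / 3)) / 6)

  # per-slide averaging
  two <- evaluateNodes(list(onehot, onehot), list(c(1, 2, 3, 1), c(1, 2, 3, 1)))
  expect_equal(two$auroc, 1.0)
  expect_equal(nrow(two$perSlide), 2L)
})

test_that("rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  expect_equal(
    aucFromScores(s, y),
    as.numeric(suppressMessages(pROC::auc(y, s))),
    tolerance = 1e-12
  )
})

test_that("graphs with mismatched vocabulary or dimension are rejected", {
  fit <- smallFit()
  g <- fit$val
  grid <- data.frame(
    row = nodeCoords(g)[, 1], col = nodeCoords(g)[, 2], label = nodeLabels(g)
  )
  attr(grid, "classNames") <- classVocabulary(g)
  gBad <- assembleWSG(grid, nodeAttributes(g)[, 1:3], edgeList(g))
  expect_error(predictProba(fit$model, gBad), "dimension")
  expect_error(
    methods::new("WholeSlideGraph",
      slideId = "x", coords = nodeCoords(g), patchPx = 256L,
      adjacency = adjacencyMatrix(g), attributes = nodeAttributes(g),
      labels = rep(99L, nodeCount(g)), classNames = classVocabulary(g)
    ),
    "classNames"
  )
})
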