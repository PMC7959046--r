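test_that("lens projections satisfy their contracts", {
  set.seed(1)
  Z <- matrix(rnorm(60), 20, 3)
  expect_equal(computeLens(Z, "first_dims", d = 3), Z, ignore_attr = TRUE)

  lens <- computeLens(Z, "pca", d = 2)
  expect_gte(var(lens[, 1]), var(lens[, 2]))

  expect_error(computeLens(matrix(1, 10, 3), "pca"), "degenerate")
})

test_that("the PCA lens matches an independent eigendecomposition", {
  Z <- rbind(
    c(2.0, 0.5, 1.0), c(1.5, 1.0, 0.0), c(0.0, 0.2, 0.3),
    c(-1.0, -0.5, 0.7), c(-2.5, -1.2, -2.0)
  )
  lens <- computeLens(Z, "pca", d = 2)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Zc) / (nrow(Z) - 1))
  proj <- Zc %*% eig$vectors[, 1:2]
  # same up to per-component sign
  for (j in 1:2) {
    expect_true(
      isTRUE(all.equal(lens[, j], proj[, j], tolerance = 1e-9)) ||
        isTRUE(all.equal(lens[, j], -proj[, j], tolerance = 1e-9))
    )
  }
})

test_that("the cover reproduces the interval width formula", {
  lens <- matrix(seq(0, 1, length.out = 11), ncol = 1)
  cov <- buildCover(lens, nIntervals = 2, g = 0.5)
  bounds <- t(vapply(cov, function(s) s$bounds[1, ], numeric(2)))
  expect_equal(bounds[1, ], c(0, 2 / 3), tolerance = 1e-9)
  expect_equal(bounds[2, ], c(1 / 3, 1), tolerance = 1e-9)
  # interior membership: 0.5 belongs to both boxes
  in05 <- vapply(cov, function(s) 6L %in% s$members, TRUE) # lens[6] = 0.5
  expect_true(all(in05))

  # general width formula on a random 2-D lens
  set.seed(4)
  L2 <- matrix(runif(200), 100, 2)
  n <- 5; g <- 0.3
  cov2 <- buildCover(L2, n, g)
  for (ax in 1:2) {
    rng <- range(L2[, ax])
    width <- diff(rng) / (n - (n - 1) * g)
    widths <- unique(round(vapply(cov2, function(s) diff(s$bounds[ax, ]), 0), 12))
    expect_equal(widths, round(width, 12), tolerance = 1e-9)
  }
})

test_that("zero overlap gives disjoint halves and zero range collapses an axis", {
  lens <- matrix(seq(0, 1, length.out = 9), ncol = 1)
  cov <- buildCover(lens, 2, 0)
  expect_equal(cov[[1]]$bounds[1, ], c(0, 0.5))
  expect_equal(cov[[2]]$bounds[1, ], c(0.5, 1))
  expect_equal(intersect(cov[[1]]$members, cov[[2]]$members), 5L) # the boundary point

  flat <- cbind(seq(0, 1, length.out = 5), rep(2, 5))
  covF <- buildCover(flat, 3, 0.2)
  expect_true(all(vapply(covF, function(s) identical(s$bounds[2, ], c(2, 2)), TRUE)))
})

test_that("every point is covered for random lenses", {
  set.seed(12)
  for (rep in 1:5) {
    L <- matrix(rnorm(2 * sample(50:200, 1)), ncol = 2)
    cov <- buildCover(L, sample(2:8, 1), runif(1, 0, 0.6))
    covered <- sort(unique(unlist(lapply(cov, `[[`, "members"))))
    expect_identical(covered, seq_len(nrow(L)))
  }
})

test_that("cover-set clustering follows the linkage gap heuristic", {
  expect_equal(clusterCoverSet(7L, matrix(rnorm(20), 10, 2)), list(7L))
  same <- matrix(1, 6, 2)
  expect_equal(clusterCoverSet(1:6, same), list(1:6))

  set.seed(3)
  blobA <- matrix(rnorm(20, sd = 0.1), 10, 2)
  blobB <- matrix(rnorm(20, sd = 0.1), 10, 2) + 10
  Z <- rbind(blobA, blobB)
  cl <- clusterCoverSet(1:20, Z)
  expect_length(cl, 2L)
  expect_equal(sort(unname(lengths(cl))), c(10L, 10L))
})

test_that("mapper edge weights equal the patch-set intersection oracle", {
  set.seed(21)
  sl <- toySlide(seed = 41L, depth = 0.6)
  g <- buildSlideGraph(sl, k = 8)
  Z <- nodeAttributes(g)
  mg <- buildMapperGraph(Z, nIntervals = 8, g = 0.3)
  expect_s4_class(mg, "MapperGraph")
  # coverage
  expect_identical(sort(unique(unlist(roiMembers(mg)))), seq_len(nrow(Z)))
  # every edge equals the brute-force intersection; no positive pair missed
  rois <- roiMembers(mg)
  e <- roiEdges(mg)
  nR <- roiCount(mg)
  seen <- matrix(0, nR, nR)
  if (nrow(e)) seen[cbind(e$i, e$j)] <- e$weight
  oracle <- matrix(0, nR, nR)
  for (a in seq_len(nR - 1)) {
    for (b in (a + 1):nR) {
      oracle[a, b] <- length(intersect(rois[[a]], rois[[b]]))
    }
  }
  expect_equal(seen, oracle)
})

test_that("disjoint cover boxes give no cross-box edges", {
  set.seed(31)
  Z <- matrix(rnorm(300), 150, 2)
  mg <- buildMapperGraph(Z, lensMethod = "first_dims", nIntervals = 4, g = 0)
  # with g = 0 only measure-zero boundary points can be shared; none here
  expect_equal(nrow(roiEdges(mg)), 0L)
})

test_that("ROI count grows with cover resolution on most seeds", {
  wins <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    Z <- matrix(rnorm(400), 200, 2) + rep(c(0, 4), each = 100)
    c1 <- roiCount(buildMapperGraph(Z, nIntervals = 3, g = 0.3))
    c2 <- roiCount(buildMapperGraph(Z, nIntervals = 8, g = 0.3))
    if (c2 >= c1) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("ROI summaries report composition percentages and centers of mass", {
  rois <- list(c(1L, 2L, 3L, 4L), c(3L, 4L, 5L, 6L))
  mg <- methods::new("MapperGraph",
    rois = rois,
    edges = data.frame(i = 1L, j = 2L, weight = 2),
    lensCenters = matrix(0, 2, 2), nPatches = 6L
  )
  labels <- c(2L, 2L, 2L, 2L, 1L, 1L) # ROI 1 pure cancer if class 2 = cancer
  coords <- cbind(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 0, 1))
  sm <- summarizeRois(mg, labels, coords, classNames = c("fat", "cancer"))
  expect_equal(sm$pct_cancer, c(100, 50))
  expect_equal(sm$pct_fat + sm$pct_cancer, c(100, 100), tolerance = 1e-9)
  expect_equal(sm$center_row, c(0.5, 1.5))
  expect_equal(sm$center_col, c(0.5, 0.5))
})
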