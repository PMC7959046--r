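test_that("ROI composition counts patch class assignments exactly", {
  # order (epithelium, fat, cancer): ROI {cancer, cancer, fat}
  labels <- c(3L, 3L, 2L, 1L)
  expect_equal(roiComposition(1:3, labels, K = 3), c(0L, 1L, 2L))
  expect_warning(z <- roiComposition(integer(0), labels, K = 3), "empty ROI")
  expect_equal(z, integer(3))
  expect_error(roiComposition(1:2, c(NA_integer_, 1L), K = 3), "unlabeled")

  set.seed(8)
  lab <- sample.int(5, 200, replace = TRUE)
  roi <- sample.int(200, 40)
  expect_equal(
    roiComposition(roi, lab, 5),
    vapply(1:5, function(k) sum(lab[roi] == k), 0L)
  )
})

test_that("edge intermingling is the overlap-scaled outer product", {
  expect_equal(edgeIntermingling(2, c(1, 0), c(0, 1)), rbind(c(0, 2), c(0, 0)))
  expect_equal(edgeIntermingling(0, c(3, 1), c(2, 2)), matrix(0, 2, 2))
  expect_equal(edgeIntermingling(3, c(2, 1), c(1, 4)), rbind(c(6, 24), c(3, 12)))
  expect_error(edgeIntermingling(-1, c(1, 0), c(0, 1)), "nonnegative")
})

test_that("the intermingling matrix symmetrizes each edge once", {
  emptyGraph <- methods::new("MapperGraph",
    rois = list(1:2, 3:4), edges = data.frame(i = integer(0), j = integer(0), weight = numeric(0)),
    lensCenters = matrix(0, 2, 2), nPatches = 4L
  )
  I0 <- interminglingMatrix(emptyGraph, c(1L, 1L, 2L, 2L), K = 2, normalize = "raw")
  expect_equal(unclass(I0), matrix(0, 2, 2), ignore_attr = TRUE)

  oneEdge <- methods::new("MapperGraph",
    rois = list(1L, 2L), edges = data.frame(i = 1L, j = 2L, weight = 2),
    lensCenters = matrix(0, 2, 2), nPatches = 2L
  )
  I1 <- interminglingMatrix(oneEdge, c(1L, 2L), K = 2, normalize = "raw")
  expect_equal(unclass(I1), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  # per-patch normalization divides by the squared patch count
  I1n <- interminglingMatrix(oneEdge, c(1L, 2L), K = 2, normalize = "per_patch")
  expect_equal(unclass(I1n), rbind(c(0, 1), c(1, 0)) / 4, ignore_attr = TRUE)
})

test_that("intermingling equals the brute-force oracle on random graphs", {
  for (s in 1:40) {
    rg <- randomMapperGraph(seed = 900 + s)
    I <- interminglingMatrix(rg$graph, rg$labels, K = rg$K, normalize = "per_patch")
    oracle <- oracleIntermingling(
      roiMembers(rg$graph), roiEdges(rg$graph), rg$labels, rg$K,
      rg$graph@nPatches
    )
    expect_equal(unclass(I), oracle, ignore_attr = TRUE, tolerance = 1e-12)
    expect_identical(unclass(I), t(unclass(I))) # exact symmetry
  }
})

test_that("the TIS is the tumor row of the intermingling matrix", {
  I <- rbind(c(0, 1), c(1, 0))
  expect_equal(tumorInvasionScore(I, 1), c(0, 1))
  expect_equal(tumorInvasionScore(matrix(0, 3, 3), 2), rep(0, 3))
  expect_error(tumorInvasionScore(I, 3), "out of range")
  named <- tumorInvasionScore(I, 1, classNames = c("cancer", "fat"))
  expect_equal(names(named), c("cancer", "fat"))
})

test_that("deeper invasion yields a larger fat TIS component", {
  # intermingling arises from contextualized embeddings, where patches on a
  # tissue boundary blend both classes; emulate the contextualization by
  # averaging each patch embedding with its spatial neighborhood mean
  tisAt <- function(depth) {
    cfg <- slideConfig(20, 20,
      invasionDepth = depth, frontRoughness = 0,
      pocketRate = 0, seed = 7L
    )
    mod <- embeddingModel(
      dim = 8, classSeparation = 4, noiseSd = 0.5,
      spatialSmoothing = 1, seed = 8L
    )
    sl <- simulateSlide(cfg, mod)
    g <- buildSlideGraph(sl, k = 8)
    A <- adjacencyMatrix(g)
    deg <- pmax(Matrix::rowSums(A), 1)
    Z <- as.matrix((sl$X + (A %*% sl$X) / deg) / 2)
    res <- slideTIS(
      Z, sl$grid$label,
      K = 8, tumorClass = match("cancer", colonClasses()),
      classNames = colonClasses(), nIntervals = 8, g = 0.3,
      linkage = "average" # keeps ROIs tissue-pure; see methods vignette
    )
    res$tis[["fat"]]
  }
  # at 0.3 the front is in the submucosa, far from fat; at 0.75 it lies inside
  # the fat band, creating a cancer-fat boundary
  expect_gt(tisAt(0.75), tisAt(0.3))
})

test_that("the fat TIS component tracks invasion depth across a cohort", {
  ms <- tisMonotonicityStudy(seed = 1L)
  expect_gte(ms$spearman, 0.8)
})
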