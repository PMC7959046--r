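test_that("layer bands occupy the configured fractions exactly", {
  cls <- c("epithelium", "submucosa", "muscularis_propria", "fat", "serosa")
  cfg <- slideConfig(10, 10,
    classNames = colonClasses(),
    layerClasses = cls, layerFractions = rep(0.2, 5),
    pocketRate = 0, invasionDepth = 0
  )
  grid <- generateTissueLayout(cfg)
  expect_equal(nrow(grid), 100L)
  lab <- matrix(grid$label, 10, 10)
  for (b in 1:5) {
    expect_true(all(lab[(2 * b - 1):(2 * b), ] == b))
  }
  # histogram equals band areas
  expect_equal(unname(tabulate(grid$label, 8)[1:5]), rep(20L, 5))
})

test_that("non-summing layer fractions are rejected", {
  expect_error(
    slideConfig(10, 10, layerFractions = c(0.2, 0.2, 0.2, 0.2, 0.3)),
    "sum to 1"
  )
})

test_that("pocket patch count stays inside a simulation envelope of the placement rule", {
  cfg <- slideConfig(30, 30, pocketRate = 0.1, invasionDepth = 0, seed = 42L)
  grid <- generateTissueLayout(cfg)
  pocketIdx <- match(c("debris", "inflammation"), colonClasses())
  observed <- sum(grid$label %in% pocketIdx)

  # independent re-simulation of the stated rule: per-patch seeds at rate
  # pocketRate / meanArea, rectangles with sides uniform on 2:4, clipped
  simOnce <- function(seed) {
    set.seed(seed)
    covered <- matrix(FALSE, 30, 30)
    seeds <- which(matrix(runif(900) < 0.1 / 9, 30, 30), arr.ind = TRUE)
    if (nrow(seeds)) {
      for (s in seq_len(nrow(seeds))) {
        h <- sample(2:4, 1); w <- sample(2:4, 1); sample(1:2, 1)
        covered[seeds[s, 1]:min(30, seeds[s, 1] + h - 1),
                seeds[s, 2]:min(30, seeds[s, 2] + w - 1)] <- TRUE
      }
    }
    sum(covered)
  }
  draws <- vapply(1000 + 1:400, simOnce, 0)
  env <- quantile(draws, c(0.005, 0.995))
  expect_gte(observed, env[[1]])
  expect_lte(observed, env[[2]])
})

test_that("invasion depth controls the cancer region by construction", {
  cfg <- slideConfig(10, 10, pocketRate = 0, seed = 1L)
  grid <- generateTissueLayout(cfg)
  cancer <- match("cancer", colonClasses())

  g0 <- injectInvasion(grid, 0, 0, seed = 1L, config = cfg)
  expect_identical(g0$label, grid$label)
  expect_equal(sum(g0$label == cancer), 0L)

  g1 <- injectInvasion(grid, 1, 0, seed = 1L, config = cfg)
  lab <- matrix(g1$label, 10, 10)
  expect_true(all(lab == cancer)) # every column reaches the last row

  gHalf <- injectInvasion(grid, 0.5, 0, seed = 1L, config = cfg)
  expect_equal(sum(gHalf$label == cancer), 50L)

  expect_error(injectInvasion(grid, 1.2, 0, 1L, cfg), "\\[0, 1\\]")
})

test_that("cancer patch count is nondecreasing in invasion depth", {
  cfg <- slideConfig(15, 15, pocketRate = 0, seed = 2L)
  grid <- generateTissueLayout(cfg)
  cancer <- match("cancer", colonClasses())
  counts <- vapply(seq(0, 1, by = 0.1), function(d) {
    sum(injectInvasion(grid, d, 0, seed = 3L, config = cfg)$label == cancer)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("embeddings reduce to class means without noise and are seed-deterministic", {
  cfg <- slideConfig(8, 8, pocketRate = 0, invasionDepth = 0.4, seed = 5L)
  grid <- injectInvasion(generateTissueLayout(cfg), 0.4, 0, 6L, cfg)
  mod0 <- embeddingModel(dim = 6, noiseSd = 0, pvSigma = 0, seed = 9L)
  X0 <- sampleEmbeddings(grid, mod0)
  expect_equal(X0, unname(mod0$classMeans[grid$label, ]))

  mod <- embeddingModel(dim = 6, noiseSd = 2, spatialSmoothing = 1, seed = 9L)
  expect_identical(sampleEmbeddings(grid, mod), sampleEmbeddings(grid, mod))

  badGrid <- grid
  badGrid$label[1] <- 99L
  expect_error(sampleEmbeddings(badGrid, mod), "99")
})

test_that("nearest-class-mean accuracy is high at wide separation", {
  # Monte-Carlo estimate of the Gaussian misclassification rate at
  # separation 5, noise 1, dim 16
  cfg <- slideConfig(32, 32, pocketRate = 0, invasionDepth = 0.5, seed = 13L)
  grid <- injectInvasion(generateTissueLayout(cfg), 0.5, 0, 14L, cfg)
  mod <- embeddingModel(
    dim = 16, classSeparation = 5, noiseSd = 1,
    spatialSmoothing = 0, pvSigma = 0, seed = 15L
  )
  X <- sampleEmbeddings(grid, mod)
  ix <- seq_len(1000)
  D <- as.matrix(dist(rbind(mod$classMeans, X[ix, ])))[-(1:8), 1:8]
  pred <- max.col(-D)
  expect_gt(mean(pred == grid$label[ix]), 0.95)
})

test_that("embedding separability is monotone in the separation/noise ratio", {
  cfg <- slideConfig(20, 20, pocketRate = 0, invasionDepth = 0.5, seed = 31L)
  grid <- injectInvasion(generateTissueLayout(cfg), 0.5, 0, 32L, cfg)
  acc <- vapply(c(0.5, 2, 6), function(sep) {
    mod <- embeddingModel(
      dim = 8, classSeparation = sep, noiseSd = 1,
      spatialSmoothing = 0, pvSigma = 0, seed = 33L
    )
    X <- sampleEmbeddings(grid, mod)
    D <- as.matrix(dist(rbind(mod$classMeans, X)))[-(1:8), 1:8]
    mean(max.col(-D) == grid$label)
  }, 0)
  expect_true(all(diff(acc) > 0))
})

test_that("cohorts tie stage to the depth threshold and are reproducible", {
  cfg <- slideConfig(8, 8, pocketRate = 0)
  mod <- embeddingModel(dim = 4, noiseSd = 1, seed = 3L)
  shallow <- suppressWarnings(generateCohort(3, 2, cfg, mod,
    depthSampler = function(n) rep(0.2, n),
    stageThreshold = 0.6, withinPatientSd = 0, seed = 8L
  ))
  expect_warning(
    generateCohort(3, 2, cfg, mod,
      depthSampler = function(n) rep(0.2, n),
      stageThreshold = 0.6, withinPatientSd = 0, seed = 8L
    ),
    "degenerate"
  )
  expect_true(all(shallow@manifest$stage == 0L))

  co1 <- generateCohort(4, 3, cfg, mod, seed = 77L)
  co2 <- generateCohort(4, 3, cfg, mod, seed = 77L)
  expect_identical(co1@manifest, co2@manifest)
  expect_identical(co1@slides[[5]]$X, co2@slides[[5]]$X)
  # repeated sections per patient
  expect_true(any(table(co1@manifest$patient_id) >= 2))
})

test_that("the default stage threshold is the top of the fat band", {
  cfg <- slideConfig(10, 10)
  expect_equal(stageThresholdFor(cfg), 0.15 + 0.2 + 0.3)
})
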