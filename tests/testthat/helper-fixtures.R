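# Shared fixtures. Heavy objects (fitted classifiers, cohorts) are built once
# per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small labeled slide with clear class structure. Partial-volume mixing is
# off: on these small grids many patches touch a band boundary, and the
# fixtures isolate classifier behavior.
toySlide <- function(seed = 11L, depth = 0.5, noiseSd = 1.5, sep = 4,
                     rows = 12L, smoothing = 1) {
  cfg <- slideConfig(rows, rows,
    invasionDepth = depth, frontRoughness = 0,
    pocketRate = 0, seed = seed
  )
  mod <- embeddingModel(
    dim = 8, classSeparation = sep, noiseSd = noiseSd,
    spatialSmoothing = smoothing, pvSigma = 0, seed = seed + 1L
  )
  simulateSlide(cfg, mod)
}

toyGraph <- function(...) buildSlideGraph(toySlide(...), k = 8)

# Two-class, well-separated toy graph for exact-fit checks.
separableGraph <- function(m = 40L, seed = 5L) {
  set.seed(seed)
  coords <- cbind(rep(0:7, length.out = m), rep(0:4, each = 8)[seq_len(m)])
  y <- as.integer(coords[, 1L] < 4) + 1L
  means <- rbind(c(2, 0, 0), c(-2, 0, 0))
  X <- means[y, ] + matrix(rnorm(m * 3, sd = 0.05), m, 3)
  grid <- data.frame(row = coords[, 1L], col = coords[, 2L], label = y)
  attr(grid, "classNames") <- c("a", "b")
  attr(grid, "dims") <- c(8L, 5L)
  attr(grid, "slideId") <- "sep"
  assembleWSG(grid, X, knnEdges(coords, 4))
}

# A fitted classifier on a handful of small slides (cached).
smallFit <- function() {
  fixture("smallFit", function() {
    mk <- function(seed, depth) {
      toyGraph(seed = seed, depth = depth, noiseSd = 1.2, sep = 5,
               rows = 20L, smoothing = 0.6)
    }
    tr <- list(mk(21L, 0.3), mk(23L, 0.55), mk(25L, 0.8))
    va <- list(mk(22L, 0.45), mk(24L, 0.7))
    cfg <- gatConfig(
      n_conv_layers = 2L, hidden_dim = 8L, attention_heads = 2L,
      dropedge_p = 0.2, dropout_p = 0.1, learning_rate = 1e-2,
      max_epochs = 60L, seed = 7L
    )
    list(
      model = fitNodeClassifier(tr, va, cfg),
      train = tr[[1L]], val = va[[1L]], trainAll = tr, valAll = va
    )
  })
}

# Independent brute-force kNN oracle: full all-pairs sort per node.
oracleKnnEdges <- function(coords, k) {
  m <- nrow(coords)
  pairs <- matrix(0L, 0, 2)
  for (i in seq_len(m)) {
    d2 <- rowSums((coords - matrix(coords[i, ], m, 2, byrow = TRUE))^2)
    ord <- order(d2, seq_len(m))
    ord <- setdiff(ord, i)[seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(i, ord), pmax(i, ord)))
  }
  u <- unique(pairs)
  u[order(u[, 1], u[, 2]), , drop = FALSE]
}

# Independent brute-force intermingling oracle: triple loop over edges and
# class pairs.
oracleIntermingling <- function(rois, edges, labels, K, nPatches, perPatch = TRUE) {
  I <- matrix(0, K, K)
  comps <- lapply(rois, function(r) tabulate(labels[r], nbins = K))
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ci <- comps[[edges$i[r]]]
      cj <- comps[[edges$j[r]]]
      w <- edges$weight[r]
      for (a in seq_len(K)) {
        for (b in seq_len(K)) {
          I[a, b] <- I[a, b] + w * (ci[a] * cj[b] + ci[b] * cj[a]) / 2
        }
      }
    }
  }
  if (perPatch) I <- I / nPatches^2
  I
}

# Random Mapper-like graph for oracle equivalence checks.
randomMapperGraph <- function(seed, maxRois = 10L, K = 5L) {
  set.seed(seed)
  n <- sample(2:maxRois, 1)
  nPatches <- sample(20:60, 1)
  rois <- lapply(seq_len(n), function(i) sort(sample.int(nPatches, sample(2:8, 1))))
  # edges from actual intersections (like Mapper) with the true overlap weight
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      w <- length(intersect(rois[[a]], rois[[b]]))
      if (w > 0) { ei <- c(ei, a); ej <- c(ej, b); ew <- c(ew, w) }
    }
  }
  labels <- sample.int(K, nPatches, replace = TRUE)
  list(
    graph = methods::new("MapperGraph",
      rois = rois, edges = data.frame(i = ei, j = ej, weight = ew),
      lensCenters = matrix(0, n, 2), nPatches = as.integer(nPatches)
    ),
    labels = labels, K = K
  )
}
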