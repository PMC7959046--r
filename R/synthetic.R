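#' Canonical colon tissue class vocabulary
#'
#' Ordered class list used throughout the package for colon sections: the five
#' anatomic wall layers from lumen to surface (epithelium, submucosa,
#' muscularis propria, fat, serosa), two non-layer classes that occur as small
#' pockets (debris, inflammation), and cancer.
#'
#' @return character vector of class names.
#' @export
colonClasses <- function() {
  c(
    "epithelium", "submucosa", "muscularis_propria", "fat", "serosa",
    "debris", "inflammation", "cancer"
  )
}

#' Configuration of a synthetic layered slide
#'
#' Describes one simulated tissue section: a `gridRows` x `gridCols` patch
#' grid whose rows are split into horizontal anatomic bands (top-to-bottom in
#' the order of `layerClasses`), with optional pockets of debris/inflammation
#' and a cancer region invading from the top (luminal) surface down to a
#' controllable depth.
#'
#' @param gridRows,gridCols positive integers, patch grid size.
#' @param patchPx patch side length in pixels (metadata only; default 256).
#' @param classNames full class vocabulary; must contain `layerClasses`,
#'   `pocketClasses` and `tumorClass`.
#' @param layerClasses classes laid out as horizontal bands, top to bottom.
#' @param layerFractions nonnegative fractions of `gridRows` per layer; must
#'   sum to 1 within 1e-9.
#' @param pocketClasses classes inserted as small contiguous blobs.
#' @param tumorClass class used for the invading region.
#' @param invasionDepth fraction of the grid depth reached by cancer, in
#'   \[0, 1\]; 0 yields no cancer patches.
#' @param frontRoughness nonnegative standard deviation (in rows) of the
#'   per-column jitter of the invasion front.
#' @param pocketRate expected fraction of patches covered by pockets, in
#'   \[0, 1\].
#' @param seed integer seed for pocket placement and invasion jitter.
#' @return a list of class `SlideConfig`.
#' @export
slideConfig <- function(gridRows, gridCols, patchPx = 256L,
                        classNames = colonClasses(),
                        layerClasses = classNames[1:5],
                        layerFractions = c(0.15, 0.2, 0.3, 0.25, 0.1),
                        pocketClasses = c("debris", "inflammation"),
                        tumorClass = "cancer",
                        invasionDepth = 0, frontRoughness = 0,
                        pocketRate = 0, seed = 1L) {
  stopifnot(gridRows >= 1, gridCols >= 1, patchPx >= 1)
  if (length(layerFractions) != length(layerClasses)) {
    stop("layerFractions must have one entry per layer class")
  }
  if (any(layerFractions < 0) || abs(sum(layerFractions) - 1) > 1e-9) {
    stop("layerFractions must be nonnegative and sum to 1 (within 1e-9)")
  }
  if (invasionDepth < 0 || invasionDepth > 1) stop("invasionDepth must lie in [0, 1]")
  if (frontRoughness < 0) stop("frontRoughness must be nonnegative")
  if (pocketRate < 0 || pocketRate > 1) stop("pocketRate must lie in [0, 1]")
  missing <- setdiff(c(layerClasses, pocketClasses, tumorClass), classNames)
  if (length(missing)) stop("classes absent from classNames: ", paste(missing, collapse = ", "))
  structure(
    list(
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      patchPx = as.integer(patchPx), classNames = classNames,
      layerClasses = layerClasses, layerFractions = layerFractions,
      pocketClasses = pocketClasses, tumorClass = tumorClass,
      invasionDepth = invasionDepth, frontRoughness = frontRoughness,
      pocketRate = pocketRate, seed = as.integer(seed)
    ),
    class = "SlideConfig"
  )
}

# Row index (0-based, exclusive upper bounds) of each layer band.
layerBounds <- function(config) {
  upper <- round(cumsum(config$layerFractions) * config$gridRows)
  upper[length(upper)] <- config$gridRows
  lower <- c(0L, upper[-length(upper)])
  data.frame(class = config$layerClasses, from = as.integer(lower), to = as.integer(upper))
}

# Mean pocket blob area under the 2-4 patch uniform side-length rule.
pocketMeanArea <- function() mean(2:4)^2

#' Generate the layered tissue layout of one synthetic slide
#'
#' Assigns every patch of the grid a tissue class: horizontal bands in the
#' configured layer order, then (at `pocketRate > 0`) axis-aligned rectangular
#' pockets of debris/inflammation with side lengths drawn uniformly from
#' 2-4 patches, seeded per patch with probability `pocketRate / 9` so that the
#' expected pocket-covered fraction is approximately `pocketRate`.
#'
#' @param config a [slideConfig()].
#' @param slideIdent slide identifier stored on the patch table.
#' @return a `data.frame` patch table with columns `row`, `col` (0-based) and
#'   `label` (1-based index into `classNames`), plus attributes `classNames`,
#'   `dims`, `slideId`, `patchPx`.
#' @export
generateTissueLayout <- function(config, slideIdent = "slide") {
  nr <- config$gridRows
  nc <- config$gridCols
  bands <- layerBounds(config)
  lab <- matrix(0L, nr, nc)
  for (b in seq_len(nrow(bands))) {
    if (bands$to[b] > bands$from[b]) {
      lab[(bands$from[b] + 1L):bands$to[b], ] <- match(bands$class[b], config$classNames)
    }
  }
  if (config$pocketRate > 0) {
    set.seed(config$seed)
    pSeed <- config$pocketRate / pocketMeanArea()
    seeds <- which(matrix(stats::runif(nr * nc) < pSeed, nr, nc), arr.ind = TRUE)
    if (nrow(seeds)) {
      for (s in seq_len(nrow(seeds))) {
        h <- sample(2:4, 1L)
        w <- sample(2:4, 1L)
        cls <- sample(config$pocketClasses, 1L)
        r0 <- seeds[s, 1L]
        c0 <- seeds[s, 2L]
        lab[r0:min(nr, r0 + h - 1L), c0:min(nc, c0 + w - 1L)] <-
          match(cls, config$classNames)
      }
    }
  }
  grid <- data.frame(
    row = rep(0:(nr - 1L), times = nc),
    col = rep(0:(nc - 1L), each = nr),
    label = as.integer(lab)
  )
  attr(grid, "classNames") <- config$classNames
  attr(grid, "dims") <- c(nr, nc)
  attr(grid, "slideId") <- slideIdent
  attr(grid, "patchPx") <- config$patchPx
  grid
}

#' Grow a cancer region into a layered slide
#'
#' The cancer invades from the luminal (top) surface downward: in each column
#' it occupies the first `floor(invasionDepth * gridRows)` rows, jittered per
#' column by a rounded Gaussian with standard deviation `frontRoughness` rows
#' (clamped to the grid). `invasionDepth = 0` leaves the grid unchanged. The
#' deepest anatomic layer containing at least one cancer patch is recorded as
#' attribute `invadedLayer`.
#'
#' @param grid a patch table from [generateTissueLayout()].
#' @param invasionDepth fraction of the grid depth in \[0, 1\].
#' @param frontRoughness nonnegative jitter sd in rows.
#' @param seed integer seed for the jitter.
#' @param config the [slideConfig()] the grid was generated from (provides the
#'   layer bands and tumor class).
#' @return the patch table with cancer labels written in and attributes
#'   `invasionDepth`, `invadedLayer` set.
#' @export
injectInvasion <- function(grid, invasionDepth, frontRoughness, seed, config) {
  if (invasionDepth < 0 || invasionDepth > 1) stop("invasionDepth must lie in [0, 1]")
  dims <- attr(grid, "dims")
  nr <- dims[1L]
  nc <- dims[2L]
  attr(grid, "invasionDepth") <- invasionDepth
  attr(grid, "invadedLayer") <- NA_character_
  base <- floor(invasionDepth * nr)
  if (invasionDepth == 0 || base == 0) {
    return(grid)
  }
  set.seed(as.integer(seed))
  jitter <- if (frontRoughness > 0) round(stats::rnorm(nc, 0, frontRoughness)) else rep(0L, nc)
  depthPerCol <- pmin(nr, pmax(0L, base + jitter))
  tumorIdx <- match(config$tumorClass, config$classNames)
  lab <- matrix(grid$label, nr, nc)
  for (cc in seq_len(nc)) {
    d <- depthPerCol[cc]
    if (d > 0) lab[1:d, cc] <- tumorIdx
  }
  grid$label <- as.integer(lab)
  deepest <- max(depthPerCol)
  bands <- layerBounds(config)
  hit <- bands$class[bands$from < deepest & bands$to > bands$from]
  if (length(hit)) attr(grid, "invadedLayer") <- hit[length(hit)]
  grid
}

#' Class-conditional patch embedding model
#'
#' Stand-in for CNN patch features: each tissue class has a mean vector in
#' `dim`-dimensional space and patches receive their class mean plus spatially
#' smoothed Gaussian noise, so that neighboring patches have correlated
#' features. Class means are drawn once from an isotropic Gaussian scaled so
#' the expected pairwise distance between class means is `classSeparation`.
#'
#' @param dim embedding dimension.
#' @param classNames class vocabulary the model covers.
#' @param classSeparation expected Euclidean distance between class means.
#' @param noiseSd marginal standard deviation of the per-dimension noise.
#' @param spatialSmoothing Gaussian blur sd of the noise field, in patch units
#'   (0 = independent noise).
#' @param pvSigma partial-volume mixing scale in patch units: a patch at a
#'   tissue boundary covers more than one compartment, so its expected
#'   embedding is a mixture of the neighboring class means, with weights from
#'   a Gaussian blur (sd `pvSigma`) of the one-hot label field. 0 disables
#'   mixing; default 0.5 (transition about one patch wide).
#' @param seed integer seed for mean generation and noise sampling.
#' @param classMeans optional explicit K x dim matrix of class means
#'   (overrides the random draw).
#' @return a list of class `EmbeddingModel`.
#' @export
embeddingModel <- function(dim = 16L, classNames = colonClasses(),
                           classSeparation = 3, noiseSd = 1,
                           spatialSmoothing = 1, pvSigma = 0.5, seed = 1L,
                           classMeans = NULL) {
  stopifnot(dim >= 1, noiseSd >= 0, spatialSmoothing >= 0, pvSigma >= 0)
  K <- length(classNames)
  if (is.null(classMeans)) {
    set.seed(as.integer(seed))
    classMeans <- matrix(
      stats::rnorm(K * dim, sd = classSeparation / sqrt(2 * dim)),
      nrow = K, ncol = dim
    )
  }
  stopifnot(nrow(classMeans) == K, ncol(classMeans) == dim)
  if (classSeparation > 0 && K > 1) {
    d <- stats::dist(classMeans)
    if (min(d) <= 0) stop("degenerate class means: zero pairwise distance")
  }
  rownames(classMeans) <- classNames
  structure(
    list(
      dim = as.integer(dim), classNames = classNames,
      classMeans = classMeans, noiseSd = noiseSd,
      spatialSmoothing = spatialSmoothing, pvSigma = pvSigma,
      seed = as.integer(seed)
    ),
    class = "EmbeddingModel"
  )
}

# Marginal sd of a unit-variance iid field after the two-axis separable blur:
# variance factor sum(k^2) per axis, so sd factor = sum(k^2).
blurSdFactor <- function(sigma) {
  if (sigma <= 0) return(1)
  R <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-R:R, sd = sigma)
  k <- k / sum(k)
  sum(k^2)
}

#' Sample class-conditional embeddings for every patch of a slide
#'
#' Each patch receives its expected embedding plus Gaussian noise. The
#' expected embedding is the patch's class mean; with `pvSigma > 0` patches at
#' compartment boundaries get a partial-volume mixture of the adjacent class
#' means (weights from a Gaussian blur of the one-hot label field), emulating
#' fixed-size patches that straddle a tissue interface. When
#' `spatialSmoothing > 0` the noise field of every embedding dimension is
#' blurred over the patch grid with a Gaussian kernel and rescaled so the
#' marginal standard deviation stays `noiseSd`, giving spatially correlated
#' features. Deterministic under the model's seed.
#'
#' @param grid a labeled patch table.
#' @param model an [embeddingModel()].
#' @return numeric matrix, one row per patch (in the order of `grid`), `dim`
#'   columns.
#' @export
sampleEmbeddings <- function(grid, model) {
  dims <- attr(grid, "dims")
  nr <- dims[1L]
  nc <- dims[2L]
  lab <- grid$label
  K <- nrow(model$classMeans)
  bad <- lab < 1L | lab > K
  if (any(bad)) stop("unknown label index: ", paste(unique(lab[bad]), collapse = ", "))
  lin <- grid$row + 1L + nr * grid$col # position in column-major field
  if (model$pvSigma > 0) {
    labField <- matrix(0L, nr, nc)
    labField[lin] <- lab
    present <- sort(unique(lab))
    W <- matrix(0, nrow(grid), length(present))
    for (ki in seq_along(present)) {
      oneHot <- matrix(as.numeric(labField == present[ki]), nr, nc)
      W[, ki] <- blurFieldRaw(oneHot, model$pvSigma)[lin]
    }
    W <- W / rowSums(W)
    X <- W %*% model$classMeans[present, , drop = FALSE]
  } else {
    X <- model$classMeans[lab, , drop = FALSE]
  }
  if (model$noiseSd > 0) {
    set.seed(model$seed)
    sigma <- model$spatialSmoothing
    sdFac <- blurSdFactor(sigma) # per-axis variance factor
    noise <- matrix(0, nrow(grid), model$dim)
    for (d in seq_len(model$dim)) {
      field <- matrix(stats::rnorm(nr * nc), nr, nc)
      if (sigma > 0) {
        field <- blurFieldRaw(field, sigma) / sdFac # restore unit marginal sd
      }
      noise[, d] <- field[lin]
    }
    X <- X + model$noiseSd * noise
  }
  dimnames(X) <- NULL
  X
}

# Raw separable blur (replicate padding), no rescaling.
blurFieldRaw <- function(field, sigma) {
  R <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-R:R, sd = sigma)
  k <- k / sum(k)
  convAxis <- function(M, along) {
    n <- if (along == 1L) nrow(M) else ncol(M)
    out <- M * 0
    for (u in -R:R) {
      idx <- pmin(n, pmax(1L, seq_len(n) + u))
      out <- out + k[u + R + 1L] * if (along == 1L) M[idx, , drop = FALSE] else M[, idx, drop = FALSE]
    }
    out
  }
  convAxis(convAxis(field, 1L), 2L)
}

#' Simulate one labeled slide with embeddings
#'
#' Convenience wrapper: tissue layout, cancer invasion at the configured depth,
#' then class-conditional embeddings.
#'
#' @inheritParams generateTissueLayout
#' @param model an [embeddingModel()].
#' @return list with elements `grid` (labeled patch table) and `X` (embedding
#'   matrix).
#' @export
simulateSlide <- function(config, model, slideIdent = "slide") {
  grid <- generateTissueLayout(config, slideIdent)
  grid <- injectInvasion(
    grid, config$invasionDepth, config$frontRoughness,
    seed = config$seed + 1L, config = config
  )
  list(grid = grid, X = sampleEmbeddings(grid, model))
}

#' Default stage threshold: invasion reaching the fat band
#'
#' Advanced stage is defined as cancer reaching the pericolic fat, i.e. an
#' invasion depth exceeding the cumulative row fraction of all layers above
#' fat.
#'
#' @param config a [slideConfig()].
#' @param layer layer whose upper boundary defines the threshold.
#' @return depth fraction in (0, 1).
#' @export
stageThresholdFor <- function(config, layer = "fat") {
  i <- match(layer, config$layerClasses)
  if (is.na(i)) stop("layer not in layerClasses: ", layer)
  sum(config$layerFractions[seq_len(i - 1L)])
}

#' Generate a synthetic slide cohort
#'
#' Simulates `nPatients * slidesPerPatient` slides: each patient draws a
#' latent invasion depth from `depthSampler`, each of that patient's slides
#' perturbs it by Gaussian within-patient noise (serial sections of one
#' specimen), and a slide is stage-positive when its depth exceeds
#' `stageThreshold` (by default: cancer reaching the fat band).
#'
#' @param nPatients number of patients (>= 2).
#' @param slidesPerPatient slides (serial sections) per patient.
#' @param config a [slideConfig()] template; its `invasionDepth` is overridden
#'   per slide.
#' @param model an [embeddingModel()]; its seed is re-derived per slide.
#' @param depthSampler function `n -> n depths in [0,1]` giving patient-level
#'   invasion depths; default uniform on \[0.05, 0.95\].
#' @param stageThreshold depth above which a slide is stage-positive; default
#'   [stageThresholdFor()] at the fat band.
#' @param withinPatientSd sd of within-patient depth perturbation (default 0.05).
#' @param seed integer master seed.
#' @return a [SyntheticCohort-class] object.
#' @export
generateCohort <- function(nPatients, slidesPerPatient, config, model,
                           depthSampler = function(n) stats::runif(n, 0.05, 0.85),
                           stageThreshold = NULL, withinPatientSd = 0.05,
                           seed = 1L) {
  if (nPatients < 2) stop("nPatients must be at least 2")
  if (is.null(stageThreshold)) stageThreshold <- stageThresholdFor(config)
  set.seed(as.integer(seed))
  patientDepths <- depthSampler(nPatients)
  if (length(unique(patientDepths)) == 1L) {
    warning("degenerate depth sampler: all patient depths identical")
  }
  nSlides <- nPatients * slidesPerPatient
  slideSeeds <- sample.int(.Machine$integer.max %/% 4L, nSlides)
  depths <- pmin(1, pmax(
    0,
    rep(patientDepths, each = slidesPerPatient) +
      stats::rnorm(nSlides, 0, withinPatientSd)
  ))
  slides <- vector("list", nSlides)
  ids <- sprintf("slide_%03d", seq_len(nSlides))
  for (s in seq_len(nSlides)) {
    cfg <- config
    cfg$invasionDepth <- depths[s]
    cfg$seed <- slideSeeds[s]
    mod <- model
    mod$seed <- slideSeeds[s] + 1L
    sim <- simulateSlide(cfg, mod, slideIdent = ids[s])
    slides[[s]] <- list(grid = sim$grid, X = sim$X, depth = depths[s])
  }
  names(slides) <- ids
  manifest <- data.frame(
    slide_id = ids,
    patient_id = rep(seq_len(nPatients), each = slidesPerPatient),
    depth = depths,
    stage = as.integer(depths > stageThreshold)
  )
  methods::new("SyntheticCohort",
    slides = slides, manifest = manifest,
    classNames = config$classNames, stageThreshold = stageThreshold
  )
}
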