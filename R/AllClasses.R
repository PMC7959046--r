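#' @import methods
#' @importFrom Matrix sparseMatrix t diag colSums rowSums
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Whole-slide graph of tissue patches
#'
#' A `WholeSlideGraph` holds one tissue section as a graph \eqn{G=(V,E,A,X)}:
#' patches are nodes located on the slide's patch grid, spatial adjacency is a
#' sparse symmetric binary matrix `A` with zero diagonal, and the patch
#' embeddings form the dense attribute matrix `X` (one row per patch).
#' Optional per-patch tissue-class labels (1-based indices into `classNames`)
#' support supervised node classification.
#'
#' @slot slideId single character identifier.
#' @slot coords integer matrix (m x 2), 0-based `(row, col)` patch grid
#'   positions, unique within the slide.
#' @slot patchPx side length of a patch in pixels (metadata only).
#' @slot adjacency sparse symmetric binary `Matrix` with zero diagonal.
#' @slot attributes dense numeric matrix, m x n embedding dimensions.
#' @slot labels integer vector of 1-based class indices, or NULL.
#' @slot classNames character vector naming the class vocabulary.
#'
#' @seealso [assembleWSG()], [knnEdges()], [radiusEdges()]
#' @export
setClass("WholeSlideGraph",
  representation(
    slideId = "character",
    coords = "matrix",
    patchPx = "integer",
    adjacency = "Matrix",
    attributes = "matrix",
    labels = "integerOrNULL",
    classNames = "character"
  )
)

setValidity("WholeSlideGraph", function(object) {
  msg <- character()
  m <- nrow(object@coords)
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have two columns (row, col)")
  if (anyDuplicated(object@coords)) msg <- c(msg, "patch coordinates must be unique within a slide")
  A <- object@adjacency
  if (nrow(A) != m || ncol(A) != m) {
    msg <- c(msg, sprintf("adjacency is %d x %d but there are %d patches", nrow(A), ncol(A), m))
  } else {
    if (!Matrix::isSymmetric(A)) msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0)) msg <- c(msg, "adjacency must have a zero diagonal")
    if (length(A@x) && any(A@x != 1)) msg <- c(msg, "adjacency entries must be binary")
  }
  if (nrow(object@attributes) != m) {
    msg <- c(msg, sprintf(
      "attribute matrix has %d rows but there are %d patches",
      nrow(object@attributes), m
    ))
  }
  if (!is.null(object@labels)) {
    if (length(object@labels) != m) msg <- c(msg, "labels length must equal patch count")
    K <- length(object@classNames)
    if (K > 0L && any(object@labels < 1L | object@labels > K)) {
      msg <- c(msg, "labels must be 1-based indices into classNames")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Mapper summary graph of regions of interest
#'
#' The output of the Mapper algorithm applied to the point cloud of
#' contextualized patch embeddings: each node is a region of interest (ROI), a
#' cluster of patches found inside one overlapping cover set of the lens space;
#' each edge connects two ROIs that share at least one patch, weighted by the
#' shared-patch count \eqn{w_{ij}}.
#'
#' @slot rois list of integer vectors; ROI i holds the (1-based) patch indices
#'   of its members. The union of all ROIs covers every input patch.
#' @slot edges data.frame with columns `i`, `j` (ROI indices, i < j) and
#'   `weight` (= size of the patch-set intersection, > 0).
#' @slot lensCenters numeric matrix, one row per ROI: center of mass in lens space.
#' @slot nPatches total number of patches the graph was built from.
#'
#' @seealso [buildMapperGraph()], [summarizeRois()], [interminglingMatrix()]
#' @export
setClass("MapperGraph",
  representation(
    rois = "list",
    edges = "data.frame",
    lensCenters = "matrix",
    nPatches = "integer"
  )
)

setValidity("MapperGraph", function(object) {
  msg <- character()
  n <- length(object@rois)
  if (!all(c("i", "j", "weight") %in% names(object@edges))) {
    msg <- c(msg, "edges must have columns i, j, weight")
  } else if (nrow(object@edges)) {
    e <- object@edges
    if (any(e$i >= e$j)) msg <- c(msg, "edges must be stored with i < j")
    if (any(e$i < 1L | e$j > n)) msg <- c(msg, "edge endpoints out of range")
    if (any(e$weight <= 0)) msg <- c(msg, "edge weights must be positive shared-patch counts")
  }
  if (n && length(unique(unlist(object@rois))) > object@nPatches) {
    msg <- c(msg, "ROIs reference more patches than nPatches")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted graph attention node classifier
#'
#' Parameters and training history of the graph attention network used for
#' patch-level tissue classification. The retained parameters are those of the
#' epoch with the highest validation weighted F1 score.
#'
#' @slot params list of per-layer parameter matrices (attention weights and
#'   projection matrices per head, final linear layer).
#' @slot config the [gatConfig()] the model was fitted with.
#' @slot classNames class vocabulary (output order of probability columns).
#' @slot inputDim attribute dimension expected at prediction time.
#' @slot trainLog data.frame with per-epoch `loss` and `valF1`.
#' @slot selectedEpoch epoch whose parameters are retained
#'   (argmax of validation weighted F1).
#'
#' @seealso [fitNodeClassifier()], [predictProba()], [extractEmbeddings()]
#' @export
setClass("FittedNodeModel",
  representation(
    params = "list",
    config = "list",
    classNames = "character",
    inputDim = "integer",
    trainLog = "data.frame",
    selectedEpoch = "integer"
  )
)

setValidity("FittedNodeModel", function(object) {
  msg <- character()
  if (nrow(object@trainLog)) {
    best <- which.max(object@trainLog$valF1)
    if (object@selectedEpoch != best) {
      msg <- c(msg, "selectedEpoch must be the argmax of validation weighted F1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Monte-Carlo posterior draws of patch class probabilities
#'
#' `T` stochastic forward passes of a fitted node classifier with Dropout and
#' DropEdge left active, giving an approximate predictive posterior per patch.
#'
#' @slot draws numeric array `T x m x K`; every `m x K` slice is a row-stochastic
#'   probability matrix.
#' @slot seed the seed the draws were generated under.
#' @export
setClass("PosteriorDraws",
  representation(draws = "array", seed = "integer")
)

setValidity("PosteriorDraws", function(object) {
  d <- object@draws
  if (length(dim(d)) != 3L) return("draws must be a T x m x K array")
  rs <- apply(d, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-6)) return("every draw's probability rows must sum to 1")
  TRUE
})

#' Synthetic slide cohort
#'
#' A cohort of simulated layered-tissue slides with known invasion depths,
#' patient assignments (several serial sections per patient) and a binary
#' advanced-stage outcome defined by invasion reaching a depth threshold.
#'
#' @slot slides named list of per-slide lists, each with elements `grid`
#'   (patch table), `X` (embedding matrix) and `depth`.
#' @slot manifest data.frame with one row per slide: `slide_id`, `patient_id`,
#'   `depth`, `stage`.
#' @slot classNames tissue class vocabulary shared by all slides.
#' @slot stageThreshold depth fraction above which a slide is stage-positive.
#' @export
setClass("SyntheticCohort",
  representation(
    slides = "list",
    manifest = "data.frame",
    classNames = "character",
    stageThreshold = "numeric"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  need <- c("slide_id", "patient_id", "depth", "stage")
  if (!all(need %in% names(object@manifest))) {
    msg <- c(msg, "manifest needs columns slide_id, patient_id, depth, stage")
  } else {
    man <- object@manifest
    expect <- as.integer(man$depth > object@stageThreshold)
    if (!identical(as.integer(man$stage), expect)) {
      msg <- c(msg, "stage must be 1 iff depth exceeds stageThreshold")
    }
    if (length(object@slides) != nrow(man)) msg <- c(msg, "one manifest row per slide required")
  }
  if (length(msg)) msg else TRUE
})
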