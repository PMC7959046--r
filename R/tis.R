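#' ROI composition vector
#'
#' Counts of predicted tissue-class assignment among the patches of one ROI:
#' the vector \eqn{c_i} entering the intermingling computation.
#'
#' @param patchIds integer patch indices of the ROI.
#' @param labels integer predicted class label per patch (1-based).
#' @param K number of classes.
#' @return nonnegative integer vector of length K summing to the ROI size.
#' @export
roiComposition <- function(patchIds, labels, K) {
  if (!length(patchIds)) {
    warning("empty ROI: zero composition vector")
    return(integer(K))
  }
  lab <- labels[patchIds]
  if (anyNA(lab)) stop("unlabeled patch in ROI")
  if (any(lab < 1L | lab > K)) stop("patch label out of range [1, K]")
  tabulate(lab, nbins = K)
}

#' Pairwise ROI intermingling matrix
#'
#' For one Mapper edge with overlap weight \eqn{w_{ij}} between ROIs with
#' composition vectors \eqn{c_i, c_j}, the class-pair intermingling is the
#' scaled outer product \eqn{A_{ij} = w_{ij}\, c_i \otimes c_j}, i.e.
#' `A[a, b] = w * c_i[a] * c_j[b]`.
#'
#' @param w nonnegative overlap weight (shared-patch count).
#' @param ci,cj composition vectors of the two ROIs.
#' @return K x K matrix.
#' @export
edgeIntermingling <- function(w, ci, cj) {
  if (w < 0) stop("overlap weight must be nonnegative")
  stopifnot(length(ci) == length(cj))
  w * outer(as.numeric(ci), as.numeric(cj))
}

#' Slide-level tissue-class intermingling matrix
#'
#' Sums the symmetrized per-edge intermingling over all undirected Mapper
#' edges: \eqn{I = \sum_{e \in E} (A_{ij} + A_{ij}^T)/2}, each undirected edge
#' counted once. With `normalize = "per_patch"` (the default for cross-slide
#' modeling) the matrix is divided by the squared slide patch count so slides
#' of different sizes are comparable; `normalize = "raw"` returns the plain
#' count-scale matrix.
#'
#' @param graph a [MapperGraph-class].
#' @param labels integer predicted class label per patch.
#' @param K number of classes (default: `max(labels)`).
#' @param normalize `"per_patch"` or `"raw"`.
#' @return K x K exactly symmetric nonnegative matrix with attribute
#'   `normalize`.
#' @export
interminglingMatrix <- function(graph, labels, K = max(labels),
                                normalize = c("per_patch", "raw")) {
  normalize <- match.arg(normalize)
  rois <- roiMembers(graph)
  comps <- lapply(rois, roiComposition, labels = labels, K = K)
  I <- matrix(0, K, K)
  e <- roiEdges(graph)
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      A <- edgeIntermingling(e$weight[r], comps[[e$i[r]]], comps[[e$j[r]]])
      I <- I + (A + t(A)) / 2
    }
  }
  if (normalize == "per_patch") I <- I / graph@nPatches^2
  attr(I, "normalize") <- normalize
  I
}

#' Tumor Invasion Score
#'
#' Extracts the tumor row of the slide-level intermingling matrix:
#' \eqn{TIS = I_{tumor}}. The tumor-tumor diagonal entry is included. Each
#' component quantifies how strongly the tumor intermingles with (invades)
#' that tissue sub-compartment on the slide.
#'
#' @param I intermingling matrix from [interminglingMatrix()].
#' @param tumorClass 1-based index of the tumor class.
#' @param classNames optional names for the returned vector.
#' @return numeric vector of length K.
#' @export
tumorInvasionScore <- function(I, tumorClass, classNames = NULL) {
  if (tumorClass < 1L || tumorClass > nrow(I)) stop("tumor class index out of range")
  tis <- I[tumorClass, ]
  if (!is.null(classNames)) names(tis) <- classNames
  tis
}

#' Per-slide TIS from predicted labels
#'
#' Convenience wrapper: Mapper graph on the contextualized embeddings, then
#' the per-patch-normalized intermingling matrix and its tumor row.
#'
#' @param Z patch embedding matrix of one slide.
#' @param labels predicted class label per patch.
#' @param K class count.
#' @param tumorClass tumor class index.
#' @param classNames optional class names.
#' @param ... passed to [buildMapperGraph()].
#' @return list with `tis`, `I`, and the `mapper` graph.
#' @export
slideTIS <- function(Z, labels, K, tumorClass, classNames = NULL, ...) {
  mg <- buildMapperGraph(Z, ...)
  I <- interminglingMatrix(mg, labels, K = K)
  list(tis = tumorInvasionScore(I, tumorClass, classNames), I = I, mapper = mg)
}
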