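#' @rdname WholeSlideGraph-class
#' @param object,x a `WholeSlideGraph` or `MapperGraph`
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("nodeAttributes", function(x) standardGeneric("nodeAttributes"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("nodeLabels<-", function(x, value) standardGeneric("nodeLabels<-"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname WholeSlideGraph-class
#' @export
setGeneric("classVocabulary", function(x) standardGeneric("classVocabulary"))

#' @rdname MapperGraph-class
#' @export
setGeneric("roiMembers", function(x) standardGeneric("roiMembers"))

#' @rdname MapperGraph-class
#' @export
setGeneric("roiEdges", function(x) standardGeneric("roiEdges"))

#' @rdname MapperGraph-class
#' @export
setGeneric("roiCount", function(x) standardGeneric("roiCount"))

setMethod("nodeCount", "WholeSlideGraph", function(x) nrow(x@coords))
setMethod("adjacencyMatrix", "WholeSlideGraph", function(x) x@adjacency)
setMethod("nodeAttributes", "WholeSlideGraph", function(x) x@attributes)
setMethod("nodeLabels", "WholeSlideGraph", function(x) x@labels)
setMethod("nodeLabels<-", "WholeSlideGraph", function(x, value) {
  x@labels <- if (is.null(value)) NULL else as.integer(value)
  validObject(x)
  x
})
setMethod("nodeCoords", "WholeSlideGraph", function(x) x@coords)
setMethod("slideId", "WholeSlideGraph", function(x) x@slideId)
setMethod("classVocabulary", "WholeSlideGraph", function(x) x@classNames)

setMethod("edgeList", "WholeSlideGraph", function(x) {
  A <- methods::as(methods::as(x@adjacency, "generalMatrix"), "TsparseMatrix")
  keep <- A@i < A@j
  cbind(i = A@i[keep] + 1L, j = A@j[keep] + 1L)
})

setMethod("edgeCount", "WholeSlideGraph", function(x) nrow(edgeList(x)))

setMethod("show", "WholeSlideGraph", function(object) {
  cat(sprintf(
    "WholeSlideGraph '%s': %d patches, %d edges, %d attribute dims%s\n",
    object@slideId, nodeCount(object), edgeCount(object),
    ncol(object@attributes),
    if (is.null(object@labels)) "" else sprintf(", %d classes", length(object@classNames))
  ))
})

setMethod("roiMembers", "MapperGraph", function(x) x@rois)
setMethod("roiEdges", "MapperGraph", function(x) x@edges)
setMethod("roiCount", "MapperGraph", function(x) length(x@rois))
setMethod("nodeCount", "MapperGraph", function(x) length(x@rois))

setMethod("show", "MapperGraph", function(object) {
  cat(sprintf(
    "MapperGraph: %d ROIs over %d patches, %d overlap edges\n",
    roiCount(object), object@nPatches, nrow(object@edges)
  ))
})

setMethod("show", "FittedNodeModel", function(object) {
  cat(sprintf(
    "FittedNodeModel: %d-class graph attention classifier (%d conv layers, hidden %d, %d heads)\n",
    length(object@classNames), object@config$n_conv_layers,
    object@config$hidden_dim, object@config$attention_heads
  ))
  if (nrow(object@trainLog)) {
    cat(sprintf(
      "  selected epoch %d / %d (validation weighted F1 = %.3f)\n",
      object@selectedEpoch, nrow(object@trainLog),
      object@trainLog$valF1[object@selectedEpoch]
    ))
  }
})

setMethod("show", "SyntheticCohort", function(object) {
  man <- object@manifest
  cat(sprintf(
    "SyntheticCohort: %d slides from %d patients (%d stage-positive, threshold %.2f)\n",
    nrow(man), length(unique(man$patient_id)), sum(man$stage), object@stageThreshold
  ))
})
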