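#' @importFrom data.table fwrite fread
NULL

#' Write / read a patch table
#'
#' CSV with columns `slide_id`, `row`, `col`, `class_label` (class names, not
#' indices). Reading restores the attributes needed downstream.
#'
#' @param grid labeled patch table (see [generateTissueLayout()]).
#' @param path file path.
#' @param classNames class vocabulary used to encode/decode `class_label`.
#' @return `writePatchTable`: the path, invisibly. `readPatchTable`: the patch
#'   table.
#' @export
writePatchTable <- function(grid, path, classNames = attr(grid, "classNames")) {
  df <- data.frame(
    slide_id = attr(grid, "slideId") %||% "slide",
    row = grid$row, col = grid$col,
    class_label = classNames[grid$label]
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writePatchTable
#' @export
readPatchTable <- function(path, classNames) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("slide_id", "row", "col", "class_label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("patch table %s is missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  lab <- match(df$class_label, classNames)
  if (anyNA(lab)) {
    stop(sprintf(
      "patch table %s has label(s) outside the vocabulary: %s",
      path, paste(unique(df$class_label[is.na(lab)]), collapse = ", ")
    ))
  }
  grid <- data.frame(row = df$row, col = df$col, label = lab)
  attr(grid, "classNames") <- classNames
  attr(grid, "dims") <- c(max(df$row) + 1L, max(df$col) + 1L)
  attr(grid, "slideId") <- df$slide_id[1L]
  grid
}

#' Write / read a dense numeric array
#'
#' Delimited text serialization of an embedding (attribute) matrix;
#' round-trips doubles bit-exactly.
#'
#' @param X numeric matrix.
#' @param path file path.
#' @return `writeArray`: the path, invisibly. `readArray`: the matrix.
#' @export
writeArray <- function(X, path) {
  # %.17g guarantees the shortest exact decimal round trip for doubles
  chars <- matrix(sprintf("%.17g", X), nrow(X), ncol(X))
  data.table::fwrite(as.data.frame(chars), path, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeArray
#' @export
readArray <- function(path) {
  unname(as.matrix(data.table::fread(path, header = FALSE)))
}

#' Write / read an edge list
#'
#' CSV with integer columns `i`, `j` (1-based, i < j).
#'
#' @param edges integer edge matrix.
#' @param path file path.
#' @export
writeEdgeList <- function(edges, path) {
  data.table::fwrite(as.data.frame(edges), path)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  e <- as.matrix(as.data.frame(data.table::fread(path)))
  storage.mode(e) <- "integer"
  colnames(e) <- c("i", "j")
  e
}

#' Convert a whole-slide graph to igraph
#'
#' Nodes carry `row`, `col` and (if present) `label`; useful for GraphML
#' export with [igraph::write_graph()].
#'
#' @param wsg a [WholeSlideGraph-class].
#' @return an igraph object.
#' @export
wsgToIgraph <- function(wsg) {
  g <- igraph::graph_from_edgelist(edgeList(wsg), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nodeCount(wsg) - igraph::vcount(g)))
  igraph::V(g)$row <- nodeCoords(wsg)[, 1L]
  igraph::V(g)$col <- nodeCoords(wsg)[, 2L]
  if (!is.null(nodeLabels(wsg))) igraph::V(g)$label_index <- nodeLabels(wsg)
  g
}

#' Export / import a Mapper graph
#'
#' `writeMapperGraphML` stores the ROI graph as GraphML with per-ROI
#' attributes (size, JSON-encoded patch ids and composition, lens center);
#' `writeMapperJSON` writes a plain JSON document with `nodes`
#' (`id`, `size`, `patches`, `center`, optional `composition`) and `edges`
#' (`source`, `target`, `weight`).
#'
#' @param graph a [MapperGraph-class].
#' @param path output file.
#' @param labels optional per-patch labels for composition annotation.
#' @param classNames optional class names.
#' @export
writeMapperGraphML <- function(graph, path, labels = NULL, classNames = NULL) {
  n <- roiCount(graph)
  e <- roiEdges(graph)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(e$i, e$j))
    igraph::E(g)$weight <- e$weight
  }
  igraph::V(g)$size <- lengths(roiMembers(graph))
  igraph::V(g)$patches <- vapply(
    roiMembers(graph),
    function(r) jsonlite::toJSON(r), ""
  )
  igraph::V(g)$center <- apply(graph@lensCenters, 1L, function(x) {
    jsonlite::toJSON(x)
  })
  if (!is.null(labels)) {
    K <- if (is.null(classNames)) max(labels) else length(classNames)
    igraph::V(g)$composition <- vapply(roiMembers(graph), function(r) {
      cnt <- tabulate(labels[r], nbins = K)
      names(cnt) <- classNames %||% paste0("class", seq_len(K))
      as.character(jsonlite::toJSON(as.list(cnt), auto_unbox = TRUE))
    }, "")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeMapperGraphML
#' @export
readMapperGraphML <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname writeMapperGraphML
#' @export
writeMapperJSON <- function(graph, path, labels = NULL, classNames = NULL) {
  nodes <- lapply(seq_len(roiCount(graph)), function(i) {
    nd <- list(
      id = i,
      size = length(roiMembers(graph)[[i]]),
      patches = roiMembers(graph)[[i]],
      center = as.numeric(graph@lensCenters[i, ])
    )
    if (!is.null(labels)) {
      K <- if (is.null(classNames)) max(labels) else length(classNames)
      cnt <- tabulate(labels[roiMembers(graph)[[i]]], nbins = K)
      names(cnt) <- classNames %||% paste0("class", seq_len(K))
      nd$composition <- as.list(cnt)
    }
    nd
  })
  e <- roiEdges(graph)
  edges <- lapply(seq_len(nrow(e)), function(r) {
    list(source = e$i[r], target = e$j[r], weight = e$weight[r])
  })
  jsonlite::write_json(
    list(nodes = nodes, edges = edges, n_patches = graph@nPatches),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
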