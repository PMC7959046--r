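#' Spatial k-nearest-neighbor edges between patches
#'
#' For every patch, edges to its `k` nearest neighbors under the Euclidean
#' metric on `(row, col)` grid coordinates; the directed neighbor lists are
#' symmetrized by union, so every node ends with degree >= k. Distance ties are
#' broken toward the lower patch index, which makes the edge set deterministic
#' on regular grids.
#'
#' @param coords integer matrix (m x 2) of 0-based `(row, col)` positions.
#' @param k positive integer, neighbors per node; must satisfy `k < m`.
#' @return integer matrix with columns `i`, `j` (1-based, i < j), one row per
#'   undirected edge.
#' @export
knnEdges <- function(coords, k = 8L) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (k >= m) stop(sprintf("k (%d) must be smaller than the patch count (%d)", k, m))
  D <- as.matrix(stats::dist(coords))
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(m)) {
    ord <- order(D[i, -i], seq_len(m)[-i])[seq_len(k)]
    nb <- seq_len(m)[-i][ord]
    from <- c(from, rep.int(i, k))
    to <- c(to, nb)
  }
  canonicalEdges(from, to)
}

#' Radius-neighbor edges between patches
#'
#' Edge between two patches iff their Euclidean grid distance is at most `r`.
#' On a unit grid, `r = 1` gives rook (4-neighbor) adjacency and `r = 1.5`
#' gives queen (8-neighbor) adjacency.
#'
#' @inheritParams knnEdges
#' @param r positive radius in patch units.
#' @return integer edge matrix as in [knnEdges()].
#' @export
radiusEdges <- function(coords, r) {
  if (r <= 0) stop("radius must be positive")
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  idx <- which(D <= r & upper.tri(D), arr.ind = TRUE)
  canonicalEdges(idx[, 1L], idx[, 2L])
}

# Deduplicated undirected edge matrix with i < j, sorted, self-edges dropped.
canonicalEdges <- function(from, to) {
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  e <- unique(cbind(i = lo, j = hi))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}

#' Assemble a whole-slide graph
#'
#' Combines a patch table, an embedding (attribute) matrix and an edge set
#' into a validated [WholeSlideGraph-class]: sparse symmetric binary adjacency
#' with zero diagonal, dense attribute matrix `X`, and optional per-patch
#' labels.
#'
#' @param grid patch table with 0-based `row`, `col` columns (and optionally a
#'   `label` column) as produced by [generateTissueLayout()], or a plain
#'   data.frame with those columns.
#' @param X numeric attribute matrix, one row per patch.
#' @param edges integer edge matrix (columns `i`, `j`, 1-based); duplicates
#'   and orientation are normalized.
#' @param classNames class vocabulary for the labels.
#' @return a [WholeSlideGraph-class].
#' @export
assembleWSG <- function(grid, X, edges,
                        classNames = attr(grid, "classNames") %||% character()) {
  coords <- as.matrix(grid[, c("row", "col")])
  storage.mode(coords) <- "integer"
  m <- nrow(coords)
  X <- as.matrix(X)
  if (nrow(X) != m) {
    stop(sprintf("attribute matrix has %d rows but the grid has %d patches", nrow(X), m))
  }
  if (length(edges)) {
    edges <- canonicalEdges(edges[, 1L], edges[, 2L])
    A <- Matrix::sparseMatrix(
      i = c(edges[, 1L], edges[, 2L]), j = c(edges[, 2L], edges[, 1L]),
      x = 1, dims = c(m, m)
    )
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(m, m))
  }
  labels <- if ("label" %in% names(grid)) as.integer(grid$label) else NULL
  methods::new("WholeSlideGraph",
    slideId = as.character(attr(grid, "slideId") %||% "slide"),
    coords = coords,
    patchPx = as.integer(attr(grid, "patchPx") %||% 256L),
    adjacency = A,
    attributes = X,
    labels = labels,
    classNames = as.character(classNames)
  )
}

#' Build the whole-slide graph of one simulated slide
#'
#' Convenience wrapper: spatial kNN edges on the patch grid plus
#' [assembleWSG()].
#'
#' @param slide list with `grid` and `X` as returned by [simulateSlide()].
#' @param k spatial neighbors per patch (default 8, the queen-adjacency
#'   analogue on a square tiling).
#' @return a [WholeSlideGraph-class].
#' @export
buildSlideGraph <- function(slide, k = 8L) {
  assembleWSG(slide$grid, slide$X, knnEdges(slide$grid[, c("row", "col")], k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
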