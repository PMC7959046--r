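#' Lens (filter) projection of patch embeddings
#'
#' Projects the point cloud of contextualized patch embeddings to a
#' low-dimensional lens space that organizes the Mapper cover. `pca` (the
#' default) is deterministic; component signs are fixed so the largest-
#' magnitude loading of each component is positive. `first_dims` simply takes
#' the leading `d` columns.
#'
#' @param Z numeric m x h embedding matrix.
#' @param method `"pca"` or `"first_dims"`.
#' @param d lens dimension (1 or 2; default 2).
#' @param seed unused for the deterministic methods; kept for interface
#'   stability.
#' @return m x d lens matrix with attribute `method`.
#' @export
computeLens <- function(Z, method = c("pca", "first_dims"), d = 2L, seed = 1L) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  if (nrow(Z) < d) stop("need at least d points")
  if (d < 1L || d > ncol(Z)) stop("lens dimension out of range")
  lens <- switch(method,
    pca = {
      sds <- apply(Z, 2L, stats::sd)
      if (all(sds == 0)) stop("degenerate projection: embeddings are constant")
      pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
      rot <- pc$rotation[, seq_len(d), drop = FALSE]
      for (j in seq_len(d)) { # deterministic sign convention
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) rot[, j] <- -rot[, j]
      }
      scale(Z, center = pc$center, scale = FALSE) %*% rot
    },
    first_dims = Z[, seq_len(d), drop = FALSE]
  )
  lens <- unname(as.matrix(lens))
  if (!all(is.finite(lens))) stop("lens values must be finite")
  attr(lens, "method") <- method
  lens
}

#' Overlapping box cover of the lens space
#'
#' Along each lens axis the range is divided into `nIntervals` equal-width
#' closed intervals with fractional overlap `g`: the box width is
#' `range / (n - (n - 1) * g)` and box `i` starts at
#' `min + i * (1 - g) * width`. Boxes of a multi-dimensional lens are the
#' cross-product of the per-axis intervals; membership is by closed-interval
#' containment, so boundary points belong to both adjacent boxes and every
#' point is covered. An axis with zero range collapses to a single interval.
#'
#' @param lens m x d lens matrix.
#' @param nIntervals intervals per axis (>= 1).
#' @param g overlap fraction in \[0, 1).
#' @return list of cover sets, each a list with `bounds` (d x 2 matrix of
#'   closed interval limits) and `members` (integer patch indices); empty sets
#'   are dropped.
#' @export
buildCover <- function(lens, nIntervals = 10L, g = 0.3) {
  if (nIntervals < 1L) stop("nIntervals must be at least 1")
  if (g < 0 || g >= 1) stop("overlap fraction g must lie in [0, 1)")
  lens <- as.matrix(lens)
  d <- ncol(lens)
  axisIntervals <- vector("list", d)
  for (ax in seq_len(d)) {
    lo <- min(lens[, ax])
    hi <- max(lens[, ax])
    if (hi == lo) {
      axisIntervals[[ax]] <- matrix(c(lo, hi), 1L, 2L)
      next
    }
    n <- nIntervals
    width <- (hi - lo) / (n - (n - 1) * g)
    starts <- lo + (0:(n - 1)) * (1 - g) * width
    iv <- cbind(starts, starts + width)
    # guard the outermost bounds against rounding so the extremes stay covered
    iv[1L, 1L] <- lo
    iv[n, 2L] <- max(iv[n, 2L], hi)
    axisIntervals[[ax]] <- iv
  }
  combos <- expand.grid(lapply(axisIntervals, function(iv) seq_len(nrow(iv))))
  sets <- list()
  for (r in seq_len(nrow(combos))) {
    inBox <- rep(TRUE, nrow(lens))
    bounds <- matrix(NA_real_, d, 2L)
    for (ax in seq_len(d)) {
      iv <- axisIntervals[[ax]][combos[r, ax], ]
      bounds[ax, ] <- iv
      inBox <- inBox & lens[, ax] >= iv[1L] & lens[, ax] <= iv[2L]
    }
    members <- which(inBox)
    if (length(members)) sets[[length(sets) + 1L]] <- list(bounds = bounds, members = members)
  }
  sets
}

#' Cluster the patches of one cover set
#'
#' Agglomerative clustering (default single linkage) in the full embedding
#' space restricted to the cover set, cut at the first gap of the
#' linkage-distance histogram: the merge heights are binned into `histBins` equal-width bins
#' spanning the observed heights; the cut threshold is the lower edge of the
#' first empty bin.
#' If the histogram has no empty bin (or the set has fewer than 3 members or
#' zero spread) the set forms a single cluster.
#'
#' @param members integer patch indices of the cover set.
#' @param Z full embedding matrix.
#' @param histBins number of histogram bins for the gap heuristic (default 10).
#' @param linkage agglomeration method passed to [stats::hclust()]; `"single"`
#'   (default) follows the classical Mapper recipe, `"average"` resists the
#'   chaining of transition patches into mixed clusters.
#' @return list of integer vectors partitioning `members`.
#' @export
clusterCoverSet <- function(members, Z, histBins = 10L, linkage = "single") {
  if (!length(members)) stop("cover set is empty")
  if (length(members) == 1L) return(list(members))
  D <- stats::dist(Z[members, , drop = FALSE])
  if (max(D) == 0) return(list(members))
  hc <- stats::hclust(D, method = linkage)
  heights <- hc$height
  if (max(heights) == min(heights)) return(list(members))
  breaks <- seq(min(heights), max(heights), length.out = histBins + 1L)
  counts <- graphics::hist(heights, breaks = breaks, plot = FALSE)$counts
  empty <- which(counts == 0L)
  if (!length(empty)) return(list(members))
  thr <- breaks[empty[1L]]
  cl <- stats::cutree(hc, h = thr)
  lapply(split(seq_along(members), cl), function(ix) members[ix])
}

#' Build the Mapper graph of regions of interest
#'
#' Runs the full Mapper pipeline on a point cloud of patch embeddings:
#' lens projection, overlapping box cover, per-set clustering; each resulting
#' cluster is one ROI, and two ROIs are connected iff they share at least one
#' patch, with edge weight equal to the shared-patch count.
#'
#' @param Z m x h embedding matrix (typically from [extractEmbeddings()]).
#' @param lensMethod,lensDim arguments to [computeLens()].
#' @param nIntervals,g arguments to [buildCover()].
#' @param histBins,linkage arguments to [clusterCoverSet()].
#' @param seed seed forwarded to the lens (unused by deterministic lenses).
#' @return a [MapperGraph-class].
#' @export
buildMapperGraph <- function(Z, lensMethod = "pca", lensDim = 2L,
                             nIntervals = 10L, g = 0.3, histBins = 10L,
                             linkage = "single", seed = 1L) {
  Z <- as.matrix(Z)
  if (!nrow(Z)) stop("empty embedding input")
  lens <- computeLens(Z, method = lensMethod, d = lensDim, seed = seed)
  cover <- buildCover(lens, nIntervals = nIntervals, g = g)
  rois <- list()
  for (cs in cover) {
    cl <- clusterCoverSet(cs$members, Z, histBins = histBins, linkage = linkage)
    rois <- c(rois, cl)
  }
  rois <- lapply(rois, function(r) sort(as.integer(r)))
  n <- length(rois)
  ei <- integer(0)
  ej <- integer(0)
  ew <- integer(0)
  if (n > 1L) {
    # invert membership: patches -> ROIs, then count co-memberships
    roiOf <- rep.int(seq_len(n), lengths(rois))
    patch <- unlist(rois)
    byPatch <- split(roiOf, patch)
    pairCount <- new.env(hash = TRUE)
    for (rs in byPatch) {
      if (length(rs) < 2L) next
      rs <- sort(rs)
      for (a in seq_len(length(rs) - 1L)) {
        for (b in (a + 1L):length(rs)) {
          key <- paste0(rs[a], "_", rs[b])
          pairCount[[key]] <- (pairCount[[key]] %||% 0L) + 1L
        }
      }
    }
    keys <- ls(pairCount)
    if (length(keys)) {
      parts <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
      ei <- as.integer(parts[, 1L])
      ej <- as.integer(parts[, 2L])
      ew <- vapply(keys, function(k) pairCount[[k]], 0L, USE.NAMES = FALSE)
      o <- order(ei, ej)
      ei <- ei[o]
      ej <- ej[o]
      ew <- ew[o]
    }
  }
  centers <- do.call(rbind, lapply(rois, function(r) colMeans(lens[r, , drop = FALSE])))
  methods::new("MapperGraph",
    rois = rois,
    edges = data.frame(i = ei, j = ej, weight = as.numeric(ew)),
    lensCenters = unname(as.matrix(centers)),
    nPatches = nrow(Z)
  )
}

#' Per-ROI tissue composition and slide layout
#'
#' For every Mapper ROI, the percentage make-up over tissue classes (from the
#' per-patch labels) and the center of mass of its patches in slide
#' coordinates.
#'
#' @param graph a [MapperGraph-class].
#' @param labels integer class label per patch (1-based).
#' @param coords optional m x 2 patch coordinate matrix for the spatial center
#'   of mass.
#' @param classNames optional class names for the percentage columns.
#' @return data.frame with one row per ROI: `roi`, `size`, `center_row`,
#'   `center_col` (if coords given) and one percentage column per class
#'   (summing to 100 per ROI).
#' @export
summarizeRois <- function(graph, labels, coords = NULL, classNames = NULL) {
  K <- if (is.null(classNames)) max(labels) else length(classNames)
  if (is.null(classNames)) classNames <- paste0("class", seq_len(K))
  rois <- roiMembers(graph)
  out <- data.frame(roi = seq_along(rois), size = lengths(rois))
  if (!is.null(coords)) {
    cm <- do.call(rbind, lapply(rois, function(r) colMeans(coords[r, , drop = FALSE])))
    out$center_row <- cm[, 1L]
    out$center_col <- cm[, 2L]
  }
  pct <- do.call(rbind, lapply(rois, function(r) {
    cnt <- tabulate(labels[r], nbins = K)
    100 * cnt / sum(cnt)
  }))
  colnames(pct) <- paste0("pct_", classNames)
  cbind(out, as.data.frame(pct))
}
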