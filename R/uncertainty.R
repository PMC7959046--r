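#' Monte-Carlo posterior draws of patch class probabilities
#'
#' Runs `T` forward passes of a fitted node classifier with its stochastic
#' layers (Dropout, DropEdge) left active, approximating draws from the
#' predictive posterior of the patch-level categorical distribution.
#' Reproducible under `seed`.
#'
#' @param model a [FittedNodeModel-class] with nonzero `dropout_p` or
#'   `dropedge_p`.
#' @param graph a [WholeSlideGraph-class].
#' @param T number of draws (>= 2; default 20).
#' @param seed integer seed.
#' @return a [PosteriorDraws-class] (`T x m x K` array).
#' @export
posteriorDraws <- function(model, graph, T = 20L, seed = 1L) {
  if (T < 2L) stop("at least 2 posterior draws are required")
  cfg <- structure(model@config, class = "GATConfig")
  if (cfg$dropout_p == 0 && cfg$dropedge_p == 0) {
    stop("draws are degenerate: model has dropout_p = 0 and dropedge_p = 0")
  }
  checkPredictInput(model, graph)
  X <- nodeAttributes(graph)
  edges <- edgeList(graph)
  m <- nrow(X)
  K <- length(model@classNames)
  draws <- array(NA_real_, c(T, m, K))
  set.seed(as.integer(seed))
  for (t in seq_len(T)) {
    draws[t, , ] <- gatForward(model@params, cfg, X, edges, stochastic = TRUE)$probs
  }
  methods::new("PosteriorDraws", draws = draws, seed = as.integer(seed))
}

#' Per-patch uncertainty from posterior draws
#'
#' Two uncertainty summaries per patch: the predictive variance (mean over
#' classes of the across-draw sample variance of the class probability) and
#' the entropy \eqn{-\sum_k \bar p_k \log \bar p_k} of the across-draw mean
#' probability vector (natural log, so entropy lies in \[0, log K\]).
#'
#' @param draws a [PosteriorDraws-class].
#' @return list with numeric vectors `variance`, `entropy`, and the `meanProbs`
#'   matrix the entropy was computed from.
#' @export
uncertaintyScores <- function(draws) {
  d <- draws@draws
  meanP <- apply(d, c(2L, 3L), mean)
  varP <- apply(d, c(2L, 3L), stats::var)
  entropy <- -rowSums(ifelse(meanP > 0, meanP * log(meanP), 0))
  list(
    variance = rowMeans(varP),
    entropy = pmin(pmax(entropy, 0), log(ncol(meanP))),
    meanProbs = meanP
  )
}

#' Prune uncertain patch labels and propagate from confident neighbors
#'
#' Patches whose entropy exceeds the `pruneQuantile` quantile lose their hard
#' label; remaining labels are then spread by synchronous neighbor-majority
#' voting over the whole-slide graph (ties keep the current label if one
#' exists, otherwise take the lowest class index) until no label changes or
#' `maxIters` sweeps. Patches that were not pruned are never relabeled. Pruned
#' patches that remain unreachable (no labeled neighbor in their component)
#' fall back to their original label with a warning.
#'
#' @param graph a [WholeSlideGraph-class].
#' @param hardLabels integer vector of current hard class labels (1-based).
#' @param scores output of [uncertaintyScores()] (its `entropy` is used).
#' @param pruneQuantile quantile of the entropy distribution above which
#'   labels are pruned, in (0, 1); default 0.9.
#' @param maxIters maximum propagation sweeps (default 20).
#' @return integer vector of refined labels, with attribute `pruned` (logical).
#' @export
pruneAndPropagate <- function(graph, hardLabels, scores, pruneQuantile = 0.9,
                              maxIters = 20L) {
  if (pruneQuantile <= 0 || pruneQuantile >= 1) stop("pruneQuantile must lie in (0, 1)")
  m <- nodeCount(graph)
  stopifnot(length(hardLabels) == m)
  entropy <- scores$entropy
  thr <- stats::quantile(entropy, pruneQuantile, names = FALSE)
  pruned <- entropy > thr
  if (all(pruned)) stop("all nodes pruned; nothing to propagate from")
  labels <- as.integer(hardLabels)
  labels[pruned] <- NA_integer_
  de <- directedEdges(edgeList(graph))
  K <- max(hardLabels)
  for (iter in seq_len(maxIters)) {
    changed <- FALSE
    newLabels <- labels
    # votes: count labeled neighbors per class for every pruned node
    src <- de$src
    dst <- de$dst
    ok <- !is.na(labels[src]) & pruned[dst]
    if (any(ok)) {
      votes <- matrix(0L, m, K)
      tab <- table(factor(dst[ok], levels = seq_len(m)), factor(labels[src[ok]], levels = seq_len(K)))
      votes <- matrix(as.integer(tab), m, K)
      for (i in which(pruned)) {
        v <- votes[i, ]
        if (sum(v) == 0L) next
        top <- which(v == max(v))
        if (length(top) == 1L) {
          cand <- top
        } else if (!is.na(labels[i]) && labels[i] %in% top) {
          cand <- labels[i] # tie: keep current label when it is among the modes
        } else {
          cand <- min(top) # tie, unlabeled: lowest class index
        }
        if (is.na(labels[i]) || cand != labels[i]) {
          newLabels[i] <- cand
          changed <- TRUE
        }
      }
    }
    labels <- newLabels
    if (!changed) break
  }
  stranded <- is.na(labels)
  if (any(stranded)) {
    warning(sprintf(
      "%d pruned node(s) had no labeled neighbor; original labels retained",
      sum(stranded)
    ))
    labels[stranded] <- as.integer(hardLabels)[stranded]
  }
  attr(labels, "pruned") <- pruned
  labels
}
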