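#' Node-wise multinomial baseline classifier
#'
#' Context-free reference model: multinomial logistic regression on the raw
#' patch embeddings, ignoring the graph. The gap between this baseline and the
#' graph attention classifier quantifies the benefit of neighborhood context.
#'
#' @param trainGraphs list of labeled [WholeSlideGraph-class] objects.
#' @param maxit optimizer iterations (default 200).
#' @return an object of class `NodeBaseline`.
#' @export
fitNodeBaseline <- function(trainGraphs, maxit = 200L) {
  X <- do.call(rbind, lapply(trainGraphs, nodeAttributes))
  y <- unlist(lapply(trainGraphs, nodeLabels))
  vocab <- classVocabulary(trainGraphs[[1L]])
  df <- data.frame(y = factor(y, levels = seq_along(vocab)), X)
  # classes absent from the training pool are expected (deep slides lose
  # superficial layers); predictBaseline maps the fitted columns back
  capture.output(withCallingHandlers(
    fit <- nnet::multinom(y ~ ., data = df, maxit = maxit, MaxNWts = 1e5, trace = FALSE),
    warning = function(w) {
      if (grepl("empty", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  ))
  structure(list(fit = fit, classNames = vocab, inputDim = ncol(X)), class = "NodeBaseline")
}

#' @rdname fitNodeBaseline
#' @param baseline a fitted `NodeBaseline`.
#' @param graph a [WholeSlideGraph-class].
#' @return `predictBaseline`: m x K probability matrix.
#' @export
predictBaseline <- function(baseline, graph) {
  X <- nodeAttributes(graph)
  stopifnot(ncol(X) == baseline$inputDim)
  p <- stats::predict(baseline$fit, newdata = data.frame(X), type = "probs")
  p <- as.matrix(p)
  if (ncol(p) == 1L) p <- cbind(1 - p, p) # two-class degenerate shape
  K <- length(baseline$classNames)
  full <- matrix(0, nrow(X), K)
  seen <- as.integer(baseline$fit$lev) # factor levels in training order
  full[, seen] <- p[, seq_along(seen)]
  full
}
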