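#' Graph attention network configuration
#'
#' Hyperparameters of the patch-level node classifier: a stack of graph
#' attention convolutions interspersed with ReLU and DropEdge, followed by one
#' Dropout layer and a linear layer with SoftMax activation. Heads are
#' concatenated between convolutions and averaged at the last convolution, so
#' the penultimate representation (the contextualized patch embedding) has
#' `hidden_dim` columns.
#'
#' @param n_conv_layers number of graph attention layers (default 4).
#' @param hidden_dim per-head output dimension of each convolution.
#' @param attention_heads attention heads per convolution.
#' @param dropedge_p probability of dropping each undirected edge per
#'   convolution during stochastic forward passes, in \[0, 1).
#' @param dropout_p dropout probability on the penultimate embedding, in \[0, 1).
#' @param learning_rate Adam learning rate.
#' @param max_epochs training epochs.
#' @param seed integer seed controlling initialization and stochastic layers.
#' @param aggregate neighbor aggregation of attention-weighted messages:
#'   `"mean"` (default; the softmax attention weights already sum to one per
#'   node, so the weighted sum is a weighted mean and is degree-robust),
#'   `"sum"` (degree-scaled), or `"max"` (elementwise).
#' @return list of class `GATConfig`.
#' @export
gatConfig <- function(n_conv_layers = 4L, hidden_dim = 64L, attention_heads = 4L,
                      dropedge_p = 0.2, dropout_p = 0.1,
                      learning_rate = 1e-3, max_epochs = 50L, seed = 1L,
                      aggregate = c("mean", "sum", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(
    n_conv_layers >= 1, hidden_dim >= 1, attention_heads >= 1,
    dropedge_p >= 0, dropedge_p < 1, dropout_p >= 0, dropout_p < 1,
    learning_rate > 0, max_epochs >= 1
  )
  structure(
    list(
      n_conv_layers = as.integer(n_conv_layers),
      hidden_dim = as.integer(hidden_dim),
      attention_heads = as.integer(attention_heads),
      dropedge_p = dropedge_p, dropout_p = dropout_p,
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      seed = as.integer(seed), aggregate = aggregate
    ),
    class = "GATConfig"
  )
}

# --- low-level helpers -------------------------------------------------------

# Scatter-add a per-edge matrix into m node rows grouped by idx.
scatterAdd <- function(m, mat, idx) {
  out <- matrix(0, m, ncol(mat))
  if (length(idx)) {
    rs <- rowsum(mat, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# Per-group maximum of x grouped by g (groups 1..m); -Inf for empty groups.
groupMax <- function(x, g, m) {
  out <- rep(-Inf, m)
  if (length(x)) {
    o <- order(g, x)
    gg <- g[o]
    last <- c(gg[-1L] != gg[-length(gg)], TRUE)
    out[gg[last]] <- x[o][last]
  }
  out
}

leakySlope <- 0.2

# Directed edge arrays (both orientations) from an undirected edge matrix.
directedEdges <- function(edges) {
  list(src = c(edges[, 2L], edges[, 1L]), dst = c(edges[, 1L], edges[, 2L]))
}

initGATParams <- function(inputDim, K, config) {
  glorot <- function(din, dout) {
    lim <- sqrt(6 / (din + dout))
    matrix(stats::runif(din * dout, -lim, lim), din, dout)
  }
  L <- config$n_conv_layers
  H <- config$attention_heads
  hd <- config$hidden_dim
  layers <- vector("list", L)
  din <- inputDim
  for (l in seq_len(L)) {
    heads <- vector("list", H)
    for (h in seq_len(H)) {
      heads[[h]] <- list(
        W = glorot(din, hd),
        aSrc = stats::runif(hd, -sqrt(3 / hd), sqrt(3 / hd)),
        aDst = stats::runif(hd, -sqrt(3 / hd), sqrt(3 / hd)),
        b = rep(0, hd)
      )
    }
    layers[[l]] <- heads
    din <- if (l < L) hd * H else hd
  }
  list(layers = layers, Wout = glorot(hd, K), bout = rep(0, K))
}

# One graph attention head: self transform + attention-softmax-weighted
# neighbor aggregation; empty neighborhoods aggregate to the zero vector.
headForward <- function(Hin, head, src, dst, m, aggregate) {
  P <- Hin %*% head$W
  d <- ncol(P)
  if (length(src)) {
    s <- as.vector(P[src, , drop = FALSE] %*% head$aSrc) +
      as.vector(P[dst, , drop = FALSE] %*% head$aDst)
    sHat <- ifelse(s > 0, s, leakySlope * s)
    mx <- groupMax(sHat, dst, m)
    ex <- exp(sHat - mx[dst])
    denom <- scatterAdd(m, cbind(ex), dst)[, 1L]
    alpha <- ex / denom[dst]
    msg <- alpha * P[src, , drop = FALSE]
    deg <- tabulate(dst, nbins = m)
    # the attention weights are softmax-normalized per node, so their weighted
    # sum is already a weighted mean of the neighbor messages
    agg <- switch(aggregate,
      mean = scatterAdd(m, msg, dst),
      sum = scatterAdd(m, msg, dst) * pmax(deg, 1L),
      max = {
        a <- matrix(0, m, d)
        for (col in seq_len(d)) {
          mxc <- groupMax(msg[, col], dst, m)
          a[, col] <- ifelse(is.finite(mxc), mxc, 0)
        }
        a
      }
    )
  } else {
    sHat <- numeric(0)
    alpha <- numeric(0)
    deg <- integer(m)
    agg <- matrix(0, m, d)
  }
  out <- P + agg
  out <- sweep(out, 2L, head$b, "+")
  list(out = out, P = P, sHat = sHat, alpha = alpha, deg = deg)
}

headBackward <- function(dOut, cache, Hin, head, src, dst, m, aggregate) {
  P <- cache$P
  d <- ncol(P)
  db <- colSums(dOut)
  dP <- dOut
  if (length(src)) {
    alpha <- cache$alpha
    deg <- cache$deg
    scale <- switch(aggregate,
      mean = rep(1, length(src)),
      sum = pmax(deg, 1L)[dst],
      max = NULL
    )
    if (aggregate == "max") {
      # route gradient to the (first) argmax message per (node, dim)
      msg <- alpha * P[src, , drop = FALSE]
      dmsg <- matrix(0, length(src), d)
      for (col in seq_len(d)) {
        mxc <- groupMax(msg[, col], dst, m)
        sel <- which(msg[, col] == mxc[dst])
        if (length(sel)) {
          sel <- sel[!duplicated(dst[sel])]
          dmsg[sel, col] <- dOut[dst[sel], col]
        }
      }
    } else {
      dmsg <- dOut[dst, , drop = FALSE] * scale
    }
    dalpha <- rowSums(dmsg * P[src, , drop = FALSE])
    dP <- dP + scatterAdd(m, alpha * dmsg, src)
    # softmax backward (grouped by dst)
    Ssum <- scatterAdd(m, cbind(alpha * dalpha), dst)[, 1L]
    ds <- alpha * (dalpha - Ssum[dst])
    dsHat <- ds * ifelse(cache$sHat > 0, 1, leakySlope)
    daSrc <- colSums(dsHat * P[src, , drop = FALSE])
    daDst <- colSums(dsHat * P[dst, , drop = FALSE])
    dP <- dP + scatterAdd(m, outer(dsHat, head$aSrc), src)
    dP <- dP + scatterAdd(m, outer(dsHat, head$aDst), dst)
  } else {
    daSrc <- rep(0, d)
    daDst <- rep(0, d)
  }
  dW <- crossprod(Hin, dP)
  dHin <- dP %*% t(head$W)
  list(dW = dW, daSrc = daSrc, daDst = daDst, db = db, dHin = dHin)
}

# Full forward pass. stochastic=TRUE activates DropEdge (per layer) and
# Dropout (before the linear head); caches are kept when backprop=TRUE.
gatForward <- function(params, config, X, edges, stochastic = FALSE,
                       backprop = FALSE) {
  m <- nrow(X)
  L <- config$n_conv_layers
  H <- config$attention_heads
  caches <- if (backprop) vector("list", L) else NULL
  Hcur <- X
  layerEdges <- vector("list", L)
  for (l in seq_len(L)) {
    e <- edges
    if (stochastic && config$dropedge_p > 0 && nrow(e)) {
      keep <- stats::runif(nrow(e)) >= config$dropedge_p
      e <- e[keep, , drop = FALSE]
    }
    de <- directedEdges(e)
    layerEdges[[l]] <- de
    outs <- vector("list", H)
    hcaches <- if (backprop) vector("list", H) else NULL
    for (h in seq_len(H)) {
      r <- headForward(Hcur, params$layers[[l]][[h]], de$src, de$dst, m, config$aggregate)
      outs[[h]] <- r$out
      if (backprop) hcaches[[h]] <- r[c("P", "sHat", "alpha", "deg")]
    }
    if (l < L) {
      comb <- do.call(cbind, outs)
      act <- pmax(comb, 0)
      if (backprop) caches[[l]] <- list(Hin = Hcur, heads = hcaches, comb = comb)
      Hcur <- act
    } else {
      comb <- Reduce(`+`, outs) / H
      if (backprop) caches[[l]] <- list(Hin = Hcur, heads = hcaches, comb = NULL)
      Hcur <- comb
    }
  }
  Z <- Hcur # contextualized embeddings z*
  dropMask <- NULL
  Zd <- Z
  if (stochastic && config$dropout_p > 0) {
    dropMask <- matrix(
      stats::rbinom(length(Z), 1L, 1 - config$dropout_p) / (1 - config$dropout_p),
      nrow(Z), ncol(Z)
    )
    Zd <- Z * dropMask
  }
  logits <- sweep(Zd %*% params$Wout, 2L, params$bout, "+")
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(
    probs = probs, Z = Z, Zd = Zd, logits = logits, caches = caches,
    layerEdges = layerEdges, dropMask = dropMask
  )
}

# Backward pass of mean cross-entropy on `labels` (1-based); returns gradients
# shaped like params.
gatBackward <- function(params, config, X, fwd, labels) {
  m <- nrow(X)
  K <- ncol(fwd$probs)
  L <- config$n_conv_layers
  H <- config$attention_heads
  Y <- matrix(0, m, K)
  Y[cbind(seq_len(m), labels)] <- 1
  dLogits <- (fwd$probs - Y) / m
  gWout <- crossprod(fwd$Zd, dLogits)
  gbout <- colSums(dLogits)
  dZ <- dLogits %*% t(params$Wout)
  if (!is.null(fwd$dropMask)) dZ <- dZ * fwd$dropMask
  grads <- vector("list", L)
  dH <- dZ
  for (l in rev(seq_len(L))) {
    cache <- fwd$caches[[l]]
    de <- fwd$layerEdges[[l]]
    hd <- config$hidden_dim
    if (l < L) {
      dComb <- dH * (cache$comb > 0)
      dOuts <- lapply(seq_len(H), function(h) {
        dComb[, ((h - 1L) * hd + 1L):(h * hd), drop = FALSE]
      })
    } else {
      dOuts <- rep(list(dH / H), H)
    }
    gHeads <- vector("list", H)
    dHin <- matrix(0, m, ncol(cache$Hin))
    for (h in seq_len(H)) {
      bk <- headBackward(
        dOuts[[h]], cache$heads[[h]], cache$Hin,
        params$layers[[l]][[h]], de$src, de$dst, m, config$aggregate
      )
      gHeads[[h]] <- bk[c("dW", "daSrc", "daDst", "db")]
      dHin <- dHin + bk$dHin
    }
    grads[[l]] <- gHeads
    dH <- dHin
  }
  list(layers = grads, Wout = gWout, bout = gbout)
}

# --- Adam over the nested parameter list ------------------------------------

flattenParams <- function(p) {
  out <- list()
  for (l in seq_along(p$layers)) {
    for (h in seq_along(p$layers[[l]])) {
      for (nm in c("W", "aSrc", "aDst", "b")) {
        out[[sprintf("L%d.H%d.%s", l, h, nm)]] <- p$layers[[l]][[h]][[nm]]
      }
    }
  }
  out$Wout <- p$Wout
  out$bout <- p$bout
  out
}

flattenGrads <- function(g) {
  out <- list()
  for (l in seq_along(g$layers)) {
    for (h in seq_along(g$layers[[l]])) {
      map <- c(W = "dW", aSrc = "daSrc", aDst = "daDst", b = "db")
      for (nm in names(map)) {
        out[[sprintf("L%d.H%d.%s", l, h, nm)]] <- g$layers[[l]][[h]][[map[[nm]]]]
      }
    }
  }
  out$Wout <- g$Wout
  out$bout <- g$bout
  out
}

unflattenParams <- function(flat, template) {
  for (l in seq_along(template$layers)) {
    for (h in seq_along(template$layers[[l]])) {
      for (nm in c("W", "aSrc", "aDst", "b")) {
        template$layers[[l]][[h]][[nm]] <- flat[[sprintf("L%d.H%d.%s", l, h, nm)]]
      }
    }
  }
  template$Wout <- flat$Wout
  template$bout <- flat$bout
  template
}

adamInit <- function(flat) {
  list(
    m = lapply(flat, function(x) x * 0),
    v = lapply(flat, function(x) x * 0),
    t = 0L
  )
}

adamStep <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# --- user-facing API ---------------------------------------------------------

#' Fit the graph attention node classifier
#'
#' Trains the patch-level tissue classifier by backpropagation of the mean
#' cross-entropy loss, one whole-slide graph per optimization step, with
#' DropEdge active per convolution and Dropout before the linear head during
#' training only. After every epoch the weighted F1 on the validation graphs
#' is computed (stochastic layers off) and the parameters of the best
#' validation epoch are retained.
#'
#' @param trainGraphs list of labeled [WholeSlideGraph-class] objects.
#' @param valGraphs list of labeled validation graphs.
#' @param config a [gatConfig()].
#' @return a [FittedNodeModel-class].
#' @export
fitNodeClassifier <- function(trainGraphs, valGraphs, config = gatConfig()) {
  if (!length(trainGraphs)) stop("no training graphs")
  dims <- vapply(c(trainGraphs, valGraphs), function(g) ncol(nodeAttributes(g)), 0L)
  if (length(unique(dims)) != 1L) stop("all graphs must share the attribute dimension")
  vocab <- classVocabulary(trainGraphs[[1L]])
  for (g in c(trainGraphs, valGraphs)) {
    if (!identical(classVocabulary(g), vocab)) stop("all graphs must share the class vocabulary")
    if (is.null(nodeLabels(g))) stop("all graphs must be labeled")
  }
  K <- length(vocab)
  inputDim <- dims[1L]
  set.seed(config$seed)
  params <- initGATParams(inputDim, K, config)
  flat <- flattenParams(params)
  state <- adamInit(flat)
  tg <- lapply(trainGraphs, function(g) {
    list(X = nodeAttributes(g), edges = edgeList(g), y = nodeLabels(g))
  })
  vg <- lapply(valGraphs, function(g) {
    list(X = nodeAttributes(g), edges = edgeList(g), y = nodeLabels(g))
  })
  log <- data.frame(epoch = seq_len(config$max_epochs), loss = NA_real_, valF1 = NA_real_)
  bestF1 <- -Inf
  bestFlat <- flat
  bestEpoch <- 1L
  for (epoch in seq_len(config$max_epochs)) {
    losses <- numeric(length(tg))
    for (i in seq_along(tg)) {
      params <- unflattenParams(flat, params)
      fwd <- gatForward(params, config, tg[[i]]$X, tg[[i]]$edges,
        stochastic = TRUE, backprop = TRUE
      )
      p <- fwd$probs[cbind(seq_along(tg[[i]]$y), tg[[i]]$y)]
      losses[i] <- -mean(log(pmax(p, 1e-12)))
      grads <- gatBackward(params, config, tg[[i]]$X, fwd, tg[[i]]$y)
      upd <- adamStep(flat, flattenGrads(grads), state, config$learning_rate)
      flat <- upd$flat
      state <- upd$state
    }
    params <- unflattenParams(flat, params)
    valF1 <- if (length(vg)) {
      mean(vapply(vg, function(g) {
        pr <- gatForward(params, config, g$X, g$edges)$probs
        weightedF1(max.col(pr, ties.method = "first"), g$y, K = K)
      }, 0))
    } else {
      # without validation graphs fall back to training F1
      mean(vapply(tg, function(g) {
        pr <- gatForward(params, config, g$X, g$edges)$probs
        weightedF1(max.col(pr, ties.method = "first"), g$y, K = K)
      }, 0))
    }
    log$loss[epoch] <- mean(losses)
    log$valF1[epoch] <- valF1
    if (valF1 > bestF1) {
      bestF1 <- valF1
      bestFlat <- flat
      bestEpoch <- epoch
    }
  }
  params <- unflattenParams(bestFlat, params)
  methods::new("FittedNodeModel",
    params = params, config = unclass(config), classNames = vocab,
    inputDim = as.integer(inputDim), trainLog = log, selectedEpoch = bestEpoch
  )
}

checkPredictInput <- function(model, graph) {
  if (ncol(nodeAttributes(graph)) != model@inputDim) {
    stop(sprintf(
      "attribute dimension %d does not match the %d the model was trained on",
      ncol(nodeAttributes(graph)), model@inputDim
    ))
  }
}

#' Predict class probabilities for every patch of a slide
#'
#' Deterministic forward pass (stochastic layers disabled); each row of the
#' returned matrix sums to 1.
#'
#' @param model a [FittedNodeModel-class].
#' @param graph a [WholeSlideGraph-class].
#' @return m x K probability matrix (columns in `classNames` order).
#' @export
predictProba <- function(model, graph) {
  checkPredictInput(model, graph)
  cfg <- structure(model@config, class = "GATConfig")
  gatForward(model@params, cfg, nodeAttributes(graph), edgeList(graph))$probs
}

#' Extract contextualized patch embeddings
#'
#' Penultimate-layer activations (output of the last graph attention layer,
#' heads averaged) per patch, with stochastic layers disabled. These are the
#' embeddings the Mapper summary operates on.
#'
#' @inheritParams predictProba
#' @return m x hidden_dim numeric matrix.
#' @export
extractEmbeddings <- function(model, graph) {
  checkPredictInput(model, graph)
  cfg <- structure(model@config, class = "GATConfig")
  gatForward(model@params, cfg, nodeAttributes(graph), edgeList(graph))$Z
}
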