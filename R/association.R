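#' Per-class region-count features of a slide
#'
#' Fraction of patches assigned to each tissue class; sums to 1.
#'
#' @param labels integer class label per patch (1-based).
#' @param K class count.
#' @param classNames optional names.
#' @return numeric vector of length K.
#' @export
regionCountFeatures <- function(labels, K, classNames = NULL) {
  if (!length(labels)) stop("empty slide: no labels")
  f <- tabulate(labels, nbins = K) / length(labels)
  if (!is.null(classNames)) names(f) <- classNames
  f
}

#' Build the cohort design matrix
#'
#' Stacks per-slide Tumor Invasion Scores and/or region-count fractions into a
#' slide-by-feature design matrix, optionally adds all pairwise products of
#' the main-effect columns (second-order terms retain the main effects), and
#' standardizes every column to zero mean / unit variance, storing the
#' centering and scaling parameters as attributes. Constant columns are
#' dropped with a warning.
#'
#' @param tis matrix of per-slide TIS vectors (slides x K), or NULL.
#' @param counts matrix of per-slide region-count fractions, or NULL.
#' @param y binary outcome per slide.
#' @param patientId patient identifier per slide.
#' @param mode which feature blocks to use: `"tis"`, `"counts"`, or `"both"`.
#' @param interactions `"main"` or `"second_order"`.
#' @return list of class `DesignMatrix` with standardized matrix `X`, outcome
#'   `y`, `patientId`, and standardization parameters `center`, `scale`.
#' @export
buildDesign <- function(tis = NULL, counts = NULL, y, patientId,
                        mode = c("tis", "counts", "both"),
                        interactions = c("main", "second_order")) {
  mode <- match.arg(mode)
  interactions <- match.arg(interactions)
  blocks <- list()
  if (mode %in% c("tis", "both")) {
    if (is.null(tis)) stop("mode requires TIS features")
    tis <- as.matrix(tis)
    colnames(tis) <- paste0("tis_", colnames(tis) %||% seq_len(ncol(tis)))
    blocks$tis <- tis
  }
  if (mode %in% c("counts", "both")) {
    if (is.null(counts)) stop("mode requires count features")
    counts <- as.matrix(counts)
    colnames(counts) <- paste0("frac_", colnames(counts) %||% seq_len(ncol(counts)))
    blocks$counts <- counts
  }
  X <- do.call(cbind, blocks)
  stopifnot(nrow(X) == length(y), length(patientId) == length(y))
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  if (interactions == "second_order") {
    p <- ncol(X)
    inter <- list()
    for (a in seq_len(p - 1L)) {
      for (b in (a + 1L):p) {
        inter[[paste0(colnames(X)[a], ":", colnames(X)[b])]] <- X[, a] * X[, b]
      }
    }
    X <- cbind(X, do.call(cbind, inter))
  }
  if (anyNA(X)) stop("design matrix contains missing values")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf(
      "dropping %d constant column(s): %s",
      sum(sds == 0), paste(colnames(X)[sds == 0], collapse = ", ")
    ))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  Xs <- scale(X, center = ctr, scale = sds)
  structure(
    list(
      X = Xs, y = as.integer(y), patientId = patientId,
      center = ctr, scale = sds
    ),
    class = "DesignMatrix"
  )
}

#' Undo the design-matrix standardization
#'
#' @param design a `DesignMatrix` from [buildDesign()].
#' @return the matrix on its original scale.
#' @export
unstandardize <- function(design) {
  sweep(sweep(unclass(design$X[, , drop = FALSE]), 2L, design$scale, "*"),
    2L, design$center, "+"
  )
}

# Assign patients to folds so every fold sees both outcome classes where
# possible; folds are grouped by patient (no patient spans folds).
groupedFolds <- function(patientId, y, nFolds, maxTries = 50L) {
  patients <- unique(patientId)
  if (nFolds > length(patients)) stop("more folds than patients")
  for (try in seq_len(maxTries)) {
    assign <- sample(rep_len(seq_len(nFolds), length(patients)))
    names(assign) <- patients
    fold <- assign[as.character(patientId)]
    bad <- vapply(seq_len(nFolds), function(f) {
      length(unique(y[fold != f])) < 2L || sum(fold == f) == 0L
    }, TRUE)
    if (!any(bad)) return(unname(fold))
    if (try == 1L) warning("refolding: a fold was missing an outcome class")
  }
  stop("could not build grouped folds with both outcome classes")
}

#' Cross-validated logistic AUC of a design matrix
#'
#' Grouped k-fold cross-validation (folds partition patients, so no patient
#' spans folds) of an unpenalized logistic regression; out-of-fold predicted
#' probabilities are pooled and a single AUROC is computed. The standard error
#' is the standard deviation of the AUROC over nonparametric bootstrap
#' resamples of the pooled (prediction, outcome) pairs.
#'
#' @param design a `DesignMatrix` from [buildDesign()].
#' @param nFolds folds (default 10).
#' @param nBoot bootstrap resamples for the SE (default 1000).
#' @param seed integer seed for fold assignment and bootstrap.
#' @return list with `auc`, `se`, pooled `predictions`, and `folds`.
#' @export
cvLogisticAuc <- function(design, nFolds = 10L, nBoot = 1000L, seed = 1L) {
  X <- design$X
  y <- design$y
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  set.seed(as.integer(seed))
  fold <- groupedFolds(design$patientId, y, nFolds)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    df <- data.frame(y = y[tr], X[tr, , drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    nd <- data.frame(X[!tr, , drop = FALSE], check.names = FALSE)
    pred[!tr] <- suppressWarnings(stats::predict(fit, newdata = nd, type = "response"))
  }
  auc <- aucFromScores(pred, y)
  boots <- vapply(seq_len(nBoot), function(b) {
    ix <- sample.int(length(y), replace = TRUE)
    aucFromScores(pred[ix], y[ix])
  }, 0)
  list(auc = auc, se = stats::sd(boots, na.rm = TRUE), predictions = pred, folds = fold)
}

#' Patient-clustered logistic effect summary
#'
#' Fits an unpenalized logistic regression on the full (standardized) design
#' and reports per-feature exponentiated coefficients with confidence
#' intervals from a patient-level (cluster) bootstrap: whole patients are
#' resampled with replacement, the model refitted, and percentile intervals
#' taken over the resampled coefficients. This approximates the clustered
#' inference of a mixed-effects model without its likelihood machinery.
#' Quasi-separation is flagged and the interval then comes from the bootstrap
#' alone.
#'
#' @param design a `DesignMatrix` from [buildDesign()].
#' @param nBoot bootstrap resamples (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame with one row per feature: `coef` (log-odds per SD),
#'   `or` (exponentiated), `lower`, `upper` (exponentiated percentile CI),
#'   `ciExcludesOne`, and attribute `separation`.
#' @export
clusteredEffectSummary <- function(design, nBoot = 500L, level = 0.95, seed = 1L) {
  X <- design$X
  y <- design$y
  pid <- design$patientId
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1L]) > 15)
  set.seed(as.integer(seed))
  patients <- unique(pid)
  rowsOf <- split(seq_along(pid), pid)
  p <- ncol(X)
  boot <- matrix(NA_real_, nBoot, p)
  for (b in seq_len(nBoot)) {
    samp <- sample(as.character(patients), replace = TRUE)
    ix <- unlist(rowsOf[samp], use.names = FALSE)
    if (length(unique(y[ix])) < 2L) next
    fb <- suppressWarnings(stats::glm(y ~ .,
      data = df[ix, , drop = FALSE],
      family = stats::binomial()
    ))
    boot[b, ] <- stats::coef(fb)[-1L]
  }
  a <- (1 - level) / 2
  lo <- apply(boot, 2L, stats::quantile, probs = a, na.rm = TRUE)
  hi <- apply(boot, 2L, stats::quantile, probs = 1 - a, na.rm = TRUE)
  est <- stats::coef(fit)[-1L]
  out <- data.frame(
    feature = colnames(X),
    coef = unname(est),
    or = exp(unname(est)),
    lower = exp(lo),
    upper = exp(hi),
    ciExcludesOne = (lo > 0) | (hi < 0),
    row.names = NULL
  )
  attr(out, "separation") <- separation
  out
}
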