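# RBF-SVM baselines with nested cross-validation.
#
# The SVM itself is e1071/libsvm; this module owns the experiment protocol:
# seeded fold assignment, inner-CV hyperparameter selection by AUROC,
# orientation of the decision values so that higher = more S/G2-like, and
# the shared-split feature-panel benchmark.

.defaultGrid <- function()
  list(cost = c(0.1, 1, 10, 100), gamma = 10^seq(-3, 1, by = 1))

# deterministic k-fold assignment of n rows
.foldIds <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Fit an RBF SVM with inner-CV hyperparameter selection
#'
#' Selects (cost, gamma) from the grid by mean inner-fold AUROC on the
#' training rows only, then refits on all training rows with the chosen
#' pair. Features are assumed already z-scored (see [zscoreFit()]). The
#' fitted object remembers the score orientation so that [scoreSvm()]
#' always returns higher-is-S/G2 scores.
#'
#' @param x numeric matrix or data.frame of scaled features (training rows).
#' @param y labels, values \code{"G1"} / \code{"SG2"}.
#' @param grid list with numeric \code{cost} and \code{gamma} candidates.
#' @param innerFolds number of inner CV folds.
#' @param seed seed for the fold assignment.
#' @return an \code{svmFit} list: the refitted \code{e1071::svm} model, the
#'   selected \code{cost}/\code{gamma}, the inner-CV AUROC table, the score
#'   orientation and the feature column names.
#' @export
fitSvm <- function(x, y, grid = .defaultGrid(), innerFolds = 5L,
                   seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("fitSvm needs both classes in the training labels")
  folds <- .foldIds(nrow(x), innerFolds, seed)
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  cvAuc <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    aucs <- numeric(innerFolds)
    for (f in seq_len(innerFolds)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
        aucs[f] <- NA_real_
        next
      }
      m <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                      kernel = "radial", cost = combos$cost[ci],
                      gamma = combos$gamma[ci], scale = FALSE)
      sc <- .svmDecision(m, x[te, , drop = FALSE])
      a <- aurocScore(sc, y[te])
      aucs[f] <- max(a, 1 - a)  # orientation-free model quality
    }
    cvAuc[ci] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cvAuc)  # ties: first grid entry
  model <- e1071::svm(x, factor(y), kernel = "radial",
                      cost = combos$cost[best], gamma = combos$gamma[best],
                      scale = FALSE)
  sc <- .svmDecision(model, x)
  flip <- aurocScore(sc, y) < 0.5
  structure(list(model = model, cost = combos$cost[best],
                 gamma = combos$gamma[best],
                 cv = cbind(combos, auroc = cvAuc),
                 flip = flip, cols = colnames(x)),
            class = "svmFit")
}

.svmDecision <- function(model, x) {
  p <- predict(model, x, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

#' Continuous S/G2 scores from a fitted SVM
#'
#' The (possibly sign-flipped) libsvm decision value: a monotone transform
#' of the margin, oriented so that higher means more S/G2-like. Suitable
#' directly for ROC analysis.
#'
#' @param fit an \code{svmFit} from [fitSvm()].
#' @param x feature matrix with the same columns the model was fitted on.
#' @return numeric scores.
#' @export
scoreSvm <- function(fit, x) {
  x <- as.matrix(x)
  if (!is.null(fit$cols) && !is.null(colnames(x)) &&
      !identical(colnames(x), fit$cols))
    stop("feature columns do not match the fitted model: expected ",
         paste(fit$cols, collapse = ", "))
  sc <- .svmDecision(fit$model, x)
  if (fit$flip) -sc else sc
}

#' Outer-CV AUROC of the nested-CV SVM protocol
#'
#' Runs the full nested protocol: the outer folds are held out in turn,
#' hyperparameters are selected by inner CV within each outer-training set,
#' and the held-out scores are pooled into one AUROC. Test rows never
#' influence scaling or hyperparameter choice.
#'
#' @inheritParams fitSvm
#' @param outerFolds number of outer folds.
#' @return list with pooled \code{auroc} and the per-fold fits' selected
#'   hyperparameters.
#' @export
nestedCvAuroc <- function(x, y, grid = .defaultGrid(), outerFolds = 5L,
                          innerFolds = 5L, seed = 1L) {
  x <- as.matrix(x); y <- as.character(y)
  folds <- .foldIds(nrow(x), outerFolds, seed)
  scores <- numeric(nrow(x))
  hp <- vector("list", outerFolds)
  for (f in seq_len(outerFolds)) {
    tr <- folds != f
    st <- zscoreFit(as.data.frame(x), trainIdx = which(tr))
    xs <- as.matrix(zscoreApply(as.data.frame(x), st))
    fit <- fitSvm(xs[tr, , drop = FALSE], y[tr], grid = grid,
                  innerFolds = innerFolds, seed = seed + f)
    scores[!tr] <- scoreSvm(fit, xs[!tr, , drop = FALSE])
    hp[[f]] <- c(cost = fit$cost, gamma = fit$gamma)
  }
  list(auroc = aurocScore(scores, y), hyperparameters = hp,
       scores = scores)
}

#' Benchmark feature subsets on a shared held-out split
#'
#' For each named feature subset: z-score on the training rows, select
#' hyperparameters by inner CV on the training rows, refit, then score the
#' shared test rows. Reports AUROC and accuracy (threshold = score 0) per
#' experiment.
#'
#' @param features data.frame of raw (unscaled) feature columns.
#' @param labels \code{"G1"}/\code{"SG2"} per row.
#' @param panel named list of character vectors (feature column subsets).
#' @param trainIdx,testIdx disjoint row indices of the shared split.
#' @param grid,innerFolds,seed passed to [fitSvm()].
#' @return data.frame: \code{experiment}, \code{n_features}, \code{auroc},
#'   \code{accuracy}, \code{cost}, \code{gamma}.
#' @export
runFeaturePanel <- function(features, labels, panel, trainIdx, testIdx,
                            grid = .defaultGrid(), innerFolds = 5L,
                            seed = 1L) {
  stopifnot(length(intersect(trainIdx, testIdx)) == 0L)
  labels <- as.character(labels)
  out <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    cols <- panel[[i]]
    if (!all(cols %in% names(features)))
      stop("panel '", names(panel)[i], "' references missing features: ",
           paste(setdiff(cols, names(features)), collapse = ", "))
    st <- zscoreFit(features, cols = cols, trainIdx = trainIdx)
    sc <- zscoreApply(features, st)
    xm <- as.matrix(sc[, cols, drop = FALSE])
    fit <- fitSvm(xm[trainIdx, , drop = FALSE], labels[trainIdx],
                  grid = grid, innerFolds = innerFolds, seed = seed)
    s <- scoreSvm(fit, xm[testIdx, , drop = FALSE])
    acc <- accuracyAt(s, labels[testIdx], threshold = 0)
    out[[i]] <- data.frame(
      experiment = names(panel)[i], n_features = length(cols),
      auroc = aurocScore(s, labels[testIdx]),
      accuracy = acc$accuracy, cost = fit$cost, gamma = fit$gamma,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
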