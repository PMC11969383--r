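# Classification and regression metrics. S/G2 is the positive class
# throughout the package: higher scores mean more S/G2-like.

#' Area under the ROC curve
#'
#' Rank-based AUROC: the probability that a uniformly drawn positive scores
#' above a uniformly drawn negative, counting ties as 1/2 (equivalent to
#' the Mann-Whitney U statistic).
#'
#' @param scores numeric scores, higher = more S/G2-like.
#' @param labels class labels; \code{positive} marks the positive class.
#' @param positive positive class value (default \code{"SG2"}).
#' @return AUROC in \code{[0, 1]}.
#' @export
aurocScore <- function(scores, labels, positive = "SG2") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps every distinct score as a threshold (predict positive when score
#' >= threshold) and returns the (FPR, TPR) staircase from (0,0) to (1,1).
#'
#' @inheritParams aurocScore
#' @return data.frame \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
rocCurve <- function(scores, labels, positive = "SG2") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct score
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / n0),
             tpr = c(0, tp[keep] / n1))
}

#' Accuracy and confusion counts at a threshold
#'
#' @inheritParams aurocScore
#' @param threshold predict positive when \code{scores >= threshold}.
#' @return list with \code{accuracy} and \code{confusion} (named counts
#'   tp, fp, tn, fn).
#' @export
accuracyAt <- function(scores, labels, threshold = 0.5, positive = "SG2") {
  pos <- labels == positive
  pred <- scores >= threshold
  conf <- c(tp = sum(pred & pos), fp = sum(pred & !pos),
            tn = sum(!pred & !pos), fn = sum(!pred & pos))
  list(accuracy = (conf[["tp"]] + conf[["tn"]]) / length(labels),
       confusion = conf)
}
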