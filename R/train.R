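# Training and evaluation of the conv-net models.
#
# Recipe: Adam (lr 1e-5, weight decay 1e-1 as L2 on the gradient), batch
# size 4, binary cross-entropy on logits for classification or mean squared
# error in degrees for regression; optional random Z-rotation augmentation
# of training samples; the checkpoint with the best validation metric
# (highest accuracy / lowest RMSE, earlier epoch on ties) is kept.

#' Training configuration
#'
#' @param epochs number of epochs (the reference recipe uses 800; scale
#'   down for desk runs).
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param weightDecay L2 penalty coefficient added to the gradient.
#' @param beta1,beta2,epsilon Adam moment/stability constants.
#' @param seed seed for shuffling, dropout and augmentation angles.
#' @param augment apply a uniform random Z-rotation (0-359 degrees) to each
#'   training sample each epoch (3D volumes only).
#' @param verbose print per-epoch progress.
#' @return list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 800L, batchSize = 4L, lr = 1e-5,
                        weightDecay = 1e-1, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, seed = 1L, augment = FALSE,
                        verbose = FALSE) {
  stopifnot(batchSize >= 1L, lr > 0, epochs >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 weightDecay = weightDecay, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed),
                 augment = augment, verbose = verbose),
            class = "trainConfig")
}

# binary cross-entropy on logits, numerically stable; y in {0, 1}
.bceLoss <- function(z, y) mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
.bceGrad <- function(z, y) (stats::plogis(z) - y) / length(z)

.mseLoss <- function(z, y) mean((z - y)^2)
.mseGrad <- function(z, y) 2 * (z - y) / length(z)

# labels to 0/1 with S/G2 positive
.binTargets <- function(labels) {
  if (is.numeric(labels)) return(as.numeric(labels))
  as.numeric(labels == "SG2")
}

#' Train a cell cycle network
#'
#' Minibatch Adam over the training volumes with per-epoch validation.
#' For classification heads the validation metric is accuracy at
#' probability 0.5 and the best (highest; earlier epoch on ties) checkpoint
#' is kept; for regression heads it is RMSE in degrees (lowest kept).
#' Deterministic for a fixed \code{cfg$seed}.
#'
#' @param net a [CycleNet-class].
#' @param trainVols,valVols lists of preprocessed volumes.
#' @param trainY,valY targets: \code{"G1"}/\code{"SG2"} labels (or 0/1,
#'   S/G2 = 1) for classification; angles in degrees for regression.
#' @param cfg a [trainConfig()].
#' @return list with \code{net} (the best checkpoint), \code{bestEpoch},
#'   \code{bestMetric}, and \code{log} (data.frame epoch, train_loss,
#'   val_metric).
#' @export
trainNet <- function(net, trainVols, trainY, valVols, valY,
                     cfg = trainConfig()) {
  if (!length(trainVols)) stop("empty training set")
  if (!length(valVols)) stop("empty validation set")
  stopifnot(length(trainVols) == length(trainY),
            length(valVols) == length(valY))
  classify <- net@mode == "classification"
  ty <- if (classify) .binTargets(trainY) else as.numeric(trainY)
  vy <- if (classify) .binTargets(valY) else as.numeric(valY)

  set.seed(cfg$seed)
  p <- net@params
  # flat-vector Adam state: one pass over all 1.8M parameters per step
  pnames <- names(p)
  plens <- vapply(p, length, integer(1))
  pends <- cumsum(plens)
  pstarts <- pends - plens + 1L
  pdims <- lapply(p, dim)
  pflat <- unlist(p, use.names = FALSE)
  mflat <- numeric(length(pflat))
  vflat <- numeric(length(pflat))
  relist <- function(flat) {
    out <- vector("list", length(pnames))
    names(out) <- pnames
    for (k in seq_along(pnames)) {
      w <- flat[pstarts[k]:pends[k]]
      if (!is.null(pdims[[k]])) dim(w) <- pdims[[k]]
      out[[k]] <- w
    }
    out
  }
  tstep <- 0L
  n <- length(trainVols)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_metric = numeric())
  best <- NULL
  bestMetric <- if (classify) -Inf else Inf
  bestEpoch <- NA_integer_

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    epLoss <- 0
    nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batchSize - 1L, n)
      sel <- ord[i:j]
      vols <- trainVols[sel]
      if (cfg$augment && net@arch == "3d")
        vols <- lapply(vols, function(vv) rotateZ(vv, runif(1, 0, 359)))
      net@params <- p
      fw <- netForward(net, vols, train = TRUE)
      z <- fw$out
      yb <- ty[sel]
      loss <- if (classify) .bceLoss(z, yb) else .mseLoss(z, yb)
      dz <- if (classify) .bceGrad(z, yb) else .mseGrad(z, yb)
      gr <- netBackward(net, fw$cache, dz)
      tstep <- tstep + 1L
      corr1 <- 1 - cfg$beta1^tstep
      corr2 <- 1 - cfg$beta2^tstep
      g <- unlist(gr[pnames], use.names = FALSE) + cfg$weightDecay * pflat
      mflat <- cfg$beta1 * mflat + (1 - cfg$beta1) * g
      vflat <- cfg$beta2 * vflat + (1 - cfg$beta2) * g * g
      pflat <- pflat - cfg$lr * (mflat / corr1) /
        (sqrt(vflat / corr2) + cfg$epsilon)
      p <- relist(pflat)
      epLoss <- epLoss + loss
      nb <- nb + 1L
      i <- j + 1L
    }
    net@params <- p
    pz <- netPredict(net, valVols)
    metric <- if (classify) {
      mean((stats::plogis(pz) >= 0.5) == (vy == 1))
    } else sqrt(mean((pz - vy)^2))
    log[nrow(log) + 1L, ] <- list(ep, epLoss / nb, metric)
    better <- if (classify) metric > bestMetric else metric < bestMetric
    if (better) {
      bestMetric <- metric
      bestEpoch <- ep
      best <- p
    }
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss %.5f  val %.4f", ep, epLoss / nb,
                      metric))
    gc(FALSE)  # cap allocator growth: each epoch churns large buffers
  }
  net@params <- best
  .nnClearBuffers()
  list(net = net, bestEpoch = bestEpoch, bestMetric = bestMetric, log = log)
}

#' Save / load a checkpoint with its JSON sidecar
#'
#' The checkpoint itself is an RDS of the [CycleNet-class]; a JSON sidecar
#' with the same stem records architecture, head mode, seed and parameter
#' total plus any extra run metadata supplied, so runs can be audited
#' without loading the binary.
#'
#' @param net a [CycleNet-class].
#' @param path checkpoint file path (e.g. \code{"run1.rds"}).
#' @param extra named list of additional metadata for the sidecar (e.g.
#'   norm constant, split manifest hash).
#' @return (invisibly) the sidecar metadata list.
#' @export
saveCheckpoint <- function(net, path, extra = list()) {
  saveRDS(net, path)
  meta <- c(list(arch = net@arch, mode = net@mode,
                 init_seed = net@initSeed,
                 n_params = countParameters(net)), extra)
  jsonlite::write_json(meta, paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(meta)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Evaluate a classification network on a held-out set
#'
#' Scores are sigmoid probabilities of S/G2; the ROC sweeps all score
#' thresholds and accuracy is reported at the stated probability threshold.
#'
#' @param net a trained classification [CycleNet-class].
#' @param vols list of test volumes (disjoint from train/val by manifest).
#' @param labels \code{"G1"}/\code{"SG2"} (or 0/1) test labels; both
#'   classes must be present.
#' @param threshold probability threshold for accuracy.
#' @return list: \code{auroc}, \code{accuracy}, \code{confusion},
#'   \code{roc} (data.frame), \code{scores} (probabilities).
#' @export
evaluateClassifier <- function(net, vols, labels, threshold = 0.5) {
  if (net@mode != "classification")
    stop("evaluateClassifier needs a classification-head network")
  y <- .binTargets(labels)
  if (length(unique(y)) < 2L)
    stop("AUROC undefined on a single-class test set")
  pr <- stats::plogis(netPredict(net, vols))
  lab <- ifelse(y == 1, "SG2", "G1")
  acc <- accuracyAt(pr, lab, threshold = threshold)
  list(auroc = aurocScore(pr, lab), accuracy = acc$accuracy,
       confusion = acc$confusion, roc = rocCurve(pr, lab), scores = pr)
}

#' Evaluate a regression network on a held-out set
#'
#' Reports RMSE (degrees), Pearson and Spearman correlations, and the
#' AUROC of the predicted angle against the 45-degree-binarized truth
#' (cells with true angle exactly 45 are dropped from that AUROC).
#' Constant predictions make the correlations undefined; they are
#' returned as NA with a warning.
#'
#' @param net a trained regression [CycleNet-class].
#' @param vols list of test volumes.
#' @param theta true angles in degrees, in [0, 90].
#' @return list: \code{rmse}, \code{pearson}, \code{spearman},
#'   \code{auroc45}, \code{predictions}.
#' @export
evaluateRegressor <- function(net, vols, theta) {
  if (net@mode != "regression")
    stop("evaluateRegressor needs a regression-head network")
  stopifnot(all(theta >= 0), all(theta <= 90))
  pred <- netPredict(net, vols)
  if (stats::sd(pred) == 0) {
    warning("constant predictions: correlations undefined")
    pe <- NA_real_; sp <- NA_real_
  } else {
    pe <- stats::cor(pred, theta)
    sp <- stats::cor(pred, theta, method = "spearman")
  }
  keep <- theta != 45
  a45 <- if (length(unique(theta[keep] > 45)) < 2L) NA_real_ else
    aurocScore(pred[keep], binarizeAngle(theta[keep]))
  list(rmse = sqrt(mean((pred - theta)^2)), pearson = pe, spearman = sp,
       auroc45 = a45, predictions = pred)
}
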