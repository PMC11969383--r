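# Training loop, checkpointing and evaluation reports.

tinyData <- function(n = 8, seed = 21) {
  set.seed(seed)
  # bright-big vs dim-small blobs at 16^3, trivially separable
  vols <- list(); y <- character(n)
  for (i in seq_len(n)) {
    sg2 <- i %% 2 == 0
    r <- if (sg2) 5 else 3
    g <- as.matrix(expand.grid(1:16, 1:16, 1:16))
    v <- array(0, c(16, 16, 16))
    v[g[rowSums((g - 8.5)^2) <= r^2, , drop = FALSE]] <-
      (if (sg2) 2 else 1) + rnorm(1, 0, 0.05)
    vols[[i]] <- v
    y[i] <- if (sg2) "SG2" else "G1"
  }
  list(vols = vols, y = y)
}

test_that("one training epoch produces a finite loss and a checkpoint", {
  d <- tinyData()
  run <- trainNet(buildCnn3d(initSeed = 2), d$vols[1:6], d$y[1:6],
                  d$vols[7:8], d$y[7:8],
                  trainConfig(epochs = 1, seed = 1))
  expect_true(is.finite(run$log$train_loss))
  expect_equal(run$bestEpoch, 1)
  expect_s4_class(run$net, "CycleNet")
  expect_error(trainNet(buildCnn3d(), list(), character(), d$vols, d$y),
               "empty")
})

test_that("training is deterministic for a fixed seed with augmentation off", {
  d <- tinyData()
  go <- function() trainNet(buildCnn3d(initSeed = 4), d$vols[1:6],
                            d$y[1:6], d$vols[7:8], d$y[7:8],
                            trainConfig(epochs = 2, seed = 9,
                                        augment = FALSE))
  r1 <- go(); r2 <- go()
  expect_identical(r1$log, r2$log)
  expect_identical(netParams(r1$net), netParams(r2$net))
})

test_that("checkpoint selection keeps the best epoch (earlier on ties)", {
  d <- tinyData(12)
  run <- trainNet(buildCnn3d(initSeed = 2), d$vols[1:8], d$y[1:8],
                  d$vols[9:12], d$y[9:12],
                  trainConfig(epochs = 3, seed = 2))
  expect_equal(run$bestMetric, max(run$log$val_metric))
  expect_equal(run$bestEpoch,
               which(run$log$val_metric == run$bestMetric)[1])
})

test_that("checkpoints round-trip through disk with a JSON sidecar", {
  net <- buildCnn3d(initSeed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(net, path, extra = list(norm_constant = 123.4))
  back <- loadCheckpoint(path)
  expect_identical(netParams(back), netParams(net))
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  expect_equal(side$n_params, 1757267)
  expect_equal(side$norm_constant, 123.4)
})

test_that("classifier evaluation rejects degenerate test sets", {
  d <- tinyData()
  net <- buildCnn3d(initSeed = 1)
  expect_error(evaluateClassifier(net, d$vols[c(1, 3)], c("G1", "G1")),
               "single-class")
  expect_error(evaluateClassifier(buildCnn3d("regression"), d$vols, d$y),
               "classification")
  ev <- evaluateClassifier(net, d$vols, d$y)
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  expect_equal(sum(ev$confusion), length(d$y))
})

test_that("regression metrics behave under shift and antitone transforms", {
  # closed-form checks of the metric definitions used by the evaluator
  theta <- c(10, 20, 40, 60, 80)
  expect_equal(sqrt(mean((theta - theta)^2)), 0)
  expect_equal(sqrt(mean(((theta + 10) - theta)^2)), 10)
  expect_equal(cor(theta + 10, theta), 1)
  expect_equal(cor(90 - theta, theta, method = "spearman"), -1)
  # evaluator contract on a real (untrained) network
  d <- tinyData()
  reg <- buildCnn3d("regression", initSeed = 3)
  ev <- evaluateRegressor(reg, d$vols, theta = c(10, 80, 12, 78, 9, 81,
                                                 11, 79))
  expect_true(is.finite(ev$rmse))
  expect_length(ev$predictions, 8)
  expect_error(evaluateRegressor(buildCnn3d(), d$vols, rep(10, 8)),
               "regression")
})

test_that("3D volumes beat matched 2D projections at scaled-down training", {
  # direction-only comparison, averaged over 3 seeds at a small scale:
  # with Z-anisotropic classes, projections lose part of the signal
  prof <- miniProfile()
  wins <- 0
  for (sd in 1:3) {
    sim <- simulateNucleusData(72, prof, seed = 500 + sd,
                               cellsPerTile = 9, preset = "anisoz",
                               classPrior = 0.5)
    key <- sprintf("%s_%d", sim$truth$tile_id, sim$truth$label_id)
    meta <- data.frame(id = names(sim$crops))
    meta$label <- sim$truth$phase[match(meta$id, key)]
    pp <- preprocessDataset(sim$crops, meta, prof, seed = sd,
                            finalShape = c(16, 16, 16))
    it <- pp$manifest$items
    pick <- function(s) it$id[it$split == s]
    lab <- function(ids) it$label[match(ids, it$id)]
    cfg <- trainConfig(epochs = 6, seed = sd)
    run3 <- trainNet(buildCnn3d(initSeed = sd),
                     pp$volumes[pick("train")], lab(pick("train")),
                     pp$volumes[pick("val")], lab(pick("val")), cfg)
    proj <- lapply(pp$volumes, function(v) maxProjectZ(v)$image)
    run2 <- trainNet(buildCnn2d(initSeed = sd),
                     proj[pick("train")], lab(pick("train")),
                     proj[pick("val")], lab(pick("val")), cfg)
    te <- c(pick("val"), pick("test"))  # small-sample held-out pool
    a3 <- evaluateClassifier(run3$net, pp$volumes[te], lab(te))$auroc
    a2 <- evaluateClassifier(run2$net, proj[te], lab(te))$auroc
    wins <- wins + (a3 - a2)
  }
  expect_gt(wins / 3, 0)
})

test_that("dataset merge keeps split structure for combined training", {
  d <- tinyData(8, seed = 30)
  names(d$vols) <- sprintf("a%02d", 1:8)
  mk <- function(tag, off) {
    vols <- d$vols
    names(vols) <- sprintf("%s%02d", tag, 1:8)
    meta <- data.frame(id = names(vols), label = d$y)
    list(volumes = vols,
         manifest = list(items = cbind(meta,
                                       split = rep(c("train", "val",
                                                     "test", "train"), 2)),
                         norm_constant = off, final_shape_zyx = c(16, 16, 16),
                         seed = 1, profile = tag))
  }
  m <- mergeDatasets(list(mk("e", 10), mk("c", 20)),
                     sources = c("epi", "conf"))
  it <- m$manifest$items
  # evaluating a combined-trained model per source gives two reports
  for (src in c("epi", "conf")) {
    sel <- it$source == src & it$split == "train"
    expect_equal(sum(sel), 4)
  }
  expect_equal(unname(m$manifest$norm_constant), c(10, 20))
})
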