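# Shared lazily-built fixtures. Heavy objects (simulated populations,
# trained networks) are built once per test run and reused across files;
# every fixture is a pure function of fixed seeds.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) {
    .fx[[name]] <- build()
    gc(FALSE)
  }
  .fx[[name]]
}

# 200 easy-preset nuclei simulated, extracted and preprocessed to 16^3
# network inputs with a 70/20/10 split
easyDataset <- function() fixture("easyDataset", function() {
  prof <- miniProfile()
  sim <- simulateNucleusData(200, prof, seed = 101, cellsPerTile = 10,
                             preset = "easy", classPrior = 0.5)
  key <- sprintf("%s_%d", sim$truth$tile_id, sim$truth$label_id)
  meta <- data.frame(id = names(sim$crops), stringsAsFactors = FALSE)
  mi <- match(meta$id, key)
  meta$label <- sim$truth$phase[mi]
  meta$theta_deg <- sim$truth$angle_deg[mi]
  pp <- preprocessDataset(sim$crops, meta, prof, seed = 7,
                          finalShape = c(16, 16, 16))
  pp$sim <- sim
  pp
})

edSelect <- function(pp, split) {
  it <- pp$manifest$items
  ids <- it$id[it$split == split]
  list(vols = pp$volumes[ids],
       label = it$label[match(ids, it$id)],
       theta = it$theta_deg[match(ids, it$id)])
}

# reference training recipe at desk scale: 30 epochs, batch 4, lr 1e-5
deskConfig <- function(seed = 11L)
  trainConfig(epochs = 30L, batchSize = 4L, lr = 1e-5, weightDecay = 1e-1,
              seed = seed, augment = FALSE)

trainedClassifier <- function() fixture("trainedClassifier", function() {
  pp <- easyDataset()
  tr <- edSelect(pp, "train"); va <- edSelect(pp, "val")
  run <- trainNet(buildCnn3d("classification", initSeed = 11),
                  tr$vols, tr$label, va$vols, va$label, deskConfig())
  te <- edSelect(pp, "test")
  run$eval <- evaluateClassifier(run$net, te$vols, te$label)
  run
})

trainedRegressor <- function() fixture("trainedRegressor", function() {
  pp <- easyDataset()
  tr <- edSelect(pp, "train"); va <- edSelect(pp, "val")
  run <- trainNet(buildCnn3d("regression", initSeed = 11),
                  tr$vols, tr$theta, va$vols, va$theta, deskConfig())
  te <- edSelect(pp, "test")
  run$eval <- evaluateRegressor(run$net, te$vols, te$theta)
  run
})

# small default-preset tile set reused by extraction/labeling tests
miniTiles <- function() fixture("miniTiles", function() {
  simulateTiles(3, miniProfile(), seed = 31, cellsPerTile = 8,
                borderFraction = 0.15)
})
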