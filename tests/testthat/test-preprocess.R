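# Crop preprocessing: downsampling, normalization, padding, splitting,
# rotation.

test_that("block-mean downsampling hits the platform output shapes", {
  v <- array(runif(150 * 150 * 90), c(90, 150, 150))  # (Z, Y, X)
  epi <- downsampleVolume(v, c(2, 2, 1))
  expect_equal(dim(epi), c(90, 75, 75))
  conf <- downsampleVolume(v, c(2, 2, 2))
  expect_equal(dim(conf), c(45, 75, 75))
  # block means conserve the integral for integer-divisible factors
  expect_equal(sum(conf) * 8, sum(v))
  # constants are preserved
  k <- downsampleVolume(array(3, c(10, 10, 10)), c(2, 2, 2))
  expect_true(all(k == 3))
  # odd lengths: ceiling shapes, trailing partial block averages itself
  o <- downsampleVolume(array(1:45, c(5, 3, 3)), c(1, 1, 2))
  expect_equal(dim(o), c(3, 3, 3))
})

test_that("normalization is the median of per-crop nonzero medians", {
  crops <- list(a = array(c(0, 10, 10), c(3, 1, 1)),
                b = array(c(20, 20, 0), c(3, 1, 1)),
                c = array(c(40, 0, 40), c(3, 1, 1)))
  expect_equal(fitNormConstant(crops), 20)
  expect_equal(fitNormConstant(lapply(crops, "*", 2)), 40)
  expect_true(all(applyNorm(array(20, c(2, 2, 2)), 20) == 1))
  crops$bad <- array(0, c(2, 2, 2))
  expect_error(fitNormConstant(crops), "bad")
})

test_that("final padding is centered with the odd plane trailing", {
  v <- array(1, c(45, 75, 75))
  p <- finalPad(v, c(75, 75, 90))
  expect_equal(dim(p), c(90, 75, 75))
  expect_true(all(p[1:22, , ] == 0))       # 22 leading zero planes
  expect_true(all(p[68:90, , ] == 0))      # 23 trailing zero planes
  expect_true(all(p[23:67, , ] == 1))
  expect_equal(sum(p), sum(v))
  # identity when already at size
  full <- array(runif(8), c(2, 2, 2))
  expect_identical(finalPad(full, c(2, 2, 2)), full)
  expect_error(finalPad(array(0, c(91, 75, 75)), c(75, 75, 90)), "larger")
})

test_that("the 70/20/10 split is exhaustive, disjoint and deterministic", {
  ids <- sprintf("c%03d", 1:100)
  sp <- makeSplit(ids, seed = 4)
  expect_length(sp$train, 70)
  expect_length(sp$val, 20)
  expect_length(sp$test, 10)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, makeSplit(ids, seed = 4))
  expect_false(identical(sp, makeSplit(ids, seed = 5)))
  # largest-remainder rounding: sizes always sum to n
  for (n in c(3, 7, 13, 99)) {
    s <- makeSplit(seq_len(n), seed = 1)
    expect_equal(length(s$train) + length(s$val) + length(s$test), n)
  }
  expect_error(makeSplit(1:2), "at least 3")
  expect_error(makeSplit(c(1, 1, 2)), "unique")
})

test_that("Z-rotation matches the index-permutation oracle at 90 degrees", {
  set.seed(6)
  v <- array(runif(5 * 11 * 11), c(5, 11, 11))
  expect_identical(rotateZ(v, 0), v)
  expect_equal(rotateZ(v, 360), v)
  expect_equal(rotateZ(v, 90), rot90Oracle(v))
  # four quarter turns compose to the identity
  r <- v
  for (i in 1:4) r <- rotateZ(r, 90)
  expect_equal(r, v)
})

test_that("rotation of a centered blob conserves intensity within 1%", {
  g <- as.matrix(expand.grid(1:5, 1:21, 1:21))
  v <- array(0, c(5, 21, 21))
  v[g[(g[, 2] - 11)^2 + (g[, 3] - 11)^2 <= 36, , drop = FALSE]] <- 2
  for (ang in c(33.7, 90, 145, 278)) {
    expect_lt(abs(sum(rotateZ(v, ang)) / sum(v) - 1), 0.01)
  }
  # rank order of voxel intensities is unchanged by normalization
  nz <- v[v > 0] + runif(sum(v > 0))
  expect_equal(order(nz / 7.3), order(nz))
})

test_that("preprocessDataset wires split, norm and shape together", {
  sim <- simulateNucleusData(20, miniProfile(), seed = 9)
  meta <- data.frame(id = names(sim$crops))
  meta$label <- "G1"
  pp <- preprocessDataset(sim$crops, meta, miniProfile(), seed = 2,
                          finalShape = c(16, 16, 16))
  expect_true(all(vapply(pp$volumes, function(v)
    identical(dim(v), c(16L, 16L, 16L)), logical(1))))
  it <- pp$manifest$items
  expect_equal(sum(it$split == "train"), 14)
  expect_equal(sum(it$split == "val"), 4)
  expect_equal(sum(it$split == "test"), 2)
  # the norm constant is reproducible from the training crops alone
  trIds <- it$id[it$split == "train"]
  ds <- lapply(sim$crops[trIds], downsampleVolume, factors = c(2, 2, 2))
  expect_equal(pp$manifest$norm_constant, fitNormConstant(ds))
})

test_that("dataset merging preserves splits and rejects bad input", {
  mk <- function(tag, seed) {
    sim <- simulateNucleusData(12, miniProfile(), seed = seed)
    crops <- sim$crops
    names(crops) <- paste0(tag, names(crops))
    meta <- data.frame(id = names(crops), label = "G1")
    preprocessDataset(crops, meta, miniProfile(), seed = seed,
                      finalShape = c(16, 16, 16))
  }
  a <- mk("a_", 1); b <- mk("b_", 2)
  m <- mergeDatasets(list(a, b), sources = c("epi", "conf"))
  expect_length(m$volumes, 24)
  expect_equal(nrow(m$manifest$items), 24)
  # per-item split assignment survives the merge
  ita <- a$manifest$items
  itm <- m$manifest$items
  expect_equal(itm$split[match(ita$id, itm$id)], ita$split)
  expect_equal(unname(m$manifest$norm_constant["epi"]),
               a$manifest$norm_constant)
  # self-merge duplicates ids
  expect_error(mergeDatasets(list(a, a)), "duplicate")
  # final-shape mismatch
  simc <- simulateNucleusData(12, miniProfile(), seed = 3)
  cc <- preprocessDataset(simc$crops,
                          data.frame(id = names(simc$crops), label = "G1"),
                          miniProfile(), seed = 3,
                          finalShape = c(16, 16, 18))
  expect_error(mergeDatasets(list(a, cc)), "shapes differ")
})

test_that("stratified splitting preserves class balance per part", {
  ids <- sprintf("c%02d", 1:40)
  cls <- rep(c("G1", "SG2"), each = 20)
  sp <- makeSplit(ids, seed = 2, stratifyBy = cls)
  expect_setequal(unlist(sp), ids)
  byPart <- function(p) table(cls[match(p, ids)])
  expect_equal(unname(byPart(sp$train)), c(14, 14), ignore_attr = TRUE)
  expect_equal(unname(byPart(sp$val)), c(4, 4), ignore_attr = TRUE)
  expect_equal(unname(byPart(sp$test)), c(2, 2), ignore_attr = TRUE)
})

test_that("per-crop training normalization divides each train crop by its median", {
  sim <- simulateNucleusData(12, miniProfile(), seed = 13)
  meta <- data.frame(id = names(sim$crops), label = "G1")
  pp <- preprocessDataset(sim$crops, meta, miniProfile(), seed = 3,
                          finalShape = c(16, 16, 16),
                          norm = "per-crop-train")
  it <- pp$manifest$items
  trId <- it$id[it$split == "train"][1]
  # the normalized training crop's nonzero median is 1 by construction
  v <- pp$volumes[[trId]]
  expect_equal(median(v[v != 0]), 1)
  # test crops still use the global constant
  teId <- it$id[it$split == "test"][1]
  ds <- downsampleVolume(sim$crops[[teId]], c(2, 2, 2))
  expect_equal(sum(pp$volumes[[teId]]),
               sum(ds) / pp$manifest$norm_constant)
})
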