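# Fucci ground-truth labeling: the three exclusion filters, label and
# angle assignment.

test_that("low-intensity thresholds are strict and platform-specific", {
  epi <- epiProfile(); conf <- confocalProfile()
  expect_true(lowIntensityFilter(1400, 5000, epi))
  expect_false(lowIntensityFilter(1500, 2200, epi))   # boundary kept
  expect_true(lowIntensityFilter(5000, 2199, epi))
  expect_false(lowIntensityFilter(700, 2000, conf))   # boundary kept
  expect_true(lowIntensityFilter(699, 5000, conf))
  # vectorized
  expect_equal(lowIntensityFilter(c(1400, 1600), c(5000, 5000), epi),
               c(TRUE, FALSE))
})

test_that("the ratio band is open and tolerates zero normalized RFP", {
  norms <- c(normR = 1, normG = 1)
  expect_true(ratioFilter(1, 1, norms))        # ratio exactly 1
  expect_false(ratioFilter(1, 0.9, norms))     # boundary 0.9 kept
  expect_false(ratioFilter(1, 1.1, norms))     # boundary 1.1 kept
  expect_false(ratioFilter(1, 2.0, norms))
  expect_false(ratioFilter(0, 1, norms))       # muR' = 0: never excluded
  expect_false(ratioFilter(0, 0, norms))
  expect_error(ratioFilter(1, 1, c(normR = 0, normG = 1)), "positive")
  # normalization matters: same means, different norms flip the verdict
  expect_true(ratioFilter(1000, 2000, c(normR = 1000, normG = 2000)))
  expect_false(ratioFilter(1000, 2000, c(normR = 1, normG = 1)))
})

test_that("the volume filter is a strict 2.5-SD rule", {
  st <- list(muV = 1000, sdV = 100)
  expect_false(volumeFilter(1000, st))
  expect_false(volumeFilter(1250, st))  # exactly 2.5 SD kept
  expect_true(volumeFilter(1300, st))
  expect_true(volumeFilter(700, st))
  # degenerate SD: only the exact mean survives
  st0 <- list(muV = 1000, sdV = 0)
  expect_false(volumeFilter(1000, st0))
  expect_true(volumeFilter(1001, st0))
})

test_that("labels follow the R/G balance and ties are an error", {
  expect_equal(assignLabel(10, 5), "G1")
  expect_equal(assignLabel(5, 10), "SG2")
  expect_equal(assignLabel(c(10, 5), c(5, 10)), c("G1", "SG2"))
  expect_error(assignLabel(7, 7), "ambiguous")
})

test_that("the cell cycle angle is the (R, G) polar coordinate in degrees", {
  expect_equal(computeAngle(1, 1), 45)
  expect_equal(computeAngle(1, 0), 0)
  expect_equal(computeAngle(0, 1), 90)
  expect_equal(computeAngle(3, 4), atan2(4, 3) * 180 / pi)
  expect_equal(round(computeAngle(3, 4), 3), 53.13)
  expect_error(computeAngle(0, 0), "undefined")
  expect_equal(binarizeAngle(10), "G1")
  expect_equal(binarizeAngle(80), "SG2")
  expect_error(binarizeAngle(45), "boundary")
})

test_that("angle and binary label agree for surviving cells", {
  set.seed(3)
  R <- runif(200, 1, 100); G <- runif(200, 1, 100)
  keep <- R != G
  expect_equal(binarizeAngle(computeAngle(R[keep], G[keep])),
               assignLabel(R[keep], G[keep]))
})

test_that("labelDataset conserves cells and tags first reasons", {
  feats <- data.frame(
    tile_id = "t", label_id = 1:6,
    rfp_mean = c(100, 8200, 8000, 9000, 3000, 8000),
    gfp_mean = c(100, 7800, 3000, 2500, 9000, 3000),
    volume_vox = c(1500, 1500, 1500, 9000, 1500, 1500))
  feats$rfp_sum <- feats$rfp_mean * feats$volume_vox
  feats$gfp_sum <- feats$gfp_mean * feats$volume_vox
  res <- labelDataset(feats, miniProfile())
  lb <- res$labels
  expect_equal(lb$reason[1], "low_intensity")  # below both thresholds
  expect_equal(nrow(lb), 6)
  expect_true(all(lb$status %in% c("G1", "SG2", "excluded")))
  expect_equal(sum(lb$status != "excluded") + sum(lb$status == "excluded"),
               6)
  expect_equal(res$summary[["n"]],
               res$summary[["G1"]] + res$summary[["SG2"]] +
                 res$summary[["excluded"]])
  # survivors carry angles consistent with their label
  surv <- lb$status != "excluded"
  expect_equal(binarizeAngle(lb$theta_deg[surv]), lb$status[surv])
})

test_that("a population below threshold is excluded wholesale", {
  feats <- data.frame(rfp_mean = rep(100, 5), gfp_mean = rep(100, 5),
                      volume_vox = rep(1000, 5))
  feats$rfp_sum <- feats$rfp_mean * 1000
  feats$gfp_sum <- feats$gfp_mean * 1000
  res <- labelDataset(feats, miniProfile())
  expect_true(all(res$labels$reason == "low_intensity"))
})

test_that("exclusion is order-invariant even though the reason is not", {
  sim <- simulateNucleusData(120, miniProfile(), seed = 17,
                             cropShape = NULL, nonExpresserFrac = 0.15,
                             extremeVolumeFrac = 0.05)
  res <- labelDataset(sim$features, miniProfile())
  lb <- res$labels
  # recompute each filter flag independently and check the union
  f <- sim$features
  fLow <- lowIntensityFilter(f$rfp_mean, f$gfp_mean, miniProfile())
  norms <- res$channelNorms
  fRatio <- ratioFilter(f$rfp_mean, f$gfp_mean, norms)
  fVol <- volumeFilter(f$volume_vox, res$volumeStats)
  expect_equal(lb$status == "excluded", fLow | fRatio | fVol)
})

test_that("widening the ratio band never decreases ratio exclusions", {
  sim <- simulateNucleusData(80, miniProfile(), seed = 23,
                             cropShape = NULL)
  cnt <- sapply(c(0.02, 0.1, 0.3), function(w)
    labelDataset(sim$features, miniProfile(),
                 band = c(1 - w, 1 + w))$summary[["ratio"]])
  expect_true(all(diff(cnt) >= 0))
})
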