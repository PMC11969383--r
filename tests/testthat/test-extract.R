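# Object QC, per-nucleus quantification and crop extraction.

# build a labeled mask from a list of coordinate matrices (z, y, x)
maskFrom <- function(dims, ...) {
  objs <- list(...)
  m <- array(0L, dims)
  for (i in seq_along(objs)) {
    co <- objs[[i]]
    m[cbind(co[, 1], co[, 2], co[, 3])] <- i
  }
  m
}

cubeCoords <- function(z, y, x) as.matrix(expand.grid(z, y, x))

test_that("border-contacting objects are removed with reason 'border'", {
  m <- maskFrom(c(20, 20, 20),
                cubeCoords(5:9, 1:5, 3:7),    # flush against Y = 1 face
                cubeCoords(8:12, 8:12, 8:12)) # interior cube
  fl <- qcFilterMask(m)
  expect_equal(fl$report$label_id, 1)
  expect_equal(fl$report$reason, "border")
  expect_true(all(fl$mask[m == 1] == 0))
  expect_true(all(fl$mask[m == 2] == 2))  # surviving ids unchanged
})

test_that("solidity QC removes concave objects but keeps spheres", {
  grid <- as.matrix(expand.grid(1:30, 1:30, 1:30))
  sph <- grid[rowSums((grid - 15)^2) <= 64, ]
  u <- rbind(cubeCoords(10:18, 10:12, 10:12),
             cubeCoords(10:18, 10:12, 16:18),
             cubeCoords(16:18, 10:12, 13:15))
  m <- maskFrom(c(30, 30, 30), sph)
  m2 <- maskFrom(c(30, 30, 30), u)
  expect_equal(nrow(qcFilterMask(m)$report), 0)
  r2 <- qcFilterMask(m2)$report
  expect_equal(r2$reason, "solidity")
})

test_that("raising the solidity threshold never lets more objects survive", {
  set.seed(12)
  m <- array(0L, c(15, 15, 15))
  for (i in 1:3) {
    co <- randomBlobCoords(i + 40, 13)
    co <- co[co[, 1] %% 5 == (i - 1) | co[, 1] %% 5 == i, , drop = FALSE]
    if (nrow(co)) m[cbind(co[, 1], co[, 2], co[, 3])] <- i
  }
  survivors <- sapply(c(0.5, 0.7, 0.9, 0.99), function(thr)
    length(setdiff(unique(as.vector(qcFilterMask(m, solidityMin = thr,
                                                 dropBorder = FALSE)$mask)),
                   0L)))
  expect_true(all(diff(survivors) <= 0))
})

test_that("quantification is exact on a constant cube", {
  m <- maskFrom(c(20, 20, 20), cubeCoords(6:15, 6:15, 6:15))
  ch <- list(dapi = array(5, c(20, 20, 20)))
  f <- quantifyNuclei(m, ch, solidity = TRUE)
  expect_equal(f$volume_vox, 1000)
  expect_equal(f$dapi_sum, 5000)
  expect_equal(f$dapi_mean, 5)
  expect_equal(f$dapi_sum, f$dapi_mean * f$volume_vox)
  expect_equal(c(f$centroid_z, f$centroid_y, f$centroid_x),
               c(10.5, 10.5, 10.5))
  expect_false(f$touches_border)
  expect_equal(f$solidity, 1)
})

test_that("axis lengths follow the moment-tensor ellipsoid convention", {
  grid <- as.matrix(expand.grid(1:40, 1:30, 1:30))
  # ellipsoid semi-axes (12, 8, 8) voxels
  ell <- grid[((grid[, 1] - 20) / 12)^2 + ((grid[, 2] - 15) / 8)^2 +
              ((grid[, 3] - 15) / 8)^2 <= 1, ]
  m <- maskFrom(c(40, 30, 30), ell)
  f <- quantifyNuclei(m, list(dapi = array(1, c(40, 30, 30))),
                      solidity = FALSE)
  expect_lt(abs(f$major_axis / f$minor_axis - 1.5), 0.15)
  expect_lt(abs(f$major_axis - 24) / 24, 0.1)

  # sphere: major ~ minor
  sph <- grid[rowSums((grid - 15)^2) <= 100, ]
  fs <- quantifyNuclei(maskFrom(c(40, 30, 30), sph),
                       list(dapi = array(1, c(40, 30, 30))),
                       solidity = FALSE)
  expect_lt(abs(fs$major_axis / fs$minor_axis - 1), 0.05)
})

test_that("quantification is invariant to label permutation", {
  tiles <- miniTiles()
  tl <- tiles[[1]]
  f1 <- quantifyNuclei(tl, solidity = FALSE)
  perm <- sample(seq_len(max(tl@mask)))
  m2 <- tl@mask
  m2[tl@mask > 0] <- perm[tl@mask[tl@mask > 0]]
  f2 <- quantifyNuclei(m2, tl@channels, tileId = tl@tileId,
                       solidity = FALSE)
  f2$label_id <- match(f2$label_id, perm)
  f2 <- f2[order(f2$label_id), ]
  rownames(f2) <- rownames(f1) <- NULL
  expect_equal(f2, f1)
})

test_that("masked crops are centered, zero-padded and conserve intensity", {
  dims <- c(30, 30, 30)
  m <- maskFrom(dims, cubeCoords(10:14, 10:14, 10:14))
  dapi <- array(runif(prod(dims), 1, 2), dims)
  cr <- cropNucleus(dapi, m, 1, cropShape = c(16, 16, 16))
  expect_equal(dim(cr), c(16, 16, 16))
  # the 5-cube lands centered on the rounded centroid (12 -> slot 8)
  expect_true(all(cr[6:10, 6:10, 6:10] > 0))
  expect_equal(sum(cr > 0), 125)
  expect_equal(sum(cr), sum(dapi[m == 1]))

  # near-corner nucleus: window exceeds the tile, padded region is zero
  m2 <- maskFrom(dims, cubeCoords(1:4, 1:4, 1:4))
  cr2 <- cropNucleus(dapi, m2, 1, cropShape = c(16, 16, 16))
  expect_equal(dim(cr2), c(16, 16, 16))
  expect_equal(sum(cr2), sum(dapi[m2 == 1]))

  # object larger than the window errors and names the label
  m3 <- maskFrom(dims, cubeCoords(5:25, 5:25, 5:25))
  expect_error(cropNucleus(dapi, m3, 1, cropShape = c(16, 16, 16)), "1")
  expect_error(cropNucleus(dapi, m, 99), "not present")
})

test_that("pipeline crop conservation holds on simulated tiles", {
  tiles <- miniTiles()
  ex <- extractNuclei(tiles, cropShape = c(32, 32, 32), solidity = FALSE)
  for (i in seq_len(nrow(ex$features))) {
    f <- ex$features[i, ]
    cr <- ex$crops[[sprintf("%s_%d", f$tile_id, f$label_id)]]
    expect_equal(sum(cr), f$dapi_sum)
  }
  # QC caught the deliberately border-placed nuclei
  expect_gt(nrow(ex$qc), 0)
  expect_true(all(ex$qc$reason %in% c("border", "solidity")))
})
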