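# Synthetic Fucci tile simulator.
#
# Nuclei are ellipsoids with lognormal size and intensity draws. S/G2 cells
# are larger (2N -> up to 4N DNA content also makes them ~1.6x denser in
# DAPI at default settings) and GFP-dominant; G1 cells are RFP-dominant.
# Rendering is purely geometric (no optical PSF): constant density inside
# the ellipsoid, flat background, additive Gaussian read noise, clipped to
# the camera bit depth. All volumes are (Z, Y, X).

# distribution parameters per preset; ratios/spreads are fixed choices, see
# the methods vignette for the margin analysis behind them
.simPreset <- function(preset = c("default", "easy", "anisoz")) {
  preset <- match.arg(preset)
  base <- list(
    dnaMeanlog = c(G1 = log(1), SG2 = log(1.6)), dnaSdlog = 0.15,
    volMeanlog = c(G1 = 0, SG2 = log(1.3)), volSdlog = 0.2,
    rfpMeanlog = c(G1 = log(12000), SG2 = log(5000)), rfpSdlog = 0.2,
    gfpMeanlog = c(G1 = log(6000), SG2 = log(15000)), gfpSdlog = 0.2,
    zMeanlog = c(G1 = 0, SG2 = 0), zSdlog = 0,
    nonExpr = c(rfpMeanlog = log(300), rfpSdlog = 0.3,
                gfpMeanlog = log(400), gfpSdlog = 0.3),
    extremeVol = c(meanlog = log(5), sdlog = 0.05),
    eccXY = c(1.15, 0.87)
  )
  if (preset == "easy") {
    base$dnaMeanlog <- c(G1 = log(1), SG2 = log(2.0)); base$dnaSdlog <- 0.1
    base$volMeanlog <- c(G1 = 0, SG2 = log(1.6)); base$volSdlog <- 0.1
    base$rfpSdlog <- 0.1; base$gfpSdlog <- 0.1
  } else if (preset == "anisoz") {
    # classes share the XY footprint; S/G2 is elongated along Z only, so
    # max projections lose most of the volume signal
    base$dnaMeanlog <- c(G1 = 0, SG2 = log(1.25)); base$dnaSdlog <- 0.25
    base$volMeanlog <- c(G1 = 0, SG2 = 0); base$volSdlog <- 0.15
    base$zMeanlog <- c(G1 = 0, SG2 = log(1.5)); base$zSdlog <- 0.15
  }
  base
}

#' Draw and place a population of synthetic nuclei
#'
#' Samples per-cell phases, intensity and geometry parameters under a named
#' preset, then places the resulting ellipsoids in one tile without overlap
#' by rejection sampling (conservative bounding-sphere test). All draws are
#' deterministic for a fixed seed.
#'
#' Presets: \code{"default"} reproduces the headline structure (S/G2 about
#' 1.6x denser in DAPI and 1.3x larger than G1, RFP-dominant G1 /
#' GFP-dominant S/G2 with moderate overlap); \code{"easy"} widens the
#' separation (2.0x density, 1.6x volume, tight spreads) for fast
#' learnability checks; \code{"anisoz"} gives both classes the same XY
#' footprint and elongates S/G2 along Z only, hiding volume from 2D
#' projections.
#'
#' @param n number of cells (>= 0).
#' @param profile an [AcquisitionProfile-class].
#' @param classPrior probability that a cell is G1 (default 0.54,
#'   the approximate G1 fraction of labeled populations in culture).
#' @param seed integer seed, or NULL to continue the current RNG stream.
#' @param preset simulation preset, see Details.
#' @param nonExpresserFrac fraction of cells drawn as Fucci non-expressers
#'   (both reporter means far below the low-intensity thresholds).
#' @param extremeVolumeFrac fraction of cells with extreme volume (about 5x
#'   baseline; emulates doublets/debris caught by the volume filter).
#' @param borderFraction fraction of cells deliberately centered within one
#'   semi-axis of a tile face so border QC has work to do.
#' @param tileShape integer(3) (X, Y, Z) tile to place into.
#' @param maxTries placement attempts per cell before giving up.
#' @return data.frame with one row per cell: identity, phase, center
#'   (fractional voxels), semi-axes, in-plane rotation, DNA scale, reporter
#'   means, volume scale, category flags (\code{non_expresser},
#'   \code{extreme_volume}, \code{flag_low} = a drawn reporter mean is
#'   strictly below its profile threshold), and the true angle
#'   \code{angle_deg} = atan2(GFP, RFP) in degrees.
#' @examples
#' cells <- sampleCells(5, miniProfile(), seed = 1)
#' cells[, c("phase", "dna_scale", "volume_scale")]
#' @export
sampleCells <- function(n, profile, classPrior = 0.54, seed = NULL,
                        preset = "default", nonExpresserFrac = 0,
                        extremeVolumeFrac = 0, borderFraction = 0,
                        tileShape = profile@tileShape, maxTries = 2000L) {
  stopifnot(n >= 0, classPrior >= 0, classPrior <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- .simPreset(preset)

  emptyDf <- data.frame(
    cell_id = integer(), phase = character(),
    center_x = numeric(), center_y = numeric(), center_z = numeric(),
    semi_x = numeric(), semi_y = numeric(), semi_z = numeric(),
    z_rotation_deg = numeric(), dna_scale = numeric(),
    rfp_mean = numeric(), gfp_mean = numeric(), volume_scale = numeric(),
    non_expresser = logical(), extreme_volume = logical(),
    flag_low = logical(), angle_deg = numeric(),
    stringsAsFactors = FALSE)
  if (n == 0L) return(emptyDf)

  phase <- ifelse(runif(n) < classPrior, "G1", "SG2")
  dna <- exp(rnorm(n, p$dnaMeanlog[phase], p$dnaSdlog))
  vol <- exp(rnorm(n, p$volMeanlog[phase], p$volSdlog))
  zf <- exp(rnorm(n, p$zMeanlog[phase], p$zSdlog))
  rfp <- exp(rnorm(n, p$rfpMeanlog[phase], p$rfpSdlog))
  gfp <- exp(rnorm(n, p$gfpMeanlog[phase], p$gfpSdlog))

  nonExpr <- runif(n) < nonExpresserFrac
  if (any(nonExpr)) {
    k <- sum(nonExpr)
    rfp[nonExpr] <- exp(rnorm(k, p$nonExpr[["rfpMeanlog"]],
                              p$nonExpr[["rfpSdlog"]]))
    gfp[nonExpr] <- exp(rnorm(k, p$nonExpr[["gfpMeanlog"]],
                              p$nonExpr[["gfpSdlog"]]))
  }
  extreme <- runif(n) < extremeVolumeFrac
  if (any(extreme))
    vol[extreme] <- vol[extreme] *
      exp(rnorm(sum(extreme), p$extremeVol[["meanlog"]],
                p$extremeVol[["sdlog"]]))

  s <- profile@semiAxesVox  # (X, Y, Z)
  g <- vol^(1 / 3)
  semiX <- s[1] * p$eccXY[1] * g
  semiY <- s[2] * p$eccXY[2] * g
  semiZ <- s[3] * g * zf
  rot <- runif(n, 0, 360)

  thr <- profile@lowIntensityThresholds
  flagLow <- rfp < thr[["muR"]] | gfp < thr[["muG"]]

  # placement: conservative bounding spheres, rejection sampling
  dimXYZ <- as.numeric(tileShape)
  rad <- pmax(semiX, semiY, semiZ) + 0.5
  nBorder <- ceiling(borderFraction * n)
  atBorder <- seq_len(n) <= nBorder  # first cells get border placement
  cx <- cy <- cz <- numeric(n)
  for (i in seq_len(n)) {
    sa <- c(semiX[i], semiY[i], semiZ[i])
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      if (atBorder[i]) {
        ax <- sample(3L, 1L)
        ctr <- numeric(3)
        for (d in 1:3) {
          if (d == ax) {
            side <- sample(c(TRUE, FALSE), 1L)
            off <- runif(1, 0.25, 1) * sa[d]
            ctr[d] <- if (side) off else dimXYZ[d] + 1 - off
          } else {
            ctr[d] <- runif(1, sa[d] + 2, dimXYZ[d] - sa[d] - 1)
          }
        }
      } else {
        ctr <- c(runif(1, sa[1] + 2, dimXYZ[1] - sa[1] - 1),
                 runif(1, sa[2] + 2, dimXYZ[2] - sa[2] - 1),
                 runif(1, sa[3] + 2, dimXYZ[3] - sa[3] - 1))
      }
      if (i > 1L) {
        j <- seq_len(i - 1L)
        d2 <- (cx[j] - ctr[1])^2 + (cy[j] - ctr[2])^2 + (cz[j] - ctr[3])^2
        if (any(d2 <= (rad[j] + rad[i])^2)) next
      }
      cx[i] <- ctr[1]; cy[i] <- ctr[2]; cz[i] <- ctr[3]
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("could not place cell %d of %d after %d tries: ",
                          "cell density exceeds what a %s tile can hold"),
                   i, n, maxTries, paste(tileShape, collapse = "x")))
  }

  data.frame(
    cell_id = seq_len(n), phase = phase,
    center_x = cx, center_y = cy, center_z = cz,
    semi_x = semiX, semi_y = semiY, semi_z = semiZ,
    z_rotation_deg = rot, dna_scale = dna,
    rfp_mean = rfp, gfp_mean = gfp, volume_scale = vol,
    non_expresser = nonExpr, extreme_volume = extreme,
    flag_low = flagLow,
    angle_deg = atan2(gfp, rfp) * 180 / pi,
    stringsAsFactors = FALSE)
}

#' Render a cell population into a multi-channel tile
#'
#' Rasterizes each ellipsoid into the DAPI/GFP/RFP channels and the instance
#' mask. Inside cell i, noiseless DAPI is
#' \code{background + dapiBaseline * dna_scale[i]}, and the reporter
#' channels are \code{background + rfp_mean[i]} / \code{+ gfp_mean[i]};
#' outside, all channels equal \code{background}. Gaussian read noise is
#' then added and everything is clipped to the camera range. Ellipsoids that
#' reach past the tile are truncated (those nuclei touch the border).
#'
#' @param cells data.frame from [sampleCells()] (must fit the tile; cells
#'   overlapping each other are an error).
#' @param profile an [AcquisitionProfile-class].
#' @param noiseSd additive Gaussian noise SD (0 = noiseless).
#' @param background flat offset added to every channel.
#' @param seed integer seed for the noise draw, or NULL.
#' @param tileId identifier stored in the tile and truth table.
#' @param tileShape integer(3) (X, Y, Z).
#' @return A [FucciTile-class]; its truth table is \code{cells} plus
#'   \code{tile_id}, \code{label_id} and rendered \code{volume_voxels}.
#' @export
renderTile <- function(cells, profile, noiseSd = profile@noiseSd,
                       background = profile@background, seed = NULL,
                       tileId = "tile1", tileShape = profile@tileShape) {
  if (!is.null(seed)) set.seed(seed)
  dimZYX <- rev(as.integer(tileShape))
  dapi <- array(background, dimZYX)
  gfpA <- array(background, dimZYX)
  rfpA <- array(background, dimZYX)
  mask <- array(0L, dimZYX)
  volVox <- integer(nrow(cells))

  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    xs <- max(1L, floor(ce$center_x - ce$semi_x - 1)):
          min(dimZYX[3], ceiling(ce$center_x + ce$semi_x + 1))
    ys <- max(1L, floor(ce$center_y - ce$semi_y - 1)):
          min(dimZYX[2], ceiling(ce$center_y + ce$semi_y + 1))
    zs <- max(1L, floor(ce$center_z - ce$semi_z - 1)):
          min(dimZYX[1], ceiling(ce$center_z + ce$semi_z + 1))
    loc <- expand.grid(z = zs, y = ys, x = xs)
    dx <- loc$x - ce$center_x; dy <- loc$y - ce$center_y
    dz <- loc$z - ce$center_z
    th <- ce$z_rotation_deg / 180
    co <- cospi(th); si <- sinpi(th)
    xr <- co * dx + si * dy
    yr <- -si * dx + co * dy
    inside <- (xr / ce$semi_x)^2 + (yr / ce$semi_y)^2 +
              (dz / ce$semi_z)^2 <= 1
    if (!any(inside)) {
      volVox[i] <- 0L
      next
    }
    lin <- (loc$x[inside] - 1L) * dimZYX[1] * dimZYX[2] +
           (loc$y[inside] - 1L) * dimZYX[1] + loc$z[inside]
    if (any(mask[lin] != 0L))
      stop(sprintf("cell %d overlaps a previously rendered cell; ",
                   ce$cell_id),
           "placement must prevent overlap upstream")
    mask[lin] <- i
    dapi[lin] <- dapi[lin] + profile@dapiBaseline * ce$dna_scale
    gfpA[lin] <- gfpA[lin] + ce$gfp_mean
    rfpA[lin] <- rfpA[lin] + ce$rfp_mean
    volVox[i] <- sum(inside)
  }

  hi <- 2^profile@bitDepth - 1
  addNoise <- function(a) {
    if (noiseSd > 0) a <- a + rnorm(length(a), 0, noiseSd)
    a[a < 0] <- 0; a[a > hi] <- hi
    array(a, dimZYX)
  }
  dapi <- addNoise(dapi); gfpA <- addNoise(gfpA); rfpA <- addNoise(rfpA)

  truth <- cells
  if (nrow(truth)) {
    truth$tile_id <- tileId
    truth$label_id <- seq_len(nrow(truth))
    truth$volume_voxels <- volVox
  } else {
    truth$tile_id <- character(); truth$label_id <- integer()
    truth$volume_voxels <- integer()
  }

  new("FucciTile", tileId = tileId,
      channels = list(dapi = dapi, gfp = gfpA, rfp = rfpA),
      mask = mask, truth = truth, profile = profile)
}

#' Simulate a list of tiles in memory
#'
#' Convenience wrapper drawing and rendering \code{nTiles} tiles from one
#' seeded RNG stream (so the whole list is reproducible from one seed).
#'
#' @inheritParams sampleCells
#' @param nTiles number of tiles.
#' @param cellsPerTile cells placed per tile.
#' @param noiseSd,background rendering parameters, see [renderTile()].
#' @param ... further arguments to [sampleCells()].
#' @return list of [FucciTile-class] objects with tile ids
#'   \code{tile001, ...}.
#' @export
simulateTiles <- function(nTiles, profile, seed = 1L, cellsPerTile = 12L,
                          noiseSd = profile@noiseSd,
                          background = profile@background, ...) {
  set.seed(seed)
  lapply(seq_len(nTiles), function(t) {
    cells <- sampleCells(cellsPerTile, profile, seed = NULL, ...)
    renderTile(cells, profile, noiseSd = noiseSd, background = background,
               seed = NULL, tileId = sprintf("tile%03d", t))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes per-tile multi-page TIFFs (one file per channel plus the instance
#' mask), a combined truth CSV, and a JSON manifest recording the seed,
#' profile and file list. Re-running with the same seed reproduces the truth
#' CSV byte for byte.
#'
#' @inheritParams simulateTiles
#' @param outDir output directory (created if needed).
#' @return (invisibly) the manifest as a list.
#' @export
generateDataset <- function(nTiles, profile, outDir, seed = 1L,
                            cellsPerTile = 12L, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tiles <- simulateTiles(nTiles, profile, seed = seed,
                         cellsPerTile = cellsPerTile, ...)
  files <- character()
  truths <- vector("list", length(tiles))
  for (t in seq_along(tiles)) {
    tl <- tiles[[t]]
    for (ch in names(tl@channels)) {
      f <- file.path(outDir, sprintf("%s_%s.tif", tl@tileId, ch))
      writeTiffVolume(tl@channels[[ch]], f)
      files <- c(files, basename(f))
    }
    f <- file.path(outDir, sprintf("%s_mask.tif", tl@tileId))
    writeTiffVolume(tl@mask, f)
    files <- c(files, basename(f))
    truths[[t]] <- tl@truth
  }
  truth <- do.call(rbind, truths)
  truthFile <- file.path(outDir, "truth.csv")
  write.csv(truth, truthFile, row.names = FALSE)
  manifest <- list(
    seed = seed, profile = profile@name,
    tile_shape_xyz = as.integer(profile@tileShape),
    n_tiles = length(tiles), n_cells = nrow(truth),
    axis_order = "volumes are (Z,Y,X); TIFF page k is plane Z=k",
    files = files, truth = basename(truthFile))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate, extract and label a nucleus population tile by tile
#'
#' Streams the full front half of the pipeline: tiles are rendered,
#' quantified and cropped one at a time and immediately discarded, so the
#' peak memory footprint is one tile regardless of the population size.
#' Returns the combined truth table, quantified features and (optionally)
#' masked DAPI crops for the whole population.
#'
#' @inheritParams sampleCells
#' @param nCells total number of nuclei to simulate (the last tile may
#'   hold fewer cells).
#' @param cellsPerTile nuclei per tile.
#' @param cropShape integer(3) (X, Y, Z) crop window, or NULL to skip
#'   crops.
#' @param qc apply [qcFilterMask()] per tile (with solidity computation);
#'   leave off for bulk runs with no border cells.
#' @param solidity compute the solidity feature column.
#' @param noiseSd,background rendering parameters (profile defaults).
#' @param ... further arguments to [sampleCells()] (preset, fractions, ...).
#' @return list with \code{truth} (row-bound truth tables), \code{features}
#'   (row-bound [quantifyNuclei()] tables; row keys
#'   \code{"<tile_id>_<label_id>"} match crop names), \code{crops} and
#'   \code{qc}.
#' @export
simulateNucleusData <- function(nCells, profile, seed = 1L,
                                cellsPerTile = 10L, cropShape = c(32, 32, 32),
                                qc = FALSE, solidity = FALSE,
                                noiseSd = profile@noiseSd,
                                background = profile@background, ...) {
  set.seed(seed)
  nTiles <- ceiling(nCells / cellsPerTile)
  truths <- feats <- qcs <- vector("list", nTiles)
  crops <- list()
  left <- nCells
  for (t in seq_len(nTiles)) {
    k <- min(cellsPerTile, left)
    left <- left - k
    cells <- sampleCells(k, profile, seed = NULL, ...)
    tile <- renderTile(cells, profile, noiseSd = noiseSd,
                       background = background, seed = NULL,
                       tileId = sprintf("tile%03d", t))
    ex <- extractNuclei(list(tile), cropShape = cropShape, qc = qc,
                        solidity = solidity, oversize = "skip")
    truths[[t]] <- tile@truth
    feats[[t]] <- ex$features
    qcs[[t]] <- ex$qc
    if (!is.null(cropShape)) crops <- c(crops, ex$crops)
  }
  out <- list(truth = do.call(rbind, truths),
              features = do.call(rbind, feats),
              crops = if (is.null(cropShape)) NULL else crops,
              qc = do.call(rbind, qcs))
  gc(FALSE)  # tiles churn ~20 MB each; return freed pages promptly
  out
}
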