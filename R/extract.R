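# Per-nucleus quality control, quantification and crop extraction.
#
# Masks are integer (Z, Y, X) instance label arrays (0 = background) from
# any external 3D segmenter (or the simulator). Quantification is purely
# voxel-based: aggregate intensity is an exact sum over mask voxels, volume
# is the voxel count, and axis lengths use the ellipsoid-equivalent
# convention 4*sqrt(eigenvalue) on the voxel-coordinate covariance.

# split linear indices of all foreground voxels by label id
.maskIndex <- function(mask) {
  idx <- which(mask != 0L)
  ids <- mask[idx]
  list(idx = idx, ids = ids, split = split(idx, ids),
       dim = dim(mask))
}

.coordsOf <- function(idx, dm) arrayInd(idx, dm)  # (z, y, x) rows

#' Object quality control on an instance mask
#'
#' Removes poorly segmented objects: any object with a voxel on a tile face
#' (truncated nuclei) when \code{dropBorder}, and any object whose solidity
#' (voxel count / lattice convex volume, see [solidity3d()]) is strictly
#' below \code{solidityMin} (doublets and debris are concave). Surviving
#' label ids are left unchanged.
#'
#' @param mask integer (Z, Y, X) label array.
#' @param solidityMin solidity threshold (objects with solidity <
#'   \code{solidityMin} are removed).
#' @param dropBorder remove objects contacting any tile face.
#' @return list with \code{mask} (filtered copy) and \code{report}
#'   (data.frame \code{label_id}, \code{reason} in \code{border},
#'   \code{solidity}; one row per removed object — empty for an empty
#'   mask). The first matching reason (border before solidity) is recorded.
#'   The report carries the centroid rounding convention used by
#'   [cropNucleus()] as attribute \code{"centroid_rounding"}.
#' @export
qcFilterMask <- function(mask, solidityMin = 0.9, dropBorder = TRUE) {
  mi <- .maskIndex(mask)
  report <- data.frame(label_id = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  attr(report, "centroid_rounding") <-
    "nearest integer, exact halves toward negative infinity"
  if (!length(mi$idx))
    return(list(mask = mask, report = report))
  dm <- mi$dim
  for (id in as.integer(names(mi$split))) {
    co <- .coordsOf(mi$split[[as.character(id)]], dm)
    onBorder <- any(co == 1L) ||
      any(co[, 1] == dm[1]) || any(co[, 2] == dm[2]) || any(co[, 3] == dm[3])
    if (dropBorder && onBorder) {
      report[nrow(report) + 1L, ] <- list(id, "border")
      next
    }
    if (solidity3d(co) < solidityMin)
      report[nrow(report) + 1L, ] <- list(id, "solidity")
  }
  if (nrow(report))
    mask[mask %in% report$label_id] <- 0L
  list(mask = mask, report = report)
}

#' Quantify per-nucleus features from a mask and channel volumes
#'
#' One row per label id present in the mask: centroid, voxel count V,
#' per-channel aggregate (exact sum) and mean intensity over the mask,
#' major/minor axis lengths, border contact, and (optionally) solidity.
#' Aggregate = mean x V holds exactly by construction.
#'
#' @param x a [FucciTile-class], or an integer (Z, Y, X) label mask.
#' @param channels named list of (Z, Y, X) intensity arrays (ignored when
#'   \code{x} is a tile).
#' @param tileId tile identifier stored in the output.
#' @param solidity compute solidity per object (the one moderately expensive
#'   column; disable for bulk runs that do not need it, where it is NA).
#' @return data.frame with columns \code{tile_id}, \code{label_id},
#'   \code{centroid_z/y/x}, \code{volume_vox}, \code{<ch>_sum} and
#'   \code{<ch>_mean} per channel, \code{major_axis}, \code{minor_axis},
#'   \code{touches_border}, \code{solidity}.
#' @export
quantifyNuclei <- function(x, channels = NULL, tileId = "tile",
                           solidity = TRUE) {
  if (is(x, "FucciTile")) {
    channels <- x@channels
    tileId <- x@tileId
    mask <- x@mask
  } else mask <- x
  stopifnot(is.list(channels), length(channels) >= 1L)
  for (ch in channels) stopifnot(identical(dim(ch), dim(mask)))

  mi <- .maskIndex(mask)
  uids <- as.integer(names(mi$split))
  n <- length(uids)
  dm <- mi$dim
  out <- data.frame(tile_id = rep(tileId, n), label_id = uids)
  if (!n) {
    for (nm in names(channels)) {
      out[[paste0(nm, "_sum")]] <- numeric()
      out[[paste0(nm, "_mean")]] <- numeric()
    }
    out$centroid_z <- out$centroid_y <- out$centroid_x <- numeric()
    out$volume_vox <- integer()
    out$major_axis <- out$minor_axis <- numeric()
    out$touches_border <- logical()
    out$solidity <- numeric()
    return(out)
  }

  fid <- factor(mi$ids, levels = uids)
  V <- as.integer(table(fid))
  co <- .coordsOf(mi$idx, dm)
  cen <- rowsum(co, fid) / V
  out$centroid_z <- cen[, 1]; out$centroid_y <- cen[, 2]
  out$centroid_x <- cen[, 3]
  out$volume_vox <- V
  for (nm in names(channels)) {
    s <- as.vector(rowsum(channels[[nm]][mi$idx], fid))
    out[[paste0(nm, "_sum")]] <- s
    out[[paste0(nm, "_mean")]] <- s / V
  }
  border <- co[, 1] == 1L | co[, 1] == dm[1] |
            co[, 2] == 1L | co[, 2] == dm[2] |
            co[, 3] == 1L | co[, 3] == dm[3]
  out$touches_border <- as.vector(rowsum(border * 1, fid)) > 0

  major <- minor <- numeric(n)
  sol <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ck <- .coordsOf(mi$split[[k]], dm)
    if (nrow(ck) > 1L) {
      cc <- sweep(ck, 2, colMeans(ck))
      ev <- eigen(crossprod(cc) / nrow(ck), symmetric = TRUE,
                  only.values = TRUE)$values
      major[k] <- 4 * sqrt(max(ev[1], 0))
      minor[k] <- 4 * sqrt(max(ev[3], 0))
    }
    if (solidity) sol[k] <- solidity3d(ck)
  }
  out$major_axis <- major
  out$minor_axis <- minor
  out$solidity <- sol
  out
}

#' Extract a standardized single-nucleus crop
#'
#' Cuts a window of \code{cropShape} voxels centered on the nucleus'
#' rounded centroid from the DAPI volume; voxels not belonging to the
#' nucleus are zeroed (masked crop), and window regions outside the tile
#' are zero-padded. The integrated intensity of the crop therefore equals
#' the nucleus' aggregate DAPI exactly.
#'
#' @param dapi (Z, Y, X) intensity volume.
#' @param mask (Z, Y, X) integer label mask.
#' @param labelId label to extract.
#' @param cropShape integer(3) (X, Y, Z) window size (default the standard
#'   150 x 150 x 90 single-nucleus window).
#' @return (Z, Y, X) array of shape \code{rev(cropShape)}.
#' @export
cropNucleus <- function(dapi, mask, labelId, cropShape = c(150L, 150L, 90L)) {
  stopifnot(identical(dim(dapi), dim(mask)))
  cs <- rev(as.integer(cropShape))  # (Z, Y, X)
  idx <- which(mask == labelId)
  if (!length(idx)) stop("label ", labelId, " not present in mask")
  dm <- dim(mask)
  co <- .coordsOf(idx, dm)
  ctr <- .roundHalfDown(colMeans(co))
  lo <- ctr - (cs - 1L) %/% 2L
  hi <- lo + cs - 1L
  if (any(apply(co, 2, min) < lo) || any(apply(co, 2, max) > hi))
    stop(sprintf("nucleus %d does not fit the %s crop window",
                 labelId, paste(cropShape, collapse = "x")))
  out <- array(0, cs)
  sLo <- pmax(lo, 1L); sHi <- pmin(hi, dm)
  dLo <- sLo - lo + 1L; dHi <- dLo + (sHi - sLo)
  src <- dapi[sLo[1]:sHi[1], sLo[2]:sHi[2], sLo[3]:sHi[3], drop = FALSE] *
    (mask[sLo[1]:sHi[1], sLo[2]:sHi[2], sLo[3]:sHi[3], drop = FALSE] ==
       labelId)
  out[dLo[1]:dHi[1], dLo[2]:dHi[2], dLo[3]:dHi[3]] <- src
  out
}

#' Run QC, quantification and cropping over a list of tiles
#'
#' Orchestrates [qcFilterMask()], [quantifyNuclei()] and [cropNucleus()]
#' over simulated or loaded tiles and returns tidy combined outputs. Crop
#' names are \code{"<tile_id>_<label_id>"}.
#'
#' @param tiles list of [FucciTile-class] objects.
#' @param cropShape integer(3) (X, Y, Z) crop window, or NULL to skip crops.
#' @param qc apply [qcFilterMask()] first.
#' @param solidityMin,dropBorder QC parameters.
#' @param solidity compute the solidity column in the feature table.
#' @param oversize what to do with a nucleus that does not fit the crop
#'   window: \code{"error"} (the [cropNucleus()] contract) or
#'   \code{"skip"} — drop it from features and crops, recording reason
#'   \code{"crop_window"} in the QC report (useful for bulk simulation
#'   runs where rare size outliers are expected).
#' @return list with \code{features} (row-bound [quantifyNuclei()] tables),
#'   \code{crops} (named list of (Z, Y, X) arrays, NULL if skipped) and
#'   \code{qc} (row-bound QC reports with a tile_id column).
#' @export
extractNuclei <- function(tiles, cropShape = c(150L, 150L, 90L), qc = TRUE,
                          solidityMin = 0.9, dropBorder = TRUE,
                          solidity = TRUE,
                          oversize = c("error", "skip")) {
  oversize <- match.arg(oversize)
  feats <- list(); crops <- list(); qcs <- list()
  for (tl in tiles) {
    mask <- tl@mask
    if (qc) {
      fl <- qcFilterMask(mask, solidityMin = solidityMin,
                         dropBorder = dropBorder)
      mask <- fl$mask
      if (nrow(fl$report))
        qcs[[tl@tileId]] <- cbind(tile_id = tl@tileId, fl$report)
    }
    ft <- quantifyNuclei(mask, tl@channels, tileId = tl@tileId,
                         solidity = solidity)
    if (!is.null(cropShape)) {
      dropped <- integer()
      for (id in ft$label_id) {
        cr <- if (oversize == "skip")
          tryCatch(cropNucleus(tl@channels$dapi, mask, id, cropShape),
                   error = function(e) NULL)
        else cropNucleus(tl@channels$dapi, mask, id, cropShape)
        if (is.null(cr)) dropped <- c(dropped, id)
        else crops[[sprintf("%s_%d", tl@tileId, id)]] <- cr
      }
      if (length(dropped)) {
        ft <- ft[!ft$label_id %in% dropped, ]
        qcs[[paste0(tl@tileId, "_crop")]] <-
          data.frame(tile_id = tl@tileId, label_id = dropped,
                     reason = "crop_window", stringsAsFactors = FALSE)
      }
    }
    feats[[tl@tileId]] <- ft
  }
  list(features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
       crops = if (is.null(cropShape)) NULL else crops,
       qc = if (length(qcs))
         do.call(rbind, c(qcs, list(make.row.names = FALSE)))
       else data.frame(tile_id = character(), label_id = integer(),
                       reason = character()))
}
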