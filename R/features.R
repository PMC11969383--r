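# Handcrafted nuclear morphology features for the SVM baselines.
#
# 2D features are measured on the Z maximum-intensity projection of the
# masked crop (background is zero, so the 2D support equals the projected
# 3D mask); 3D features are measured on the crop itself. All geometry is in
# voxel/pixel units on voxel-center coordinates — the SVMs z-score every
# feature, so global unit scaling is irrelevant.

#' Maximum-intensity projection along Z
#'
#' @param volume nonnegative (Z, Y, X) array (a masked single-nucleus crop).
#' @return list with \code{image} ((Y, X) matrix of per-pixel Z maxima) and
#'   \code{mask} ((Y, X) logical union of the per-plane support).
#' @export
maxProjectZ <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  d <- dim(volume)
  img <- apply(volume, c(2, 3), max)
  list(image = img, mask = img > 0)
}

#' 2D morphology features of a projected nucleus
#'
#' Integrated intensity, area, lattice convex area, bounding box area,
#' equivalent diameter \eqn{\sqrt{4 A / \pi}}, extent (area / bbox area),
#' maximum Feret diameter (largest distance between convex hull vertex
#' centers) and solidity (area / convex area).
#'
#' @param image (Y, X) intensity matrix.
#' @param mask (Y, X) logical support; defaults to \code{image > 0}.
#' @return one-row data.frame: \code{intden2d}, \code{area},
#'   \code{convex_area}, \code{bbox_area}, \code{equiv_diameter},
#'   \code{extent}, \code{feret_max}, \code{solidity2d}.
#' @export
features2d <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- image > 0
  if (!any(mask)) stop("features2d: empty mask")
  idx <- which(mask)
  co <- arrayInd(idx, dim(mask))
  area <- length(idx)
  bbox <- (diff(range(co[, 1])) + 1L) * (diff(range(co[, 2])) + 1L)
  convA <- convexAreaPx(co)
  data.frame(
    intden2d = sum(image[idx]),
    area = area,
    convex_area = convA,
    bbox_area = bbox,
    equiv_diameter = sqrt(4 * area / pi),
    extent = area / bbox,
    feret_max = feretMaxPx(co),
    solidity2d = area / convA)
}

#' 3D morphology features of a nucleus crop
#'
#' Integrated intensity, voxel count, lattice convex volume, bounding box
#' volume, surface area of the triangulated 0.5-isosurface of the
#' (lightly smoothed) binary mask, and sphericity
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}. Discretization can push sphericity of
#' near-spherical objects marginally above 1; such values are clamped to 1
#' with a warning.
#'
#' @param volume (Z, Y, X) intensity array (masked crop).
#' @param mask (Z, Y, X) logical support; defaults to \code{volume > 0}.
#' @param smoothSigma Gaussian pre-smoothing SD for [surfaceArea3d()].
#' @return one-row data.frame: \code{intden3d}, \code{volume_vox},
#'   \code{convex_volume}, \code{bbox_volume}, \code{surface_area},
#'   \code{sphericity}.
#' @export
features3d <- function(volume, mask = NULL, smoothSigma = 0.8) {
  if (is.null(mask)) mask <- volume > 0
  if (!any(mask)) stop("features3d: empty mask")
  idx <- which(mask)
  co <- arrayInd(idx, dim(mask))
  V <- length(idx)
  bbox <- prod(apply(co, 2, function(v) diff(range(v)) + 1L))
  sa <- surfaceArea3d(mask, sigma = smoothSigma)
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / sa
  if (sph > 1) {
    warning(sprintf("sphericity %.4f > 1 from discretization; clamped to 1",
                    sph))
    sph <- 1
  }
  data.frame(
    intden3d = sum(volume[idx]),
    volume_vox = V,
    convex_volume = convexVolumeVox(co),
    bbox_volume = bbox,
    surface_area = sa,
    sphericity = sph)
}

#' Feature table over a list of single-nucleus crops
#'
#' Computes the selected feature set for every crop; the 2D set is measured
#' on the Z max projection via [maxProjectZ()].
#'
#' @param crops named list of (Z, Y, X) masked crops.
#' @param set \code{"2d"}, \code{"3d"} or \code{"both"}.
#' @param ... passed on to [features3d()].
#' @return data.frame with an \code{id} column (crop names) and the feature
#'   columns.
#' @export
featureTable <- function(crops, set = c("both", "2d", "3d"), ...) {
  set <- match.arg(set)
  rows <- lapply(names(crops), function(nm) {
    v <- crops[[nm]]
    parts <- list(data.frame(id = nm, stringsAsFactors = FALSE))
    if (set %in% c("2d", "both")) {
      pr <- maxProjectZ(v)
      parts <- c(parts, list(features2d(pr$image, pr$mask)))
    }
    if (set %in% c("3d", "both"))
      parts <- c(parts, list(features3d(v, ...)))
    do.call(cbind, parts)
  })
  do.call(rbind, rows)
}

#' Z-score scaling fitted on training rows
#'
#' `zscoreFit()` computes per-feature mean and SD on the training rows
#' only; `zscoreApply()` standardizes any table with those statistics, so
#' validation/test rows never influence the scaling. Constant features are
#' rejected by name.
#'
#' @param rows data.frame of numeric feature columns.
#' @param cols character vector of columns to scale (default: all numeric).
#' @param trainIdx integer/logical index of training rows (>= 2 rows).
#' @return `zscoreFit()`: a \code{ScalingStats} list with \code{cols},
#'   \code{mean}, \code{sd}.
#' @export
zscoreFit <- function(rows, cols = NULL, trainIdx = seq_len(nrow(rows))) {
  if (is.null(cols))
    cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
  tr <- rows[trainIdx, cols, drop = FALSE]
  if (nrow(tr) < 2L) stop("zscoreFit needs at least 2 training rows")
  mu <- vapply(tr, mean, numeric(1))
  sg <- vapply(tr, stats::sd, numeric(1))
  bad <- sg == 0 | !is.finite(sg)
  if (any(bad))
    stop("constant feature(s) cannot be z-scored: ",
         paste(cols[bad], collapse = ", "))
  structure(list(cols = cols, mean = mu, sd = sg), class = "ScalingStats")
}

#' @rdname zscoreFit
#' @param stats a \code{ScalingStats} from `zscoreFit()`.
#' @return `zscoreApply()`: \code{rows} with the scaled columns replaced.
#' @export
zscoreApply <- function(rows, stats) {
  for (j in seq_along(stats$cols)) {
    cl <- stats$cols[j]
    rows[[cl]] <- (rows[[cl]] - stats$mean[j]) / stats$sd[j]
  }
  rows
}
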