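# Crop-to-tensor preprocessing: platform-specific block-mean downsampling,
# median-of-medians normalization, centered zero-padding, the 70/20/10
# split, and Z-rotation augmentation. The end-to-end contract is that every
# profile's pipeline emits volumes of one final shape — with the standard
# 150x150x90 crop, (Z, Y, X) = (90, 75, 75) for both instrument profiles.

# block mean along the first axis; output length ceil(len/f), trailing
# partial blocks average over the voxels that exist
.blockMean1 <- function(a, f) {
  if (f == 1L) return(a)
  d <- dim(a)
  L <- d[1]
  Lo <- ceiling(L / f)
  m <- matrix(a, L, prod(d[-1]))
  grp <- rep(seq_len(Lo), each = f, length.out = L)
  out <- rowsum(m, grp) / as.vector(table(grp))
  array(out, c(Lo, d[-1]))
}

#' Block-mean downsampling of a volume
#'
#' Each output voxel is the mean of its factor-block (anti-aliased, and
#' conserving integrated intensity up to edge effects), so a constant
#' volume stays constant. Output axis lengths are \code{ceiling(len /
#' factor)}.
#'
#' @param volume (Z, Y, X) array.
#' @param factors integer(3) downsampling factors in (X, Y, Z) order (the
#'   user-facing convention; e.g. epifluorescence crops use (2, 2, 1)).
#' @return downsampled (Z, Y, X) array.
#' @export
downsampleVolume <- function(volume, factors) {
  stopifnot(length(dim(volume)) == 3L, length(factors) == 3L,
            all(factors >= 1), all(factors == round(factors)))
  f <- rev(as.integer(factors))  # to (Z, Y, X)
  for (ax in 1:3) volume <- aperm(.blockMean1(volume, f[ax]), c(2, 3, 1))
  volume
}

#' Median-of-medians intensity normalization
#'
#' `fitNormConstant()` computes, on the training crops only, the median of
#' the per-crop medians of nonzero voxels; `applyNorm()` divides any crop
#' by that constant. One global constant keeps intensity scales comparable
#' across the train/validation/test splits.
#'
#' @param crops list of (Z, Y, X) masked crops (each needs at least one
#'   nonzero voxel).
#' @return `fitNormConstant()`: the normalization constant (scalar > 0).
#' @export
fitNormConstant <- function(crops) {
  med <- vapply(seq_along(crops), function(i) {
    v <- crops[[i]]
    nz <- v[v != 0]
    if (!length(nz))
      stop("all-zero crop at position ", i,
           if (!is.null(names(crops))) paste0(" ('", names(crops)[i], "')")
           else "", "; cannot take a nonzero-voxel median")
    median(nz)
  }, numeric(1))
  median(med)
}

#' @rdname fitNormConstant
#' @param volume a crop.
#' @param normConstant constant from `fitNormConstant()`.
#' @return `applyNorm()`: \code{volume / normConstant}.
#' @export
applyNorm <- function(volume, normConstant) {
  stopifnot(normConstant > 0)
  volume / normConstant
}

#' Centered zero-padding to a final shape
#'
#' Pads each axis symmetrically with zeros; an odd remainder puts the extra
#' plane on the trailing side. Integrated intensity is unchanged.
#'
#' @param volume (Z, Y, X) array, no larger than \code{finalShape} per axis.
#' @param finalShape integer(3) target shape in (X, Y, Z) order (default
#'   the standard 75 x 75 x 90 network input).
#' @return (Z, Y, X) array of shape \code{rev(finalShape)}.
#' @export
finalPad <- function(volume, finalShape = c(75L, 75L, 90L)) {
  fs <- rev(as.integer(finalShape))
  d <- dim(volume)
  if (any(d > fs))
    stop(sprintf("volume (%s) larger than the final shape (%s)",
                 paste(d, collapse = "x"), paste(fs, collapse = "x")))
  before <- (fs - d) %/% 2L
  out <- array(0, fs)
  out[before[1] + seq_len(d[1]), before[2] + seq_len(d[2]),
      before[3] + seq_len(d[3])] <- volume
  out
}

#' Deterministic 70/20/10 split
#'
#' Shuffles the ids with a fixed seed and cuts them into train/validation/
#' test sets whose sizes follow the fractions under largest-remainder
#' rounding, so the parts are disjoint and exhaustive.
#'
#' @param ids vector of unique ids (at least 3).
#' @param fractions numeric(3) summing to 1.
#' @param seed integer seed.
#' @param stratifyBy optional vector (same length as \code{ids}) of group
#'   labels; when given, each stratum is split separately so class
#'   balance is preserved across the parts.
#' @return list \code{train}, \code{val}, \code{test}.
#' @export
makeSplit <- function(ids, fractions = c(0.7, 0.2, 0.1), seed = 1L,
                      stratifyBy = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  if (anyDuplicated(ids)) stop("split ids must be unique")
  if (!is.null(stratifyBy)) {
    stopifnot(length(stratifyBy) == length(ids))
    parts <- list(train = c(), val = c(), test = c())
    for (g in seq_along(unique(stratifyBy))) {
      sel <- stratifyBy == unique(stratifyBy)[g]
      sp <- makeSplit(ids[sel], fractions, seed = seed + g)
      for (nm in names(parts)) parts[[nm]] <- c(parts[[nm]], sp[[nm]])
    }
    return(parts)
  }
  n <- length(ids)
  if (n < 3L) stop("need at least 3 ids to split")
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1L
  }
  set.seed(seed)
  ord <- sample(ids)
  list(train = ord[seq_len(sizes[1])],
       val = ord[sizes[1] + seq_len(sizes[2])],
       test = ord[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Rotate a volume about the Z axis
#'
#' Rotates every Z-plane by the same angle about the plane center with
#' bilinear interpolation and zero fill, preserving the shape. Multiples of
#' 90 degrees are exact index permutations (the trigonometry goes through
#' \code{cospi}/\code{sinpi}, so the weights are exact 0/1).
#'
#' @param volume (Z, Y, X) array.
#' @param angle rotation angle in degrees, counterclockwise in the (X, Y)
#'   plane.
#' @return rotated (Z, Y, X) array.
#' @export
rotateZ <- function(volume, angle) {
  d <- dim(volume)
  if (angle %% 360 == 0) return(volume)
  Y <- d[2]; X <- d[3]
  cy <- (Y + 1) / 2; cx <- (X + 1) / 2
  g <- expand.grid(y = seq_len(Y), x = seq_len(X))
  dy <- g$y - cy; dx <- g$x - cx
  a <- angle / 180
  co <- cospi(a); si <- sinpi(a)
  # inverse mapping: source coordinate for each output pixel
  sx <- co * dx + si * dy + cx
  sy <- -si * dx + co * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  m <- matrix(volume, d[1], Y * X)  # planes as rows; columns (y, x)
  out <- matrix(0, d[1], Y * X)
  for (ky in 0:1) for (kx in 0:1) {
    yy <- y0 + ky; xx <- x0 + kx
    w <- (if (ky == 1) fy else 1 - fy) * (if (kx == 1) fx else 1 - fx)
    ok <- which(yy >= 1 & yy <= Y & xx >= 1 & xx <= X & w > 0)
    if (!length(ok)) next
    srcCol <- (xx[ok] - 1L) * Y + yy[ok]
    out[, ok] <- out[, ok] + m[, srcCol, drop = FALSE] *
      rep(w[ok], each = d[1])
  }
  array(out, d)
}

#' Preprocess crops into network-ready volumes with a split manifest
#'
#' Runs the full pipeline: split ids 70/20/10 (seeded), downsample each
#' crop by the profile's factors, fit the normalization constant on the
#' training crops only, normalize everything with it, and zero-pad to the
#' final shape. The manifest records ids, split assignment, labels, the
#' seed and the constant, so no-leakage audits are mechanical.
#'
#' @param crops named list of (Z, Y, X) masked crops.
#' @param meta data.frame with columns \code{id} (matching crop names) and
#'   any per-nucleus targets to carry (e.g. \code{label}, \code{theta_deg}).
#' @param profile an [AcquisitionProfile-class] (supplies the downsampling
#'   factors).
#' @param seed split seed.
#' @param finalShape integer(3) (X, Y, Z) network input shape.
#' @param fractions split fractions.
#' @param norm \code{"global"} (default): every crop, including training
#'   crops, is divided by the one median-of-training-medians constant;
#'   \code{"per-crop-train"}: each training crop is divided by its own
#'   nonzero-voxel median instead, validation/test still by the global
#'   constant.
#' @param stratifyBy optional column name in \code{meta} to stratify the
#'   split by (e.g. the class label).
#' @return list with \code{volumes} (named list, all of shape
#'   \code{rev(finalShape)}) and \code{manifest} (list: \code{items}
#'   data.frame with \code{id}, \code{split} and the meta columns;
#'   \code{norm_constant}; \code{final_shape_zyx}; \code{seed};
#'   \code{profile}).
#' @export
preprocessDataset <- function(crops, meta, profile, seed = 1L,
                              finalShape = c(75L, 75L, 90L),
                              fractions = c(0.7, 0.2, 0.1),
                              norm = c("global", "per-crop-train"),
                              stratifyBy = NULL) {
  norm <- match.arg(norm)
  stopifnot(all(names(crops) %in% meta$id), all(meta$id %in% names(crops)))
  strat <- if (is.null(stratifyBy)) NULL
           else meta[[stratifyBy]][match(names(crops), meta$id)]
  sp <- makeSplit(names(crops), fractions = fractions, seed = seed,
                  stratifyBy = strat)
  ds <- lapply(crops, downsampleVolume,
               factors = profile@downsampleFactors)
  k <- fitNormConstant(ds[sp$train])
  vols <- lapply(names(ds), function(id) {
    v <- ds[[id]]
    ki <- if (norm == "per-crop-train" && id %in% sp$train)
      median(v[v != 0]) else k
    finalPad(applyNorm(v, ki), finalShape)
  })
  names(vols) <- names(ds)
  items <- meta
  items$split <- NA_character_
  items$split[match(sp$train, items$id)] <- "train"
  items$split[match(sp$val, items$id)] <- "val"
  items$split[match(sp$test, items$id)] <- "test"
  list(volumes = vols,
       manifest = list(items = items, norm_constant = k,
                       final_shape_zyx = rev(as.integer(finalShape)),
                       seed = seed, profile = profile@name))
}

#' Merge preprocessed datasets from multiple acquisitions
#'
#' Concatenates manifests while preserving each source's own train/val/test
#' assignment (no item changes split, so there is no leakage across the
#' merge) and each source's own normalization constant. Ids must be
#' globally unique.
#'
#' @param datasets list of results from [preprocessDataset()].
#' @param sources character vector naming each dataset (recorded per item).
#' @return a merged dataset: \code{volumes}, and \code{manifest} with
#'   per-source \code{norm_constant}s.
#' @export
mergeDatasets <- function(datasets,
                          sources = paste0("source", seq_along(datasets))) {
  stopifnot(length(datasets) >= 2L, length(sources) == length(datasets))
  fs <- lapply(datasets, function(d) d$manifest$final_shape_zyx)
  if (!all(vapply(fs, identical, logical(1), y = fs[[1]])))
    stop("final shapes differ between datasets; cannot merge")
  ids <- unlist(lapply(datasets, function(d) d$manifest$items$id))
  if (anyDuplicated(ids))
    stop("duplicate ids across datasets: ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  items <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    it <- datasets[[i]]$manifest$items
    it$source <- sources[i]
    it
  }))
  vols <- do.call(c, lapply(datasets, function(d) d$volumes))
  list(volumes = vols,
       manifest = list(items = items,
                       norm_constant = setNames(
                         vapply(datasets,
                                function(d) d$manifest$norm_constant,
                                numeric(1)), sources),
                       final_shape_zyx = fs[[1]],
                       seed = vapply(datasets,
                                     function(d) d$manifest$seed,
                                     numeric(1)),
                       profile = vapply(datasets,
                                        function(d) d$manifest$profile,
                                        character(1))))
}
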