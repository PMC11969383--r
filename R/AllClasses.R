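#' Acquisition profile for an imaging platform
#'
#' Bundles the platform-specific constants the pipeline needs: voxel size,
#' default tile geometry, camera bit depth, the low-intensity thresholds used
#' by the Fucci ground-truth filters, and the XY(Z) downsampling factors used
#' during volume preprocessing. Simulator baselines (nominal nucleus
#' semi-axes, DAPI density, background, read noise) live here too so that a
#' profile fully determines how synthetic tiles look.
#'
#' All user-facing triples are in (X, Y, Z) order; volumes themselves are
#' stored (Z, Y, X), matching planewise TIFF page order.
#'
#' @slot name profile name, e.g. \code{"epifluorescence"}.
#' @slot voxelNm numeric(3), voxel edge lengths in nanometres (X, Y, Z).
#' @slot tileShape integer(3), default tile shape in voxels (X, Y, Z),
#'   each at least 64.
#' @slot bitDepth camera bit depth (14 or 16); intensities live in
#'   \eqn{[0, 2^{bit} - 1]}.
#' @slot lowIntensityThresholds named numeric(2) \code{c(muR=, muG=)}:
#'   a nucleus whose mean RFP or mean GFP falls strictly below its threshold
#'   is treated as not expressing the Fucci reporter.
#' @slot downsampleFactors integer(3) (X, Y, Z) block-mean downsampling
#'   factors applied to single-nucleus crops before model input.
#' @slot semiAxesVox numeric(3) baseline nucleus ellipsoid semi-axes in
#'   voxels (X, Y, Z) for the simulator.
#' @slot dapiBaseline baseline DAPI density (intensity per voxel at DNA
#'   scale 1) for the simulator.
#' @slot background flat background offset added to every channel by the
#'   simulator.
#' @slot noiseSd default additive Gaussian read-noise SD for the simulator.
#'
#' @seealso [epiProfile()], [confocalProfile()], [miniProfile()]
#' @export
setClass("AcquisitionProfile",
  representation(
    name = "character",
    voxelNm = "numeric",
    tileShape = "integer",
    bitDepth = "integer",
    lowIntensityThresholds = "numeric",
    downsampleFactors = "integer",
    semiAxesVox = "numeric",
    dapiBaseline = "numeric",
    background = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("AcquisitionProfile", function(object) {
  msg <- character()
  if (length(object@voxelNm) != 3L || any(object@voxelNm <= 0))
    msg <- c(msg, "voxelNm must be 3 strictly positive values")
  if (length(object@tileShape) != 3L || any(object@tileShape < 64L))
    msg <- c(msg, "tileShape must be 3 values, each >= 64")
  if (!object@bitDepth %in% c(14L, 16L))
    msg <- c(msg, "bitDepth must be 14 or 16")
  thr <- object@lowIntensityThresholds
  if (length(thr) != 2L || any(thr < 0) ||
      !all(c("muR", "muG") %in% names(thr)))
    msg <- c(msg, "lowIntensityThresholds must be named c(muR=, muG=), >= 0")
  if (length(object@downsampleFactors) != 3L ||
      any(object@downsampleFactors < 1L))
    msg <- c(msg, "downsampleFactors must be 3 positive integers")
  if (length(object@semiAxesVox) != 3L || any(object@semiAxesVox <= 0))
    msg <- c(msg, "semiAxesVox must be 3 strictly positive values")
  if (length(msg)) msg else TRUE
})

#' Synthetic multi-channel imaging tile
#'
#' One simulated field of view: three 3D intensity volumes (DAPI, GFP, RFP),
#' the instance label mask (0 = background, ids 1..n), and the per-nucleus
#' truth table recording each cell's drawn parameters, rendered voxel count
#' and true phase/angle. Volumes are (Z, Y, X) arrays.
#'
#' @slot tileId tile identifier.
#' @slot channels named list of three numeric (Z, Y, X) arrays:
#'   \code{dapi}, \code{gfp}, \code{rfp}.
#' @slot mask integer (Z, Y, X) array of instance labels.
#' @slot truth data.frame, one row per rendered cell (see [sampleCells()]
#'   for columns); every nonzero mask id appears here.
#' @slot profile the [AcquisitionProfile-class] the tile was rendered under.
#'
#' @export
setClass("FucciTile",
  representation(
    tileId = "character",
    channels = "list",
    mask = "array",
    truth = "data.frame",
    profile = "AcquisitionProfile"
  )
)

setValidity("FucciTile", function(object) {
  msg <- character()
  chn <- object@channels
  if (!identical(sort(names(chn)), c("dapi", "gfp", "rfp")))
    msg <- c(msg, "channels must be named dapi, gfp, rfp")
  dm <- dim(object@mask)
  for (nm in names(chn)) {
    if (!identical(dim(chn[[nm]]), dm))
      msg <- c(msg, sprintf("channel '%s' shape differs from mask", nm))
  }
  hi <- 2^object@profile@bitDepth - 1
  for (nm in names(chn)) {
    r <- range(chn[[nm]])
    if (r[1] < 0 || r[2] > hi) {
      msg <- c(msg, sprintf("channel '%s' outside [0, %d]", nm, hi))
      break
    }
  }
  ids <- setdiff(unique(as.vector(object@mask)), 0L)
  if (!all(ids %in% object@truth$label_id))
    msg <- c(msg, "mask contains label ids missing from truth")
  if (length(msg)) msg else TRUE
})

#' Volumetric convolutional cell cycle model
#'
#' A 3D (or 2D) convolutional network for staging nuclei from DAPI volumes.
#' The encoder is four convolutional blocks with channel-group normalization
#' and rectified-linear units; a global max-pool head reduces any admissible
#' input to a 256-vector which a dropout + single affine unit maps to one
#' scalar (a logit under the classification head, degrees under the
#' regression head). Parameters are plain numeric arrays; the forward and
#' backward passes run through the package's GEMM-based layer engine.
#'
#' @slot arch \code{"3d"} or \code{"2d"}.
#' @slot mode \code{"classification"} or \code{"regression"}.
#' @slot layers list of layer descriptors (internal).
#' @slot params named list of numeric parameter arrays.
#' @slot initSeed integer seed the weights were initialized from.
#'
#' @seealso [buildCnn3d()], [buildCnn2d()], [countParameters()]
#' @export
setClass("CycleNet",
  representation(
    arch = "character",
    mode = "character",
    layers = "list",
    params = "list",
    initSeed = "integer"
  )
)

setValidity("CycleNet", function(object) {
  msg <- character()
  if (!object@arch %in% c("3d", "2d"))
    msg <- c(msg, "arch must be '3d' or '2d'")
  if (!object@mode %in% c("classification", "regression"))
    msg <- c(msg, "mode must be 'classification' or 'regression'")
  if (length(msg)) msg else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "AcquisitionProfile", function(object) {
  cat(sprintf("AcquisitionProfile '%s'\n", object@name))
  cat(sprintf("  voxel (nm, XYZ): %s\n",
              paste(object@voxelNm, collapse = " x ")))
  cat(sprintf("  tile shape (vox, XYZ): %s   bit depth: %d\n",
              paste(object@tileShape, collapse = " x "), object@bitDepth))
  cat(sprintf("  low-intensity thresholds: muR < %g, muG < %g\n",
              object@lowIntensityThresholds[["muR"]],
              object@lowIntensityThresholds[["muG"]]))
  cat(sprintf("  crop downsampling (XYZ): %s\n",
              paste(object@downsampleFactors, collapse = " x ")))
})

setMethod("show", "FucciTile", function(object) {
  dm <- dim(object@mask)
  cat(sprintf("FucciTile '%s' (%s profile)\n", object@tileId,
              object@profile@name))
  cat(sprintf("  volume (Z,Y,X): %s   cells: %d\n",
              paste(dm, collapse = " x "), nrow(object@truth)))
  if (nrow(object@truth))
    cat(sprintf("  phases: %s\n",
                paste(names(table(object@truth$phase)),
                      table(object@truth$phase),
                      sep = "=", collapse = ", ")))
})

setMethod("show", "CycleNet", function(object) {
  cat(sprintf("CycleNet (%s, %s head)\n", object@arch, object@mode))
  tab <- paramCountTable(object)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-6s %10d params\n", tab$part[i], tab$n_params[i]))
  cat(sprintf("  total  %10d params\n", countParameters(object)))
})

# ---- accessors ------------------------------------------------------------

#' @describeIn FucciTile-class channel volumes (named list of (Z,Y,X) arrays)
#' @param tile a \code{FucciTile}
#' @export
tileChannels <- function(tile) tile@channels

#' @describeIn FucciTile-class instance label mask ((Z,Y,X) integer array)
#' @export
tileMask <- function(tile) tile@mask

#' @describeIn FucciTile-class per-nucleus truth table
#' @export
tileTruth <- function(tile) tile@truth

#' @describeIn FucciTile-class acquisition profile of the tile
#' @export
tileProfile <- function(tile) tile@profile

#' @describeIn CycleNet-class named list of parameter arrays
#' @param net a \code{CycleNet}
#' @export
netParams <- function(net) net@params

#' @describeIn CycleNet-class architecture tag ("3d" or "2d")
#' @export
netArch <- function(net) net@arch

#' @describeIn CycleNet-class head mode ("classification" or "regression")
#' @export
netMode <- function(net) net@mode
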