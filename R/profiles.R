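#' Built-in acquisition profiles
#'
#' Three ready-made [AcquisitionProfile-class] objects:
#'
#' \describe{
#'   \item{`epiProfile()`}{Widefield epifluorescence: 188 x 188 x 500 nm
#'     voxels, 14-bit camera, strongly anisotropic Z. Crops are downsampled
#'     2x in X and Y only, which roughly isotropizes the voxel.
#'     Low-intensity thresholds: mean RFP < 1500 or mean GFP < 2200.}
#'   \item{`confocalProfile()`}{Spinning-disk confocal: 182 x 182 x 200 nm
#'     voxels, 16-bit camera. Crops are downsampled 2x in X, Y and Z.
#'     Low-intensity thresholds: mean RFP < 700 or mean GFP < 2000.}
#'   \item{`miniProfile()`}{A synthetic desk-scale profile (isotropic 400 nm
#'     voxels, small tiles) used for fast end-to-end exercises of the
#'     pipeline. It shares the epifluorescence thresholds and is not meant
#'     to emulate any real instrument.}
#' }
#'
#' The default tile shapes are intentionally smaller than real microscope
#' fields so that simulated datasets stay desk-sized; nucleus geometry is
#' scaled to the voxel size so nuclei have realistic ~8-10 micron diameters
#' under the two instrument profiles.
#'
#' @param tileShape optional integer(3) (X, Y, Z) overriding the default
#'   tile shape; each entry must be >= 64.
#' @return An [AcquisitionProfile-class].
#' @examples
#' epiProfile()
#' confocalProfile(tileShape = c(128, 128, 64))
#' @export
epiProfile <- function(tileShape = c(192L, 192L, 64L)) {
  new("AcquisitionProfile",
    name = "epifluorescence",
    voxelNm = c(188, 188, 500),
    tileShape = as.integer(tileShape),
    bitDepth = 14L,
    lowIntensityThresholds = c(muR = 1500, muG = 2200),
    downsampleFactors = c(2L, 2L, 1L),
    semiAxesVox = c(21, 21, 5),
    dapiBaseline = 3000,
    background = 100,
    noiseSd = 150
  )
}

#' @rdname epiProfile
#' @export
confocalProfile <- function(tileShape = c(192L, 192L, 96L)) {
  new("AcquisitionProfile",
    name = "confocal",
    voxelNm = c(182, 182, 200),
    tileShape = as.integer(tileShape),
    bitDepth = 16L,
    lowIntensityThresholds = c(muR = 700, muG = 2000),
    downsampleFactors = c(2L, 2L, 2L),
    semiAxesVox = c(22, 22, 12),
    dapiBaseline = 3000,
    background = 100,
    noiseSd = 150
  )
}

#' @rdname epiProfile
#' @export
miniProfile <- function(tileShape = c(96L, 96L, 64L)) {
  new("AcquisitionProfile",
    name = "miniature",
    voxelNm = c(400, 400, 400),
    tileShape = as.integer(tileShape),
    bitDepth = 16L,
    lowIntensityThresholds = c(muR = 1500, muG = 2200),
    downsampleFactors = c(2L, 2L, 2L),
    semiAxesVox = c(8, 8, 6),
    dapiBaseline = 3000,
    background = 100,
    noiseSd = 150
  )
}

#' Look up a built-in profile by name
#'
#' @param name one of \code{"epifluorescence"} (alias \code{"epi"}),
#'   \code{"confocal"}, \code{"miniature"} (alias \code{"mini"}).
#' @param ... passed to the profile constructor.
#' @return An [AcquisitionProfile-class].
#' @export
getProfile <- function(name, ...) {
  switch(match.arg(name, c("epifluorescence", "epi", "confocal",
                           "miniature", "mini")),
    epifluorescence = ,
    epi = epiProfile(...),
    confocal = confocalProfile(...),
    miniature = ,
    mini = miniProfile(...)
  )
}
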