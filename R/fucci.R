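# Fucci ground-truth labeling.
#
# A nucleus' mean mCherry-hCdt1 (RFP, "R") and mVenus-hGeminin (GFP, "G")
# intensities report its cell cycle stage: hCdt1 accumulates in G1 and
# hGeminin in S/G2. Before labeling, three filters remove nuclei that are
# unusable as ground truth: reporter non-expressers (low intensity),
# cells transitioning between phases (normalized G/R ratio near 1), and
# abnormally sized objects (volume far from the population mean). The
# survivors are labeled G1 when R > G and S/G2 when R < G; the continuous
# alternative is the angle of the (R, G) coordinate.

#' Fucci exclusion filters
#'
#' Each filter returns TRUE for cells to \emph{exclude}; all comparisons are
#' strict, so boundary cells are kept.
#'
#' \describe{
#'   \item{`lowIntensityFilter()`}{mean RFP or mean GFP strictly below the
#'     profile's low-intensity thresholds (epifluorescence: muR < 1500 or
#'     muG < 2200; confocal: muR < 700 or muG < 2000) — the cell does not
#'     express the reporter.}
#'   \item{`ratioFilter()`}{0.9 < muG'/muR' < 1.1 after per-channel
#'     normalization — the cell sits on the S-phase border where the two
#'     reporters are balanced and the label would be unreliable. Cells with
#'     normalized muR' = 0 are never excluded here (their ratio is infinite,
#'     outside the band).}
#'   \item{`volumeFilter()`}{|V - muV| > 2.5 sigmaV over the candidate
#'     population — abnormally small/large objects (debris, doublets).
#'     With sigmaV = 0, only cells exactly at muV are kept.}
#' }
#'
#' @param muR,muG mean RFP / GFP intensity (vectorized).
#' @param profile an [AcquisitionProfile-class] supplying the thresholds.
#' @return logical vector, TRUE = exclude.
#' @export
lowIntensityFilter <- function(muR, muG, profile) {
  thr <- profile@lowIntensityThresholds
  muR < thr[["muR"]] | muG < thr[["muG"]]
}

#' @rdname lowIntensityFilter
#' @param channelNorms named numeric \code{c(normR=, normG=)}, strictly
#'   positive per-channel normalizers (typically population medians).
#' @param band numeric(2), open exclusion band for the normalized ratio.
#' @export
ratioFilter <- function(muR, muG, channelNorms, band = c(0.9, 1.1)) {
  if (any(channelNorms <= 0))
    stop("channel normalizers must be strictly positive")
  r <- (muG / channelNorms[["normG"]]) / (muR / channelNorms[["normR"]])
  out <- r > band[1] & r < band[2]
  out[!is.finite(r)] <- FALSE  # muR' = 0 (or 0/0): never excluded here
  out
}

#' @rdname lowIntensityFilter
#' @param V voxel counts (vectorized).
#' @param stats list or named vector with \code{muV} and \code{sdV},
#'   computed over the candidate population.
#' @param k exclusion width in SDs.
#' @export
volumeFilter <- function(V, stats, k = 2.5) {
  abs(V - stats[["muV"]]) > k * stats[["sdV"]]
}

#' Binary stage label from aggregate Fucci signals
#'
#' G1 when R > G, S/G2 when R < G. A tie is an error: ties cannot survive
#' the ratio filter when the two channel normalizers are equal, so reaching
#' one indicates the filters were skipped.
#'
#' @param R,G aggregate (or mean — the voxel count cancels) RFP and GFP
#'   intensities, vectorized.
#' @return character vector of \code{"G1"} / \code{"SG2"}.
#' @export
assignLabel <- function(R, G) {
  if (any(R == G))
    stop("ambiguous label: R == G for ",
         sum(R == G), " cell(s); ties must be excluded upstream")
  ifelse(R > G, "G1", "SG2")
}

#' Continuous cell cycle angle
#'
#' The angle theta (degrees) between the R axis and the line from the
#' origin to the cell's (R, G) intensity coordinate: 0 for pure-RFP (deep
#' G1), 90 for pure-GFP (late S/G2), 45 on the R = G boundary. A proxy for
#' continuous cell cycle position.
#'
#' @param R,G nonnegative aggregate or mean RFP/GFP intensities; R + G must
#'   be positive.
#' @return theta in degrees in \code{[0, 90]}.
#' @export
computeAngle <- function(R, G) {
  if (any(R + G <= 0)) stop("angle undefined: R + G must be positive")
  atan2(G, R) * 180 / pi
}

#' @rdname computeAngle
#' @param theta angle in degrees in \code{[0, 90]}.
#' @param boundary decision boundary in degrees (45 = the R = G line).
#' @return \code{binarizeAngle()}: character vector \code{"G1"} (theta <
#'   boundary) / \code{"SG2"} (theta > boundary); exactly hitting the
#'   boundary is an error (ties are excluded upstream).
#' @export
binarizeAngle <- function(theta, boundary = 45) {
  stopifnot(all(theta >= 0), all(theta <= 90))
  if (any(theta == boundary))
    stop("theta equal to the decision boundary; ties must be excluded ",
         "upstream")
  ifelse(theta > boundary, "SG2", "G1")
}

#' Label a quantified population
#'
#' Applies the three exclusion filters in order (low intensity, ratio,
#' volume), labels the survivors by R > G / R < G, and computes the
#' continuous angle for every cell with positive total reporter signal.
#' Each excluded cell is tagged with the \emph{first} filter that caught it;
#' the surviving set itself does not depend on the order, because a cell is
#' excluded iff it meets at least one criterion.
#'
#' Normalizers for the ratio filter are the per-channel medians of the mean
#' intensities over cells that pass the low-intensity filter (expressing
#' cells); the volume statistics (muV, sdV) are computed over the same
#' population. Both choices are recorded in the output.
#'
#' @param features data.frame from [quantifyNuclei()] (needs columns
#'   \code{rfp_mean}, \code{gfp_mean}, \code{rfp_sum}, \code{gfp_sum},
#'   \code{volume_vox}; \code{tile_id}/\code{label_id} are carried through).
#' @param profile an [AcquisitionProfile-class].
#' @param band ratio filter band.
#' @param volumeK volume filter width in SDs.
#' @return list with \code{labels} (data.frame \code{tile_id},
#'   \code{label_id}, \code{status} in G1/SG2/excluded, \code{reason} in
#'   none/low_intensity/ratio/volume, \code{theta_deg}), \code{summary}
#'   (named exclusion/label counts), \code{channelNorms} and
#'   \code{volumeStats} as used.
#' @export
labelDataset <- function(features, profile, band = c(0.9, 1.1),
                         volumeK = 2.5) {
  stopifnot(nrow(features) > 0)
  muR <- features$rfp_mean; muG <- features$gfp_mean
  V <- features$volume_vox

  fLow <- lowIntensityFilter(muR, muG, profile)
  expressing <- !fLow
  if (!any(expressing)) {
    norms <- c(normR = 1, normG = 1)
    vstats <- list(muV = NA_real_, sdV = NA_real_)
    fRatio <- rep(FALSE, length(muR))
    fVol <- rep(FALSE, length(muR))
  } else {
    norms <- c(normR = median(muR[expressing]),
               normG = median(muG[expressing]))
    vstats <- list(muV = mean(V[expressing]),
                   sdV = stats::sd(V[expressing]))
    if (sum(expressing) < 2L || is.na(vstats$sdV)) vstats$sdV <- 0
    fRatio <- ratioFilter(muR, muG, norms, band = band)
    fVol <- volumeFilter(V, vstats, k = volumeK)
  }

  reason <- rep("none", length(muR))
  reason[fVol] <- "volume"
  reason[fRatio] <- "ratio"
  reason[fLow] <- "low_intensity"  # first filter wins

  status <- rep("excluded", length(muR))
  keep <- reason == "none"
  if (any(keep))
    status[keep] <- assignLabel(features$rfp_sum[keep],
                                features$gfp_sum[keep])

  theta <- rep(NA_real_, length(muR))
  pos <- features$rfp_sum + features$gfp_sum > 0
  theta[pos] <- computeAngle(features$rfp_sum[pos], features$gfp_sum[pos])

  labels <- data.frame(
    tile_id = if (!is.null(features$tile_id)) features$tile_id else "tile",
    label_id = if (!is.null(features$label_id)) features$label_id
               else seq_along(muR),
    status = status, reason = reason, theta_deg = theta,
    stringsAsFactors = FALSE)
  summary <- c(n = length(muR),
               G1 = sum(status == "G1"), SG2 = sum(status == "SG2"),
               excluded = sum(status == "excluded"),
               low_intensity = sum(reason == "low_intensity"),
               ratio = sum(reason == "ratio"),
               volume = sum(reason == "volume"))
  list(labels = labels, summary = summary, channelNorms = norms,
       volumeStats = vstats)
}
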