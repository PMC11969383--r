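# TIFF volume I/O. Volumes are (Z, Y, X) arrays written as multi-page
# TIFFs, one page per Z-plane, 16-bit unsigned container regardless of the
# camera bit depth (14-bit data fits losslessly).

.TIFF_MAX <- 65535

#' Read / write a 3D volume as a multi-page 16-bit TIFF
#'
#' `writeTiffVolume()` stores a (Z, Y, X) volume planewise (page k = plane
#' Z = k); values are rounded to integers and must lie in [0, 65535].
#' `readTiffVolume()` inverts it exactly.
#'
#' @param vol numeric (Z, Y, X) array.
#' @param path file path.
#' @return `readTiffVolume()`: the (Z, Y, X) array of integers (as doubles).
#' @export
writeTiffVolume <- function(vol, path) {
  vol <- round(vol)
  if (min(vol) < 0 || max(vol) > .TIFF_MAX)
    stop("volume values outside the 16-bit range for: ", path)
  pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ] / .TIFF_MAX)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
  invisible(path)
}

#' @rdname writeTiffVolume
#' @export
readTiffVolume <- function(path) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vol <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vol[z, , ] <- round(pages[[z]] * .TIFF_MAX)
  vol
}
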