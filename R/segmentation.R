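#' Segment root-like signal from a grayscale volume
#'
#' A deliberately simple root segmenter standing behind a pluggable
#' interface: slice-wise median-filter background removal, an intensity
#' band-pass on the residual selecting root-like signal (below the bright
#' mineral particles, above the noise floor), and removal of connected
#' components smaller than a voxel-count floor. Externally produced
#' root-segmented volumes can be passed through verbatim with
#' `passthrough = TRUE`.
#'
#' @param volume a [volume3d()] (grayscale, aligned to the reference frame).
#' @param band numeric length-2, residual-intensity band `[lo, hi]` kept as
#'   root signal.
#' @param median_radius radius (pixels) of the 2D median filter estimating
#'   the slice background.
#' @param min_voxels connected components (26-connectivity) smaller than
#'   this are discarded; 0 disables the cleanup.
#' @param passthrough return the input unchanged (already-segmented data).
#' @return a [volume3d()] whose intensities are 0 (non-root) or 1 (root).
#' @export
segment_roots <- function(volume, band = c(30, 110), median_radius = 5,
                          min_voxels = 27, passthrough = FALSE) {
  stopifnot(inherits(volume, "volume3d"))
  if (passthrough) return(volume)
  if (band[1] > band[2]) stopf("band limits inverted: [%g, %g]", band[1], band[2])
  v <- volume$intensities
  d <- dim(v)
  scale <- max(v, 1)
  mask <- array(FALSE, d)
  for (k in seq_len(d[1])) {
    sl <- v[k, , ]
    bg <- EBImage::medianFilter(sl / scale, median_radius) * scale
    res <- sl - bg
    mask[k, , ] <- res >= band[1] & res <= band[2]
  }
  if (min_voxels > 0 && any(mask)) {
    lab <- label_components_3d(mask)
    sizes <- tabulate(lab$label)
    drop <- sizes[lab$label] < min_voxels
    if (any(drop)) mask[lab$coords[drop, , drop = FALSE]] <- FALSE
  }
  out <- array(0L, d)
  out[mask] <- 1L
  volume3d(out, volume$voxel_size_mm, volume$day)
}
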