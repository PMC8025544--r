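# Patient-specific geometric distortion from B0 deviation maps. Off-resonance
# shifts the reconstructed position along the frequency-encoding axis
# (anterior/posterior for the Dixon protocol emulated here) by
# d = |dB0| / BW * pixel_size.

#' Convert a B0 deviation map to absolute distortion (mm)
#'
#' Voxel-wise `d = |dB0| / BW * pixel_size`. Exactly linear in |dB0| and
#' inverse in the bandwidth.
#'
#' @param b0 an [image_volume()] of B0 deviation, Hz.
#' @param bandwidth receiver bandwidth, Hz/pixel, > 0 (744 for the emulated
#'   protocol).
#' @param pixel_size frequency-encoding pixel size, mm, > 0 (1.1 for the
#'   emulated protocol).
#' @param encoding_axis axis label carried for bookkeeping.
#' @return A `distortion_map`: an [image_volume()] of mm with attributes
#'   `bandwidth`, `pixel_size`, `encoding_axis`.
#' @export
b0_to_distortion <- function(b0, bandwidth = 744, pixel_size = 1.1,
                             encoding_axis = "Y") {
  stopifnot(inherits(b0, "image_volume"))
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel size must be > 0", call. = FALSE)
  out <- image_volume(abs(b0$values) / bandwidth * pixel_size, b0$spacing,
                      b0$origin, unit = "mm")
  attr(out, "bandwidth") <- bandwidth
  attr(out, "pixel_size") <- pixel_size
  attr(out, "encoding_axis") <- encoding_axis
  class(out) <- c("distortion_map", class(out))
  out
}

#' Per-region distortion statistics
#'
#' Mean, SD, max and the 99th percentile (linear interpolation between
#' order statistics) of absolute distortion within each region mask —
#' typically brain, bone (>= 250 HU) and air (< -900 HU) within the body
#' contour. Empty regions are skipped with a warning.
#'
#' @param dmap a `distortion_map` from [b0_to_distortion()].
#' @param masks named list of [binary_mask()] regions.
#' @return A tibble: region, mean, sd, max, p99, n_voxels.
#' @export
region_distortion_stats <- function(dmap, masks) {
  stopifnot(inherits(dmap, "image_volume"))
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    check_same_grid(dmap, m, "distortion map and mask")
    sel <- m$values
    if (!any(sel)) {
      warning("region '", nm, "' is empty; skipped")
      return(NULL)
    }
    v <- dmap$values[sel]
    tibble::tibble(region = nm, mean = mean(v), sd = stats::sd(v),
                   max = max(v),
                   p99 = as.numeric(stats::quantile(v, 0.99, type = 7)),
                   n_voxels = sum(sel))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
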