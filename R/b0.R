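# Synthetic B0 deviation maps: a smooth low-order polynomial background
# (shim imperfection) plus dipole-like susceptibility excursions centred on
# the phantom's air cavities, decaying as (a/r)^3 with the characteristic
# 3cos^2(theta)-1 angular pattern about the main-field (Z) axis.

#' Generate a B0 deviation map for a head phantom
#'
#' @param phantom a `head_phantom` from [generate_head_phantom()].
#' @param background_amplitude peak |background| field over the body, Hz.
#' @param cavity_amplitude peak excursion at an air-cavity wall, Hz.
#' @param seed RNG seed for the polynomial coefficients.
#' @return An [image_volume()] in Hz, with attribute `max_abs` recording the
#'   maximum |B0| deviation.
#' @export
generate_b0_map <- function(phantom, background_amplitude = 60,
                            cavity_amplitude = 600, seed = 1L) {
  stopifnot(inherits(phantom, "head_phantom"))
  if (background_amplitude < 0 || cavity_amplitude < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  ct <- phantom$ct
  d <- dim(ct$values)
  b0 <- array(0, d)

  if (background_amplitude > 0) {
    co <- with_seed(seed, stats::runif(9, -1, 1))
    ax <- axis_coords(ct)
    half <- (d - 1) / 2 * ct$spacing
    xn <- ax[[1]] / half[1]; yn <- ax[[2]] / half[2]; zn <- ax[[3]] / half[3]
    X <- array(rep(xn, times = d[2] * d[3]), d)
    Y <- array(rep(rep(yn, each = d[1]), times = d[3]), d)
    Z <- array(rep(zn, each = d[1] * d[2]), d)
    poly <- co[1] * X + co[2] * Y + co[3] * Z + co[4] * X * Y +
      co[5] * X * Z + co[6] * Y * Z + co[7] * X^2 + co[8] * Y^2 + co[9] * Z^2
    mx <- max(abs(poly[phantom$labels$body$values]))
    if (mx > 0) b0 <- b0 + poly * (background_amplitude / mx)
  }

  if (cavity_amplitude > 0 && length(phantom$spec$air_cavities)) {
    ctr <- voxel_centers(ct)
    for (cav in phantom$spec$air_cavities) {
      rel <- sweep(ctr, 2, as.numeric(cav$center))
      r <- sqrt(rowSums(rel^2))
      a <- cav$radius
      rr <- pmax(r, a)
      cth2 <- ifelse(r > 0, (rel[, 3] / rr)^2, 1)
      dip <- cavity_amplitude * (a / rr)^3 * (3 * cth2 - 1) / 2
      dip[r <= a] <- cavity_amplitude   # capped inside the cavity
      b0 <- b0 + array(dip, d)
    }
  }

  out <- image_volume(b0, ct$spacing, ct$origin, unit = "Hz")
  attr(out, "max_abs") <- max(abs(b0))
  out
}
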