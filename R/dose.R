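# Simplified analytic photon dose engine: per beam, exponential attenuation
# along the radiological depth (HU -> relative density via a bilinear ramp)
# with a flat circular field and Gaussian-smoothed penumbra about the beam
# axis through the target centroid; beams are summed and scaled so the mean
# target dose equals the prescription. Deliberately simple: it makes dose
# differences a deterministic function of HU differences, it does not
# emulate a clinical convolution/superposition algorithm.

#' Analytic dose-engine specification
#'
#' @param prescription prescribed target dose, Gy, > 0.
#' @param target a [binary_mask()], the planning target volume (PTV).
#' @param beam_directions list of length-3 vectors (need not be unit); each
#'   beam travels along its direction through the target centroid.
#' @param penumbra_sigma Gaussian edge width of the lateral profile, mm.
#' @param mu effective attenuation per mm of unit-density path.
#' @param field_margin field radius margin beyond the target extent, mm.
#' @param step ray-marching step for the depth integral, mm.
#' @return A `dose_spec` object.
#' @export
dose_spec <- function(prescription, target,
                      beam_directions = list(c(1, 0, 0), c(-1, 0, 0),
                                             c(0, -1, 0)),
                      penumbra_sigma = 5, mu = 0.005, field_margin = 6,
                      step = 1.5) {
  if (prescription <= 0) stop("prescription must be > 0", call. = FALSE)
  if (!length(beam_directions)) stop("need at least one beam", call. = FALSE)
  if (!any(target$values)) stop("target mask is empty", call. = FALSE)
  structure(list(prescription = prescription, target = target,
                 beam_directions = beam_directions,
                 penumbra_sigma = penumbra_sigma, mu = mu,
                 field_margin = field_margin, step = step),
            class = "dose_spec")
}

#' HU to relative electron density (bilinear ramp)
#'
#' Air/soft-tissue segment `1 + HU/1000` below 0 HU (clamped at 0) and a
#' shallower bone segment `1 + HU/1950` above, the usual two-segment CT
#' calibration shape.
#'
#' @param hu numeric HU values.
#' @return Relative density, same shape.
#' @export
hu_to_density <- function(hu) {
  ifelse(hu <= 0, pmax(0, 1 + hu / 1000), 1 + hu / 1950)
}

#' Compute an analytic dose grid on a CT (or sCT)
#'
#' @param ct an [image_volume()] of HU sharing the target grid.
#' @param spec a [dose_spec()].
#' @return An [image_volume()] of dose (Gy) with mean target dose equal to
#'   the prescription.
#' @export
generate_dose <- function(ct, spec) {
  stopifnot(inherits(ct, "image_volume"), inherits(spec, "dose_spec"))
  check_same_grid(ct, spec$target, "CT and target mask")
  dens <- array(hu_to_density(ct$values), dim(ct$values))
  ctrs <- voxel_centers(ct)
  tsel <- as.logical(spec$target$values)
  centroid <- colMeans(ctrs[tsel, , drop = FALSE])
  ext <- sqrt(max(rowSums(sweep(ctrs[tsel, , drop = FALSE], 2,
                                centroid)^2)))
  field_r <- ext + spec$field_margin
  total <- array(0, dim(ct$values))
  for (dir in spec$beam_directions) {
    u <- dir / sqrt(sum(dir^2))
    b <- cpp_beam_dose(dens, dim(ct$values), ct$spacing, ct$origin, u,
                       centroid, spec$mu, field_r, spec$penumbra_sigma,
                       spec$step)
    total <- total + array(b, dim(ct$values))
  }
  mt <- mean(total[tsel])
  if (mt <= 0) stop("no dose reaches the target", call. = FALSE)
  image_volume(total * (spec$prescription / mt), ct$spacing, ct$origin,
               unit = "Gy")
}
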