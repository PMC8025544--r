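# Digital head phantom: nested ellipsoids (scalp / skull shell / brain) with
# optional air cavities and full-thickness cylindrical bone-resection
# defects. All generators are pure functions of (spec, seed).

# run code under a seed without disturbing the global RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parametric head-phantom specification
#'
#' Describes an ellipsoidal head: an outer scalp layer, a skull shell of
#' constant thickness, brain inside, optional air cavities (sinus-like) and
#' optional full-thickness cylindrical bone-resection defects placed on the
#' skull surface. Tissue HU are class means with Gaussian spread.
#'
#' @param head_radii outer semi-axes (x, y, z), mm.
#' @param scalp_thickness,skull_thickness layer thicknesses, mm.
#' @param tissue_hu named list of `c(mean, sd)` HU per class
#'   (air, brain, bone, scalp).
#' @param air_cavities list of `list(center=, radius=)`, mm (world coords).
#' @param resections list of `list(center=, diameter=)`; centres must lie on
#'   the mid-skull surface (see [skull_surface_point()]); diameters in the
#'   10-30 mm range typical of post-surgical defects.
#' @param grid_dim,grid_spacing grid shape and voxel size (mm); the grid is
#'   centred on the origin.
#' @param texture_sigma correlation length (Gaussian sigma, mm) of the HU
#'   texture; CT texture is spatially correlated, not white. 0 gives white
#'   voxel noise. The per-class SD is preserved after smoothing.
#' @param seed RNG seed for the HU noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(head_radii = c(72, 88, 80),
                         scalp_thickness = 6,
                         skull_thickness = 7,
                         tissue_hu = list(air = c(-1000, 3),
                                          brain = c(40, 10),
                                          bone = c(1000, 150),
                                          scalp = c(60, 20)),
                         air_cavities = list(
                           list(center = c(0, -45, 38), radius = 11)),
                         resections = list(),
                         grid_dim = c(64, 80, 64),
                         grid_spacing = c(3, 3, 3),
                         texture_sigma = 3,
                         seed = 1L) {
  if (skull_thickness <= 0) stop("skull_thickness must be > 0", call. = FALSE)
  for (r in resections)
    if (r$diameter <= 0) stop("resection diameter must be > 0", call. = FALSE)
  ext <- (grid_dim - 1) / 2 * grid_spacing
  if (any(head_radii >= ext))
    stop("head does not fit inside the grid", call. = FALSE)
  structure(list(head_radii = head_radii, scalp_thickness = scalp_thickness,
                 skull_thickness = skull_thickness, tissue_hu = tissue_hu,
                 air_cavities = air_cavities, resections = resections,
                 grid_dim = as.integer(grid_dim),
                 grid_spacing = grid_spacing,
                 texture_sigma = texture_sigma, seed = seed),
            class = "phantom_spec")
}

# squared "ellipsoid radius" field (==1 on the ellipsoid surface) for the
# centred ellipsoid with given semi-axes, evaluated on the spec grid
ellipsoid_field <- function(spec, radii) {
  d <- spec$grid_dim; sp <- spec$grid_spacing
  org <- -(d - 1) / 2 * sp
  x <- (org[1] + (seq_len(d[1]) - 1) * sp[1]) / radii[1]
  y <- (org[2] + (seq_len(d[2]) - 1) * sp[2]) / radii[2]
  z <- (org[3] + (seq_len(d[3]) - 1) * sp[3]) / radii[3]
  outer(outer(x^2, y^2, "+"), z^2, "+")
}

#' Point on the mid-skull surface along a direction
#'
#' Helper for placing resection defects: returns the point where the ray
#' from the head centre along `direction` crosses the middle of the skull
#' shell.
#'
#' @param spec a [phantom_spec()].
#' @param direction length-3 direction (need not be unit).
#' @return World coordinate (mm) on the mid-skull ellipsoid.
#' @export
skull_surface_point <- function(spec, direction) {
  rm <- spec$head_radii - spec$scalp_thickness - spec$skull_thickness / 2
  v <- direction / sqrt(sum(direction^2))
  as.numeric(v / sqrt(sum((v / rm)^2)))
}

#' Generate a head-phantom CT and its class label maps
#'
#' Builds the noiseless class map (air / brain / bone / scalp, with
#' resection defects carved to soft tissue), assigns per-class HU with
#' Gaussian spread, and returns both. Label maps describe the geometry
#' before noise, so they are exact oracles for threshold-based segmentations
#' away from class boundaries.
#'
#' @param spec a [phantom_spec()].
#' @return A `head_phantom` list: `ct` ([image_volume()]), `labels` (named
#'   list of [binary_mask()]: air, brain, bone, scalp, body, air_cavity,
#'   resection), `class_map` (integer array), `spec`.
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim; sp <- spec$grid_spacing
  org <- -(d - 1) / 2 * sp
  r_out <- spec$head_radii
  r_skull <- r_out - spec$scalp_thickness
  r_brain <- r_skull - spec$skull_thickness

  f_out <- ellipsoid_field(spec, r_out)
  f_skull <- ellipsoid_field(spec, r_skull)
  f_brain <- ellipsoid_field(spec, r_brain)

  # 0 air, 1 brain, 2 bone, 3 scalp
  cls <- array(0L, d)
  cls[f_out <= 1] <- 3L
  cls[f_skull <= 1] <- 2L
  cls[f_brain <= 1] <- 1L
  body <- f_out <= 1

  # world coordinates, reused for cavities and resections
  ctr <- voxel_centers(image_volume(array(0, d), sp, org, unit = ""))

  cavity <- array(FALSE, d)
  for (cav in spec$air_cavities) {
    dd <- (ctr[, 1] - cav$center[1])^2 + (ctr[, 2] - cav$center[2])^2 +
      (ctr[, 3] - cav$center[3])^2
    cavity <- cavity | array(dd <= cav$radius^2, d)
  }
  cls[cavity] <- 0L

  resection <- array(FALSE, d)
  rm_ <- r_out - spec$scalp_thickness - spec$skull_thickness / 2
  for (rs in spec$resections) {
    cc <- as.numeric(rs$center)
    if (abs(sum((cc / rm_)^2) - 1) > 0.3)
      stop("resection centre not on skull surface", call. = FALSE)
    n <- (cc / rm_^2); n <- n / sqrt(sum(n^2))   # outward ellipsoid normal
    rel <- sweep(ctr, 2, cc)
    ax <- rel %*% n
    rad2 <- rowSums(rel^2) - ax^2
    hit <- array(rad2 <= (rs$diameter / 2)^2 &
                   abs(ax) <= spec$skull_thickness + spec$scalp_thickness, d)
    carved <- hit & cls == 2L
    resection <- resection | carved
    cls[carved] <- 1L   # soft tissue fills the defect
  }

  hu_mean <- vapply(spec$tissue_hu, `[`, numeric(1), 1)
  hu_sd <- vapply(spec$tissue_hu, `[`, numeric(1), 2)
  classes <- c("air", "brain", "bone", "scalp")
  ct <- array(hu_mean[classes[cls + 1L]], d)
  noise <- with_seed(spec$seed, array(stats::rnorm(prod(d)), d))
  if (isTRUE(spec$texture_sigma > 0)) {
    noise <- smooth3d(noise, spec$texture_sigma, sp)
    noise <- noise / stats::sd(noise)   # keep unit variance
  }
  ct <- ct + noise * hu_sd[classes[cls + 1L]]

  labels <- list(
    air = binary_mask(cls == 0L, sp, org),
    brain = binary_mask(cls == 1L & !resection, sp, org),
    bone = binary_mask(cls == 2L, sp, org),
    scalp = binary_mask(cls == 3L, sp, org),
    body = binary_mask(body, sp, org),
    air_cavity = binary_mask(cavity, sp, org),
    resection = binary_mask(resection, sp, org)
  )
  structure(list(ct = image_volume(ct, sp, org, unit = "HU"),
                 labels = labels, class_map = cls, spec = spec),
            class = "head_phantom")
}

#' sCT corruption model
#'
#' Describes how a synthetic CT differs from the reference CT: per-class HU
#' bias and extra noise (bone bias negative by default, reproducing the
#' systematic bone underestimation of CNN-generated sCTs), optional Gaussian
#' blur of the error field at the bone boundary, optional bone thickening in
#' a ring around resection defects, and an optional residual rigid
#' misalignment applied last.
#'
#' @param bias named per-class HU bias (air, brain, bone, scalp).
#' @param noise_sd named per-class extra noise SD, HU, all >= 0.
#' @param bone_boundary_blur Gaussian sigma (mm) applied to the error field
#'   in a band around the bone boundary; 0 disables.
#' @param bone_thickening_near_resection ring width (mm) outside the true
#'   skull, near resections, that the sCT renders as bone; 0 disables.
#' @param residual_misalignment a [rigid_transform()] applied to the
#'   finished sCT (identity by default).
#' @param seed RNG seed.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(bias = c(air = 0, brain = 1, bone = -40,
                                       scalp = 2),
                              noise_sd = c(air = 2, brain = 12, bone = 200,
                                           scalp = 20),
                              bone_boundary_blur = 0,
                              bone_thickening_near_resection = 0,
                              residual_misalignment = rigid_transform(),
                              seed = 1L) {
  if (any(noise_sd < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(bias = bias, noise_sd = noise_sd,
                 bone_boundary_blur = bone_boundary_blur,
                 bone_thickening_near_resection =
                   bone_thickening_near_resection,
                 residual_misalignment = residual_misalignment, seed = seed),
            class = "perturbation_spec")
}

# separable Gaussian smoothing of a 3D array, sigma in mm
smooth3d <- function(arr, sigma_mm, spacing) {
  for (ax in 1:3) {
    sg <- sigma_mm / spacing[ax]
    if (sg <= 0) next
    hw <- max(1L, ceiling(3 * sg))
    w <- exp(-((-hw:hw)^2) / (2 * sg^2)); w <- w / sum(w)
    n <- dim(arr)[ax]
    out <- array(0, dim(arr))
    for (m in -hw:hw) {
      src <- pmin(pmax(seq_len(n) + m, 1L), n)  # replicate edges
      idx <- switch(ax,
                    arr[src, , , drop = FALSE],
                    arr[, src, , drop = FALSE],
                    arr[, , src, drop = FALSE])
      out <- out + w[m + hw + 1] * idx
    }
    arr <- out
  }
  arr
}

#' Derive a perturbed sCT from a phantom CT
#'
#' Applies the corruption model of a [perturbation_spec()] to the phantom
#' CT. With an all-zero spec the sCT is identical to the CT. The expected
#' mean error over the bone label equals the configured bone bias.
#'
#' @param phantom a `head_phantom` from [generate_head_phantom()].
#' @param pert a [perturbation_spec()].
#' @return The sCT as an [image_volume()] (HU).
#' @export
derive_sct <- function(phantom, pert) {
  stopifnot(inherits(phantom, "head_phantom"),
            inherits(pert, "perturbation_spec"))
  ct <- phantom$ct
  cls <- phantom$class_map
  d <- dim(ct$values)
  classes <- c("air", "brain", "bone", "scalp")
  cname <- classes[cls + 1L]
  err <- array(pert$bias[cname], d)
  if (any(pert$noise_sd > 0))
    err <- err + with_seed(pert$seed,
                           array(stats::rnorm(prod(d)), d) *
                             pert$noise_sd[cname])
  if (pert$bone_boundary_blur > 0) {
    bone <- phantom$labels$bone
    band <- dilate_mask(bone, pert$bone_boundary_blur)$values &
      !erode_mask(bone, pert$bone_boundary_blur)$values
    sm <- smooth3d(err, pert$bone_boundary_blur, ct$spacing)
    err[band] <- sm[band]
  }
  sct <- ct$values + err
  if (pert$bone_thickening_near_resection > 0 &&
      any(phantom$labels$resection$values)) {
    # a ring thinner than one voxel cannot be rasterised directly: take
    # the one-voxel shell around the true skull and mix bone HU in with
    # the ring's partial-volume fraction of the voxel size
    th <- pert$bone_thickening_near_resection
    grow <- max(th, max(ct$spacing))
    frac <- min(1, th / max(ct$spacing))
    ring <- dilate_mask(phantom$labels$bone, grow)$values &
      !phantom$labels$bone$values &
      dilate_mask(phantom$labels$resection, 20)$values &
      phantom$labels$body$values
    bone_hu <- phantom$spec$tissue_hu$bone[1] + pert$bias["bone"]
    sct[ring] <- sct[ring] + frac * (bone_hu - sct[ring])
  }
  out <- image_volume(sct, ct$spacing, ct$origin, unit = "HU")
  p <- transform_params(pert$residual_misalignment)
  if (any(p != 0))
    out <- resample_volume(out, pert$residual_misalignment, target = ct)
  out
}

#' Erode a mask by a physical radius
#'
#' Complement-dilation: spherical element of radius `radius_mm`.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm erosion radius, mm.
#' @return The eroded [binary_mask()], a subset of the input.
#' @export
erode_mask <- function(mask, radius_mm) {
  inv <- binary_mask(!mask$values, mask$spacing, mask$origin)
  binary_mask(!dilate_mask(inv, radius_mm)$values, mask$spacing, mask$origin)
}
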