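#' @useDynLib sctval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D image volume on a regular grid
#'
#' A scalar 3D grid with physical geometry: per-axis voxel size (mm) and the
#' world position of the centre of voxel (1,1,1). Depending on its role the
#' grid holds Hounsfield units, absorbed dose in Gy, or a resonance-frequency
#' offset in Hz. Axes follow the patient convention X = left to right,
#' Y = anterior to posterior, Z = superior to inferior.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, voxel size per axis in mm, all > 0.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre. Default `c(0, 0, 0)`.
#' @param unit character tag (`"HU"`, `"Gy"`, `"Hz"`, ...), informational.
#' @return An `image_volume` object.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0), unit = "HU") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume values must be finite", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin, unit = unit),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm, unit %s\n",
    d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
    paste(format(x$origin), collapse = ", "), x$unit
  ))
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Binary mask sharing image-volume geometry
#'
#' @param values logical 3D array.
#' @param spacing,origin grid geometry as in [image_volume()].
#' @return A `binary_mask` object; `n_voxels` attribute carries the exact
#'   count of TRUE voxels.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D mask", call. = FALSE)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must not be NA", call. = FALSE)
  m <- image_volume(array(0, dim(values)), spacing, origin, unit = "bool")
  m$values <- values
  class(m) <- c("binary_mask", "image_volume")
  m$n_voxels <- sum(values)
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d TRUE\n",
              d[1], d[2], d[3], x$n_voxels))
  invisible(x)
}

# shared-grid check used throughout the pipeline
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s must share a grid: dimensions differ", what),
         call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-4)
    stop(sprintf("%s must share a grid: geometry differs", what),
         call. = FALSE)
  invisible(TRUE)
}

# world coordinates (mm) of every voxel centre, n x 3
voxel_centers <- function(vol) {
  d <- dim(vol$values)
  cbind(
    rep(vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
        times = d[2] * d[3]),
    rep(rep(vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
            each = d[1]), times = d[3]),
    rep(vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3],
        each = d[1] * d[2])
  )
}

# per-axis world coordinate vectors
axis_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Grid geometry (spacing, origin) is taken from the NIfTI header. Only 3D
#' axis-aligned volumes are supported; oblique orientations are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param unit unit tag to attach, see [image_volume()].
#' @return An [image_volume()].
#' @export
read_volume <- function(path, unit = "HU") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D",
                            call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (any(pd <= 0)) stop("non-positive spacing in header", call. = FALSE)
  xf <- RNifti::xform(img)
  off <- matrix(TRUE, 3, 3); diag(off) <- FALSE
  if (max(abs(xf[1:3, 1:3][off])) > 1e-4 * max(pd))
    stop("oblique orientation not supported", call. = FALSE)
  # NIfTI xform is RAS+; stored sign per axis is irrelevant for the metrics
  # here, keep magnitudes and the translation column as the origin.
  origin <- as.numeric(xf[1:3, 4])
  image_volume(array(as.numeric(img), d), spacing = pd[1:3],
               origin = origin, unit = unit)
}

#' Write a volume (or mask) to NIfTI-1
#'
#' Values are stored as float32 for image volumes and uint8 for masks; the
#' round trip preserves float32 values bit-exactly and geometry to better
#' than 1e-4 mm.
#'
#' @param volume an [image_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "binary_mask")
  arr <- if (is_mask) array(as.integer(volume$values), dim(volume$values))
         else volume$values
  img <- RNifti::asNifti(arr)
  sp <- volume$spacing; o <- volume$origin
  # pixdim must be set before the xforms: RNifti factors the voxel size
  # out of the qform rotation, so a unit pixdim would absorb the scales
  RNifti::pixdim(img) <- sp
  xf <- rbind(cbind(diag(sp), o), c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' @param path path to a mask NIfTI (any non-zero voxel is TRUE).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, unit = "bool")
  binary_mask(v$values != 0, v$spacing, v$origin)
}

#' Spherical mask on an existing grid
#'
#' Voxels whose centre lies within `radius_mm` of `center` (world mm).
#'
#' @param like an [image_volume()] or [binary_mask()] providing the grid.
#' @param center world coordinate, mm.
#' @param radius_mm sphere radius, mm.
#' @return A [binary_mask()].
#' @export
sphere_mask <- function(like, center, radius_mm) {
  ctr <- voxel_centers(like)
  dd <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
    (ctr[, 3] - center[3])^2
  binary_mask(array(dd <= radius_mm^2, dim(like$values)), like$spacing,
              like$origin)
}

#' HU window rule for mask extraction
#'
#' Inclusive lower bound, exclusive upper bound, with an optional exclusion
#' mask (e.g. a teeth/jaw region left out of bone analyses).
#'
#' @param lower lower HU bound, inclusive.
#' @param upper upper HU bound, exclusive; default `Inf`.
#' @param exclusion optional [binary_mask()] of voxels to drop.
#' @return A `mask_rule` object.
#' @export
mask_rule <- function(lower, upper = Inf, exclusion = NULL) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper)
    stop("mask_rule requires lower < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper, exclusion = exclusion),
            class = "mask_rule")
}

#' Threshold an HU volume into a binary mask
#'
#' A voxel is TRUE iff `lower <= HU < upper` and it is not excluded. The
#' standard bone rule is `mask_rule(250)` (250 HU and above) and the air rule
#' `mask_rule(-Inf, -900)`.
#'
#' @param volume an [image_volume()] of HU.
#' @param rule a [mask_rule()].
#' @return A [binary_mask()] with an exact TRUE-voxel count in `n_voxels`.
#' @export
threshold_mask <- function(volume, rule) {
  stopifnot(inherits(volume, "image_volume"), inherits(rule, "mask_rule"))
  m <- volume$values >= rule$lower & volume$values < rule$upper
  if (!is.null(rule$exclusion)) {
    check_same_grid(volume, rule$exclusion, "volume and exclusion mask")
    m <- m & !rule$exclusion$values
  }
  binary_mask(m, volume$spacing, volume$origin)
}

#' Dilate a mask by a physical radius
#'
#' Spherical structuring element of radius `radius_mm`, respecting
#' anisotropic voxel spacing: a voxel is added if its centre lies within
#' `radius_mm` of a TRUE voxel centre.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm dilation radius in mm, >= 0.
#' @return The dilated [binary_mask()], a superset of the input.
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(radius_mm) || radius_mm < 0)
    stop("radius must be >= 0", call. = FALSE)
  if (radius_mm == 0 || !any(mask$values)) return(mask)
  sp <- mask$spacing
  r <- floor(radius_mm / sp)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (g$dx * sp[1])^2 + (g$dy * sp[2])^2 + (g$dz * sp[3])^2 <=
    radius_mm^2
  offs <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(offs) <- "integer"
  out <- cpp_dilate(as.logical(mask$values), dim(mask$values), offs)
  binary_mask(array(out, dim(mask$values)), sp, mask$origin)
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' The transform maps points of the input volume into target space; the value
#' at a target voxel centre q is interpolated from the input at T^-1(q).
#' Out-of-field voxels take `fill` (default -1000 for HU images, 0
#' otherwise). Masks must use `mode = "nearest"` and stay strictly boolean.
#'
#' @param volume an [image_volume()] or [binary_mask()].
#' @param transform a [rigid_transform()]; identity by default.
#' @param target grid to resample onto: an [image_volume()]/[binary_mask()]
#'   whose geometry is used, or `NULL` to keep the input grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill out-of-field fill value.
#' @return A volume (or mask) on the target grid.
#' @export
resample_volume <- function(volume, transform = rigid_transform(),
                            target = NULL,
                            mode = if (inherits(volume, "binary_mask"))
                              "nearest" else "linear",
                            fill = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (!mode %in% c("linear", "nearest"))
    stop("unknown mode: ", mode, call. = FALSE)
  is_mask <- inherits(volume, "binary_mask")
  if (is.null(fill))
    fill <- if (is_mask) 0 else if (identical(volume$unit, "HU")) -1000 else 0
  if (is.null(target)) target <- volume
  if (any(target$spacing <= 0)) stop("target spacing must be > 0",
                                     call. = FALSE)
  inv <- transform_inverse(transform)
  aff <- transform_affine(inv)   # p = M q + b
  src <- if (is_mask) array(as.numeric(volume$values), dim(volume$values))
         else volume$values
  out <- cpp_resample(src, dim(volume$values), volume$spacing, volume$origin,
                      dim(target$values), target$spacing, target$origin,
                      aff$M, aff$b, fill, mode == "nearest")
  out <- array(out, dim(target$values))
  if (is_mask)
    binary_mask(out != 0, target$spacing, target$origin)
  else
    image_volume(out, target$spacing, target$origin, unit = volume$unit)
}
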