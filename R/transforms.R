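#' 6-DoF rigid transform
#'
#' Three translations (mm) and three rotations (degrees) about a fixed
#' centre. Rotations are intrinsic, applied in the order rz (yaw), then ry
#' (roll), then rx (pitch), i.e. the rotation matrix is
#' `R = Rz %*% Ry %*% Rx`. A point p maps to `R (p - c) + c + t`. Angles are
#' normalised to (-180, 180].
#'
#' @param tx,ty,tz translations, mm.
#' @param rx,ry,rz rotations about X (pitch), Y (roll), Z (yaw), degrees.
#' @param center rotation centre, world mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                            center = c(0, 0, 0)) {
  ang <- vapply(c(rx, ry, rz), wrap_angle, numeric(1))
  structure(
    list(tx = tx, ty = ty, tz = tz,
         rx = ang[1], ry = ang[2], rz = ang[3],
         center = as.numeric(center)),
    class = "rigid_transform"
  )
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (a == -180) 180 else a
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg, centre (%g, %g, %g)\n",
    x$tx, x$ty, x$tz, x$rx, x$ry, x$rz,
    x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Transform parameters as a numeric vector
#' @param x a [rigid_transform()].
#' @return Named numeric: tx, ty, tz (mm), rx, ry, rz (deg).
#' @export
transform_params <- function(x) {
  c(tx = x$tx, ty = x$ty, tz = x$tz, rx = x$rx, ry = x$ry, rz = x$rz)
}

rot_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# ZYX Euler decomposition, degrees
rot_angles <- function(R) {
  ry <- -asin(max(-1, min(1, R[3, 1])))
  if (abs(cos(ry)) < 1e-12) {  # gimbal lock: fold into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  } else {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  }
  c(rx, ry, rz) * 180 / pi
}

# affine form q = M p + b of the forward map
transform_affine <- function(tf) {
  R <- rot_matrix(tf$rx, tf$ry, tf$rz)
  cc <- tf$center
  list(M = R, b = cc + c(tf$tx, tf$ty, tf$tz) - as.numeric(R %*% cc))
}

#' Apply a rigid transform to world points
#' @param tf a [rigid_transform()].
#' @param pts n x 3 matrix of world coordinates, mm.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(tf, pts) {
  pts <- rbind(pts)
  aff <- transform_affine(tf)
  sweep(pts %*% t(aff$M), 2, aff$b, "+")
}

#' Inverse of a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse `rigid_transform`, sharing the same centre.
#' @export
transform_inverse <- function(tf) {
  R <- rot_matrix(tf$rx, tf$ry, tf$rz)
  Rt <- t(R)
  tt <- -as.numeric(Rt %*% c(tf$tx, tf$ty, tf$tz))
  ang <- rot_angles(Rt)
  rigid_transform(tt[1], tt[2], tt[3], ang[1], ang[2], ang[3],
                  center = tf$center)
}

#' Compose two rigid transforms (a after b)
#'
#' Returns the transform equivalent to applying `b` first, then `a`. Both
#' must share the same rotation centre.
#'
#' @param a,b [rigid_transform()] objects with identical centres.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  if (max(abs(a$center - b$center)) > 1e-9)
    stop("transforms must share a rotation centre", call. = FALSE)
  Ra <- rot_matrix(a$rx, a$ry, a$rz)
  Rb <- rot_matrix(b$rx, b$ry, b$rz)
  R <- Ra %*% Rb
  # c(p): R(p - c) + c + t with t solved from composing the affine maps
  affa <- transform_affine(a); affb <- transform_affine(b)
  b2 <- as.numeric(affa$M %*% affb$b) + affa$b
  cc <- a$center
  tt <- b2 - cc + as.numeric(R %*% cc)
  ang <- rot_angles(R)
  rigid_transform(tt[1], tt[2], tt[3], ang[1], ang[2], ang[3], center = cc)
}

#' Re-express a rigid transform about a different rotation centre
#'
#' Returns a transform describing the same mapping with its rotation centre
#' moved to `new_center` (the translation parameters absorb the change).
#'
#' @param tf a [rigid_transform()].
#' @param new_center world coordinate, mm.
#' @return An equivalent `rigid_transform` centred at `new_center`.
#' @export
transform_with_center <- function(tf, new_center) {
  R <- rot_matrix(tf$rx, tf$ry, tf$rz)
  aff <- transform_affine(tf)
  new_center <- as.numeric(new_center)
  # solve t' from: R(p - c') + c' + t' == M p + b
  tt <- aff$b - new_center + as.numeric(R %*% new_center)
  rigid_transform(tt[1], tt[2], tt[3], tf$rx, tf$ry, tf$rz,
                  center = new_center)
}

#' Per-parameter difference between two registrations
#'
#' Parameter-wise subtraction `a - b` of two 6-DoF results that share a fixed
#' image, rotation convention and centre — the quantity histogrammed when
#' setup-verification registrations against sCT and CT references are
#' compared per degree of freedom. The composed alternative
#' `a o b^-1` is returned alongside for comparison.
#'
#' @param a,b [rigid_transform()] objects (e.g. sCT-CBCT and CT-CBCT).
#' @return A list with `delta` (named numeric, tx..rz of a - b) and
#'   `composed` (the `rigid_transform` a o b^-1).
#' @export
registration_delta <- function(a, b) {
  if (max(abs(a$center - b$center)) > 1e-6)
    stop("transform centres differ: deltas are not comparable",
         call. = FALSE)
  d <- transform_params(a) - transform_params(b)
  list(delta = d, composed = transform_compose(a, transform_inverse(b)))
}

#' Serialize / deserialize a transform as JSON
#' @param tf a [rigid_transform()].
#' @param path file path.
#' @return `path` (write) or a `rigid_transform` (read).
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(
    list(parameters = as.list(transform_params(tf)),
         center = tf$center,
         convention = "intrinsic rz-ry-rx, degrees; translations mm"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$parameters
  rigid_transform(p$tx, p$ty, p$tz, p$rx, p$ry, p$rz,
                  center = as.numeric(j$center))
}
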