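# Marker-phantom system-distortion analysis: render a lattice of ~1200
# bright spherical markers (optionally displaced by a known distortion
# field), detect them as connected components with intensity-weighted
# centroids, and match detections to the control template.

#' Regular marker lattice for the distortion phantom
#'
#' @param n per-axis marker counts; the default 12 x 10 x 10 gives the
#'   customary ~1200 markers.
#' @param pitch lattice pitch, mm.
#' @return n_total x 3 matrix of world coordinates centred on the origin.
#' @export
marker_template <- function(n = c(12, 10, 10), pitch = 20) {
  g <- expand.grid(x = (seq_len(n[1]) - (n[1] + 1) / 2) * pitch,
                   y = (seq_len(n[2]) - (n[2] + 1) / 2) * pitch,
                   z = (seq_len(n[3]) - (n[3] + 1) / 2) * pitch)
  as.matrix(g)
}

#' Render a marker-phantom image
#'
#' Spheres of unit intensity with a one-voxel partial-volume edge on a zero
#' background plus Gaussian noise, at template positions displaced by
#' `distortion_field`.
#'
#' @param template n x 3 matrix of marker positions (mm),
#'   e.g. [marker_template()].
#' @param distortion_field `NULL` (no distortion) or a function taking an
#'   n x 3 position matrix and returning an n x 3 displacement matrix (mm).
#' @param marker_radius sphere radius, mm.
#' @param noise_sd background/image Gaussian noise SD (marker peak is 1).
#' @param grid_spacing voxel size, mm (isotropic scalar or length-3).
#' @param margin empty margin beyond the displaced markers, mm.
#' @param seed RNG seed for the noise.
#' @return A list: `image` ([image_volume()]), `template`, `displaced` (the
#'   true displaced positions), `true_displacement`.
#' @export
generate_marker_phantom <- function(template = marker_template(),
                                    distortion_field = NULL,
                                    marker_radius = 3, noise_sd = 0.03,
                                    grid_spacing = 1.5, margin = 15,
                                    seed = 1L) {
  sp <- rep(grid_spacing, length.out = 3)
  disp <- if (is.null(distortion_field)) template * 0
          else distortion_field(template)
  pos <- template + disp
  lo <- apply(pos, 2, min) - margin
  hi <- apply(pos, 2, max) + margin
  d <- as.integer(ceiling((hi - lo) / sp)) + 1L
  org <- lo
  img <- array(0, d)
  edge <- mean(sp)
  # pairwise marker separation check (post-displacement)
  if (nrow(pos) > 1 && min(stats::dist(pos)) < 2 * marker_radius)
    warning("overlapping markers after displacement; markers kept")
  hw <- ceiling((marker_radius + edge) / sp)
  for (m in seq_len(nrow(pos))) {
    cidx <- round((pos[m, ] - org) / sp)   # 0-based nearest voxel
    i0 <- pmax(cidx - hw, 0); i1 <- pmin(cidx + hw, d - 1L)
    xs <- org[1] + (i0[1]:i1[1]) * sp[1]
    ys <- org[2] + (i0[2]:i1[2]) * sp[2]
    zs <- org[3] + (i0[3]:i1[3]) * sp[3]
    dd <- sqrt(outer(outer((xs - pos[m, 1])^2, (ys - pos[m, 2])^2, "+"),
                     (zs - pos[m, 3])^2, "+"))
    val <- pmin(pmax((marker_radius - dd) / edge + 0.5, 0), 1)
    blk <- img[(i0[1]:i1[1]) + 1L, (i0[2]:i1[2]) + 1L, (i0[3]:i1[3]) + 1L]
    img[(i0[1]:i1[1]) + 1L, (i0[2]:i1[2]) + 1L, (i0[3]:i1[3]) + 1L] <-
      pmax(blk, val)
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, array(stats::rnorm(prod(d), 0, noise_sd), d))
  list(image = image_volume(img, sp, org, unit = "signal"),
       template = template, displaced = pos, true_displacement = disp)
}

#' Detect spherical markers as bright connected components
#'
#' Voxels above `threshold` are grouped by 26-connectivity; components with
#' at least `min_voxels` voxels are reported with their intensity-weighted
#' centroid (weights are the supra-threshold excess, which cancels the
#' background level).
#'
#' The threshold's role is background-noise rejection, so the default sits
#' well above the noise floor but *low* on the marker's partial-volume
#' edge ramp: the centroid then integrates (nearly) the whole edge
#' profile, which is symmetric about the marker surface. Thresholding at
#' half-max instead truncates the ramp asymmetrically relative to the
#' voxel lattice and biases centroids by a noticeable fraction of a voxel.
#'
#' @param volume an [image_volume()].
#' @param threshold intensity threshold; must lie within the image range.
#' @param min_voxels smallest component kept.
#' @return A tibble: x, y, z (mm), n_voxels, peak. Zero detections give an
#'   empty tibble.
#' @export
detect_markers <- function(volume, threshold = 0.2, min_voxels = 4L) {
  stopifnot(inherits(volume, "image_volume"))
  if (threshold >= max(volume$values))
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          n_voxels = integer(), peak = numeric()))
  m <- volume$values > threshold
  lab <- cpp_label3d(as.logical(m), dim(volume$values), 26L)
  sel <- lab > 0L
  if (!any(sel))
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          n_voxels = integer(), peak = numeric()))
  ids <- lab[sel]
  w <- volume$values[sel] - threshold
  ctr <- voxel_centers(volume)[sel, , drop = FALSE]
  sw <- tapply(w, ids, sum)
  keep <- tabulate(ids) >= min_voxels
  cx <- tapply(w * ctr[, 1], ids, sum) / sw
  cy <- tapply(w * ctr[, 2], ids, sum) / sw
  cz <- tapply(w * ctr[, 3], ids, sum) / sw
  pk <- tapply(volume$values[sel], ids, max)
  nv <- tabulate(ids)[as.integer(names(sw))]
  out <- tibble::tibble(x = as.numeric(cx), y = as.numeric(cy),
                        z = as.numeric(cz), n_voxels = as.integer(nv),
                        peak = as.numeric(pk))
  out[keep[as.integer(names(sw))], ]
}

#' Match detected centroids to the control template
#'
#' Greedy one-to-one matching by ascending distance within `match_radius`.
#' Displacement = centroid - template. Summaries (mean and max |d|) are
#' reported over matched markers whose template radius from `isocenter` is
#' at most `radial_limit` (default 150 mm, the head-covering radius).
#'
#' @param centroids tibble from [detect_markers()] (columns x, y, z).
#' @param template n x 3 matrix of template positions, mm.
#' @param match_radius maximum template-centroid distance, mm.
#' @param isocenter world coordinate of the scanner isocentre, mm.
#' @param radial_limit radius for the summary statistics, mm.
#' @return A `marker_analysis` list: `pairs` (tibble with template/centroid
#'   coordinates, displacement components, |d|, radius), `n_unmatched`,
#'   `mean_abs`, `max_abs`, `rms`, `radial` (per-25mm-bin mean/max).
#' @export
match_and_summarize <- function(centroids, template, match_radius = 3,
                                isocenter = c(0, 0, 0), radial_limit = 150) {
  if (match_radius <= 0) stop("match_radius must be > 0", call. = FALSE)
  cm <- as.matrix(centroids[, c("x", "y", "z")])
  nt <- nrow(template); nc <- nrow(cm)
  pairs <- NULL
  if (nc > 0 && nt > 0) {
    d2 <- outer(rowSums(template^2), rep(1, nc)) +
      outer(rep(1, nt), rowSums(cm^2)) - 2 * template %*% t(cm)
    d2[d2 < 0] <- 0
    cand <- which(d2 <= match_radius^2, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d2[cand])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(nt); used_c <- logical(nc)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        ti <- cand[i, 1]; ci <- cand[i, 2]
        if (!used_t[ti] && !used_c[ci]) {
          used_t[ti] <- TRUE; used_c[ci] <- TRUE; keep[i] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      disp <- cm[cand[, 2], , drop = FALSE] -
        template[cand[, 1], , drop = FALSE]
      rad <- sqrt(rowSums(sweep(template[cand[, 1], , drop = FALSE], 2,
                                isocenter)^2))
      pairs <- tibble::tibble(
        tx = template[cand[, 1], 1], ty = template[cand[, 1], 2],
        tz = template[cand[, 1], 3],
        cx = cm[cand[, 2], 1], cy = cm[cand[, 2], 2], cz = cm[cand[, 2], 3],
        dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
        dabs = sqrt(rowSums(disp^2)), radius = rad)
    }
  }
  if (is.null(pairs))
    pairs <- tibble::tibble(tx = numeric(), ty = numeric(), tz = numeric(),
                            cx = numeric(), cy = numeric(), cz = numeric(),
                            dx = numeric(), dy = numeric(), dz = numeric(),
                            dabs = numeric(), radius = numeric())
  inr <- pairs$radius <= radial_limit
  bins <- seq(0, max(radial_limit, if (nrow(pairs)) max(pairs$radius) else 0)
              + 25, by = 25)
  bi <- cut(pairs$radius, bins, include.lowest = TRUE)
  radial <- tibble::tibble(
    bin = levels(bi),
    n = as.integer(table(bi)),
    mean_abs = as.numeric(tapply(pairs$dabs, bi, mean)),
    max_abs = as.numeric(tapply(pairs$dabs, bi, max)))
  structure(list(
    pairs = pairs,
    n_unmatched = nt - nrow(pairs),
    mean_abs = if (any(inr)) mean(pairs$dabs[inr]) else NA_real_,
    max_abs = if (any(inr)) max(pairs$dabs[inr]) else NA_real_,
    rms = if (any(inr)) sqrt(mean(pairs$dabs[inr]^2)) else NA_real_,
    radial_limit = radial_limit, radial = radial),
    class = "marker_analysis")
}

#' @export
print.marker_analysis <- function(x, ...) {
  cat(sprintf(
    "<marker_analysis> %d matched, %d unmatched; within %g mm: mean |d| = %.3f mm, max |d| = %.3f mm\n",
    nrow(x$pairs), x$n_unmatched, x$radial_limit, x$mean_abs, x$max_abs))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.marker_analysis <- function(x, ...) x$pairs
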