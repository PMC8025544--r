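# 6-DoF rigid bone-window registration. Similarity is the normalized
# cross-correlation of window-clamped HU inside the registration box,
# maximized by a deterministic multi-resolution pattern search (fixed step
# schedule, derivative-free, strictly monotone in accepted steps).

#' Registration specification
#'
#' @param window a [mask_rule()] HU window; intensities are clamped to it
#'   (values outside set to the window floor). The CBCT setup convention is
#'   200-1700 HU; sCT-to-CT bone match uses 250 HU and above.
#' @param box optional world-coordinate registration box,
#'   `list(lower = c(x,y,z), upper = c(x,y,z))` in mm; `NULL` uses the whole
#'   fixed image. The conventional head box keeps the whole head with a
#'   caudal cut-off below the brain.
#' @param levels multi-resolution downsampling factors, coarse to fine.
#' @param init_step initial pattern-search steps, `c(mm, deg)`.
#' @param min_step convergence steps, `c(mm, deg)`; the search stops when
#'   both fall below these.
#' @param min_similarity final NCC below this reports failure.
#' @param center rotation centre: `"centroid"` (intensity centroid of the
#'   window-clamped fixed image inside the box, which decouples rotations
#'   from translations) or an explicit world coordinate (mm). Registrations
#'   whose deltas will be compared must share an explicit centre.
#' @return A `registration_spec` object.
#' @export
registration_spec <- function(window = mask_rule(200, 1700), box = NULL,
                              levels = c(4, 2, 1),
                              init_step = c(8, 4),
                              min_step = c(0.02, 0.02),
                              min_similarity = 0.7,
                              center = "centroid") {
  stopifnot(inherits(window, "mask_rule"))
  if (!is.null(box) && any(box$upper <= box$lower))
    stop("degenerate registration box", call. = FALSE)
  structure(list(window = window, box = box, levels = levels,
                 init_step = init_step, min_step = min_step,
                 min_similarity = min_similarity, center = center),
            class = "registration_spec")
}

#' Head registration box with caudal cut-off
#'
#' Axis-aligned box covering the whole fixed image except the most caudal
#' part: the box ends `caudal_fraction` of the Z extent above the inferior
#' end (Z runs superior to inferior).
#'
#' @param fixed an [image_volume()].
#' @param caudal_fraction fraction of the Z extent cut off inferiorly.
#' @return A box list usable in [registration_spec()].
#' @export
head_box <- function(fixed, caudal_fraction = 0.15) {
  d <- dim(fixed$values)
  lo <- fixed$origin
  hi <- fixed$origin + (d - 1) * fixed$spacing
  hi[3] <- hi[3] - caudal_fraction * (hi[3] - lo[3])
  list(lower = lo, upper = hi)
}

#' Window-weighted intensity centroid
#'
#' Centroid of `vol` weighted by intensity above the window floor, inside
#' the box. This is the default rotation centre of [rigid_register()];
#' compute it once and pass it as an explicit `center` when two
#' registrations against different fixed images must share a centre (e.g.
#' for [registration_delta()]).
#'
#' @param vol an [image_volume()].
#' @param window a [mask_rule()] HU window.
#' @param box optional registration box (see [registration_spec()]).
#' @return World coordinate (mm).
#' @export
windowed_centroid <- function(vol, window = mask_rule(200, 1700),
                              box = NULL) {
  if (is.null(box)) {
    d <- dim(vol$values)
    box <- list(lower = vol$origin,
                upper = vol$origin + (d - 1) * vol$spacing)
  }
  w <- clamp_window(vol$values, window) - window$lower
  ctr <- voxel_centers(vol)
  inbox <- ctr[, 1] >= box$lower[1] & ctr[, 1] <= box$upper[1] &
    ctr[, 2] >= box$lower[2] & ctr[, 2] <= box$upper[2] &
    ctr[, 3] >= box$lower[3] & ctr[, 3] <= box$upper[3]
  wv <- as.numeric(w) * inbox
  if (sum(wv) <= 0) (box$lower + box$upper) / 2
  else colSums(ctr * wv) / sum(wv)
}

clamp_window <- function(v, window) {
  hi <- if (is.finite(window$upper)) window$upper else Inf
  out <- pmin(pmax(v, window$lower), hi)
  out[v < window$lower] <- window$lower
  out
}

#' Rigid 6-DoF registration by bone-window NCC
#'
#' Finds the rigid transform mapping `moving` into the fixed frame that
#' maximizes the normalized cross-correlation of window-clamped intensities
#' at the fixed voxel centres inside the registration box, over a coarse-to-
#' fine level schedule. Deterministic given `init`.
#'
#' @param fixed,moving [image_volume()] objects (HU).
#' @param spec a [registration_spec()].
#' @param init initial [rigid_transform()]; its centre is ignored — the
#'   rotation centre comes from `spec$center` (see [registration_spec()]).
#' @return A `registration_result`: `transform` ([rigid_transform()]),
#'   `similarity` (final NCC), `status` (`"converged"` or `"failed"`),
#'   `trace` (tibble of accepted steps: level, eval, similarity).
#' @export
rigid_register <- function(fixed, moving, spec = registration_spec(),
                           init = rigid_transform()) {
  stopifnot(inherits(fixed, "image_volume"),
            inherits(moving, "image_volume"))
  box <- if (is.null(spec$box)) {
    d <- dim(fixed$values)
    list(lower = fixed$origin, upper = fixed$origin + (d - 1) * fixed$spacing)
  } else spec$box
  mov_clamped <- array(clamp_window(moving$values, spec$window),
                       dim(moving$values))
  floor_val <- spec$window$lower
  center <- if (is.numeric(spec$center)) as.numeric(spec$center)
            else windowed_centroid(fixed, spec$window, box)

  # fixed sample points and clamped values per level
  level_data <- lapply(spec$levels, function(f) {
    d <- dim(fixed$values)
    idx <- lapply(1:3, function(a) seq(1L, d[a], by = f))
    ax <- axis_coords(fixed)
    pts <- as.matrix(expand.grid(x = ax[[1]][idx[[1]]],
                                 y = ax[[2]][idx[[2]]],
                                 z = ax[[3]][idx[[3]]]))
    vals <- clamp_window(
      fixed$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], spec$window)
    inbox <- pts[, 1] >= box$lower[1] & pts[, 1] <= box$upper[1] &
      pts[, 2] >= box$lower[2] & pts[, 2] <= box$upper[2] &
      pts[, 3] >= box$lower[3] & pts[, 3] <= box$upper[3]
    list(pts = pts[inbox, , drop = FALSE], vals = as.numeric(vals)[inbox])
  })

  ncc <- function(p, ld) {
    tf <- rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6],
                          center = center)
    src <- transform_points(transform_inverse(tf), ld$pts)
    mv <- cpp_interp_points(mov_clamped, dim(moving$values), moving$spacing,
                            moving$origin, src, floor_val, FALSE)
    if (stats::sd(mv) == 0 || stats::sd(ld$vals) == 0) return(-1)
    stats::cor(ld$vals, mv)
  }

  p <- unname(transform_params(init))
  trace <- list()
  n_eval <- 0L
  for (li in seq_along(spec$levels)) {
    ld <- level_data[[li]]
    if (length(ld$vals) < 10 || stats::sd(ld$vals) == 0)
      return(structure(list(transform = NULL, similarity = NA_real_,
                            status = "failed", trace = NULL),
                       class = "registration_result"))
    lf <- spec$levels[li]
    step <- c(rep(spec$init_step[1], 3), rep(spec$init_step[2], 3)) *
      lf / max(spec$levels)
    best <- ncc(p, ld); n_eval <- n_eval + 1L
    trace[[length(trace) + 1]] <- c(li, n_eval, best)
    repeat {
      improved <- FALSE
      for (d6 in 1:6) {
        for (s in c(step[d6], -step[d6])) {
          cand <- p; cand[d6] <- cand[d6] + s
          val <- ncc(cand, ld); n_eval <- n_eval + 1L
          if (val > best + 1e-12) {
            p <- cand; best <- val; improved <- TRUE
            trace[[length(trace) + 1]] <- c(li, n_eval, best)
          }
        }
      }
      if (!improved) {
        step <- step / 2
        if (all(step[1:3] < spec$min_step[1]) &&
            all(step[4:6] < spec$min_step[2])) break
      }
    }
  }
  # simplex polish at the finest level: the coordinate search can stall on
  # ridges where rotations trade off against translations
  ld <- level_data[[length(level_data)]]
  pol <- stats::optim(p, function(q) -ncc(q, ld), method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12,
                                     parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
  n_eval <- n_eval + pol$counts[1]
  if (-pol$value > best) {
    p <- pol$par; best <- -pol$value
    trace[[length(trace) + 1]] <- c(length(spec$levels), n_eval, best)
  }
  tr <- do.call(rbind, trace)
  status <- if (best >= spec$min_similarity) "converged" else "failed"
  structure(list(
    transform = rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6],
                                center = center),
    similarity = best, status = status,
    trace = tibble::tibble(level = tr[, 1], eval = tr[, 2],
                           similarity = tr[, 3])),
    class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s, NCC = %.4f\n", x$status,
              x$similarity))
  if (!is.null(x$transform)) print(x$transform)
  invisible(x)
}

#' @export
tidy.registration_result <- function(x, ...) {
  p <- transform_params(x$transform)
  tibble::tibble(parameter = names(p), value = unname(p),
                 unit = c(rep("mm", 3), rep("deg", 3)))
}

#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(status = x$status, similarity = x$similarity,
                 n_eval = if (is.null(x$trace)) 0L else max(x$trace$eval))
}
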