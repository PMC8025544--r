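# 3D global gamma analysis with dose cut-off. For each evaluated reference
# voxel r the gamma index is the minimum over nearby evaluation positions e
# of sqrt(((D_e - D_r)/dD)^2 + (|e - r|/DTA)^2); the evaluation dose is
# sampled trilinearly on a subgrid of step DTA/10 within a search radius of
# 3 x DTA, with early termination once the distance term alone exceeds the
# best gamma found.

#' Gamma-analysis criteria
#'
#' @param dose_tol dose-difference tolerance, percent of the normalization
#'   dose, > 0.
#' @param dta distance-to-agreement, mm, > 0.
#' @param cutoff dose cut-off, percent of the normalization dose, in
#'   `[0, 100)`; reference voxels below it are not evaluated.
#' @param normalization `"prescription"` (global normalization at the
#'   prescribed dose; the default, since results are reported as percent of
#'   prescription) or `"global-max"` (maximum reference dose).
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_tol, dta, cutoff = 15,
                           normalization = c("prescription", "global-max")) {
  if (dose_tol <= 0) stop("dose_tol must be > 0", call. = FALSE)
  if (dta <= 0) stop("dta must be > 0", call. = FALSE)
  if (cutoff < 0 || cutoff >= 100) stop("cutoff must be in [0, 100)",
                                        call. = FALSE)
  structure(list(dose_tol = dose_tol, dta = dta, cutoff = cutoff,
                 normalization = match.arg(normalization)),
            class = "gamma_criteria")
}

# spherical search-offset table: rows (dx, dy, dz) in mm sorted by ascending
# distance, plus the normalized squared distance term
gamma_offsets <- function(dta, step = dta / 10, radius = 3 * dta) {
  n <- floor(radius / step)
  s <- (-n:n) * step
  g <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  d2 <- rowSums(g^2)
  keep <- d2 <= radius^2
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  list(offsets = g[ord, , drop = FALSE], dist2 = d2[ord] / dta^2)
}

#' 3D global gamma index between two dose grids
#'
#' CT dose is the reference, sCT dose the evaluated distribution. The
#' cut-off applies to the reference dose; an optional restriction mask
#' (e.g. the PTV) further intersects the evaluated set.
#'
#' @param ref_dose,eval_dose [image_volume()] dose grids (Gy) on the same
#'   grid (resample first otherwise).
#' @param criteria a [gamma_criteria()].
#' @param prescription prescribed dose, Gy; required when
#'   `normalization = "prescription"`.
#' @param restriction optional [binary_mask()] limiting the evaluated
#'   voxels.
#' @return A `gamma_result`: `gamma` ([image_volume()], NA outside the
#'   evaluated set), `eval_mask`, `pass_rate` (percent of evaluated voxels
#'   with gamma <= 1), `n_evaluated`, `criteria`.
#' @export
gamma_3d <- function(ref_dose, eval_dose, criteria, prescription = NULL,
                     restriction = NULL) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  check_same_grid(ref_dose, eval_dose, "dose grids")
  norm_dose <- switch(criteria$normalization,
                      "prescription" = {
                        if (is.null(prescription) || prescription <= 0)
                          stop("normalization dose must be > 0",
                               call. = FALSE)
                        prescription
                      },
                      "global-max" = max(ref_dose$values))
  if (norm_dose <= 0) stop("normalization dose must be > 0", call. = FALSE)
  dd_abs <- criteria$dose_tol / 100 * norm_dose
  cutoff_abs <- criteria$cutoff / 100 * norm_dose
  emask <- ref_dose$values >= cutoff_abs
  if (!is.null(restriction)) {
    check_same_grid(ref_dose, restriction, "dose and restriction mask")
    emask <- emask & restriction$values
  }
  off <- gamma_offsets(criteria$dta)
  g <- cpp_gamma(ref_dose$values, eval_dose$values, dim(ref_dose$values),
                 ref_dose$spacing, ref_dose$origin, off$offsets, off$dist2,
                 dd_abs, as.integer(emask))
  g <- array(g, dim(ref_dose$values))
  n_eval <- sum(emask)
  pass <- if (n_eval) 100 * sum(g[emask] <= 1) / n_eval else NA_real_
  gmap <- image_volume(array(0, dim(g)), ref_dose$spacing, ref_dose$origin,
                       unit = "gamma")
  gmap$values <- g   # NA outside the evaluated set, by design
  structure(list(
    gamma = gmap,
    eval_mask = binary_mask(emask, ref_dose$spacing, ref_dose$origin),
    pass_rate = pass, n_evaluated = n_eval, norm_dose = norm_dose,
    criteria = criteria), class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %g%%/%g mm, cutoff %g%%: pass rate %.1f%% over %d voxels\n",
    x$criteria$dose_tol, x$criteria$dta, x$criteria$cutoff, x$pass_rate,
    x$n_evaluated))
  invisible(x)
}

#' @export
glance.gamma_result <- function(x, ...) {
  tibble::tibble(dose_tol = x$criteria$dose_tol, dta = x$criteria$dta,
                 cutoff = x$criteria$cutoff,
                 normalization = x$criteria$normalization,
                 pass_rate = x$pass_rate, n_evaluated = x$n_evaluated)
}

#' @importFrom generics glance
#' @export
generics::glance
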