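# ZTE-like couch imaging: the treatment couch gives no signal in the Dixon
# images used for sCT generation, so a short low-SNR zero-echo-time scan is
# emulated to localise the couch top (its anterior face) behind the head.

#' Generate a ZTE-like image with a treatment-couch slab
#'
#' The body yields unit signal, the couch a flat horizontal slab of lower
#' signal posterior to the head (larger Y), everything degraded with
#' Gaussian noise of SD 1/SNR.
#'
#' @param phantom a `head_phantom`.
#' @param couch_y_top world Y (mm) of the couch top (anterior face);
#'   `NULL` for no couch.
#' @param couch_thickness slab thickness, mm.
#' @param couch_signal slab signal relative to the body's 1.
#' @param snr body-signal-to-noise ratio; `Inf` for noiseless.
#' @param seed RNG seed.
#' @return A list: `image` ([image_volume()]), `couch_y_top` (the truth).
#' @export
generate_zte_couch_image <- function(phantom, couch_y_top = 96,
                                     couch_thickness = 60,
                                     couch_signal = 0.6, snr = 5,
                                     seed = 1L) {
  stopifnot(inherits(phantom, "head_phantom"))
  ct <- phantom$ct
  d <- dim(ct$values)
  img <- array(0, d)
  img[phantom$labels$body$values] <- 1
  if (!is.null(couch_y_top)) {
    ys <- axis_coords(ct)[[2]]
    body_max_y <- max(voxel_centers(ct)[phantom$labels$body$values, 2])
    if (couch_y_top <= body_max_y)
      stop("couch must lie posterior to the body", call. = FALSE)
    sel <- ys >= couch_y_top & ys <= couch_y_top + couch_thickness
    img[, sel, ] <- pmax(img[, sel, ], couch_signal)
  }
  if (is.finite(snr))
    img <- img + with_seed(seed, array(stats::rnorm(prod(d), 0, 1 / snr), d))
  list(image = image_volume(img, ct$spacing, ct$origin, unit = "signal"),
       couch_y_top = couch_y_top)
}

# Otsu's threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256) {
  h <- hist(x, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Locate the treatment-couch top in a ZTE-like image
#'
#' For every transverse (X, Z) column the posterior-most sustained
#' supra-threshold run is located (threshold: Otsu split of the image). The
#' couch is a flat slab, so its anterior-face coordinate is consistent
#' across columns; the body's posterior surface is curved and is not. The
#' couch top is the median anterior-face Y over the consistent columns; if
#' fewer than half of all columns agree, the couch is reported as not found.
#'
#' @param zte an [image_volume()] (e.g. from [generate_zte_couch_image()]).
#' @param min_run shortest accepted run, voxels.
#' @param consistency_mm columns within this distance of the median count as
#'   consistent.
#' @return A list: `found` (logical), `y_mm` (couch-top world Y, or NA),
#'   `support` (fraction of columns consistent with the median).
#' @export
detect_couch_top <- function(zte, min_run = 3L, consistency_mm = 6) {
  stopifnot(inherits(zte, "image_volume"))
  d <- dim(zte$values)
  thr <- otsu_threshold(as.numeric(zte$values))
  ys <- axis_coords(zte)[[2]]
  n_col <- d[1] * d[3]
  face <- rep(NA_real_, n_col)
  m <- zte$values > thr
  col <- 0L
  for (k in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      col <- col + 1L
      v <- m[i, , k]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- which(r$values & r$lengths >= min_run)
      if (length(ok))
        face[col] <- ys[starts[ok[length(ok)]]]   # posterior-most run
    }
  }
  if (!any(!is.na(face)))
    return(list(found = FALSE, y_mm = NA_real_, support = 0))
  med <- stats::median(face, na.rm = TRUE)
  support <- sum(!is.na(face) & abs(face - med) <= consistency_mm) / n_col
  if (support < 0.5)
    return(list(found = FALSE, y_mm = NA_real_, support = support))
  consistent <- face[!is.na(face) & abs(face - med) <= consistency_mm]
  # run start is the first voxel centre inside the slab; the face lies half
  # a voxel anterior to it
  list(found = TRUE,
       y_mm = stats::median(consistent) - zte$spacing[2] / 2,
       support = support)
}
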