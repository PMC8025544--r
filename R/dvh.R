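# Cumulative dose-volume histograms and their clinical endpoints.

#' Compute a cumulative DVH over a structure
#'
#' The curve gives, for each dose level, the fraction of the structure
#' receiving at least that dose: 1 at 0 Gy, non-increasing, 0 above the
#' maximum dose.
#'
#' @param dose an [image_volume()] of dose, Gy.
#' @param mask a non-empty [binary_mask()] (the structure).
#' @param prescription prescribed dose, Gy, > 0 (the unit for relative
#'   endpoint differences).
#' @param bin_width histogram bin width, Gy.
#' @return A `dvh_curve`: `dose` (bin edges, Gy), `volume` (cumulative
#'   relative volume), `n_voxels`, `prescription`, `d_mean`.
#' @export
compute_dvh <- function(dose, mask, prescription, bin_width = 0.01) {
  stopifnot(inherits(dose, "image_volume"), inherits(mask, "binary_mask"))
  check_same_grid(dose, mask, "dose and mask")
  if (!any(mask$values)) stop("empty mask", call. = FALSE)
  if (prescription <= 0) stop("prescription must be > 0", call. = FALSE)
  v <- dose$values[mask$values]
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  # fraction of voxels receiving at least each edge dose
  cum <- 1 - stats::ecdf(v)(edges - bin_width * 1e-9)
  cum[1] <- 1
  structure(list(dose = edges, volume = cum, n_voxels = length(v),
                 prescription = prescription, d_mean = mean(v)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> %d voxels, prescription %g Gy, Dmean %.3f Gy, D98%% %.3f Gy, D2%% %.3f Gy\n",
    x$n_voxels, x$prescription, x$d_mean,
    d_at_volume(x, 98), d_at_volume(x, 2)))
  invisible(x)
}

#' Dose covering a given volume fraction (DX%)
#'
#' The highest dose D such that at least `v_pct` percent of the structure
#' receives >= D, read from the cumulative curve at its bin resolution
#' (the largest bin edge whose cumulative volume is still >= `v_pct`).
#' This matches the order-statistic definition to within one bin width.
#'
#' @param dvh a `dvh_curve`.
#' @param v_pct volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
d_at_volume <- function(dvh, v_pct) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (v_pct <= 0 || v_pct > 100) stop("v_pct must be in (0, 100]",
                                      call. = FALSE)
  f <- v_pct / 100
  idx <- which(dvh$volume >= f - 1e-12)
  dvh$dose[idx[length(idx)]]
}

#' Evaluate a named DVH endpoint
#'
#' @param dvh a `dvh_curve`.
#' @param endpoint `"Dmean"`, or `"DX"`/`"DX%"` for the dose covering X% of
#'   the volume (e.g. `"D98"`, `"D2"`).
#' @return Dose in Gy.
#' @export
dvh_endpoint <- function(dvh, endpoint) {
  if (identical(endpoint, "Dmean")) return(dvh$d_mean)
  mm <- regmatches(endpoint, regexec("^D([0-9.]+)%?$", endpoint))[[1]]
  if (length(mm) < 2) stop("unknown endpoint: ", endpoint, call. = FALSE)
  d_at_volume(dvh, as.numeric(mm[2]))
}

#' Endpoint differences between two DVHs, in percent of prescription
#'
#' diff = (endpoint_sCT - endpoint_CT) / prescription * 100; the sign
#' convention is evaluation minus reference (sCT - CT).
#'
#' @param dvh_sct,dvh_ct `dvh_curve` objects with the same prescription.
#' @param endpoints character vector of endpoints, see [dvh_endpoint()].
#' @return A tibble: endpoint, sct_gy, ct_gy, diff_pct.
#' @export
dvh_difference <- function(dvh_sct, dvh_ct,
                           endpoints = c("Dmean", "D98", "D2")) {
  if (abs(dvh_sct$prescription - dvh_ct$prescription) > 1e-9)
    stop("prescription mismatch", call. = FALSE)
  rx <- dvh_ct$prescription
  s <- vapply(endpoints, dvh_endpoint, numeric(1), dvh = dvh_sct)
  r <- vapply(endpoints, dvh_endpoint, numeric(1), dvh = dvh_ct)
  tibble::tibble(endpoint = endpoints, sct_gy = unname(s),
                 ct_gy = unname(r), diff_pct = unname((s - r) / rx * 100))
}

#' @export
tidy.dvh_curve <- function(x, ...) {
  tibble::tibble(dose = x$dose, volume = x$volume)
}

#' DVH plot
#'
#' @param object a `dvh_curve`.
#' @param ... unused.
#' @return A ggplot of cumulative relative volume vs dose.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$volume)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Relative volume") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
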