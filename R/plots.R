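# Result-type plots. All plotting is cosmetic: every number shown is taken
# from the tibbles the analysis functions return.

#' Histogram of setup-verification registration deltas
#'
#' Per-degree-of-freedom histograms of the sCT-CBCT minus CT-CBCT
#' registration differences, with the conventional 0.1-unit bins.
#'
#' @param report a `pipeline_report` from [run_pipeline()] (needs
#'   `reg_delta`).
#' @param binwidth histogram bin size (mm or degrees).
#' @return A ggplot, faceted by parameter.
#' @export
plot_registration_deltas <- function(report, binwidth = 0.1) {
  if (is.null(report$reg_delta))
    stop("report carries no registration deltas", call. = FALSE)
  ggplot2::ggplot(report$reg_delta,
                  ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            closed = "right", fill = "grey40") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "sCT-CBCT minus CT-CBCT", y = "Cases") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.marker_analysis <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$radius, y = .data$dabs)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$radial_limit,
                        linetype = "dashed") +
    ggplot2::labs(x = "Template radius from isocentre (mm)",
                  y = "|displacement| (mm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gamma_result <- function(object, ...) {
  d <- dim(object$gamma$values)
  k <- which.max(apply(object$eval_mask$values, 3, sum))
  sl <- object$gamma$values[, , k]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$gamma <- as.numeric(sl)
  ggplot2::ggplot(df[!is.na(df$gamma), ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("gamma %g%%/%g mm, slice %d",
                                  object$criteria$dose_tol,
                                  object$criteria$dta, k)) +
    ggplot2::theme_minimal()
}
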