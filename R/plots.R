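#' Plot a solved pO2 field
#'
#' @param object A `po2_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.po2_field <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_along(object$x_um),
                           j = seq_along(object$y_um))
  df$x_um <- object$x_um[df$i]
  df$y_um <- object$y_um[df$j]
  df$po2 <- object$values[cbind(df$i, df$j)]
  ggplot2::ggplot(df[!is.na(df$po2), ],
                  ggplot2::aes(.data$x_um, .data$y_um, fill = .data$po2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "pO2 (mmHg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("Simulated pO2 field (CMRO2 = %g)",
                                  object$cmro2)) +
    ggplot2::theme_minimal()
}

#' Plot a radial fit over its data
#'
#' @param object A `cmro2_fit`.
#' @param ... Unused.
#' @export
autoplot.cmro2_fit <- function(object, ...) {
  rr <- seq(min(object$data$r_um), max(object$data$r_um), length.out = 200)
  curve <- tibble(r_um = rr, po2 = predict(object, rr))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$r_um, .data$po2_mmhg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$po2),
                       colour = "#2a9d34", linewidth = 0.9) +
    ggplot2::labs(x = "distance from arteriole center (um)", y = "pO2 (mmHg)",
                  title = sprintf("%s fit: CMRO2 = %.2f umol cm^-3 min^-1",
                                  toupper(object$model), object$cmro2)) +
    ggplot2::theme_minimal()
}

#' Plot an Rt sensitivity scan
#'
#' @param object An `rt_sensitivity` tibble.
#' @param ... Unused.
#' @export
autoplot.rt_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$r_t_assumed, .data$cmro2_hat,
                                       colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "true_cmro2"),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(odaciti = "#2a9d34",
                                            krogh = "black")) +
    ggplot2::labs(x = "assumed Rt (um)", y = "estimated CMRO2",
                  title = "Sensitivity to the assumed capillary-free radius") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation mask over the measurement grid
#'
#' @param object A `segmentation` result.
#' @param ... Unused.
#' @export
autoplot.segmentation <- function(object, ...) {
  ggplot2::ggplot(object$mask,
                  ggplot2::aes(.data$x_um, .data$y_um, colour = .data$reason)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(derivative = "#2a9d34",
                                            low_tail = "#457b9d",
                                            excluded = "grey75")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", title = "Segmented ROI") +
    ggplot2::theme_minimal()
}
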