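#' Plot a colored point cloud in plan view
#'
#' Top-down scatter of the cloud, colored either by its RGB radiometry, by
#' elevation, or by any column (e.g. `class`, `row_id`, `roughness`).
#'
#' @param cloud A point-cloud tibble.
#' @param color `"rgb"` (true color, default), `"z"`, or a column name.
#' @param size Point size.
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, color = "rgb", size = 0.3) {
  cloud <- tibble::as_tibble(cloud)
  p <- ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y))
  if (identical(color, "rgb")) {
    cloud$.col <- grDevices::rgb(cloud$r, cloud$g, cloud$b,
                                 maxColorValue = 255)
    p <- ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$.col), size = size) +
      ggplot2::scale_colour_identity()
  } else {
    col <- if (identical(color, "z")) "z" else color
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[col]]),
                                 size = size)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' 1:1 validation scatter for a cross-validated biomass model
#'
#' Out-of-fold predicted versus measured AGB with the 1:1 line and the
#' regression line through the predictions — the standard visual check of an
#' estimation model.
#'
#' @param object An `agb_report` from [loocv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agb_report <- function(object, ...) {
  d <- object$predictions[!is.na(object$predictions$pred), , drop = FALSE]
  lim <- range(c(d$agb, d$pred))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$agb, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "blue",
                         linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(
      x = expression("measured AGB (g/" * m^2 * ")"),
      y = expression("estimated AGB (g/" * m^2 * ")"),
      title = sprintf("LOOCV, %s model: R² = %.3f, RMSE = %.1f g/m²",
                      object$model$family, object$metrics$r2,
                      object$metrics$rmse)) +
    ggplot2::theme_minimal()
}

#' Per-genotype error bars
#'
#' @param genotype_table The tibble from [genotype_report()].
#' @return A ggplot object of RRMSE, ASE and MPSE by genotype.
#' @export
plot_genotype_errors <- function(genotype_table) {
  long <- tidyr::pivot_longer(genotype_table,
                              cols = c("rrmse", "ase", "mpse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genotype, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "error (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
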