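#' Plot methods
#'
#' ggplot2 visualisations of the package's result types: feature maps and
#' classification maps as raster tiles, elbow curves as annotated line
#' plots, evaluation reports as confusion heat maps, centroid spectra as
#' reflectance curves.
#'
#' @param object The object to plot.
#' @param ... Ignored.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot feature_map
#' @export
autoplot.feature_map <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$col, .data$row,
                                 fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$measure,
                                "dissimilarity to scene mean"),
                  x = NULL, y = NULL, fill = object$measure)
}

#' @rdname plots
#' @method autoplot hkmeans
#' @export
autoplot.hkmeans <- function(object, ...) {
  augment(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$col, .data$row,
                                 fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("hybrid K-means (k = %d)", object$k),
                  x = NULL, y = NULL, fill = "cluster")
}

#' @rdname plots
#' @method autoplot elbow_curve
#' @export
autoplot.elbow_curve <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("distortion", "inertia"),
                        names_to = "metric", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "suggested_k"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Elbow diagnostics",
                  subtitle = paste("suggested k =",
                                   attr(object, "suggested_k")),
                  x = "number of clusters", y = NULL)
}

#' @rdname plots
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  m <- cm_counts(object$confusion)
  as.data.frame.table(m, responseName = "count") |>
    ggplot2::ggplot(ggplot2::aes(.data$true, .data$predicted,
                                 fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("OA %.3f, kappa %.3f",
                      object$overall_accuracy, object$kappa),
      x = "true class", y = "predicted class")
}

#' @rdname plots
#' @param x An endmember set from [make_endmembers()] or a
#'   `spectral_library`.
#' @export
plot_spectra <- function(x, ...) {
  df <- if (inherits(x, "spectral_library")) {
    as_tibble(x)
  } else {
    tibble(id = rep(x$classes, each = length(x$wavelengths)),
           class = rep(x$classes, each = length(x$wavelengths)),
           wavelength = rep(x$wavelengths, nrow(x$spectra)),
           reflectance = as.vector(t(x$spectra)))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$reflectance,
                                   group = .data$id,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance")
}
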