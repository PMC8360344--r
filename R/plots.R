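# ggplot2 display methods for the package's result containers.

#' Plot a field-map tibble as a |B| contour/raster map
#'
#' @param object A field-map tibble from [selection_field()],
#'   [drive_field()] or [receive_sensitivity()] evaluated on a planar
#'   grid (exactly two of x, y, z varying).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_field_map <- function(object, ...) {
  varying <- c("x", "y", "z")[vapply(c("x", "y", "z"), function(a)
    length(unique(object[[a]])) > 1, logical(1))]
  if (length(varying) != 2)
    stop("plot_field_map: need a planar grid (two varying axes)")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[varying[1]]] * 1000, y = .data[[varying[2]]] * 1000)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$B * 1000)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$B * 1000),
                          colour = "white", linewidth = 0.2,
                          bins = 12) +
    ggplot2::scale_fill_viridis_c(name = "|B| (mT)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(varying[1], " (mm)"),
                  y = paste0(varying[2], " (mm)"))
}

#' @export
autoplot.mpi_phantom <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$x * 1000, y = .data$y * 1000,
    fill = .data$concentration)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "c (mg/ml)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @export
autoplot.mpi_sinogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$shift * 1000, y = .data$angle, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "signal (V)") +
    ggplot2::labs(x = "FFL shift (mm)", y = "angle (deg)")
}

#' @export
autoplot.mpi_image <- function(object, ...) {
  d <- tidy(object)
  d$intensity <- pmax(d$intensity, 0)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$x * 1000, y = .data$y * 1000, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @export
autoplot.ffl_calibration <- function(object, ...) {
  if (is.null(object$arc_data) || nrow(object$samples) == 0)
    stop("autoplot.ffl_calibration: calibration has no stored samples")
  arc <- object$arc_data
  arc$fit <- poly_eval(object$arc_poly, arc$S)
  ggplot2::ggplot(arc, ggplot2::aes(x = .data$S)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$z * 1000)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit * 1000),
                       colour = "steelblue") +
    ggplot2::labs(x = "shift parameter S",
                  y = "uncorrected FFL height (mm)")
}

#' Export a reconstructed image as 16-bit greyscale PNG
#'
#' Intensities are clipped at zero and scaled to the full 16-bit range;
#' the scaling is recorded in a JSON sidecar next to the image.
#'
#' @param image An `mpi_image`.
#' @param path Output path (".png").
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("write_image_png: the png package is not installed")
  v <- pmax(image$values, 0)
  peak <- max(v)
  if (peak > 0) v <- v / peak
  # rows of the PNG run top to bottom: transpose and flip y
  png::writePNG(t(v)[rev(seq_len(ncol(v))), , drop = FALSE], path)
  jsonlite::write_json(
    list(peak_intensity = peak, pixels = dim(image$values),
         fov_m = c(diff(range(image$x)), diff(range(image$y)))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
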