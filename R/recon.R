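# Filtered backprojection with apodized ramp filters.
#
# The discrete ramp is realized through the band-limited ramp's spatial
# kernel (h[0] = 1/(4 ds^2), h[n] = -1/(pi n ds)^2 for odd n, 0 for
# even n) transformed to frequency space, which avoids the DC bias of
# sampling |f| directly.  Projections are zero-padded to at least twice
# their length to suppress circular-convolution wrap-around.

#' Reconstruction filter
#'
#' Frequency response of an apodized ramp filter on the discrete
#' frequency axis of a (padded) shift axis.  The ramp `|f|` is
#' multiplied by a window `w(f)` with `f_N` the Nyquist frequency of
#' the shift axis:
#' ram-lak `w = 1`; shepp-logan `w = sinc(f / (2 f_N))`;
#' cosine `w = cos(pi f / (2 f_N))`; hann `w = 0.5 (1 + cos(pi f / f_N))`.
#'
#' @param name One of "ram-lak", "shepp-logan", "cosine", "hann".
#' @param n_samples Number of shift samples to be filtered.
#' @param spacing Shift-axis spacing (m).
#' @param pad_factor Zero-padding factor (>= 2).
#' @return A list of class `recon_filter` with the padded length `n_pad`,
#'   frequency axis `freq` (1/m) and response `H`.
#' @export
recon_filter <- function(name = c("hann", "cosine", "shepp-logan",
                                  "ram-lak"),
                         n_samples, spacing, pad_factor = 2) {
  name <- match.arg(name)
  n_pad <- 2^ceiling(log2(pad_factor * n_samples))
  ds <- spacing
  # band-limited ramp kernel, wrapped for the FFT
  j <- c(0:(n_pad / 2), -(n_pad / 2 - 1):-1)
  h <- numeric(n_pad)
  h[j == 0] <- 1 / (4 * ds^2)
  odd <- j %% 2 != 0
  h[odd] <- -1 / (pi * j[odd] * ds)^2
  # kernel truncation leaves a ~0.1% DC term; zero it exactly, which is
  # equivalent to convolving with the mean-subtracted kernel
  H <- Re(fft(h))
  H[1] <- 0
  f <- c(0:(n_pad / 2), -(n_pad / 2 - 1):-1) / (n_pad * ds)
  fn <- 1 / (2 * ds)
  w <- switch(name,
    "ram-lak" = rep(1, n_pad),
    "shepp-logan" = {
      u <- f / (2 * fn)
      ifelse(u == 0, 1, sin(pi * u) / (pi * u))
    },
    "cosine" = cos(pi * f / (2 * fn)),
    "hann" = 0.5 * (1 + cos(pi * f / fn))
  )
  structure(list(name = name, n_samples = n_samples, spacing = spacing,
                 n_pad = n_pad, freq = f, H = H * w),
            class = "recon_filter")
}

#' @export
print.recon_filter <- function(x, ...) {
  cat("<recon_filter> ", x$name, ", ", x$n_samples, " samples padded to ",
      x$n_pad, "\n", sep = "")
  invisible(x)
}

#' Filter sinogram projections in frequency space
#'
#' Row-wise: forward FFT along the shift axis (zero-padded), multiply
#' by the filter response, inverse FFT, truncate the padding.
#'
#' @param sinogram An `mpi_sinogram`.
#' @param filter A [recon_filter()] (or a filter name; the filter is
#'   then built for the sinogram's shift axis).
#' @return The filtered `mpi_sinogram` (units V/m).
#' @export
filter_projections <- function(sinogram, filter = "hann") {
  ns <- ncol(sinogram$values)
  ds <- sinogram$shifts[2] - sinogram$shifts[1]
  if (is.character(filter)) filter <- recon_filter(filter, ns, ds)
  if (filter$n_samples != ns || abs(filter$spacing - ds) > 1e-12 * ds)
    stop("filter_projections: filter does not match the shift axis")
  pad <- matrix(0, nrow(sinogram$values), filter$n_pad)
  pad[, seq_len(ns)] <- sinogram$values
  sp <- t(apply(pad, 1, fft))
  sp <- sweep(sp, 2, filter$H, `*`)
  out <- t(apply(sp, 1, function(r) Re(fft(r, inverse = TRUE)))) /
    filter$n_pad
  mpi_sinogram(out[, seq_len(ns), drop = FALSE] * ds,
               sinogram$angles, sinogram$shifts)
}

#' Reconstructed image container
#'
#' @param values Intensity matrix, rows = x, cols = y.
#' @param x,y Axis coordinates (m).
#' @param normalization Optional record of any scaling applied.
#' @export
mpi_image <- function(values, x, y, normalization = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  structure(list(values = values, x = x, y = y,
                 normalization = normalization),
            class = "mpi_image")
}

#' @export
print.mpi_image <- function(x, ...) {
  cat("<mpi_image> ", nrow(x$values), " x ", ncol(x$values),
      " pixels; range [", signif(min(x$values), 3), ", ",
      signif(max(x$values), 3), "]\n", sep = "")
  invisible(x)
}

#' Tidy a reconstructed image into a long tibble
#' @param x An `mpi_image`.
#' @param ... Unused.
#' @export
tidy.mpi_image <- function(x, ...) {
  xs <- rep(x$x, times = length(x$y))
  ys <- rep(x$y, each = length(x$x))
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, intensity = vals)
}

#' Backproject filtered projections
#'
#' For every pixel and angle, samples the filtered projection at
#' `s = x cos(theta) + y sin(theta)` by linear interpolation (zero
#' outside the shift axis) and sums over angles, scaled by
#' `pi / n_rotations`.
#'
#' @param filtered A filtered `mpi_sinogram`.
#' @param grid_n Output grid edge size in pixels.
#' @param fov Output field-of-view edge length (m); defaults to the
#'   span of the shift axis.
#' @return An [mpi_image()].
#' @export
backproject <- function(filtered, grid_n = 201L, fov = NULL) {
  if (is.null(fov)) fov <- diff(range(filtered$shifts))
  ax <- seq(-fov / 2, fov / 2, length.out = grid_n)
  gx <- rep(ax, times = grid_n); gy <- rep(ax, each = grid_n)
  img <- numeric(grid_n^2)
  sh <- filtered$shifts
  ds <- sh[2] - sh[1]
  ns <- length(sh)
  for (k in seq_along(filtered$angles)) {
    th <- filtered$angles[k] * pi / 180
    s <- gx * cos(th) + gy * sin(th)
    fi <- (s - sh[1]) / ds + 1
    i0 <- floor(fi); w <- fi - i0
    row <- filtered$values[k, ]
    v0 <- ifelse(i0 >= 1 & i0 <= ns, row[pmax(pmin(i0, ns), 1)], 0)
    v1 <- ifelse(i0 + 1 >= 1 & i0 + 1 <= ns,
                 row[pmax(pmin(i0 + 1, ns), 1)], 0)
    img <- img + v0 * (1 - w) + v1 * w
  }
  img <- img * pi / length(filtered$angles)
  mpi_image(matrix(img, grid_n, grid_n), ax, ax)
}

#' Filtered backprojection
#'
#' `recon_filter` + [filter_projections()] + [backproject()]: linear in
#' the sinogram.
#'
#' @param sinogram An `mpi_sinogram`.
#' @param filter_name Filter window name (see [recon_filter()]).
#' @param grid_n Output grid edge size in pixels.
#' @param fov Output field of view (m); defaults to the shift span.
#' @return An [mpi_image()].
#' @export
fbp <- function(sinogram, filter_name = "hann", grid_n = 201L,
                fov = NULL) {
  backproject(filter_projections(sinogram, filter_name), grid_n, fov)
}
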