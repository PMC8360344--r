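# Quantitative image evaluation: line profiles, two-dot contrast, SNR.

#' Sample an intensity profile along a line segment
#'
#' Bilinear samples of the image along the segment from `p1` to `p2`.
#'
#' @param image An `mpi_image`.
#' @param p1,p2 Segment endpoints, c(x, y) (m).
#' @param n_samples Number of samples.
#' @return A tibble: `s` (distance along the segment, m), `x`, `y`,
#'   `intensity`.
#' @export
line_profile <- function(image, p1, p2, n_samples = 201L) {
  tfrac <- seq(0, 1, length.out = n_samples)
  sx <- p1[1] + tfrac * (p2[1] - p1[1])
  sy <- p1[2] + tfrac * (p2[2] - p1[2])
  v <- bilinear_sample(image$values, image$x, image$y, sx, sy)
  tibble::tibble(s = tfrac * sqrt(sum((p2 - p1)^2)), x = sx, y = sy,
                 intensity = v)
}

#' Two-dot contrast
#'
#' Contrast `C = (I_max - I_min)/(I_max + I_min)` evaluated on the
#' intensity cross-section through the two dot centres of a resolution
#' phantom.  The image is clipped at zero, `I_max` is the mean of the
#' two profile peaks (the local maxima nearest the expected dot
#' positions) and `I_min` is the minimum strictly between them.  If no
#' valley separates the peaks the dots are unresolved and `C = 0` is
#' reported with `resolved = FALSE`.
#'
#' An alternative `mode = "global"` uses the maximum and minimum of the
#' whole (zero-clipped) image instead of the inter-dot profile.
#'
#' @param image An `mpi_image`.
#' @param center1,center2 Dot centres, c(x, y) (m).
#' @param n_samples Profile samples.
#' @param mode "profile" (default) or "global".
#' @return A tibble row: `C`, `I_max`, `I_min`, `resolved`.
#' @export
dot_contrast <- function(image, center1, center2, n_samples = 201L,
                         mode = c("profile", "global")) {
  mode <- match.arg(mode)
  img <- image
  img$values <- pmax(img$values, 0)
  if (mode == "global") {
    I_max <- max(img$values); I_min <- min(img$values)
    C <- if (I_max + I_min > 0) (I_max - I_min) / (I_max + I_min) else 0
    return(tibble::tibble(C = C, I_max = I_max, I_min = I_min,
                          resolved = C > 0))
  }
  d <- sqrt(sum((center2 - center1)^2))
  if (d == 0) stop("dot_contrast: dot centres coincide")
  u <- (center2 - center1) / d
  ext <- 0.75 * d
  prof <- line_profile(img, center1 - ext * u, center2 + ext * u,
                       n_samples)
  # peaks: maxima within a half-separation window of each expected centre
  near1 <- which(abs(prof$s - ext) <= d / 2)
  near2 <- which(abs(prof$s - (ext + d)) <= d / 2)
  i1 <- near1[which.max(prof$intensity[near1])]
  i2 <- near2[which.max(prof$intensity[near2])]
  if (i2 <= i1 + 1) {
    return(tibble::tibble(C = 0, I_max = max(prof$intensity),
                          I_min = max(prof$intensity),
                          resolved = FALSE))
  }
  I_max <- mean(c(prof$intensity[i1], prof$intensity[i2]))
  I_min <- min(prof$intensity[(i1 + 1):(i2 - 1)])
  if (I_min >= min(prof$intensity[i1], prof$intensity[i2])) {
    # monotone between the maxima: no separating valley
    return(tibble::tibble(C = 0, I_max = I_max, I_min = I_min,
                          resolved = FALSE))
  }
  C <- (I_max - I_min) / (I_max + I_min)
  tibble::tibble(C = C, I_max = I_max, I_min = I_min, resolved = C > 0)
}

#' Image signal-to-noise ratio
#'
#' Peak intensity inside the signal region divided by the standard
#' deviation inside the background region.  Default regions: signal =
#' discs of `signal_radius` around the supplied centres; background =
#' a border frame of width `border_frac` of the field of view.
#'
#' @param image An `mpi_image`.
#' @param centers List of signal-region centres, each c(x, y) (m).
#' @param signal_radius Signal disc radius (m).
#' @param border_frac Border-frame width as a fraction of the FOV.
#' @return SNR (dimensionless).
#' @export
image_snr <- function(image, centers, signal_radius = 0.005,
                      border_frac = 0.1) {
  nx <- length(image$x); ny <- length(image$y)
  gx <- rep(image$x, times = ny); gy <- rep(image$y, each = nx)
  insig <- rep(FALSE, nx * ny)
  for (ct in centers)
    insig <- insig | ((gx - ct[1])^2 + (gy - ct[2])^2 <=
                        signal_radius^2)
  fovx <- diff(range(image$x)); fovy <- diff(range(image$y))
  inbg <- gx < min(image$x) + border_frac * fovx |
    gx > max(image$x) - border_frac * fovx |
    gy < min(image$y) + border_frac * fovy |
    gy > max(image$y) - border_frac * fovy
  v <- as.vector(image$values)
  peak <- max(v[insig])
  noise <- sd(v[inbg])
  peak / noise
}
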