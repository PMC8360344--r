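# Phantom generators: 2D tracer concentration maps on a regular grid.
#
# A phantom is a matrix of mass concentrations (mg/ml) with rows
# indexing x and columns indexing y, pinned to the rotating-platform
# frame at a fixed slice height.

#' Construct a phantom from a concentration matrix
#'
#' @param values Concentration matrix (mg/ml), rows = x, cols = y.
#' @param pixel_size Pixel edge length (m).
#' @param slice_thickness Slab thickness represented by the 2D map (m).
#' @return An object of class `mpi_phantom`.
#' @export
mpi_phantom <- function(values, pixel_size = 0.25e-3,
                        slice_thickness = 1e-3) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("mpi_phantom: concentrations must be >= 0")
  nx <- nrow(values); ny <- ncol(values)
  structure(list(
    values = values, pixel_size = pixel_size,
    slice_thickness = slice_thickness,
    x = (seq_len(nx) - (nx + 1) / 2) * pixel_size,
    y = (seq_len(ny) - (ny + 1) / 2) * pixel_size
  ), class = "mpi_phantom")
}

#' @export
print.mpi_phantom <- function(x, ...) {
  cat("<mpi_phantom> ", nrow(x$values), " x ", ncol(x$values),
      " pixels at ", x$pixel_size * 1000, " mm; total mass ",
      signif(phantom_mass(x), 4), " mg ml^-1 px\n", sep = "")
  invisible(x)
}

#' Total concentration mass of a phantom (sum over pixels)
#' @param phantom An [mpi_phantom()].
#' @export
phantom_mass <- function(phantom) sum(phantom$values)

# pixel-centre grid convention: n = fov/pixel pixels per axis, centres
# at odd multiples of pixel/2, so an axis-aligned region whose edges
# fall on the pixel lattice rasterizes exactly
empty_grid <- function(fov, pixel_size) {
  n <- round(fov / pixel_size)
  matrix(0, n, n)
}

#' Two-dot resolution phantom
#'
#' Two square dots of the stated concentration, centred symmetrically
#' about the field-of-view centre along x and separated centre-to-centre
#' by `separation`.
#'
#' @param separation Centre-to-centre dot separation along x (m).
#' @param dot_size Dot edge length (m); default 1 mm.
#' @param concentration Tracer concentration in the dots (mg/ml);
#'   default 5 (undiluted).
#' @param fov Field of view edge length (m).
#' @param pixel_size Pixel edge length (m).
#' @return An [mpi_phantom()].
#' @export
two_dot_phantom <- function(separation, dot_size = 1e-3,
                            concentration = 5, fov = 0.02,
                            pixel_size = 0.25e-3) {
  v <- empty_grid(fov, pixel_size)
  ph <- mpi_phantom(v, pixel_size)
  for (s in c(-1, 1)) {
    cx <- s * separation / 2
    ix <- which(ph$x > cx - dot_size / 2 & ph$x < cx + dot_size / 2)
    iy <- which(ph$y > -dot_size / 2 & ph$y < dot_size / 2)
    v[ix, iy] <- concentration
  }
  mpi_phantom(v, pixel_size)
}

#' Filled-disc phantom
#'
#' Uniform disc; its Radon transform is the chord length
#' `2 c sqrt(r^2 - s^2)`, available in closed form via
#' [disc_radon()] for reconstruction tests.
#'
#' @param radius Disc radius (m).
#' @param center Disc centre c(x, y) (m).
#' @param concentration Concentration inside the disc (mg/ml).
#' @inheritParams two_dot_phantom
#' @export
disc_phantom <- function(radius, center = c(0, 0), concentration = 5,
                         fov = 0.02, pixel_size = 0.25e-3) {
  v <- empty_grid(fov, pixel_size)
  ph <- mpi_phantom(v, pixel_size)
  r2 <- outer(ph$x - center[1], ph$y - center[2],
              function(a, b) a^2 + b^2)
  v[r2 <= radius^2] <- concentration
  mpi_phantom(v, pixel_size)
}

#' Analytic Radon transform of a centred disc
#'
#' Chord length through a uniform disc: `2 c sqrt(r^2 - s^2)` for
#' `|s| < r`, zero outside; independent of the projection angle.
#'
#' @param s Signed distance of the projection line from the centre (m).
#' @param radius Disc radius (m).
#' @param concentration Disc concentration.
#' @export
disc_radon <- function(s, radius, concentration = 5) {
  ifelse(abs(s) < radius,
         2 * concentration * sqrt(pmax(radius^2 - s^2, 0)), 0)
}

# block-letter glyphs as unit-square stroke rectangles
# (x0, x1, y0, y1) in [0,1]^2, y up
letter_strokes <- list(
  U = rbind(c(0.00, 0.25, 0.0, 1.0), c(0.75, 1.00, 0.0, 1.0),
            c(0.00, 1.00, 0.0, 0.25)),
  M = rbind(c(0.00, 0.22, 0.0, 1.0), c(0.78, 1.00, 0.0, 1.0),
            c(0.22, 0.50, 0.55, 0.8), c(0.50, 0.78, 0.55, 0.8),
            c(0.39, 0.61, 0.3, 0.8)),
  B = rbind(c(0.00, 0.25, 0.0, 1.0), c(0.00, 1.00, 0.80, 1.00),
            c(0.00, 1.00, 0.42, 0.60), c(0.00, 1.00, 0.00, 0.20),
            c(0.75, 1.00, 0.60, 0.80), c(0.75, 1.00, 0.20, 0.42))
)

#' Block-letter phantom
#'
#' Rasterizes a string of block letters built from hand-defined stroke
#' rectangles (no font dependence).  Letters are laid out side by side,
#' centred in the field of view, filling `fill_frac` of it.
#'
#' @param text Uppercase string; supported glyphs: U, M, B.
#' @param concentration Concentration in the strokes (mg/ml).
#' @param fov Field of view edge length (m).
#' @param pixel_size Pixel edge length (m).
#' @param fill_frac Fraction of the FOV spanned by the text block.
#' @export
letters_phantom <- function(text = "UMB", concentration = 5,
                            fov = 0.04, pixel_size = 0.25e-3,
                            fill_frac = 0.8) {
  v <- empty_grid(fov, pixel_size)
  ph <- mpi_phantom(v, pixel_size)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  if (n == 0) return(mpi_phantom(v, pixel_size))
  unknown <- setdiff(chars, names(letter_strokes))
  if (length(unknown) > 0)
    stop("letters_phantom: no glyph for ", paste(unknown, collapse = ", "))
  block_w <- fov * fill_frac
  gap <- 0.25                            # inter-letter gap, letter widths
  letter_w <- block_w / (n + (n - 1) * gap)
  letter_h <- min(1.6 * letter_w, fov * fill_frac)
  x_left <- -block_w / 2
  for (k in seq_len(n)) {
    lx <- x_left + (k - 1) * letter_w * (1 + gap)
    for (r in seq_len(nrow(letter_strokes[[chars[k]]]))) {
      st <- letter_strokes[[chars[k]]][r, ]
      ix <- which(ph$x >= lx + st[1] * letter_w &
                  ph$x <= lx + st[2] * letter_w)
      iy <- which(ph$y >= (st[3] - 0.5) * letter_h &
                  ph$y <= (st[4] - 0.5) * letter_h)
      v[ix, iy] <- concentration
    }
  }
  mpi_phantom(v, pixel_size)
}

#' Read / write a phantom as a delimited text matrix
#'
#' Plain TSV of concentrations with a `# pixel_size_m:` header comment.
#'
#' @param phantom An [mpi_phantom()].
#' @param path File path.
#' @export
write_phantom <- function(phantom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pixel_size_m: ", phantom$pixel_size),
               paste0("# slice_thickness_m: ", phantom$slice_thickness)),
             con)
  utils::write.table(phantom$values, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  hdr <- readLines(path, n = 2)
  px <- as.numeric(sub(".*: ", "", hdr[1]))
  th <- as.numeric(sub(".*: ", "", hdr[2]))
  v <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(v) <- NULL
  mpi_phantom(v, px, th)
}

#' Tidy a phantom into a long tibble
#' @param x An [mpi_phantom()].
#' @param ... Unused.
#' @export
tidy.mpi_phantom <- function(x, ...) {
  xs <- rep(x$x, times = length(x$y))
  ys <- rep(x$y, each = length(x$x))
  vals <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, concentration = vals)
}

# simple 4-connected component labelling (used by letter layout checks)
#' Count 4-connected components of a phantom's support
#' @param phantom An [mpi_phantom()].
#' @param threshold Support threshold (mg/ml).
#' @export
phantom_components <- function(phantom, threshold = 0) {
  m <- phantom$values > threshold
  lab <- matrix(0L, nrow(m), ncol(m))
  nlab <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j] || lab[i, j] != 0L) next
    nlab <- nlab + 1L
    queue <- list(c(i, j)); lab[i, j] <- nlab
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 &&
            q[2] <= ncol(m) && m[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nlab
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  nlab
}
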