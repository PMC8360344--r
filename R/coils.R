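# Coil geometries and Biot-Savart field evaluation.
#
# Scanner frame: right-handed, z = 0 at the top surface of the device,
# z increasing away from it (into the imaging volume).  The field-free
# line (FFL) runs parallel to the y-axis.  All lengths in metres.

#' Wire segment set
#'
#' A polyline discretization of one or more closed current loops.  Each
#' turn of a coil is represented explicitly as a stacked filament loop.
#'
#' @param start,end n x 3 matrices of segment start/end points (m).
#' @param loop integer vector tagging each segment with its loop index.
#' @return An object of class `wire_set`.
#' @export
wire_set <- function(start, end, loop = rep(1L, nrow(start))) {
  start <- as.matrix(start); end <- as.matrix(end)
  stopifnot(ncol(start) == 3, ncol(end) == 3, nrow(start) == nrow(end),
            nrow(start) > 0, length(loop) == nrow(start))
  ws <- structure(list(start = unname(start), end = unname(end),
                       loop = as.integer(loop)),
                  class = "wire_set")
  for (l in unique(ws$loop)) {
    idx <- which(ws$loop == l)
    gap <- sqrt(sum((ws$end[idx[length(idx)], ] - ws$start[idx[1], ])^2))
    if (gap > 1e-9)
      stop("wire_set: loop ", l, " is not closed (gap ", signif(gap, 3), " m)")
  }
  ws
}

#' @export
print.wire_set <- function(x, ...) {
  cat("<wire_set> ", nrow(x$start), " segments in ",
      length(unique(x$loop)), " loops; total length ",
      signif(wire_length(x), 4), " m\n", sep = "")
  invisible(x)
}

#' Total wire path length of a segment set (m)
#' @param wires A [wire_set()].
#' @export
wire_length <- function(wires) {
  sum(sqrt(rowSums((wires$end - wires$start)^2)))
}

#' Concatenate wire sets
#' @param ... `wire_set` objects.
#' @export
wire_bind <- function(...) {
  sets <- list(...)
  off <- 0L
  loops <- list()
  for (i in seq_along(sets)) {
    loops[[i]] <- sets[[i]]$loop + off
    off <- off + max(sets[[i]]$loop)
  }
  wire_set(do.call(rbind, lapply(sets, `[[`, "start")),
           do.call(rbind, lapply(sets, `[[`, "end")),
           unlist(loops))
}

#' Racetrack selection-coil specification
#'
#' Dimensions of one racetrack electromagnet: overall length along the
#' FFL direction (y), overall width across it (x), winding-bundle height
#' (z), number of turns, and the core gap (the inner opening between the
#' two straight sections).  Defaults are the selection-coil dimensions of
#' the single-sided scanner this package models.
#'
#' @param length Overall outer length along y (m).
#' @param width Overall outer width along x (m).
#' @param height Winding-bundle height along z (m).
#' @param turns Number of turns.
#' @param core_gap Inner opening between the straight sections (m).
#' @param wire_size Conductor cross-section, c(width, height) in m.
#' @param center_x Coil centre x-coordinate (m).
#' @param z_top z of the top of the winding bundle (m); the bundle
#'   occupies `[z_top - height, z_top]`.
#' @param circulation +1 for counter-clockwise current seen from +z,
#'   -1 for clockwise.
#' @return A list of class `racetrack_spec`.
#' @export
racetrack_spec <- function(length = 0.245, width = 0.054, height = 0.0183,
                           turns = 26L, core_gap = 0.010,
                           wire_size = c(0.001, 0.001),
                           center_x = 0, z_top = 0, circulation = 1) {
  if (any(c(length, width, height, core_gap, wire_size) <= 0))
    stop("racetrack_spec: all dimensions must be positive")
  if (turns < 1 || turns != round(turns))
    stop("racetrack_spec: turns must be a positive integer")
  if (width <= core_gap)
    stop("racetrack_spec: width must exceed core_gap")
  if (length <= width)
    stop("racetrack_spec: length must exceed width")
  structure(list(length = length, width = width, height = height,
                 turns = as.integer(turns), core_gap = core_gap,
                 wire_size = wire_size, center_x = center_x,
                 z_top = z_top, circulation = sign(circulation)),
            class = "racetrack_spec")
}

# closed planar racetrack loop polyline: straights along y of length ls,
# semicircular ends of radius r, centred at (cx, 0, z)
racetrack_loop_nodes <- function(cx, z, r, ls, arc_points, circulation) {
  th1 <- seq(0, pi, length.out = arc_points + 1)[-1]
  th2 <- seq(pi, 2 * pi, length.out = arc_points + 1)[-1]
  xy <- rbind(
    c(r, -ls / 2),
    c(r, ls / 2),
    cbind(r * cos(th1), ls / 2 + r * sin(th1)),
    c(-r, -ls / 2),
    cbind(r * cos(th2), -ls / 2 + r * sin(th2))
  )
  if (circulation < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  cbind(xy[, 1] + cx, xy[, 2], z)
}

#' Discretize a racetrack coil into filament loops
#'
#' The `turns` turns are laid out as a regular filament lattice filling
#' the winding cross-section: `n_layers` layers stacked in z over the
#' bundle height, and `turns / n_layers` lateral positions spanning the
#' radial build `(width - core_gap) / 2`.  Every filament shares the same
#' straight-section length `length - width`; the semicircular ends are
#' concentric, so the innermost filament bounds the core gap and the
#' outermost reaches the stated outer width.
#'
#' @param spec A [racetrack_spec()].
#' @param arc_points Segments per semicircular end (>= 4).
#' @param n_layers Number of z-layers in the filament lattice.
#' @return A [wire_set()] with `turns` closed loops.
#' @export
discretize_racetrack <- function(spec, arc_points = 24L, n_layers = 2L) {
  stopifnot(inherits(spec, "racetrack_spec"))
  if (arc_points < 4) stop("discretize_racetrack: arc_points must be >= 4")
  if (spec$turns %% n_layers != 0)
    stop("discretize_racetrack: turns must be divisible by n_layers")
  n_lat <- spec$turns %/% n_layers
  build <- (spec$width - spec$core_gap) / 2
  radii <- spec$core_gap / 2 + (seq_len(n_lat) - 0.5) * build / n_lat
  zs <- spec$z_top - spec$height * (seq_len(n_layers) - 0.5) / n_layers
  ls <- spec$length - spec$width
  starts <- ends <- list(); loop <- integer(0); k <- 0L
  for (z in zs) for (r in radii) {
    k <- k + 1L
    nodes <- racetrack_loop_nodes(spec$center_x, z, r, ls,
                                  arc_points, spec$circulation)
    n <- nrow(nodes)
    starts[[k]] <- nodes[-n, , drop = FALSE]
    ends[[k]] <- nodes[-1, , drop = FALSE]
    loop <- c(loop, rep(k, n - 1))
  }
  wire_set(do.call(rbind, starts), do.call(rbind, ends), loop)
}

#' Analytic racetrack centreline perimeter (m)
#'
#' Perimeter of a single racetrack loop with straight sections of length
#' `ls` and semicircular ends of radius `r`: `2 ls + 2 pi r`.
#' @param ls Straight-section length (m).
#' @param r End radius (m).
#' @export
racetrack_perimeter <- function(ls, r) 2 * ls + 2 * pi * r

#' Discretize a planar circular (pancake) coil
#'
#' `turns` concentric circular filaments in the plane `z`, wound inward
#' from `radius` with pitch `pitch`.
#'
#' @param radius Outer filament radius (m).
#' @param turns Number of turns.
#' @param z Plane height (m).
#' @param center_xy Coil centre in the plane, c(x, y) (m).
#' @param n_points Segments per full circle.
#' @param pitch Radial distance between adjacent filaments (m).
#' @param circulation +1 counter-clockwise from +z.
#' @return A [wire_set()].
#' @export
discretize_circular <- function(radius, turns = 1L, z = 0,
                                center_xy = c(0, 0), n_points = 64L,
                                pitch = 0.001, circulation = 1) {
  if (radius <= 0) stop("discretize_circular: radius must be positive")
  radii <- radius - (seq_len(turns) - 1) * pitch
  if (any(radii <= 0))
    stop("discretize_circular: turns * pitch exceeds radius")
  starts <- ends <- list(); loop <- integer(0)
  for (k in seq_len(turns)) {
    th <- seq(0, 2 * pi, length.out = n_points + 1)
    if (circulation < 0) th <- rev(th)
    nodes <- cbind(center_xy[1] + radii[k] * cos(th),
                   center_xy[2] + radii[k] * sin(th), z)
    starts[[k]] <- nodes[-(n_points + 1), , drop = FALSE]
    ends[[k]] <- nodes[-1, , drop = FALSE]
    loop <- c(loop, rep(k, n_points))
  }
  wire_set(do.call(rbind, starts), do.call(rbind, ends), loop)
}

# internal fast path: points as n x 3 matrix -> n x 3 field matrix (T)
bs_matrix <- function(wires, points, current, min_dist = 5e-4) {
  if (current == 0) return(matrix(0, nrow(points), 3))
  B <- bs_field_cpp(wires$start, wires$end, points, current, min_dist)
  if (anyNA(B))
    stop("biot_savart: evaluation point within ", min_dist,
         " m of a wire segment (singularity guard)")
  B
}

#' Biot-Savart field of a wire set
#'
#' Evaluates the magnetic field of a discretized coil carrying `current`
#' at arbitrary points, using the exact closed form for straight
#' filament segments.  Points closer than `min_dist` (default: the wire
#' half-thickness, 0.5 mm) to any segment raise an error.
#'
#' @param wires A [wire_set()].
#' @param current Current (A); the field is linear in it.
#' @param points Data frame with columns x, y, z, or an n x 3 matrix (m).
#' @param min_dist Singularity guard distance (m).
#' @return A tibble with columns x, y, z, Bx, By, Bz (T).
#' @export
biot_savart <- function(wires, current, points, min_dist = 5e-4) {
  pts <- as_points_matrix(points)
  B <- bs_matrix(wires, pts, current, min_dist)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 Bx = B[, 1], By = B[, 2], Bz = B[, 3])
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    cbind(points$x, points$y, points$z)
  } else {
    m <- as.matrix(points)
    stopifnot(ncol(m) == 3)
    m
  }
}

#' Scanner coil system
#'
#' Builds the discretized coil set of the single-sided FFL scanner: two
#' racetrack selection coils side by side along x (gap `coil_gap`
#' between their facing outer edges), a planar circular drive coil
#' centred below them, and a planar circular receive coil on the
#' surface.  Both selection coils are wound with the same circulation;
#' the innermost straight conductors then carry opposite currents and
#' the superposed field vanishes on a line parallel to y above the
#' mid-plane, the field-free line.
#'
#' @param racetrack A [racetrack_spec()] giving the common selection-coil
#'   dimensions (centre and circulation are set per coil).
#' @param coil_gap Gap between the two selection coils' facing edges (m).
#' @param drive_radius,drive_turns Drive-coil outer radius (m) and turns.
#' @param drive_z_offset Distance from the selection coils' lower surface
#'   to the drive coil's upper surface (m).
#' @param receive_radius,receive_turns Receive-coil outer radius (m), turns.
#' @param arc_points Segments per semicircular racetrack end.
#' @param circle_points Segments per circular turn.
#' @return A list of class `scanner_geometry` with wire sets `sel1`
#'   (at -x), `sel2` (at +x), `drive`, `receive`.
#' @export
scanner_geometry <- function(racetrack = racetrack_spec(),
                             coil_gap = 0.011,
                             drive_radius = 0.025, drive_turns = 20L,
                             drive_z_offset = 0.004,
                             receive_radius = 0.015, receive_turns = 10L,
                             arc_points = 24L, circle_points = 64L) {
  cx <- coil_gap / 2 + racetrack$width / 2
  s1 <- racetrack_spec(racetrack$length, racetrack$width, racetrack$height,
                       racetrack$turns, racetrack$core_gap,
                       racetrack$wire_size, center_x = -cx,
                       z_top = racetrack$z_top, circulation = 1)
  s2 <- racetrack_spec(racetrack$length, racetrack$width, racetrack$height,
                       racetrack$turns, racetrack$core_gap,
                       racetrack$wire_size, center_x = +cx,
                       z_top = racetrack$z_top, circulation = 1)
  z_drive <- racetrack$z_top - racetrack$height - drive_z_offset
  structure(list(
    racetrack = racetrack, coil_gap = coil_gap,
    sel1 = discretize_racetrack(s1, arc_points),
    sel2 = discretize_racetrack(s2, arc_points),
    drive = discretize_circular(drive_radius, drive_turns, z = z_drive,
                                n_points = circle_points),
    receive = discretize_circular(receive_radius, receive_turns, z = 0,
                                  n_points = circle_points),
    drive_radius = drive_radius, drive_turns = drive_turns,
    receive_radius = receive_radius, receive_turns = receive_turns,
    z_drive = z_drive
  ), class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat("<scanner_geometry>\n",
      "  selection coils: 2 x ", x$racetrack$turns, " turns, ",
      x$racetrack$length * 100, " cm x ", x$racetrack$width * 1000,
      " mm, gap ", x$coil_gap * 1000, " mm\n",
      "  drive coil: ", x$drive_turns, " turns, r = ",
      x$drive_radius * 1000, " mm at z = ", x$z_drive * 1000, " mm\n",
      "  receive coil: ", x$receive_turns, " turns, r = ",
      x$receive_radius * 1000, " mm at z = 0\n", sep = "")
  invisible(x)
}

#' Regular evaluation grid
#'
#' @param xlim,ylim,zlim Length-2 ranges (m); a length-1 value fixes the
#'   coordinate.
#' @param n Number of samples per varying axis (recycled).
#' @return A tibble of grid points with columns x, y, z.
#' @export
field_grid <- function(xlim = c(-0.02, 0.02), ylim = 0,
                       zlim = c(0.005, 0.03), n = 41L) {
  ax <- function(lim, k) if (length(lim) == 1) lim else
    seq(lim[1], lim[2], length.out = k)
  n <- rep(n, length.out = 3)
  g <- expand.grid(x = ax(xlim, n[1]), y = ax(ylim, n[2]),
                   z = ax(zlim, n[3]), KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g)
}

#' Selection field on a grid
#'
#' Superposition of the two racetrack coil fields at currents `I1`
#' (coil at -x) and `I2` (coil at +x).  With `I1 = I2` the field
#' magnitude vanishes on a line parallel to y at the natural FFL height.
#'
#' @param geom A [scanner_geometry()].
#' @param I1,I2 Selection-coil currents (A).
#' @param grid Points (tibble with x, y, z or n x 3 matrix).
#' @return A tibble x, y, z, Bx, By, Bz, B (field magnitude, T).
#' @export
selection_field <- function(geom, I1, I2, grid) {
  pts <- as_points_matrix(grid)
  B <- bs_matrix(geom$sel1, pts, I1) + bs_matrix(geom$sel2, pts, I2)
  field_tibble(pts, B, current = c(I1 = I1, I2 = I2))
}

#' Drive-coil field per applied current, on a grid
#'
#' Static spatial amplitude of the drive coil per the applied current
#' `I_drive`; the sinusoidal time factor is applied during acquisition.
#'
#' @inheritParams selection_field
#' @param I_drive Drive current (A).
#' @export
drive_field <- function(geom, I_drive, grid) {
  pts <- as_points_matrix(grid)
  field_tibble(pts, bs_matrix(geom$drive, pts, I_drive),
               current = c(I_drive = I_drive))
}

#' Receive-coil sensitivity map
#'
#' Field of the receive coil at unit current (T/A), the sensitivity
#' profile that weights the induced-voltage integral by reciprocity.
#'
#' @inheritParams selection_field
#' @export
receive_sensitivity <- function(geom, grid) {
  pts <- as_points_matrix(grid)
  field_tibble(pts, bs_matrix(geom$receive, pts, 1),
               current = c(I_rx = 1))
}

field_tibble <- function(pts, B, current = NULL) {
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        Bx = B[, 1], By = B[, 2], Bz = B[, 3],
                        B = sqrt(rowSums(B^2)))
  attr(out, "current_setting") <- current
  out
}

# total static field (selection + drive offset) as an n x 3 matrix
total_static_field <- function(geom, pts, I1, I2, I_drive = 0) {
  B <- bs_matrix(geom$sel1, pts, I1) + bs_matrix(geom$sel2, pts, I2)
  if (I_drive != 0) B <- B + bs_matrix(geom$drive, pts, I_drive)
  B
}

#' Transverse FFL gradient of the static field
#'
#' Gradient of the field magnitude across the FFL, estimated from
#' samples at `x0 +/- step` at height `z`.  Near the line the magnitude
#' behaves as `sqrt((G dx)^2 + B0^2)` with `B0` the (small) residual at
#' the line, so `G` is recovered from the magnitude-squared difference,
#' which removes the residual's bias.
#'
#' @param geom A [scanner_geometry()].
#' @param x0,z FFL position (m).
#' @param I1,I2,I_drive Static currents (A).
#' @param step Finite-difference half-step (m).
#' @return Gradient magnitude (T/m).
#' @export
transverse_gradient <- function(geom, x0, z, I1, I2, I_drive = 0,
                                step = 5e-4) {
  pts <- cbind(c(x0 - step, x0, x0 + step), 0, z)
  B <- total_static_field(geom, pts, I1, I2, I_drive)
  m2 <- rowSums(B^2)
  g2 <- (m2[1] + m2[3]) / 2 - m2[2]
  sqrt(max(g2, 0)) / step
}

#' Gradient profile along a corrected FFL scan
#'
#' Evaluates the transverse gradient of the total static field
#' (selection + drive offset) at each FFL scan position at a fixed
#' slice height, and normalizes to the value at the scan centre
#' (x = 0).  The FFL is held on the flat trajectory by solving the
#' exact current parameters for every position with [place_ffl()]
#' (continuation from the scan centre outward), so the profile covers
#' positions beyond any fitted calibration's range.
#'
#' @param geom A [scanner_geometry()].
#' @param scan_x Scan positions along x (m).
#' @param z Slice height (m).
#' @param I0 Reference selection current (A); the normalized profile is
#'   independent of it.
#' @param step Finite-difference half-step (m).
#' @return A tibble: position, S, O, gradient (T/m), normalized.
#' @export
gradient_profile <- function(geom, scan_x, z, I0 = 77, step = 5e-4) {
  ord <- order(abs(scan_x))
  S <- O <- g <- numeric(length(scan_x))
  # continuation outward from the centre, separately per side
  last <- list("-1" = NULL, "1" = NULL)
  for (i in ord) {
    side <- as.character(sign(scan_x[i]) + (scan_x[i] == 0))
    init <- last[[side]] %||% last[["1"]] %||% last[["-1"]]
    p <- place_ffl(geom, scan_x[i], z, init = init)
    last[[side]] <- p
    S[i] <- p$S; O[i] <- p$O
    g[i] <- transverse_gradient(geom, scan_x[i], z, I0 * (1 + p$S),
                                I0 * (1 - p$S), 2 * I0 * p$O,
                                step = step)
  }
  g0 <- if (any(scan_x == 0)) g[which(scan_x == 0)[1]] else {
    p <- place_ffl(geom, 0, z)
    transverse_gradient(geom, 0, z, I0 * (1 + p$S), I0 * (1 - p$S),
                        2 * I0 * p$O, step = step)
  }
  tibble::tibble(position = scan_x, S = S, O = O, gradient = g,
                 normalized = g / g0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
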