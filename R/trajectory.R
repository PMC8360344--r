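# FFL localisation and trajectory-correction calibration.
#
# The FFL position in the y = 0 plane is a function of the current
# *ratios* only: scaling (I1, I2, I_drive) together scales the whole
# static field and leaves its zero line unmoved.  Calibration therefore
# works in the dimensionless shift parameter S = (I1 - I2)/(I1 + I2)
# and offset parameter O = I_drive/(I1 + I2).

#' Shift parameter of a selection-current pair
#' @param I1,I2 Selection-coil currents (A); `I1 + I2` must be nonzero.
#' @return S = (I1 - I2)/(I1 + I2).
#' @export
shift_param <- function(I1, I2) {
  if (any(I1 + I2 == 0)) stop("shift_param: I1 + I2 must be nonzero")
  (I1 - I2) / (I1 + I2)
}

#' Offset parameter of a drive-coil bias current
#' @param I_drive Drive-coil DC offset current (A).
#' @inheritParams shift_param
#' @return O = I_drive/(I1 + I2).
#' @export
offset_param <- function(I_drive, I1, I2) {
  if (any(I1 + I2 == 0)) stop("offset_param: I1 + I2 must be nonzero")
  I_drive / (I1 + I2)
}

# static field per unit I0 at S, O:  B/I0 = (1+S) B1u + (1-S) B2u + 2 O Bdu
field_at_SO <- function(geom, pts, S, O) {
  B <- bs_matrix(geom$sel1, pts, 1 + S) + bs_matrix(geom$sel2, pts, 1 - S)
  if (O != 0) B <- B + bs_matrix(geom$drive, pts, 2 * O)
  B
}

#' Locate the field-free line in the y = 0 plane
#'
#' Finds the (x, z) minimizing the static field magnitude for the given
#' currents by a coarse grid scan followed by Nelder-Mead refinement.
#'
#' @param geom A [scanner_geometry()].
#' @param I1,I2 Selection currents (A).
#' @param I_drive_offset Drive-coil DC bias current (A).
#' @param xlim,zlim Search region (m).
#' @param n_coarse Coarse-grid samples per axis.
#' @return A list with `x`, `z` (m) and `residual` (|B| at optimum, T).
#' @export
locate_ffl <- function(geom, I1, I2, I_drive_offset = 0,
                       xlim = c(-0.028, 0.028), zlim = c(0.004, 0.032),
                       n_coarse = 25L) {
  S <- shift_param(I1, I2)
  O <- offset_param(I_drive_offset, I1, I2)
  locate_ffl_SO(geom, S, O, xlim, zlim, n_coarse)
}

locate_ffl_SO <- function(geom, S, O, xlim = c(-0.028, 0.028),
                          zlim = c(0.004, 0.032), n_coarse = 25L,
                          init = NULL) {
  f <- function(p) {
    if (p[1] < xlim[1] || p[1] > xlim[2] ||
        p[2] < zlim[1] || p[2] > zlim[2]) return(1e6 * (1 + sum(p^2)))
    sum(field_at_SO(geom, matrix(c(p[1], 0, p[2]), 1), S, O)^2)
  }
  edge <- sqrt(rowSums(field_at_SO(
    geom, matrix(c(xlim[2], 0, zlim[2]), 1), S, O)^2))
  if (!is.null(init)) {
    # warm start: refine directly and accept only a true interior null
    o <- optim(init, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 800))
    margin <- c(diff(xlim), diff(zlim)) * 0.01
    interior <- o$par[1] > xlim[1] + margin[1] &&
      o$par[1] < xlim[2] - margin[1] &&
      o$par[2] > zlim[1] + margin[2] && o$par[2] < zlim[2] - margin[2]
    if (interior && sqrt(o$value) < 1e-4 * edge)
      return(list(x = o$par[1], z = o$par[2], residual = sqrt(o$value),
                  edge_field = edge))
  }
  xs <- seq(xlim[1], xlim[2], length.out = n_coarse)
  zs <- seq(zlim[1], zlim[2], length.out = n_coarse)
  g <- as.matrix(expand.grid(x = xs, y = 0, z = zs))
  m2 <- rowSums(field_at_SO(geom, g, S, O)^2)
  i0 <- which.min(m2)
  # reject minima on the region boundary: no interior null
  ix <- (i0 - 1) %% n_coarse + 1
  iz <- (i0 - 1) %/% n_coarse + 1
  if (ix %in% c(1, n_coarse) || iz %in% c(1, n_coarse))
    stop("locate_ffl: no interior |B| minimum in the search region")
  o <- optim(c(g[i0, 1], g[i0, 3]), f, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 800))
  list(x = o$par[1], z = o$par[2], residual = sqrt(o$value),
       edge_field = edge)
}

# least-squares polynomial fit; R^2 is reported as 1 when the response
# has no meaningful variance at the fitted scale (e.g. coefficients that
# vanish identically by coil symmetry), where the ratio is undefined
poly_fit <- function(x, y, degree, null_scale = 0) {
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0
  r2 <- if (all(y == y[1]) ||
            (null_scale > 0 && sd(y) < null_scale)) 1
        else summary(fit)$r.squared
  list(coef = cf, r2 = r2, range = range(x))
}

poly_eval <- function(p, x) {
  out <- 0
  for (k in rev(seq_along(p$coef))) out <- out * x + p$coef[k]
  out
}

#' Calibrate the FFL trajectory correction
#'
#' Maps the dimensionless current parameters (S, O) to the FFL position
#' (x, z) and back, in three fitting stages:
#'
#' 1. the uncorrected arc `z_FFL(S)` at O = 0 is fit by a degree-6
#'    polynomial;
#' 2. for each S, `z` versus O is fit by a quadratic
#'    `z = A2 O^2 + A1 O + A0`, and the coefficients `A0, A1, A2` are
#'    regressed against S;
#' 3. for each target height z, `x` versus S is fit by a cubic
#'    `x = B3 S^3 + B2 S^2 + B1 S + B0`, and `B0..B3` are regressed
#'    against z.
#'
#' Inverting stage 2 gives the drive current for a commanded height;
#' inverting stage 3 gives the shift parameter for a commanded x.
#'
#' @param geom A [scanner_geometry()].
#' @param S_range Range of S spanned by the calibration (|S| <= 1).
#' @param n_S Number of S samples (>= 13 for the degree-6 arc fit).
#' @param O_range Range of O spanned per S sample.
#' @param n_O Number of O samples per S (>= 5 for the quadratic fit).
#' @param z_targets Heights (m) at which stage-3 cubics are fit.
#' @param coef_degree Polynomial degree of the A_i(S) and B_i(z)
#'   coefficient regressions.
#' @param x_fit_max Stage-3 cubics are fit only from samples with
#'   `|x| <= x_fit_max` (m), the commanded-position domain.
#' @param xlim,zlim FFL search region passed to [locate_ffl()].
#' @return An object of class `ffl_calibration`.
#' @export
calibrate_trajectory <- function(geom,
                                 S_range = c(-0.72, 0.72), n_S = 21L,
                                 O_range = c(-0.45, 0.55), n_O = 11L,
                                 z_targets = seq(0.009, 0.022,
                                                 by = 0.0013),
                                 coef_degree = 4L,
                                 x_fit_max = 0.021,
                                 xlim = c(-0.033, 0.033),
                                 zlim = c(0.003, 0.040)) {
  if (n_S < 13) stop("calibrate_trajectory: need >= 13 S samples")
  if (n_O < 5) stop("calibrate_trajectory: need >= 5 O samples per S")
  S_vals <- seq(S_range[1], S_range[2], length.out = n_S)
  O_vals <- seq(O_range[1], O_range[2], length.out = n_O)

  # some (S, O) corners push the null out of the search region; those
  # samples are dropped (each S keeps its quadratic if >= 5 survive).
  # successive locates are warm-started from the previous null position.
  samples <- vector("list", n_S * n_O)
  k <- 0L
  for (S in S_vals) {
    init <- NULL
    for (O in O_vals) {
      loc <- tryCatch(locate_ffl_SO(geom, S, O, xlim, zlim, init = init),
                      error = function(e) NULL)
      if (is.null(loc)) { init <- NULL; next }
      init <- c(loc$x, loc$z)
      k <- k + 1L
      samples[[k]] <- tibble::tibble(S = S, O = O, x = loc$x, z = loc$z,
                                     residual = loc$residual)
    }
  }
  samples <- dplyr::bind_rows(samples)
  n_per_S <- table(samples$S)
  if (any(n_per_S < 5))
    stop("calibrate_trajectory: stage 2 rank-deficient (fewer than 5 ",
         "usable O samples at some S)")

  # stage 1: uncorrected arc z(S) at O = 0
  arc_data <- dplyr::bind_rows(lapply(S_vals, function(S) {
    loc <- locate_ffl_SO(geom, S, 0, xlim, zlim)
    tibble::tibble(S = S, O = 0, x = loc$x, z = loc$z,
                   residual = loc$residual)
  }))
  arc_poly <- poly_fit(arc_data$S, arc_data$z, 6L)

  # stage 2: per-S quadratics z = A2 O^2 + A1 O + A0
  A_tab <- samples |>
    dplyr::group_by(.data$S) |>
    dplyr::group_modify(function(d, key) {
      cf <- unname(coef(lm(z ~ O + I(O^2), data = d)))
      r2 <- summary(lm(z ~ O + I(O^2), data = d))$r.squared
      tibble::tibble(A0 = cf[1], A1 = cf[2], A2 = cf[3], r2 = r2)
    }) |>
    dplyr::ungroup()
  # a coefficient whose contribution to z stays below 0.1 mm over the
  # calibrated O range carries no trajectory information; its regression
  # R^2 is reported as 1 (see poly_fit)
  O_max <- max(abs(O_vals))
  A_polys <- Map(function(nm, p)
    poly_fit(A_tab$S, A_tab[[nm]], coef_degree,
             null_scale = 1e-4 / O_max^p),
    c("A0", "A1", "A2"), 0:2)
  names(A_polys) <- c("A0", "A1", "A2")

  # stage 3: per-z cubics x = B3 S^3 + B2 S^2 + B1 S + B0,
  # fit from (S, O) samples re-solved so every S sits at the target z;
  # one secant refinement on O tightens z onto the target before the x
  # sample is taken
  # stage 3 samples S twice as densely as stage 1/2: the per-z cubic
  # coefficients feed a regression in z, and coarse S sampling leaves
  # visible coefficient noise when the usable S window shifts with z
  S3_vals <- seq(S_range[1], S_range[2], length.out = 2L * n_S - 1L)
  B_rows <- lapply(z_targets, function(zt) {
    init <- NULL
    xs <- vapply(S3_vals, function(S) {
      O <- solve_offset_for_z(A_polys, S, zt, O_range)
      if (is.na(O)) return(NA_real_)
      loc <- tryCatch(locate_ffl_SO(geom, S, O, xlim, zlim, init = init),
                      error = function(e) NULL)
      if (is.null(loc)) return(NA_real_)
      if (abs(loc$z - zt) > 5e-5) {
        dz_dO <- poly_eval(A_polys$A1, S) +
          2 * poly_eval(A_polys$A2, S) * O
        if (abs(dz_dO) > 1e-6) {
          O2 <- O + (zt - loc$z) / dz_dO
          loc2 <- tryCatch(
            locate_ffl_SO(geom, S, O2, xlim, zlim,
                          init = c(loc$x, loc$z)),
            error = function(e) NULL)
          if (!is.null(loc2) && abs(loc2$z - zt) < abs(loc$z - zt))
            loc <- loc2
        }
      }
      init <<- c(loc$x, loc$z)
      if (abs(loc$z - zt) > 5e-4) return(NA_real_)
      loc$x
    }, numeric(1))
    # fit only over the commanded-position domain: the cubic is used to
    # invert x(S) inside |x| <= x_fit_max, and truncation error from
    # more extreme samples would leak into that domain
    ok <- !is.na(xs) & abs(xs) <= x_fit_max
    if (sum(ok) < 6) return(NULL)
    fit <- lm(xs[ok] ~ S3_vals[ok] + I(S3_vals[ok]^2) +
                I(S3_vals[ok]^3))
    cf <- unname(coef(fit))
    tibble::tibble(z = zt, B0 = cf[1], B1 = cf[2], B2 = cf[3],
                   B3 = cf[4], r2 = summary(fit)$r.squared,
                   S_min = min(S3_vals[ok]), S_max = max(S3_vals[ok]))
  })
  B_tab <- dplyr::bind_rows(B_rows)
  if (nrow(B_tab) < coef_degree + 1)
    stop("calibrate_trajectory: stage 3 rank-deficient ",
         "(too few usable z targets)")
  S_max_fit <- max(abs(c(B_tab$S_min, B_tab$S_max)))
  B_polys <- Map(function(nm, p)
    poly_fit(B_tab$z, B_tab[[nm]], coef_degree,
             null_scale = 1e-4 / S_max_fit^p),
    c("B0", "B1", "B2", "B3"), 0:3)
  names(B_polys) <- c("B0", "B1", "B2", "B3")

  structure(list(
    arc_poly = arc_poly, A_polys = A_polys, B_polys = B_polys,
    A_table = A_tab, B_table = B_tab, samples = samples,
    arc_data = arc_data,
    S_range = range(S_vals), O_range = range(O_vals),
    z_range = range(z_targets)
  ), class = "ffl_calibration")
}

#' @export
print.ffl_calibration <- function(x, ...) {
  cat("<ffl_calibration>\n",
      "  S range [", paste(signif(x$S_range, 3), collapse = ", "), "], ",
      "O range [", paste(signif(x$O_range, 3), collapse = ", "), "]\n",
      "  z range [", paste(signif(x$z_range * 1000, 3), collapse = ", "),
      "] mm\n", sep = "")
  invisible(x)
}

# quadratic root of z = A2 O^2 + A1 O + A0 at given S; branch chosen so
# the offset lies inside (or nearest to) the calibrated O range
solve_offset_for_z <- function(A_polys, S, z_target, O_range = NULL) {
  A0 <- poly_eval(A_polys$A0, S)
  A1 <- poly_eval(A_polys$A1, S)
  A2 <- poly_eval(A_polys$A2, S)
  if (abs(A2) < 1e-12) {
    if (abs(A1) < 1e-15) return(NA_real_)
    return((z_target - A0) / A1)
  }
  disc <- A1^2 - 4 * A2 * (A0 - z_target)
  if (disc < 0) return(NA_real_)
  roots <- (-A1 + c(-1, 1) * sqrt(disc)) / (2 * A2)
  if (!is.null(O_range)) {
    inside <- roots >= O_range[1] & roots <= O_range[2]
    if (any(inside)) roots <- roots[inside]
  }
  roots[which.min(abs(roots))]
}

#' Drive current required to hold a target FFL height
#'
#' Solves the calibrated quadratic height model for the offset parameter
#' and converts to amperes, `I_drive = O (I1 + I2)`.  Of the two
#' quadratic roots the one inside (or nearest) the calibrated O range is
#' returned.
#'
#' @param cal An `ffl_calibration`.
#' @param z_target Commanded height (m), inside the calibrated z range.
#' @param I1,I2 Selection currents (A).
#' @return Drive offset current (A).
#' @export
solve_drive_current <- function(cal, z_target, I1, I2) {
  S <- shift_param(I1, I2)
  O <- solve_offset_for_z(cal$A_polys, S, z_target, cal$O_range)
  if (is.na(O))
    stop("solve_drive_current: height ", z_target,
         " m unreachable (negative discriminant)")
  O * (I1 + I2)
}

#' Shift parameter required to reach a target x at a target height
#'
#' Solves the calibrated cubic `B3(z) S^3 + B2(z) S^2 + B1(z) S + B0(z)
#' = x` for S.  If several real roots fall inside the calibrated S
#' range, the one closest to the linear estimate `(x - B0)/B1` is
#' chosen.
#'
#' @param cal An `ffl_calibration`.
#' @param x_target,z_target Commanded FFL position (m).
#' @return Shift parameter S.
#' @export
solve_shift <- function(cal, x_target, z_target) {
  B <- vapply(cal$B_polys, poly_eval, numeric(1), x = z_target)
  roots <- polyroot(c(B[["B0"]] - x_target, B[["B1"]], B[["B2"]],
                      B[["B3"]]))
  real <- Re(roots[abs(Im(roots)) < 1e-7 * (1 + abs(Re(roots)))])
  tol <- 0.05 * diff(cal$S_range)
  inside <- real[real >= cal$S_range[1] - tol &
                 real <= cal$S_range[2] + tol]
  if (length(inside) == 0)
    stop("solve_shift: x = ", x_target, " m unreachable at z = ",
         z_target, " m (no real root in the calibrated S range)")
  lin <- (x_target - B[["B0"]]) / B[["B1"]]
  inside[which.min(abs(inside - lin))]
}

#' Current settings for a commanded FFL position
#'
#' Composes [solve_shift()] and [solve_drive_current()]:
#' `I1 = I0 (1 + S)`, `I2 = I0 (1 - S)`, plus the drive offset current
#' holding the height flat.
#'
#' @param cal An `ffl_calibration`.
#' @param x_target,z_target Commanded position (m).
#' @param I0 Reference selection current (A).
#' @return A list with `I1`, `I2`, `I_drive_offset`, `S`, `O`.
#' @export
currents_for_position <- function(cal, x_target, z_target, I0 = 77) {
  S <- solve_shift(cal, x_target, z_target)
  I1 <- I0 * (1 + S); I2 <- I0 * (1 - S)
  Id <- solve_drive_current(cal, z_target, I1, I2)
  list(I1 = I1, I2 = I2, I_drive_offset = Id, S = S,
       O = offset_param(Id, I1, I2))
}

#' Place the FFL exactly at a target position
#'
#' Solves the dimensionless current parameters (S, O) putting the field
#' null at `(x_target, z_target)` by Newton iteration on the located
#' null position (finite-difference Jacobian).  Unlike the fitted
#' calibration this is exact (to the localisation tolerance) and not
#' restricted to a fitted range; it is the reference the calibration is
#' judged against, and the workhorse of field-characterisation scans.
#'
#' @param geom A [scanner_geometry()].
#' @param x_target,z_target Target FFL position (m).
#' @param init Optional list with starting `S`, `O`.
#' @param tol Position tolerance (m).
#' @param xlim,zlim Null search region (m).
#' @return A list with `S`, `O`, `x`, `z` (achieved position).
#' @export
place_ffl <- function(geom, x_target, z_target, init = NULL,
                      tol = 1e-6, xlim = c(-0.035, 0.035),
                      zlim = c(0.002, 0.040)) {
  S <- init$S %||% (x_target / 0.03)
  O <- init$O %||% 0
  l <- NULL
  for (it in 1:15) {
    l <- locate_ffl_SO(geom, S, O, xlim, zlim,
                       init = c(x_target, z_target))
    ex <- l$x - x_target; ez <- l$z - z_target
    if (abs(ex) < tol && abs(ez) < tol) break
    h <- 1e-3
    lS <- locate_ffl_SO(geom, S + h, O, xlim, zlim, init = c(l$x, l$z))
    lO <- locate_ffl_SO(geom, S, O + h, xlim, zlim, init = c(l$x, l$z))
    J <- matrix(c(lS$x - l$x, lS$z - l$z, lO$x - l$x, lO$z - l$z) / h, 2)
    d <- tryCatch(solve(J, -c(ex, ez)), error = function(e) NULL)
    if (is.null(d)) stop("place_ffl: singular position Jacobian")
    # damp large steps to stay on the continuation branch
    sc <- min(1, 0.3 / max(abs(d)))
    S <- S + sc * d[1]; O <- O + sc * d[2]
  }
  if (abs(l$x - x_target) > 1e-4 || abs(l$z - z_target) > 1e-4)
    stop("place_ffl: did not converge to (", x_target, ", ", z_target,
         ") m")
  list(S = S, O = O, x = l$x, z = l$z)
}

#' Scale the reference current to hit a target transverse gradient
#'
#' The static field is linear in the current scale, so the transverse
#' FFL gradient at any corrected position scales with I0.  Returns the
#' I0 for which the gradient at (x = 0, z) equals `G_target`.
#'
#' @param geom A [scanner_geometry()].
#' @param cal An `ffl_calibration`.
#' @param z Slice height (m).
#' @param G_target Target gradient (T/m).
#' @param I0_ref Reference current at which the gradient is probed (A).
#' @export
i0_for_gradient <- function(geom, cal, z, G_target, I0_ref = 77) {
  cs <- currents_for_position(cal, 0, z, I0_ref)
  g <- transverse_gradient(geom, 0, z, cs$I1, cs$I2, cs$I_drive_offset)
  I0_ref * G_target / g
}

#' @describeIn calibrate_trajectory Tidy per-stage fit summaries: one row
#'   per fitted polynomial with its R^2 and coefficients.
#' @param x An `ffl_calibration`.
#' @param ... Unused.
#' @export
tidy.ffl_calibration <- function(x, ...) {
  rows <- list(tibble::tibble(stage = "arc", term = "z(S)",
                              degree = length(x$arc_poly$coef) - 1,
                              r2 = x$arc_poly$r2,
                              coefs = list(x$arc_poly$coef)))
  for (nm in names(x$A_polys))
    rows[[length(rows) + 1]] <-
      tibble::tibble(stage = "height", term = paste0(nm, "(S)"),
                     degree = length(x$A_polys[[nm]]$coef) - 1,
                     r2 = x$A_polys[[nm]]$r2,
                     coefs = list(x$A_polys[[nm]]$coef))
  for (nm in names(x$B_polys))
    rows[[length(rows) + 1]] <-
      tibble::tibble(stage = "shift", term = paste0(nm, "(z)"),
                     degree = length(x$B_polys[[nm]]$coef) - 1,
                     r2 = x$B_polys[[nm]]$r2,
                     coefs = list(x$B_polys[[nm]]$coef))
  dplyr::bind_rows(rows)
}

#' @describeIn calibrate_trajectory One-row calibration summary.
#' @export
glance.ffl_calibration <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    S_min = x$S_range[1], S_max = x$S_range[2],
    O_min = x$O_range[1], O_max = x$O_range[2],
    z_min = x$z_range[1], z_max = x$z_range[2],
    min_r2 = min(x$arc_poly$r2,
                 vapply(x$A_polys, `[[`, numeric(1), "r2"),
                 vapply(x$B_polys, `[[`, numeric(1), "r2"))
  )
}

#' Save / load a trajectory calibration as JSON
#'
#' @param cal An `ffl_calibration`.
#' @param path File path.
#' @export
write_calibration <- function(cal, path) {
  doc <- list(
    arc_poly = cal$arc_poly,
    A_polys = cal$A_polys, B_polys = cal$B_polys,
    S_range = cal$S_range, O_range = cal$O_range, z_range = cal$z_range
  )
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_poly <- function(p) list(coef = as.numeric(p$coef),
                               r2 = as.numeric(p$r2),
                               range = as.numeric(p$range))
  structure(list(
    arc_poly = fix_poly(doc$arc_poly),
    A_polys = lapply(doc$A_polys, fix_poly),
    B_polys = lapply(doc$B_polys, fix_poly),
    samples = tibble::tibble(), A_table = NULL, B_table = NULL,
    S_range = as.numeric(doc$S_range),
    O_range = as.numeric(doc$O_range),
    z_range = as.numeric(doc$z_range)
  ), class = "ffl_calibration")
}
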