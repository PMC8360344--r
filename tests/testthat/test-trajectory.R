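# FFL localisation and trajectory-correction calibration.

test_that("shift and offset parameters follow their defining ratios", {
  expect_equal(shift_param(77, 77), 0)
  expect_equal(shift_param(77, 0), 1)
  # I1 = I0(1+a), I2 = I0(1-a)  =>  S = a
  a <- 0.37
  expect_equal(shift_param(77 * (1 + a), 77 * (1 - a)), a)
  expect_equal(offset_param(15.4, 77, 77), 0.1)
  expect_error(shift_param(1, -1), "nonzero")
})

test_that("FFL localisation finds the null with mirror symmetry and converged refinement", {
  geom <- test_geometry()
  l0 <- locate_ffl(geom, 80, 80)
  expect_lt(abs(l0$x), 1e-5)
  expect_lt(l0$residual, 1e-4 * l0$edge_field)
  # x increases with S
  lp <- locate_ffl(geom, 80 * 1.3, 80 * 0.7)
  expect_gt(lp$x, 0.005)
  # warm-started refinement agrees with the cold search to < 0.01 mm
  lw <- fflmpi:::locate_ffl_SO(geom, 0.3, 0, c(-0.033, 0.033),
                               c(0.003, 0.04),
                               init = c(lp$x, lp$z))
  lc <- fflmpi:::locate_ffl_SO(geom, 0.3, 0, c(-0.033, 0.033),
                               c(0.003, 0.04))
  expect_lt(abs(lw$x - lc$x), 1e-5)
  expect_lt(abs(lw$z - lc$z), 1e-5)
  # no null outside the region
  expect_error(locate_ffl(geom, 77, 77, xlim = c(0.02, 0.03),
                          zlim = c(0.025, 0.035)),
               "minimum")
})

test_that("calibration stages fit their samples and expose the documented structure", {
  cal <- test_calibration()
  td <- tidy(cal)
  expect_true(all(td$r2 >= 0.98))           # coefficient regressions
  expect_gte(min(cal$A_table$r2), 0.99)     # per-S quadratics
  expect_gte(min(cal$B_table$r2), 0.99)     # per-z cubics
  expect_gte(cal$arc_poly$r2, 0.99)

  # end-to-end: the stored fits reproduce >= 99% of the variance of the
  # located-null calibration samples
  s <- cal$samples
  zhat <- fflmpi:::poly_eval(cal$A_polys$A2, s$S) * s$O^2 +
    fflmpi:::poly_eval(cal$A_polys$A1, s$S) * s$O +
    fflmpi:::poly_eval(cal$A_polys$A0, s$S)
  r2_z <- 1 - sum((s$z - zhat)^2) / sum((s$z - mean(s$z))^2)
  expect_gte(r2_z, 0.99)
  sb <- dplyr::filter(s, abs(.data$x) <= 0.021,
                      .data$z >= cal$z_range[1],
                      .data$z <= cal$z_range[2])
  B <- lapply(cal$B_polys, function(p) fflmpi:::poly_eval(p, sb$z))
  xhat <- B$B0 + B$B1 * sb$S + B$B2 * sb$S^2 + B$B3 * sb$S^3
  r2_x <- 1 - sum((sb$x - xhat)^2) / sum((sb$x - mean(sb$x))^2)
  expect_gte(r2_x, 0.99)

  # A0(S) reproduces the drive-free arc z(S)
  S <- seq(-0.5, 0.5, by = 0.1)
  a0 <- fflmpi:::poly_eval(cal$A_polys$A0, S)
  arc <- fflmpi:::poly_eval(cal$arc_poly, S)
  expect_lt(max(abs(a0 - arc)), 5e-4)

  # at O = 0 (the natural height), x(S) is essentially linear
  z0 <- fflmpi:::poly_eval(cal$arc_poly, 0)
  B <- vapply(cal$B_polys, fflmpi:::poly_eval, numeric(1), x = z0)
  Sref <- 0.3
  expect_lt(abs(B[["B2"]] * Sref^2) + abs(B[["B3"]] * Sref^3),
            0.15 * abs(B[["B1"]] * Sref))

  # quadratic height-model residuals < 0.1 mm over the O range
  res <- cal$samples |>
    dplyr::group_by(S) |>
    dplyr::group_modify(function(d, k) {
      fit <- lm(z ~ O + I(O^2), data = d)
      tibble::tibble(maxres = max(abs(residuals(fit))))
    })
  expect_lt(max(res$maxres), 1e-4)
})

test_that("height and shift solvers invert the calibration (closed loop)", {
  geom <- test_geometry()
  cal <- test_calibration()
  # z = A0(S)  =>  I_drive = 0
  S <- 0.2
  zA0 <- fflmpi:::poly_eval(cal$A_polys$A0, S)
  Id <- solve_drive_current(cal, zA0, 77 * 1.2, 77 * 0.8)
  expect_lt(abs(Id), 0.05 * 2 * 77)
  # commanded heights are realized within 0.2 mm
  for (z in c(0.010, 0.014, 0.020)) {
    Id <- solve_drive_current(cal, z, 77, 77)
    l <- locate_ffl(geom, 77, 77, Id, xlim = c(-0.033, 0.033),
                    zlim = c(0.003, 0.040))
    expect_lt(abs(l$z - z), 2e-4)
  }
  # unreachable height errors out
  expect_error(solve_drive_current(cal, 0.3, 77, 77), "unreachable")

  # solve_shift: cubic root against bisection on the same polynomial
  zt <- 0.015
  B <- vapply(cal$B_polys, fflmpi:::poly_eval, numeric(1), x = zt)
  fx <- function(S) B[["B0"]] + B[["B1"]] * S + B[["B2"]] * S^2 +
    B[["B3"]] * S^3
  for (xt in c(-0.008, 0, 0.006)) {
    S1 <- solve_shift(cal, xt, zt)
    S2 <- uniroot(function(S) fx(S) - xt, c(-0.9, 0.9),
                  tol = 1e-12)$root
    expect_lt(abs(S1 - S2), 1e-8)
  }
  expect_error(solve_shift(cal, 0.2, 0.015), "unreachable")
})

test_that("commanded scans hold the slice height flat across the FOV", {
  geom <- test_geometry()
  cal <- test_calibration()
  # 40 mm span at z = 10 mm: corrected height within 0.5 mm
  xs <- seq(-0.02, 0.02, by = 0.005)
  pos <- vapply(xs, function(x) {
    cs <- currents_for_position(cal, x, 0.010, 77)
    l <- locate_ffl(geom, cs$I1, cs$I2, cs$I_drive_offset,
                    xlim = c(-0.033, 0.033), zlim = c(0.003, 0.040))
    c(l$x, l$z)
  }, numeric(2))
  expect_lt(max(abs(pos[2, ] - 0.010)), 5e-4)
  expect_lt(max(abs(pos[1, ] - xs)), 5e-4)

  # uncorrected arc spread exceeds the corrected spread by >= 5x
  arc_z <- vapply(xs, function(x) {
    S <- solve_shift(cal, x, 0.010)
    l <- locate_ffl(geom, 77 * (1 + S), 77 * (1 - S), 0,
                    xlim = c(-0.033, 0.033), zlim = c(0.003, 0.040))
    l$z
  }, numeric(1))
  corrected_spread <- diff(range(pos[2, ]))
  expect_gt(diff(range(arc_z)), 5 * corrected_spread)

  # x_FFL(S) strictly increasing over the calibrated range
  S <- seq(cal$S_range[1], cal$S_range[2], length.out = 41)
  zt <- 0.015
  B <- vapply(cal$B_polys, fflmpi:::poly_eval, numeric(1), x = zt)
  xS <- B[["B0"]] + B[["B1"]] * S + B[["B2"]] * S^2 + B[["B3"]] * S^3
  expect_true(all(diff(xS) > 0))
})

test_that("exact FFL placement converges and agrees with the calibration", {
  geom <- test_geometry()
  p <- place_ffl(geom, 0.008, 0.012)
  expect_lt(abs(p$x - 0.008), 1e-5)
  expect_lt(abs(p$z - 0.012), 1e-5)
  cal <- test_calibration()
  cs <- currents_for_position(cal, 0.008, 0.012, 77)
  expect_lt(abs(cs$S - p$S), 0.02)
})

test_that("calibration JSON round trip preserves the solvers", {
  cal <- test_calibration()
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  cal2 <- read_calibration(f)
  expect_equal(solve_shift(cal2, 0.007, 0.015),
               solve_shift(cal, 0.007, 0.015), tolerance = 1e-12)
  expect_equal(solve_drive_current(cal2, 0.012, 80, 74),
               solve_drive_current(cal, 0.012, 80, 74),
               tolerance = 1e-12)
  unlink(f)
})
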