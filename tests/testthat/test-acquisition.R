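# Stepped-scan acquisition: rotation, projections, sinograms, noise.

test_that("phantom rotation is exact at identity, composes, and conserves mass", {
  ph <- two_dot_phantom(5e-3)
  expect_identical(rotate_phantom(ph, 0)$values, ph$values)
  expect_identical(rotate_phantom(ph, 360)$values, ph$values)
  # four 90-degree steps return the original within interpolation error
  # (exact on the symmetric pixel-centre grid)
  r <- ph
  for (k in 1:4) r <- rotate_phantom(r, 90)
  expect_lt(sum(abs(r$values - ph$values)) / sum(ph$values), 0.02)
  # mass conserved within 1% for support resolved by several pixels
  disc <- disc_phantom(3e-3, fov = 0.02)
  r37 <- rotate_phantom(disc, 37)
  expect_lt(abs(sum(r37$values) / sum(disc$values) - 1), 0.01)
  # pixel-scale dots are edge-dominated: conservation within ~2.5%
  d37 <- rotate_phantom(ph, 37)
  expect_lt(abs(sum(d37$values) / sum(ph$values) - 1), 0.025)
  # centred circularly symmetric phantom invariant under any angle
  # (L1 difference is concentrated in the one-pixel edge ring of the
  # binary disc, ~4% of its mass)
  rd <- rotate_phantom(disc, 53)
  expect_lt(sum(abs(rd$values - disc$values)) / sum(disc$values), 0.06)
  expect_lt(max(abs(rd$values - disc$values)[abs(outer(
    disc$x, disc$y, function(a, b) sqrt(a^2 + b^2)) - 3e-3) > 5e-4]),
    0.02 * max(disc$values))
})

test_that("scan axes span the protocol ranges with the documented conventions", {
  prot <- scan_protocol(fov = 0.02, n_shifts = 81, n_rotations = 54)
  ax <- scan_axes(prot)
  expect_equal(range(ax$shifts), c(-0.01, 0.01))
  expect_length(ax$shifts, 81)
  expect_equal(ax$angles[1], 0)
  expect_equal(ax$angles[54], 180 - 180 / 54)   # endpoint excluded
  expect_error(scan_protocol(n_shifts = 1), "n_shifts")
  expect_error(scan_protocol(samples_per_period = 8), "samples")
})

test_that("projections vanish for empty phantoms and peak where the tracer sits", {
  geom <- test_geometry()
  cal <- test_calibration()
  prot <- scan_protocol(fov = 0.016, n_shifts = 17, n_rotations = 4,
                        slice_height = 0.012, I0 = 100)
  empty <- mpi_phantom(matrix(0, 64, 64), 0.25e-3)
  expect_equal(acquire_projection(empty, geom, prot, cal),
               rep(0, 17))
  # centred circular dot: peak at the centre shift for every angle
  dot <- disc_phantom(1.5e-3, fov = 0.016)
  sino <- acquire_sinogram(dot, geom, prot, cal)
  expect_equal(dim(sino$values), c(4, 17))
  for (k in 1:4)
    expect_equal(which.max(sino$values[k, ]), 9)
  # rotational invariance: rows equal within 1% for the centred disc
  rng <- apply(sino$values, 2, function(c) diff(range(c)))
  expect_lt(max(rng) / max(sino$values), 0.01)
})

test_that("two dots 7 mm apart give two resolved projection peaks 7 mm apart", {
  geom <- test_geometry()
  cal <- test_calibration()
  ph <- two_dot_phantom(7e-3, fov = 0.02)
  prot <- scan_protocol(fov = 0.02, n_shifts = 41, n_rotations = 1,
                        slice_height = 0.010,
                        I0 = i0_for_gradient(geom, cal, 0.010, 2.08))
  pr <- acquire_projection(ph, geom, prot, cal)
  sh <- scan_axes(prot)$shifts
  left <- which(sh < 0); right <- which(sh > 0)
  i1 <- left[which.max(pr[left])]
  i2 <- right[which.max(pr[right])]
  expect_equal(sh[i2] - sh[i1], 7e-3, tolerance = 0.15)
  # a valley separates the peaks
  expect_lt(min(pr[i1:i2]), 0.95 * min(pr[i1], pr[i2]))
})

test_that("the sinogram is linear in tracer concentration", {
  geom <- test_geometry()
  cal <- test_calibration()
  prot <- scan_protocol(fov = 0.012, n_shifts = 9, n_rotations = 2,
                        slice_height = 0.014, I0 = 100)
  ph1 <- two_dot_phantom(4e-3, concentration = 5, fov = 0.012)
  ph2 <- two_dot_phantom(4e-3, concentration = 10, fov = 0.012)
  s1 <- acquire_sinogram(ph1, geom, prot, cal)
  s2 <- acquire_sinogram(ph2, geom, prot, cal)
  expect_equal(s2$values, 2 * s1$values, tolerance = 1e-10)
})

test_that("off-centre dot traces a sinusoid across angles", {
  geom <- test_geometry()
  cal <- test_calibration()
  prot <- scan_protocol(fov = 0.02, n_shifts = 41, n_rotations = 8,
                        slice_height = 0.012, I0 = 100)
  v <- matrix(0, 80, 80)
  ph0 <- mpi_phantom(v, 0.25e-3)
  ix <- which(abs(ph0$x - 0.004) < 5e-4)
  iy <- which(abs(ph0$y) < 5e-4)
  v[ix, iy] <- 5
  ph <- mpi_phantom(v, 0.25e-3)
  sino <- acquire_sinogram(ph, geom, prot, cal)
  sh <- scan_axes(prot)$shifts
  peaks <- sh[apply(sino$values, 1, which.max)]
  pred <- 0.004 * cos(sino$angles * pi / 180)
  expect_lt(max(abs(peaks - pred)), 2 * (sh[2] - sh[1]))
})

test_that("noise injection follows the amplitude-dB convention deterministically", {
  sino <- mpi_sinogram(matrix(runif(54 * 81), 54, 81),
                       (0:53) * 180 / 54,
                       seq(-0.01, 0.01, length.out = 81))
  n1 <- add_noise(sino, -20, seed = 5)
  n2 <- add_noise(sino, -20, seed = 5)
  expect_identical(n1$values, n2$values)
  n3 <- add_noise(sino, -20, seed = 6)
  expect_false(identical(n1$values, n3$values))
  # sample std ~ max * 10^(dB/20) within 5% at 54 x 81 samples
  resid <- n1$values - sino$values
  expect_equal(sd(as.vector(resid)), max(sino$values) * 0.1,
               tolerance = 0.05)
  expect_identical(add_noise(sino, -Inf)$values, sino$values)
  expect_error(add_noise(sino, 3), "level_db")
  # caller RNG state untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_noise(sino, -20, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("sinogram CSV round trip preserves values and axes", {
  sino <- mpi_sinogram(matrix(rnorm(12), 3, 4), c(0, 60, 120),
                       seq(-0.01, 0.01, length.out = 4))
  f <- tempfile(fileext = ".csv")
  write_sinogram(sino, f)
  s2 <- read_sinogram(f)
  expect_equal(s2$values, sino$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s2$angles, sino$angles)
  expect_equal(s2$shifts, sino$shifts, tolerance = 1e-12)
  unlink(f)
})
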