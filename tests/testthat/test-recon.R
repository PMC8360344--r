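# Filtered backprojection: filters, frequency filtering, backprojection.

test_that("filter responses have the documented window structure", {
  ns <- 81; ds <- 0.25e-3
  flts <- lapply(c("ram-lak", "shepp-logan", "cosine", "hann"),
                 recon_filter, n_samples = ns, spacing = ds)
  names(flts) <- c("ram-lak", "shepp-logan", "cosine", "hann")
  for (f in flts) {
    expect_identical(f$H[1], 0)                    # H(0) = 0
    expect_equal(f$H, f$H * 1)                     # real
    # even in f: response at +f equals response at -f
    np <- f$n_pad
    expect_equal(f$H[2:(np / 2)], rev(f$H[(np / 2 + 2):np]),
                 tolerance = 1e-9)
  }
  # window endpoints at the shift-axis Nyquist
  iN <- which.max(abs(flts$`ram-lak`$freq))
  expect_lt(flts$hann$H[iN], 1e-6 * max(flts$`ram-lak`$H))
  expect_equal(max(flts$`ram-lak`$H), flts$`ram-lak`$H[iN],
               tolerance = 1e-6)
  # pointwise ordering shepp-logan >= cosine >= hann on (0, f_N)
  inner <- which(flts$hann$freq > 0)
  expect_true(all(flts$`shepp-logan`$H[inner] >=
                    flts$cosine$H[inner] - 1e-12))
  expect_true(all(flts$cosine$H[inner] >= flts$hann$H[inner] - 1e-12))
  # apodized responses stay below the pure ramp
  for (nm in c("shepp-logan", "cosine", "hann"))
    expect_true(all(flts[[nm]]$H[inner] <=
                      flts$`ram-lak`$H[inner] + 1e-12))
})

test_that("frequency filtering removes DC, is symmetric, and matches direct convolution", {
  ns <- 64; ds <- 0.5e-3
  shifts <- (seq_len(ns) - (ns + 1) / 2) * ds
  angles <- 0
  zero <- mpi_sinogram(matrix(0, 1, ns), angles, shifts)
  expect_equal(filter_projections(zero, "hann")$values,
               matrix(0, 1, ns))
  # constant row -> near-zero interior (DC removed; the zero-padded row
  # is a box, so only its edges respond to the ramp)
  const <- mpi_sinogram(matrix(3, 1, ns), angles, shifts)
  fc <- filter_projections(const, "ram-lak")
  interior <- fc$values[1, (ns / 4):(3 * ns / 4)]
  peak_response <- 3 / (4 * ds)   # impulse peak for this amplitude
  expect_lt(max(abs(interior)), 0.02 * peak_response)
  # symmetric row stays symmetric
  sym <- mpi_sinogram(matrix(disc_radon(shifts, 0.004), 1), angles,
                      shifts)
  fs <- filter_projections(sym, "hann")$values[1, ]
  expect_equal(fs, rev(fs), tolerance = 1e-9)

  # impulse row reproduces the (DC-corrected) band-limited ramp kernel:
  # compare frequency-space path against direct spatial convolution
  np <- recon_filter("ram-lak", ns, ds)$n_pad
  kern <- function(j) ifelse(j == 0, 1 / (4 * ds^2),
                             ifelse(j %% 2 != 0,
                                    -1 / (pi * j * ds)^2, 0))
  jfull <- c(0:(np / 2), -(np / 2 - 1):-1)
  kmean <- sum(kern(jfull)) / np
  imp <- matrix(0, 1, ns); imp[1, 20] <- 1
  fi <- filter_projections(mpi_sinogram(imp, angles, shifts),
                           "ram-lak")$values[1, ]
  h <- kern(seq_len(ns) - 20) - kmean
  expect_equal(fi, h * ds, tolerance = 1e-6)

  # convolution oracle on a full disc sinogram
  sino <- disc_sinogram(0.004, n_shifts = ns, n_rotations = 3,
                        fov = diff(range(shifts)) + ds)
  sino$shifts <- shifts
  ff <- filter_projections(sino, "ram-lak")$values[2, ]
  direct <- vapply(seq_len(ns), function(i)
    sum(sino$values[2, ] * (kern(i - seq_len(ns)) - kmean)) * ds,
    numeric(1))
  expect_equal(ff, direct, tolerance = 1e-6 * max(abs(direct)))
})

test_that("backprojection smears single projections and recovers the analytic disc", {
  sino <- disc_sinogram(0.005)
  expect_equal(backproject(mpi_sinogram(
    matrix(0, 54, 81), sino$angles, sino$shifts), 41)$values,
    matrix(0, 41, 41))
  # one angle: image constant along that angle's line direction (y at 0 deg)
  one <- mpi_sinogram(sino$values[1, , drop = FALSE], 0, sino$shifts)
  img1 <- backproject(filter_projections(one, "hann"), 41)
  expect_lt(max(abs(sweep(img1$values, 1, img1$values[, 21]))),
            1e-9 * max(abs(img1$values)))

  # analytic Radon disc: reconstruction correlates > 0.95 with truth
  img <- fbp(sino, "hann", grid_n = 81)
  truth <- disc_phantom(0.005, fov = 0.02,
                        pixel_size = 0.25e-3)$values
  # evaluate truth on the image grid (81 pts incl endpoints vs centres):
  gx <- rep(img$x, times = 81); gy <- rep(img$y, each = 81)
  tr <- as.numeric(gx^2 + gy^2 <= 0.005^2)
  expect_gt(cor(as.vector(img$values), tr), 0.95)
})

test_that("the FBP pipeline is linear and localizes an off-centre dot", {
  s1 <- disc_sinogram(0.004)
  s2 <- disc_sinogram(0.002)
  s2$values <- 0.7 * s2$values
  both <- mpi_sinogram(s1$values + s2$values, s1$angles, s1$shifts)
  i1 <- fbp(s1, "cosine", 61)
  i2 <- fbp(s2, "cosine", 61)
  ib <- fbp(both, "cosine", 61)
  expect_equal(ib$values, i1$values + i2$values,
               tolerance = 1e-10 * max(abs(ib$values)))

  # dot at a known off-centre position: sinogram from the analytic
  # Radon geometry s = x0 cos(theta) + y0 sin(theta)
  x0 <- 0.004; y0 <- -0.003
  shifts <- seq(-0.01, 0.01, length.out = 81)
  angles <- (0:53) * 180 / 54
  vals <- t(vapply(angles, function(th) {
    s0 <- x0 * cos(th * pi / 180) + y0 * sin(th * pi / 180)
    dnorm(shifts, mean = s0, sd = 4e-4)
  }, numeric(81)))
  img <- fbp(mpi_sinogram(vals, angles, shifts), "hann", 81)
  pk <- which(img$values == max(img$values), arr.ind = TRUE)
  px <- img$x[2] - img$x[1]
  expect_lt(abs(img$x[pk[1]] - x0), px + 1e-9)
  expect_lt(abs(img$y[pk[2]] - y0), px + 1e-9)
})

test_that("off-centre dot sinogram peak traces a sinusoid in angle", {
  x0 <- 0.004; y0 <- -0.003
  shifts <- seq(-0.01, 0.01, length.out = 161)
  angles <- (0:35) * 5
  vals <- t(vapply(angles, function(th) {
    s0 <- x0 * cos(th * pi / 180) + y0 * sin(th * pi / 180)
    dnorm(shifts, mean = s0, sd = 4e-4)
  }, numeric(161)))
  peaks <- shifts[apply(vals, 1, which.max)]
  pred <- x0 * cos(angles * pi / 180) + y0 * sin(angles * pi / 180)
  expect_lt(max(abs(peaks - pred)), shifts[2] - shifts[1] + 1e-9)
})
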