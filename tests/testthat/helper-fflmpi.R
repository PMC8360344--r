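# Shared fixtures, memoized across test files.  The scanner geometry
# and the trajectory calibration are expensive; they are computed once
# per test run.

.fixtures <- new.env(parent = emptyenv())

test_geometry <- function() {
  if (is.null(.fixtures$geom))
    .fixtures$geom <- scanner_geometry()
  .fixtures$geom
}

# full-fidelity calibration shared by the trajectory, acquisition and
# acceptance tests (the study conditions)
test_calibration <- function() {
  if (is.null(.fixtures$cal))
    .fixtures$cal <- calibrate_trajectory(test_geometry())
  .fixtures$cal
}

# memoized study-condition sinograms used by several acceptance checks
test_sinogram <- function(key, fun) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fun()
  .fixtures[[key]]
}

# synthetic two-Gaussian-dot image for metric unit tests
gaussian_dots_image <- function(separation, sigma = 1e-3, fov = 0.02,
                                n = 101L, amplitude = 1) {
  ax <- seq(-fov / 2, fov / 2, length.out = n)
  gx <- rep(ax, times = n); gy <- rep(ax, each = n)
  v <- amplitude * (exp(-((gx - separation / 2)^2 + gy^2) /
                          (2 * sigma^2)) +
                    exp(-((gx + separation / 2)^2 + gy^2) /
                          (2 * sigma^2)))
  mpi_image(matrix(v, n, n), ax, ax)
}

# ideal parallel-beam sinogram of a centred disc from the closed-form
# Radon transform
disc_sinogram <- function(radius, n_shifts = 81L, n_rotations = 54L,
                          fov = 0.02, concentration = 5) {
  shifts <- seq(-fov / 2, fov / 2, length.out = n_shifts)
  angles <- (seq_len(n_rotations) - 1) * 180 / n_rotations
  row <- disc_radon(shifts, radius, concentration)
  mpi_sinogram(matrix(row, n_rotations, n_shifts, byrow = TRUE),
               angles, shifts)
}
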