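# SPION magnetization (adiabatic Langevin model) and induced-voltage
# signal synthesis.

#' Langevin function
#'
#' `L(xi) = coth(xi) - 1/xi`, the equilibrium magnetization law of an
#' ideal superparamagnetic particle.  For `|xi| < 1e-4` the series
#' `xi/3 - xi^3/45` is used to avoid catastrophic cancellation.  Odd,
#' monotone, bounded by 1 in magnitude.
#'
#' @param xi Dimensionless field argument `beta |B|` (any finite value).
#' @return `L(xi)`, same shape as `xi`.
#' @export
langevin <- function(xi) {
  out <- xi
  small <- abs(xi) < 1e-4
  xs <- xi[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Magnetic moment of a single particle core
#'
#' `m = M_sat * (pi/6) d_c^3`: saturation moment of a spherical core of
#' diameter `d_c` and bulk saturation magnetization `M_sat`.
#'
#' @param d_c Core diameter (m).
#' @param M_sat_core Core-material saturation magnetization (A/m).
#' @return Moment (A m^2).
#' @export
moment_from_core <- function(d_c, M_sat_core) {
  M_sat_core * pi / 6 * d_c^3
}

#' Tracer particle model
#'
#' Parameters of the superparamagnetic iron oxide tracer: core size,
#' core saturation magnetization, material density (to convert a mass
#' concentration into a moment density), and temperature.  `beta =
#' m/(kB T)` sets the field scale of the Langevin nonlinearity.
#'
#' @param core_diameter Core diameter (m); default 25 nm.
#' @param M_sat_core Core saturation magnetization (A/m); default
#'   474 kA/m (magnetite).
#' @param density Core material density (kg/m^3); default 5170
#'   (magnetite).
#' @param temperature Particle temperature (K).
#' @return A list of class `particle_model` with fields `m` (A m^2)
#'   and `beta` (1/T) derived.
#' @export
particle_model <- function(core_diameter = 25e-9, M_sat_core = 474e3,
                           density = 5170, temperature = 300) {
  if (any(c(core_diameter, M_sat_core, density, temperature) <= 0))
    stop("particle_model: all parameters must be positive")
  m <- moment_from_core(core_diameter, M_sat_core)
  structure(list(core_diameter = core_diameter, M_sat_core = M_sat_core,
                 density = density, temperature = temperature,
                 m = m, beta = m / (KB * temperature)),
            class = "particle_model")
}

#' @export
print.particle_model <- function(x, ...) {
  cat("<particle_model> d_c = ", x$core_diameter * 1e9, " nm, m = ",
      signif(x$m, 4), " A m^2, beta = ", signif(x$beta, 4), " 1/T\n",
      sep = "")
  invisible(x)
}

#' Equilibrium magnetization of a phantom pixel
#'
#' `M = c_m m L(beta |B|) B/|B|` where `c_m` is the particle number
#' density implied by the mass concentration.  Returned as magnetic
#' moment per unit volume (A/m).  At `B = 0` the zero vector is
#' returned (`L(0) = 0`).
#'
#' @param concentration Mass concentration (mg/ml == kg/m^3).
#' @param B Total field, length-3 vector or n x 3 matrix (T).
#' @param particle A [particle_model()].
#' @return Magnetization vector(s), same shape as `B` (A/m).
#' @export
magnetization <- function(concentration, B, particle) {
  B <- if (is.matrix(B)) B else matrix(B, ncol = 3)
  Bm <- sqrt(rowSums(B^2))
  # moment density at saturation: volume fraction x core magnetization
  Msat <- concentration / particle$density * particle$M_sat_core
  scale <- ifelse(Bm > 0,
                  Msat * langevin(particle$beta * Bm) / Bm, 0)
  B * scale
}

#' Induced receive-coil voltage from a magnetization time series
#'
#' Faraday-law signal `v(t) = sum_pixels dM/dt . B_Rx * V_pixel`,
#' with the time derivative taken by central differences with periodic
#' wrap-around (the series must cover an integer number of drive
#' cycles).
#'
#' @param M_t List of n_pix x 3 magnetization matrices (A/m), one per
#'   time sample, or a 3-d array n_pix x 3 x n_t.
#' @param B_rx n_pix x 3 receive sensitivity (T/A).
#' @param dt Time step (s).
#' @param pixel_volume Volume represented by each pixel (m^3).
#' @return Sampled voltage (V), length n_t.
#' @export
induced_voltage <- function(M_t, B_rx, dt, pixel_volume) {
  if (is.list(M_t)) {
    nt <- length(M_t)
    flux <- vapply(M_t, function(M) sum(M * B_rx) * pixel_volume,
                   numeric(1))
  } else {
    nt <- dim(M_t)[3]
    flux <- vapply(seq_len(nt), function(k)
      sum(M_t[, , k] * B_rx) * pixel_volume, numeric(1))
  }
  if (nt < 16) stop("induced_voltage: need >= 16 time samples per period")
  ip <- c(2:nt, 1); im <- c(nt, 1:(nt - 1))
  (flux[ip] - flux[im]) / (2 * dt)
}

#' Harmonic amplitude of a sampled periodic signal
#'
#' Discrete Fourier magnitude at `n` times the drive frequency,
#' normalized so a pure sinusoid of amplitude `a` returns `a`.  The
#' samples must cover an integer number `cycles` of drive periods.
#'
#' @param v Sampled signal.
#' @param n Harmonic index (1 = fundamental).
#' @param cycles Number of drive cycles covered by `v`.
#' @return Harmonic magnitude (same units as `v`).
#' @export
harmonic_amplitude <- function(v, n, cycles = 1L) {
  N <- length(v)
  if (N %% cycles != 0)
    stop("harmonic_amplitude: sample count is not an integer multiple ",
         "of the cycle count")
  bin <- n * cycles
  if (bin >= N / 2)
    stop("harmonic_amplitude: harmonic ", n, " above Nyquist")
  sp <- fft(v)
  2 * Mod(sp[bin + 1]) / N
}
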