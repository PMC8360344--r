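# fflmpi

Forward simulation and filtered-backprojection image reconstruction for
a **single-sided field-free-line (FFL) magnetic particle imaging (MPI)
scanner**, in R.

Magnetic particle imaging maps the concentration of superparamagnetic
iron oxide nanoparticle (SPION) tracers through the harmonics their
nonlinear magnetization induces in a receive coil.  In the single-sided
FFL topology simulated here, two racetrack electromagnets generate a
static selection field that vanishes on a line parallel to the y-axis;
only tracer near that line responds to the 25 kHz drive field, so each
line position contributes one projection sample.  Stepping the line
along x (electronically, via the selection-current imbalance) and
rotating the sample platform (mechanically, 0–180°) yields a sinogram
that filtered backprojection inverts into a 2D concentration image.
The package is aimed at scanner designers and reconstruction
researchers who want a transparent, fully scripted model of this
acquisition chain.

## What is modelled

* **Coil fields** — Biot–Savart over filament segments (Rcpp core) for
  the two 26-turn racetrack selection coils, the planar drive coil and
  the planar receive coil; selection currents
  `I1 = I0(1+S)`, `I2 = I0(1−S)` with shift parameter
  `S = (I1−I2)/(I1+I2)` and drive-bias offset parameter
  `O = I_drive/(I1+I2)`.
* **Trajectory correction** — the FFL naturally travels on an arc as S
  varies; a three-stage polynomial calibration (degree-6 arc,
  quadratic-in-O height model `z = A2·O² + A1·O + A0`, cubic-in-S shift
  model `x = B3·S³ + B2·S² + B1·S + B0`, coefficients regressed on S
  and z) flattens scans to < 0.1 mm height error across a 40 mm span.
* **Tracer signal** — adiabatic Langevin magnetization
  `M = (c/ρ) M_sat L(β|B|) B/|B|` with `L(ξ) = coth ξ − 1/ξ`
  (25 nm magnetite cores, β = 936 T⁻¹), Faraday induction against the
  receive-coil sensitivity map, and third-harmonic detection.
* **Reconstruction** — frequency-space ramp filtering (band-limited
  kernel; ram-lak / shepp-logan / cosine / hann windows), zero-padded,
  followed by interpolating backprojection; contrast
  `C = (I_max − I_min)/(I_max + I_min)` and peak/background-σ SNR
  metrics; two-dot, disc, and block-letter phantom generators.

## A worked example

```r
library(fflmpi)

geom <- scanner_geometry()
geom
#> <scanner_geometry>
#>   selection coils: 2 x 26 turns, 24.5 cm x 54 mm, gap 11 mm
#>   drive coil: 20 turns, r = 25 mm at z = -22.3 mm
#>   receive coil: 10 turns, r = 15 mm at z = 0

loc <- locate_ffl(geom, I1 = 77, I2 = 77)
sprintf("FFL at x = %.2f mm, z = %.2f mm", loc$x * 1e3, loc$z * 1e3)
#> "FFL at x = 0.00 mm, z = 16.20 mm"
transverse_gradient(geom, loc$x, loc$z, 77, 77)
#> [1] 0.5373  # T/m

# exact current parameters placing the line at (5, 12) mm
place_ffl(geom, x_target = 0.005, z_target = 0.012)[c("S", "O")]
#> $S [1] 0.202    $O [1] 0.280
```

With equal 77 A currents the field null sits 16.2 mm above the scanner
surface with a 0.54 T/m transverse gradient; commanding the line to
(5 mm, 12 mm) requires a 20% current imbalance plus a drive-coil bias
of 0.28 × (I1+I2).

An end-to-end imaging study (calibration ≈ 1 min, each 54-angle ×
81-shift sinogram ≈ 15 s):

```r
cal  <- calibrate_trajectory(geom)
I0   <- i0_for_gradient(geom, cal, z = 0.010, G_target = 2.08)
ph   <- two_dot_phantom(separation = 7e-3, fov = 0.02)
prot <- scan_protocol(fov = 0.02, slice_height = 0.010, I0 = I0)
sino <- acquire_sinogram(ph, geom, prot, cal)
img  <- fbp(sino, "hann", grid_n = 201)
dot_contrast(img, c(-3.5e-3, 0), c(3.5e-3, 0))
#> # A tibble: 1 × 4
#>       C    I_max     I_min resolved
#>   <dbl>    <dbl>     <dbl> <lgl>
#> 1 0.915 0.000476 0.0000211 TRUE
autoplot(img)
```

The 7 mm dot pair reconstructs with contrast 0.92 (clearly resolved);
`run_study(study_config("noise"))` chains the same pipeline over the
three filters and four noise levels and returns a metrics tibble, and
`tidy()/glance()` methods expose the calibration fits.

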