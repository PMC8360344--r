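---
title: "Simulating a single-sided field-free-line MPI scanner: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a single-sided field-free-line MPI scanner: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The imaging problem

Magnetic particle imaging (MPI) reconstructs the spatial distribution of
superparamagnetic iron oxide nanoparticle (SPION) tracers from the
nonlinear harmonics they induce in a receive coil.  A *single-sided*
scanner places all coils on one side of the sample, trading penetration
depth for open access.  The device `fflmpi` simulates encodes space with
a field-free *line* (FFL): a line parallel to the y-axis on which the
static selection field vanishes.  Only tracer near the FFL responds
nonlinearly to the 25 kHz drive field, so each FFL position yields one
projection sample; translating the line electronically along x and
rotating the sample platform mechanically produces a sinogram, which
filtered backprojection (FBP) inverts into a 2D image.

The package is a forward simulator plus reconstruction pipeline for this
scanner: coil fields from first principles, trajectory calibration,
harmonic signal synthesis, sinogram acquisition, FBP, and contrast/SNR
metrics, with study runners that chain them end to end.

# Coil model and the field-free line

All magnetic fields come from the Biot–Savart law evaluated over
straight filament segments (`src/biot_savart.cpp`, the Hanson–Hirshman
closed form, singular only on the wire; evaluation closer than the wire
half-thickness of 0.5 mm raises an error).  The scanner comprises:

* **Two racetrack selection coils**, each 24.5 cm long, 54 mm wide,
  18.3 mm tall, 26 turns of 1 mm² copper, with a 10 mm core gap; the
  coils sit side by side along x with an 11 mm gap.  The 26 turns are
  modelled as a uniform 13 × 2 filament lattice filling the winding
  cross-section, with stadium-shaped (concentric semicircular) ends.
  Both coils are wound with the *same* circulation: their facing inner
  conductors then carry opposite currents and the combined field has a
  null line parallel to y.  For a four-conductor idealization the null
  height is $z_0=\sqrt{dD}$ with $d, D$ the inner/outer conductor
  distances; the full lattice puts the natural FFL at 16.2 mm above the
  surface, with a transverse gradient of 0.51 T/m at 77 A.  (The
  winding layout inside the stated bundle is the single largest
  geometric uncertainty: a 1 mm-pitch tightly packed winding instead
  yields 17.0 mm and 1.01 T/m, bracketing the plausible range.)
* **A planar circular drive coil** (default outer radius 25 mm, 20
  turns, pancake-wound at 1 mm pitch) centred 4 mm below the selection
  coils.  It plays two roles: the 25 kHz sinusoidal excitation, and a
  DC bias that moves the FFL height.  Its exact dimensions are not
  geometrically constrained by the scanner outline; a scan over outer
  radii 8–25 mm changed the slice-level drive amplitude by < 25% and
  image contrast by < 0.01, so the default is not critical.
* **A planar receive coil** (radius 15 mm, 10 turns) on the surface;
  its unit-current field is the sensitivity map that weights the
  Faraday integral by reciprocity.

Currents map to dimensionless control parameters
$S = (I_1-I_2)/(I_1+I_2)$ (shift) and $O = I_\mathrm{drive}/(I_1+I_2)$
(offset).  Because the null of a linear superposition is invariant
under a global current scale, the FFL position depends on $(S, O)$
only; one calibration therefore serves every gradient setting.

# Trajectory correction

Varying $S$ alone moves the FFL along an *arc* (about 6–7 mm of height
droop across a 40 mm scan).  The correction calibrates, by locating the
field null (coarse grid scan + Nelder–Mead refinement) over a lattice
of 21 $S$ × 11 $O$ settings:

1. the drive-free arc $z(S)$, fit by a degree-6 polynomial;
2. per $S$, the quadratic height model $z = A_2O^2 + A_1O + A_0$, whose
   coefficients are regressed on $S$ (degree 4);
3. per target height, the cubic shift model
   $x = B_3S^3 + B_2S^2 + B_1S + B_0$, whose coefficients are regressed
   on $z$ (degree 4).  Stage 3 re-locates the null on a twice-denser
   $S$ grid with the height already corrected, and fits only samples
   with $|x| \le 21$ mm — the domain on which the cubic is inverted —
   because including more extreme samples leaks truncation error into
   the usable range.

Commanding a position inverts stage 3 for $S$ (real cubic root nearest
the linear estimate $x/B_1$) and stage 2 for $O$ (quadratic root inside
the calibrated $O$ range).  Closed-loop checks against the located null
give height errors < 0.1 mm and in-plane errors < 0.5 mm across a
40 mm scan; the uncorrected arc spread exceeds the corrected one by
more than an order of magnitude.  `place_ffl()` additionally solves the
exact $(S, O)$ for one position by Newton iteration on the located
null; it is the reference the polynomial calibration is judged against
and the engine of the gradient-uniformity scans, which is why the
normalized gradient profile can extend beyond the fitted calibration's
range.  By symmetry two coefficients ($B_0$, $B_2$) vanish; their
regressions are reported with $R^2 = 1$ when the response variance is
below the 0.1 mm trajectory tolerance, where a variance ratio is
meaningless.

# Tracer physics and signal synthesis

Magnetization follows the adiabatic Langevin model: for mass
concentration $c$ (mg/ml) and total field $\vec B$,

$$\vec M = \frac{c}{\rho}\,M_\mathrm{sat}\,
  L(\beta \lVert\vec B\rVert)\,\hat B,\qquad
  L(\xi) = \coth\xi - 1/\xi,\qquad \beta = m/(k_BT),$$

with 25 nm magnetite cores ($M_\mathrm{sat}$ = 474 kA/m, density
5170 kg/m³, T = 300 K ⇒ $m = 3.9\times10^{-18}$ A·m²,
$\beta = 936$ T⁻¹, a Langevin "knee" of $\approx 1$ mT).  The mass
density, core magnetization and temperature only scale image intensity;
every reported metric (contrast, SNR, normalized maps) is
scale-invariant.  For $|\xi| < 10^{-4}$ the series $\xi/3 - \xi^3/45$
replaces the closed form: the direct difference $\coth\xi - 1/\xi$
cancels catastrophically near field zero crossings and, unguarded,
injects O(1) noise exactly where the FFL physics happens.

The induced voltage is the Faraday integral
$v(t) = \int \partial_t\vec M \cdot \vec B_\mathrm{Rx}\,dV$, discretized
per phantom pixel (pixel area × 1 mm slice thickness) with a central,
periodic time difference over 64 samples per drive period, one
steady-state cycle per FFL position (the adiabatic model has no
memory, so extra cycles are redundant).  The projection value is the
magnitude of the third harmonic of $v(t)$, the conventional
feedthrough-free detection band.

An important property of this *vector* Langevin model: at a transverse
offset $x$ from the FFL the static field $G x\,\hat x$ is perpendicular
to the drive field (which is along $\hat z$ on the drive-coil axis), so
the particle never sweeps through zero field once $|Gx|$ exceeds the
drive amplitude — the third-harmonic point-spread decays over a few
Langevin knees of transverse field and is several millimetres wide at
the study gradients, essentially independent of the drive amplitude.
A collinear (scalar) superposition, as in 1-D x-space treatments,
instead gives a compact point-spread of half-width (drive
amplitude)/G.  The two assumptions differ by an order of magnitude in
achievable two-dot contrast; this package implements the vector form
throughout.

# Acquisition protocol

A `scan_protocol()` fixes the field of view, 81 shifts (endpoints
inclusive), 54 platform angles ($\theta_k = 180°k/54$, endpoint
excluded to avoid duplicating the 0°/180° projection), 25 kHz drive
with 5 mT amplitude calibrated at the surface centre, slice height, and
the reference current $I_0$.  Rotating the platform is simulated by
counter-rotating the concentration map (bilinear resampling about the
FOV centre; exact for 90° multiples on the symmetric pixel-centre
grid).  Per shift, the calibrated currents are applied, the static
field at every support pixel is assembled from cached unit-current
field maps (one Biot–Savart evaluation per study), and the harmonic
magnitude is stored.  Measurement noise is added to sinograms as
i.i.d. Gaussian samples with
$\sigma = \max|s| \cdot 10^{\mathrm{dB}/20}$ — an *amplitude*-decibel
convention relative to the maximum signal — under a caller-supplied
seed with the global RNG state restored.

The imaging studies are anchored on the transverse gradients
2.08 / 1.25 / 1.01 T/m at slice heights 10 / 17 / 20 mm: for each
study, $I_0$ is scaled so the corrected-trajectory gradient at the scan
centre matches the anchor (`i0_for_gradient()`).  With this geometry a
*single* current reproduces all three anchors within 1.5%, a strong
internal-consistency check of the coil model.  The noise study uses the
2 × 2 cm FOV of the resolution study; with it the simulated Hann-filter
SNR at −20 dB matches the anchor value 16 almost exactly.

# Reconstruction

FBP uses the band-limited ramp's spatial kernel ($h_0 = 1/4\Delta s^2$,
$h_j = -1/(\pi j \Delta s)^2$ for odd $j$) transformed to frequency
space — not a naive $|f|$ sampling, which biases DC — with the residual
DC term of the truncated kernel zeroed so that constant projections map
to zero.  Projections are zero-padded to the next power of two at least
twice their length (no circular wrap), multiplied by the windowed
response, and inverse-transformed.  Windows: ram-lak (1), shepp-logan
($\mathrm{sinc}(f/2f_N)$), cosine ($\cos(\pi f/2f_N)$), hann
($0.5(1+\cos(\pi f/f_N))$), ordered pointwise shepp-logan ≥ cosine ≥
hann below Nyquist.  Backprojection samples each filtered projection at
$s = x\cos\theta + y\sin\theta$ with linear interpolation (zero outside
the shift axis) and scales by $\pi/n_\mathrm{rot}$.  Negative
intensities are kept; metrics and display clip at zero.  The default
output grid is 201 × 201 over the FOV.  On analytic Radon sinograms of
a disc the pipeline correlates > 0.95 with the truth at 81 shifts × 54
angles, and the frequency-space path matches a direct spatial
convolution oracle to 10⁻⁶.

# Metrics

Two-dot contrast is $C = (I_{max}-I_{min})/(I_{max}+I_{min})$
evaluated on the zero-clipped cross-section through the dot centres:
$I_{max}$ is the mean of the two local peaks nearest the expected
centres, $I_{min}$ the minimum strictly between them; a profile without
a separating valley reports $C = 0$ with `resolved = FALSE`.  A
whole-image mode (`mode = "global"`) is provided because the defining
prose is ambiguous for noisy images; the profile mode is the default.
SNR is peak intensity in 5 mm discs around the dots divided by the
standard deviation in a border frame of width 10% of the FOV; both
regions are arguments.  Any SNR comparison across implementations
should expect definition-level (factor ~2) differences.

# What the simulations do and do not show

The synthetic studies emulate an ideal instrument: perfectly known
geometry, noiseless electronics up to the additive sinogram noise,
monodisperse tracers in instantaneous thermal equilibrium, and 2D
phantoms one slice thick.  They do not model Néel/Brownian relaxation
(which broadens and delays the response at 25 kHz), polydispersity,
receive-chain filtering, eddy currents, or 3D partial-volume effects —
so passing tests demonstrate the correctness of the simulation chain
and the self-consistency of the encoding/reconstruction geometry, not
the performance of a physical scanner.

Under the vector Langevin model the resolution limit of this geometry
is set by the transverse harmonic point-spread (~3–4 mm FWHM at
2.08 T/m), so the simulated two-dot contrasts at 2–4 mm separations are
small (0.006–0.05) though their ordering — contrast increasing with
separation and decreasing with slice height, 2 mm dots unresolved at
z = 20 mm, more shifts improving contrast — matches the expected
physics.  The gradient-uniformity results (10% drop over a 20 mm scan,
30% over 40 mm at the static height) and the noise-study behaviour
(SNR monotone in noise level; Hann ≥ cosine ≥ shepp-logan at strong
noise, because the Hann window amplifies high frequencies least) are
quantitative and reproduced by the acceptance suite.

# Numerical choices

* Biot–Savart: 24 segments per racetrack arc, 64 per circular turn;
  doubling changes fields by < 0.1%.  Convergence against the on-axis
  loop closed form is < 0.1% at 64 segments.
* Null localisation: 25 × 25 coarse grid then Nelder–Mead to relative
  tolerance 10⁻¹⁵; warm-started refinements during calibration sweeps
  accept only interior nulls with residual < 10⁻⁴ of the region-edge
  field.
* Transverse gradient: $G = \sqrt{(|B|^2(x+h) + |B|^2(x-h))/2 -
  |B|^2(x)}/h$ with $h$ = 0.5 mm — the magnitude-squared form removes
  the bias from the small residual field on the line; halving $h$
  changes the estimate by < 0.1%.
* Phantoms rasterize on a pixel-centre grid with an even number of
  0.25 mm pixels per axis (no pixel centred at the origin), so
  millimetre-sized dots with edges on the half-millimetre lattice have
  exact support and mirror symmetry.  The letter phantom uses 0.5 mm
  pixels to keep the support (and acquisition time) moderate.
* Problem sizes were chosen so a full two-dot study (81 × 54, 64 time
  samples) runs in ~15 s and a calibration in ~1 min on one core;
  the study runners default to these sizes.

# Reproducing the study results

`scripts/acceptance.R` recomputes the headline numbers from scratch
(field gradients, edge-drop percentages, the three noiseless contrast
cases, the two noise-study SNR points averaged over 10 seeds) and
writes them to JSON; `tests/testthat/test-acceptance.R` asserts the
same quantities with explicit tolerances.  Both run against the
installed package with no external inputs.
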