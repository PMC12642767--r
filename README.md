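# fflmpi

Model-based 3D image reconstruction for field-free-line (FFL) magnetic
particle imaging (MPI), with a physics-grounded forward operator, harmonic-
domain data compression, tomographic multi-angle coupling, a regularized
heavy-ball solver, and a seeded scan simulator so that the entire pipeline
is testable without scanner hardware.

## The problem

MPI detects superparamagnetic iron-oxide tracers through their nonlinear
(Langevin) magnetization. An FFL scanner nulls the field along a line,
sweeps that line through the field of view with a sinusoidal drive plus a
slow zig-zag raster, and records the induced coil voltage. Conventional
processing reconstructs each 2D projection independently and stitches them
with CT methods; reconstructing **all** angles jointly against one physical
model improves resolution, sensitivity and dynamic range, but is only
tractable if the operator and the data are compressed aggressively.

`fflmpi` implements that joint model:

- `M = Γ V E H B` — receive-sensitivity weighting, Langevin point-spread
  tensor convolution, trajectory sampling, velocity weighting, notch
  filtering; every factor a fast linear operator with an exact adjoint;
- `A_DC = S D_Γ F V E H B` — the compressed operator: one FFT and a
  selection of narrow bands around drive harmonics 2..K (default 0.5 kHz
  around harmonics 2–5, keeping <1% of the samples and ≥95% of the
  notch-filtered signal energy);
- `A = diag(A_DC) · [P_θ1; …; P_θM]` — sparse parallel-beam projectors
  coupling a 3D volume to per-angle 2D scans (two drive axes per angle);
- `min_x ‖Ax − b‖² + λ‖Tx‖²` — Tikhonov inversion by heavy-ball
  accelerated projected gradient descent with step
  `τ = (‖A*A‖(1+0.05) + λ‖T*T‖)⁻¹` and a real/nonnegative projection.

## Worked example

Simulate a three-point-source phantom (amplitudes 1 : 5 : 50 at voxels
(7,18,16), (17,12,8), (12,6,13)), scan it at 12 angles with two drive axes
at 30 dB SNR, and reconstruct:

```r
library(fflmpi)

st  <- default_study()                 # 24^3 volume, 12 angles, 45 kHz drive
rho <- make_phantom(phantom_spec("point_sources",
         positions = rbind(c(-0.825e-3,  0.825e-3,  0.525e-3),
                           c( 0.675e-3, -0.075e-3, -0.675e-3),
                           c(-0.075e-3, -0.975e-3,  0.075e-3)),
         amplitudes = c(1, 5, 50)), st$grid)

scan  <- simulate_scan(rho, st$m3, noise_snr_db = 30, seed = 7)
normA <- estimate_operator_norm(
  function(v) Re(adjoint_A(forward_A(v, st$m3), st$m3)),
  st$m3$n_voxel, seed = 1, iterations = 12)
rec   <- mpi_reconstruct(st$m3, scan$b,
                         recon_config(lambda = 1e-3 * normA / 12,
                                      iterations = 150))
find_peaks(rec$volume, 3, min_separation = 4)
partition_mass(rec$volume, rbind(c(7,18,16), c(17,12,8), c(12,6,13)))
```

```
#>    i  j  k     value
#> 1 12  6 13 1.0381900
#> 2 18 13  7 0.1055325
#> 3  6 20 15 0.0277551
#> [1]  0.530  3.469 54.765
```

The 50x source is localized exactly at its seeded voxel (12,6,13) and the
nearest-source mass partition attributes 54.8 of the total mass to it (true
value 50, +10%). The two much weaker sources are found but displaced by one
to a few voxels, and their mass estimates (0.53 and 3.47 against 1 and 5)
are biased low: at this 1:50 dynamic range the streak artifacts of a
12-angle scan and the halo of the under-converged bright source dominate —
both biases shrink with more iterations or more angles (see the methods
vignette). A single compressed scan stores 804 complex coefficients instead
of 192,000 time samples (99.2% memory reduction). The same pipeline is
scriptable from a shell via the thin CLI in `inst/cli/fflmpi` (`simulate`,
`compress`, `reconstruct`, `sensitivity-analysis`).

The detection-limit procedure from the sensitivity-series analysis is
available as `sensitivity_analysis()`: a least-squares line through ROI
values versus tracer mass, a noise floor from five void regions (mean
absolute deviation), and the detection limit at the crossing of the fit
with 3x the noise level.

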