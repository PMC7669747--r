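# isptrack

Trajectory and image analysis for interferometric single-particle
tracking (iSPT) of membrane proteins.

High-speed interferometric scattering (iSCAT) microscopy follows a gold
nanoparticle–labelled receptor (e.g. EGFR) on a live cell at
1,000–30,000 frames per second with nanometre precision in 3D. At that
resolution, a trajectory encodes every transient encounter the protein
has with the organized membrane: actin-fenced compartments, sticky
nanodomains, endocytic pits, motor-driven transport. `isptrack` is for
researchers who have such trajectories (or want to prototype against
realistic synthetic ones) and need the standard quantitative readouts:

* **Rolling-window MSD exponent.** The time-averaged mean square
  displacement is fitted to MSD(τ) = Γ<sub>α</sub> τ<sup>α</sup> in a
  sliding window; α classifies mobility (α = 1 free diffusion with
  Γ = 4D, α < 1 sub-diffusive/confined, α > 1 directed). The static
  localization-error offset 4σ<sub>xy</sub>² is subtracted, and lags with
  displacements comparable to the precision are excluded — omitting this
  correction systematically underestimates α.
* **Rolling directional correlation.** C = mean cosine between
  consecutive τ-frame steps (default τ = 5 frames): 0 for memoryless
  walks, negative under knock-back from obstacles, positive under
  persistent transport.
* **Occupancy (ATOM) maps.** Trajectory points accumulated in 4 × 4 nm²
  bins; counts × exposure time = residence time. Extended-residency
  patches (≥ 1 ms, 8-connected) are reported with equivalent circular
  diameters d<sub>eq</sub> = 2√(A/π).
* **Directed-transport steps.** Travel-axis projection (principal
  component), plateau/step extraction by prominence-thresholded
  difference detection, 1-nm step-size histograms, 4·sd track width.
* **Bowl geometry.** Least-squares sphere fits of 3D trajectories
  confined to endocytic pit-like invaginations, plus the unwrapped
  angular position φ(t) about the bowl axis.
* **Synthetic ground truth.** Seeded generators for Brownian (±drift),
  exact fractional Brownian, hop (picket-fence), reflecting-corral,
  spherical-cap, stepper and 3D-landing motion, plus an interferometric
  imaging module (ring-patterned iPSF from the interference law
  I = |E<sub>ref</sub> + E<sub>sca</sub>|², dynamic speckle background,
  temporal-median background removal, radial-symmetry lateral
  localization, central-contrast axial calibration) so the whole
  localization-and-analysis chain can be validated end to end.

## Worked example

A receptor confined in a reflecting corral of radius 50 nm, recorded at
30,000 fps for 1.7 s:

```r
library(isptrack)

cfg <- sim_config("corral", framerate = 30000, n_frames = 50000,
                  diffusion_coefficient = 5e5, corral_radius = 50, seed = 8)
tr <- simulate_trajectory(cfg)

ws <- rolling_exponent(tr, window = 1000, stride = 100)
ws
#> <window_series> 491 windows of 1000 frames (T_w = 0.0333333 s), stride 100
#>   mean alpha = 0.699
#>   window start  end   t_center     alpha   alpha_se     gamma n_lags
#> 1      1     1 1000 0.01665000 0.6819721 0.03592137  98903.35     18

dc <- rolling_directional_correlation(tr, tau = 5, window = 1000, stride = 100)
mean(dc$C, na.rm = TRUE)
#> [1] -0.068

atom <- compute_atom(tr, bin_size = 4)
detect_patches(atom)[1, ]
#>   id n_bins area_nm2  d_eq_nm residence_s      cx_nm     cy_nm
#> 1  1    501     8016 101.0262    1.647267 0.05988024 0.1716567
```

Reading the numbers: the mean rolling exponent 0.70 flags sub-diffusion
(free diffusion would give 1.0 — and does, if you swap the model for
`"brownian"`); the negative directional correlation is the knock-back
signature of a confining boundary; and the dominant occupancy patch has
an equivalent circular diameter of 101 nm ≈ 2R, i.e. the corral itself.

`run_pipeline(traj, analysis_config(...))` runs all stages on one
trajectory (shared window grid for α and C, whole-trajectory MSD, ATOM +
patches, bowl fit for 3D input) and writes CSV tables plus a manifest
with config, seed and input checksum. `inst/scripts/ispt-cli.R` is a thin
command-line wrapper (`simulate` / `analyze` / `localize`) over the same
functions.

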