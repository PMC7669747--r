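---
title: "Quantifying membrane-protein mobility from high-speed iSCAT tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein mobility from high-speed iSCAT tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isptrack)
```

## The problem

Interferometric scattering (iSCAT) microscopy tracks a gold-nanoparticle
(GNP) labelled membrane protein at tens of thousands of frames per second
with nanometre localization precision, in all three dimensions. At that
resolution a trajectory is no longer a smooth path but a dense record of
every transient interaction the protein has with the organized membrane:
actin-fenced compartments, sticky nanodomains, endocytic pits, motor-driven
transport. `isptrack` implements the statistics that turn such a trajectory
into quantitative statements about those interactions, together with
seeded generators for every mobility mode so that each estimator can be
validated against known ground truth — the live-cell recordings such
studies are based on are generally not deposited, so verifiability has to
come from synthetic data.

## Rolling-window MSD and the temporal exponent

The workhorse statistic is the time-averaged mean square displacement
(MSD) fitted to a power law,

$$\mathrm{MSD}(\tau) = \Gamma_\alpha\,\tau^{\alpha},$$

where the temporal exponent $\alpha$ classifies mobility: $\alpha = 1$ is
free (normal) diffusion with $\Gamma_{\alpha=1} = 4D$ in 2D, $\alpha < 1$
sub-diffusion (obstruction, confinement, binding), $\alpha > 1$
super-diffusion (directed transport). Because a single exponent for a
whole trajectory averages away exactly the transient behaviour that is of
interest, `rolling_exponent()` fits $\alpha_i$ in a sliding window
(default 1,000 frames, stride = window/10) and assigns it to the window's
centre time. Windows where the fit fails carry `NA`, never a made-up
number.

Numerical choices, all configurable:

* **Fit lags.** Within each window, every frame lag from 1 to window/4,
  log-thinned to at most 20 lags; the window/4 cap keeps at least 3/4 of
  the window contributing pairs to every lag. The fit is weighted least
  squares of $\log \mathrm{MSD}$ on $\log \tau$ with weights proportional
  to the number of displacement pairs per lag.
* **Static localization error.** A per-point precision $\sigma_{xy}$
  (per axis) inflates the measured 2D MSD by a constant offset
  $4\sigma_{xy}^2$ at every lag. Left uncorrected this flattens the
  apparent slope, i.e. systematically *underestimates* $\alpha$ — at
  30,000 fps the offset from $\sigma_{xy} = 3$ nm (36 nm²) is nearly
  three times the per-lag displacement of a protein with
  $D = 10^5\,\mathrm{nm^2/s}$ (13 nm²). `fit_temporal_exponent()`
  subtracts the offset by default; lags whose *measured* MSD is below
  twice the offset are excluded from the fit entirely, because a
  displacement comparable to the precision carries no slope information.
  The factor 2 is a declared default (`exclusion_factor`). Whether the
  offset should be subtracted as known or co-estimated is genuinely open;
  both are provided (`error_mode = "subtract"` / `"fit"`), with
  subtract-known the default. No motion-blur (finite-exposure) correction
  is applied.
* **Window placement.** The stride default window/10 gives overlapping
  windows; $\alpha_i$ is plotted at the window centre. A 1,000-frame
  window spans 33 ms at 30,000 fps, 167 ms at 6,000 fps, 100 ms at
  10,000 fps (the `T_w` attribute of the result).

## Directional correlation

A complementary statistic is the mean cosine between consecutive steps
separated by $\tau$ frames,

$$C_i = \left\langle
  \frac{\Delta\vec r_1}{|\Delta\vec r_1|} \cdot
  \frac{\Delta\vec r_2}{|\Delta\vec r_2|}
\right\rangle_i,$$

with $\Delta\vec r_1 = \vec r(t+\tau) - \vec r(t)$ and
$\Delta\vec r_2 = \vec r(t+2\tau) - \vec r(t+\tau)$. A memoryless walk has
$C = 0$; knock-back from obstacles makes $C < 0$; persistent transport
makes $C > 0$. The default $\tau$ = 5 frames regardless of framerate.
All overlapping pair start frames inside a window contribute
("all pairs"), and `rolling_directional_correlation()` shares its window
grid with the exponent so the two series can be read side by side. Pairs
in which either step is shorter than `min_step` are skipped and counted;
the cosine of a noise-dominated displacement is meaningless, and
$\sigma_{xy}\sqrt{8}$ (the RMS length of a pure-noise step) is the
recommended floor when noise is present.

## Occupancy maps and patches

`compute_atom()` accumulates the trajectory into 4 × 4 nm² bins (the ATOM
map); counts convert to residence times by multiplying with the exposure
time of one frame. `detect_patches()` formalizes "patches of
extra-ordinary occupancy": bins with residence at or above 1 ms
(the declared stickiness criterion), 8-connected, components of at least
3 bins. Each patch is summarized by its equivalent circular diameter
$d_{eq} = 2\sqrt{A/\pi}$. Published patch outlines in this kind of figure
are explicitly guides to the eye; this thresholded surrogate is
reproducible, and its three knobs are all exposed. Bins are half-open
(`[origin + kb, origin + (k+1)b)`), so every point lands in exactly one
bin and totals are conserved under origin shifts.

## Directed transport and steps

For transport phases, `project_onto_axis()` defines the travel axis as
the principal eigenvector of the lateral position covariance (robust to
back-and-forth legs; an endpoint-vector mode is available), oriented
along the net displacement. `extract_steps()` then treats the on-axis
coordinate as a staircase: moving-average smoothing (default 50 frames),
a two-window difference detector whose local extrema above a prominence
threshold (default 2 nm) mark transitions, plateau levels as medians
between transitions, and step sizes as plateau differences. Histograms
use 1-nm bins centred on integers; absolute step sizes are histogrammed
and the signed table retained. The track width is reported as
$4\,\mathrm{sd}(\mathrm{perp})$, the ~95% envelope of a Gaussian spread —
"width" has no standard definition, so the convention travels with the
value. Trajectories with genuine direction switches should be segmented
before analysis; the detector itself is deliberately simple and fully
specified rather than adaptive.

## Bowls and angular motion

Trajectories confined to endocytic pit-like invaginations are summarized
by `fit_bowl()`: an algebraic least-squares sphere fit (linear in centre
and radius-squared) refined by Gauss–Newton iterations on the geometric
residuals. "Diameter" is ambiguous for a cap, so both the sphere diameter
$2R$ (headline) and the opening diameter (maximal in-plane extent) are
reported. The bowl axis points from the sphere centre toward the point
centroid — into the cap. `angular_series()` gives the unwrapped azimuth
$\phi(t)$ about that axis, with the first frame's in-plane direction as
the reference (the reference is otherwise arbitrary and is recorded).
Near-coplanar input makes a sphere unidentifiable and raises an explicit
degeneracy error rather than returning a wild radius.

## The synthetic generators

`simulate_trajectory()` provides seeded ground truth for each mobility
mode the estimators target: free Brownian motion (optionally with drift,
which is how drift-diffusion directed transport is parameterized); exact
fractional Brownian motion via circulant embedding of the fractional
Gaussian noise covariance (the exponent maps to the Hurst index as
$\alpha = 2H$, and exactness is what makes tight recovery tests
possible); reflecting circular corrals (specular reflection, with
sub-stepping once the RMS step exceeds $R/4$ to avoid tunnelling);
hop diffusion on a square compartment lattice in the picket-fence
picture — wall crossings succeed with one probability, otherwise the step
reflects; diffusion on a spherical cap (tangent-plane proposal, radial
reprojection, reflecting rim); a processive stepper with instantaneous
jumps at exponential dwell times plus Gaussian positional jitter; and a
3D landing above an absorbing membrane plane. Localization noise is a
separate observation step so every estimator can be tested with and
without it.

What the generators deliberately do **not** model: hydrodynamic and
membrane-viscosity effects, interacting particles, motor mechanochemistry
beyond dwell/step statistics, and any specific molecular mechanism of
sub-diffusion — fractional Brownian motion is used as *a* sub-diffusive
test generator without claiming it is *the* mechanism underlying any real
membrane recording (candidate mechanisms such as CTRW or obstructed
walks age and break ergodicity differently). Passing recovery tests
therefore demonstrates estimator correctness, not biological fidelity.

## The imaging module

To validate the localization chain itself, `synthesize_frame()` renders a
phenomenological interferometric PSF from the interference law
$I = |E_{ref}|^2 + |E_{sca}|^2 + 2|E_{ref}||E_{sca}|\cos\theta$: a
Gaussian-envelope cosine ring pattern whose axial phase $4\pi n_m z /
\lambda$ is the physically correct reflection path difference. The
$|E_{sca}|^2$ term (at most $s^2 \le 0.25$) is dropped; this keeps the
central-contrast calibration $c(z) = 2s\cos(\theta_0 + 4\pi n_m z
/\lambda)$ exactly invertible. The full vectorial iPSF is published
elsewhere and out of scope; the phenomenological model preserves exactly
the properties the analysis uses (alternating central contrast, defocus
rings).

The recovery chain is: sliding per-pixel temporal **median** background
removal (the cell's speckle background is quasi-static relative to a
median window, while a moving particle occupies any one pixel for less
than half the window); **radial-symmetry** lateral localization on the
squared contrast $(I-1)^2$ (squaring makes the alternating rings
uniformly positive), solving the 2×2 gradient-line least-squares system
in direction-vector form with gradient-power weights damped by distance
from the gradient centroid; **central-contrast inversion** on one
monotonic branch of the cosine calibration, read by local 3×3 quadratic
interpolation at the recovered centre (bilinear reading is first-order
and measurably biases the contrast where the ring phase curves the
centre), with the branch chosen by temporal continuity — nearest
un-clipped solution among the previous branch and its neighbours.

Two physical limits are worth stating plainly. First, central contrast
alone cannot disambiguate a *diffusive* crossing of a calibration
extremum — both the reflected and the crossed path produce identical
contrast sequences — so heights are trustworthy only within one monotonic
branch (about $\lambda/4n_m \approx$ 103 nm); tracking over micrometre
ranges requires ring-pattern information that is out of scope here.
Second, temporal-median background removal requires the particle to keep
moving: a particle parked on one spot for longer than half the window is
absorbed into its own background estimate. Heights are relative (branch
convention recorded in metadata), not absolute.

In the validation tests the imaging loop is closed end-to-end at
conditions chosen once: a 48-nm GNP landing event at 30,000 fps with the
free-particle Stokes–Einstein diffusivity of $5\,\mu m^2/s$, a 40-nm
start height inside one calibration branch, binding on first contact,
2,400 frames (80 ms), 40 nm pixels, scattering amplitude $s = 0.15$ with
the focal plane 400 nm below the membrane so rings are visible at all
heights, frozen-to-slow speckle (amplitude 0.03, AR(1) coefficient
0.99999 at 30,000 fps, i.e. a background correlation time of seconds)
plus shot noise $5\times10^{-4}$, and an 801-frame median window. RMS
errors are scored over the frames where the sliding median window is
fully defined and, for the height, where the true height lies inside the
calibration branch.

## Problem sizes used in the validation suite

The test suite regenerates everything from code; no fixtures are stored.
The standard sizes are $10^5$-frame trajectories for exponent and
correlation calibration (windows of 1,000 frames, stride 100), ensembles
of 10 trajectories per fractional-Brownian exponent, 100 corral
trajectories for the confinement plateau oracle, a 101,000-frame stepper
recording at 10,000 fps with a mean dwell of 200 ms (so that essentially
all dwells exceed the 50-frame smoothing window; exponential dwells make
occasional unresolvable double-steps unavoidable, which is why step-count
recovery is asserted approximately and the histogram mode exactly), and
the 2,400-frame imaging loop above.

## Known limitations

* Analyses assume uniform frame intervals; the reader rejects non-uniform
  time stamps rather than resampling.
* The rolling-window exponent has the usual time-averaged-MSD bias: at
  lags approaching the window length the estimator fluctuates and the
  per-window $\alpha_i$ scatters; means over many windows are unbiased to
  within a few percent, which is the level the calibration tests assert.
* Patch detection is a surrogate for hand-drawn outlines; its absolute
  diameters inherit the bin size at the ±1-bin level.
* Automatic multi-leg segmentation of transport trajectories is
  deliberately not attempted; direction switches must be segmented by the
  caller.
* The landing generator uses a single diffusivity for the free and the
  membrane-bound phase; real bound receptors are slower. This matters
  only for the imaging validation, where faster in-plane motion is the
  conservative choice for background removal.
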