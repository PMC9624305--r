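---
title: "Methods: traction force and atomic force microscopy analysis in neurotfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traction force and atomic force microscopy analysis in neurotfm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotfm)
```

# The physical model

A cell adhering to a soft hydrogel pulls tangentially on the surface
through its adhesion sites. For gels that are thick compared to the lateral
scale of the traction pattern, the substrate is modelled as a homogeneous,
isotropic, semi-infinite elastic half-space in the linear (small-strain)
regime. The in-plane surface displacement $u$ is then the convolution of
the tangential traction stress $T$ with the Boussinesq surface Green's
function,

$$G_{ij}(r) = \frac{1+\sigma}{\pi E}\left[(1-\sigma)\frac{\delta_{ij}}{r}
  + \sigma\frac{x_i x_j}{r^3}\right],$$

with $E$ the substrate Young's modulus (Pa) and $\sigma$ its Poisson
ratio. In Fourier space the convolution factorizes per wave vector,

$$\tilde G_{ij}(k) = \frac{2(1+\sigma)}{E k^3}
  \left(k^2\delta_{ij} - \sigma k_i k_j\right),$$

which is the basis of Fourier transform traction cytometry (FTTC): the
measured displacement spectrum is multiplied by $\tilde G^{-1}$ mode by
mode. Written as a prefactor $A/(2\pi k^3)$ times the bracketed tensor this
corresponds to $A = 4\pi(1+\sigma)/E$; the package pins the constant by
requiring that the Fourier route reproduce the closed-form real-space
point-force solution (`boussinesq_point_displacement()`), and the test
suite asserts that match. The same check fixes the sign of the off-diagonal
coupling: the Fourier transform of the $+\sigma x y/r^3$ real-space term is
$-\sigma k_x k_y$ (times the scalar prefactor).

Units are micrometres, Pascal, and nano-Newton throughout;
$\tilde G$ carries µm/Pa. The force conversion is
$1\,\mathrm{Pa\,\mu m^2} = 10^{-12}\,\mathrm{N} = 10^{-3}\,\mathrm{nN}$,
exported as `pa_um2_to_nn` and unit-tested, because silent unit slips are
the dominant failure mode of traction calculations.

## Discrete conventions

* Matrices store fields with rows indexing $y$ and columns $x$; physical
  coordinates refer to node centres, node $(i,j)$ at
  $(x_0+(j-1)h,\; y_0+(i-1)h)$.
* The continuous transform of a gridded field is approximated by
  $h^2\,\mathrm{DFT}$; in the products $\tilde u = \tilde G\tilde T$ and
  $\tilde T = \tilde G^{-1}\tilde u$ the $h^2$ factors cancel, so the
  solvers multiply raw DFT coefficients by the continuous $\tilde G$ at the
  DFT wave vectors $k = 2\pi f$.
* $\tilde G$ is singular at $k=0$: a tangential rigid offset carries no
  elastic information, and a mechanically isolated cell exerts a balanced
  force system. The forward solver therefore projects the mean traction to
  zero, and the inverse sets $\tilde T(0)=0$ (zero net force).
* The physical convolution is aperiodic. Both solvers zero-pad to twice
  the linear grid size by default and crop back, which suppresses
  wrap-around from periodic images; the Fourier forward solution then
  agrees with the aperiodic real-space summation to within ~1.5 % RMS in
  the grid interior. The padded inverse is **not** the exact algebraic
  inverse of the padded forward (truncating the displacement window loses
  the field outside it), so the round-trip identity
  $\mathrm{invert}(\mathrm{forward}(T)) = T$ holds to machine precision
  only under the shared periodic discretization, `pad = FALSE` on both
  sides. That is how the identity is tested; the padded default path is
  validated independently against the real-space oracle.
* Tikhonov regularization (`regularization`, units $(\mathrm{µm/Pa})^2$)
  solves $(\tilde G^2+\lambda I)\tilde T = \tilde G\tilde u$ per wave
  vector. The default is $\lambda = 0$: the demonstration scenes are
  shot-noise-limited but densely sampled, and the spectral damping mainly
  biases peak stresses down. The knob exists because sparse or noisy bead
  data need it in practice.

# Measuring the displacement field

**Detection.** Beads image as diffraction-limited Gaussian spots
(σ ≈ 1.3 px). Candidate peaks are 8-neighbour local maxima above a
threshold combining a 5×MAD noise floor with a fraction of the image
range; detections closer than `min_separation` are suppressed
brightest-first. Sub-pixel refinement uses an iterative Gaussian-weighted
centroid on a 7×7 window, re-centring the weights on the running estimate:
for a Gaussian spot the fixed point is the true centre, so the estimator
has no truncation bias (a plain hard-window centroid is biased by
~0.08 px at these spot sizes), and at peak SNR 10 the mean rigid-shift
error across a bead field is ~0.02 px.

**Linking.** `match_beads()` links mutual nearest neighbours within
`max_displacement` (default 3/4 of the mean bead spacing). Near stress
foci the displacement approaches the bead spacing and single-pass linking
fails exactly where the signal is largest, so the pipeline default
`match_beads_predictive()` adds corrector passes: confident vectors
(validated by the universal-outlier median test, threshold 2) define a
thin-plate displacement predictor; every unmatched reference bead is
advected by the predictor and linked to the closest free loaded bead
within 0.35 µm of its predicted position; passes repeat until no bead is
added, so an unmatched core is recovered from its rim inward. Corrector
additions are validated by their distance to the model prediction and are
deliberately *not* re-passed through the global median filter, which
over-rejects in steep but genuine gradients. Stage drift, when a cell
mask is supplied, is removed as the median vector of out-of-cell beads.

**Gridding.** `interpolate_to_grid()` interpolates each component with a
thin-plate spline (exact interpolation at `smoothing = 0`; a positive
value gives the standard bending-energy-penalized smoother). Exactness
matters: any systematic attenuation of the displacement field is amplified
by the $k$-growing inverse operator into a traction deficit — local
least-squares smoothers were measured to lose 5–15 % of the mean stress.
The spline reproduces affine fields exactly; nodes outside the convex
hull of the beads are flagged in the validity mask.

# AFM force–indentation analysis

Force curves are fitted with the Sneddon solution for a rigid cone,
$F = \frac{2}{\pi}\tan(\alpha)\,\frac{E}{1-\nu^2}\,\delta^2$, with
$\alpha$ the half-opening angle (30° in the reference configuration) and
$\nu = 0.5$ for the incompressible cell. The indentation is the piezo
travel past contact corrected for cantilever bending,
$\delta = (z - z_c) - F/k$; the correction is what makes a stiff
(2.8 N/m) and a soft (0.03 N/m) lever agree on the same sample. The
contact point is found by a sustained 5×noise threshold crossing of the
baseline, refined by a continuous piecewise fit (flat baseline +
quadratic branch) whose breakpoint minimizes the total squared residual;
ties resolve to the earliest crossing, making the output deterministic.
Given the contact point, $E$ follows from a linear least-squares fit of
$F$ on $\delta^2$ restricted to $\delta \le$ 0.5 µm (10 % of a nominal
5 µm soma height, respecting small-deformation validity). Fits with
relative RMS error above 20 % are flagged by quality control;
`build_elasticity_map()` masks those pixels and marks a map unreliable
when more than half its fits fail. Failed fits (no contact, non-positive
modulus) return `converged = FALSE` rather than raising, except for the
explicit not-in-contact error. At 2 % force noise the recovery bias
across 0.4–2.3 kPa is below 0.2 % with CV below 1 %.

# Overlap statistics

`overlap_fraction()` thresholds the elasticity map at 1 kPa (the
higher-than-average cutoff for neuronal somas), intersects with the
quality mask, thresholds the registered actin image (Otsu by default,
since no absolute intensity scale is assumed; a fixed fraction-of-max
rule is available), and reports
$100\,|S\cap A|/|S|$ with the reverse fraction alongside. An empty stiff
mask is an error — the statistic is undefined. Registration between the
AFM and fluorescence frames is an input, not computed here.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated under.

| parameter | default | rationale |
| --- | --- | --- |
| substrate | E = 470 Pa, σ = 0.5 | soft polyacrylamide; incompressible hydrogel |
| field / grid | 64 µm, h = 2 µm | cell plus surrounding gel; grid ≈ bead spacing |
| adhesion sites | 6 Gaussian patches, radius 4–5 µm, centripetal | contractile cell anchored at its periphery |
| peak stresses | uniform 30–70 Pa | measured stress scale on such gels |
| contact area | 100–250 µm² | neuronal soma footprints; forces then span ~4–13 nN |
| bead density | 0.15 /µm², 1 µm hard core | resolvable, trackable subset (see below) |
| imaging | 0.25 µm/px, PSF σ = 0.325 µm, peak SNR ≈ 10 | 40× fluorescence with Poisson shot noise |
| stress dynamics | growing: high/low alternation (~30 min dwell) spanning 28–70 Pa; quiescent: constant 8–30 Pa | intermittent traction of actively growing cells |
| sampling | every 10 min for 2 h (13 points) | live-imaging protocol |
| stiffness coupling | E = 0.4 kPa + 0.025 kPa/Pa × mean stress | spans 0.4–2.3 kPa over the stress range; growing cells land at 1–2 kPa |
| AFM maps | 16 × 16 px, 1 µm pitch, 2 % force noise | force–volume protocol |

Two generator choices deserve explanation:

* **Bead density.** A nominal 5 % v/v of 200 nm beads is ~12 beads/µm³;
  even a thin optical section therefore contains far more beads than a
  diffraction-limited image can separate. The generator plants the
  *resolvable tracked subset*: 0.15 beads/µm² with a 1 µm hard-core
  exclusion (sequential dart throwing, count drawn from the Poisson law of
  the nominal density). Individual spots stay separable at the detector's
  default minimum separation, and the ~1.6 µm mean spacing samples the
  displacement field finely enough for the inverse problem to be
  well-posed without regularization.
* **Continuous-world rendering.** The scene's analysis-grid truth obeys
  `truth_displacement = forward_displacement(truth_traction)` exactly
  (shared code path, asserted in tests). The bead renderer, however,
  samples a displacement field computed from the same analytic traction
  pattern on a 4× finer grid: beads sit between analysis nodes and ride a
  continuously deforming substrate, not a bilinear interpolant of the
  coarse grid. Without this, the rendered data inherit a grid artifact
  that dominates the end-to-end error budget.

What the generator does **not** emulate: optical aberrations and focus
drift, bead polydispersity and aggregation, finite gel thickness,
out-of-plane (z) displacements and tractions, fluorophore bleaching,
segmentation uncertainty of the cell outline (masks are exact disks), and
the spatial statistics of real neuronal adhesions (patches are a stylized
stand-in). Passing tests therefore certify the computational chain under
controlled conditions, not instrument-specific behaviour on real data.

# Validation design and problem sizes

The test suite and the acceptance script validate, at sizes chosen to keep
a full run in tens of seconds: solver-vs-oracle agreement on a 64×64 grid
(interior RMS < 2 %); the round-trip identity under the shared
discretization (< 1 %, in practice ~1e-13); Hertz recovery at
E ∈ {400, 1000, 2300} Pa with 100 noise seeds per level (bias < 2 %,
CV < 5 %) and soft/stiff lever agreement (< 5 %); rigid-shift tracking at
SNR 10 (mean error < 0.05 px); end-to-end recovery of 50 Pa scenes
averaged over five seeds (< 5 % noise-free, < 15 % at shot noise); a
30-cell force-versus-area cohort (Spearman ρ > 0.9); and exact unit,
force-balance, and overlap identities. The stiffness–actin harness plants
two equal disks offset by a calibrated 1.2 px jitter (ideal-disk overlap
81.9 %); pixelation of the 16×16 grid spreads individual draws by a few
percent, so the demonstration asserts the mean within 78–85 % and
individual draws within 74–89 %.

# Known limitations

* 2-D TFM only: out-of-plane tractions and displacements are ignored, and
  the half-space assumption breaks down on thin gels.
* Unregularized inversion slightly over-estimates *peak* stresses on noisy
  data (noise rectification in $|T|$) while mean stresses stay accurate;
  choose `regularization > 0` when peaks matter.
* Exact thin-plate interpolation presumes outlier-free vectors; the
  median-test/corrector combination removes gross mismatches, but
  correlated detection biases (e.g. overlapping spots in strongly
  compressed regions) pass through and set the end-to-end error floor.
* The Hertz fit assumes a homogeneous, semi-infinite, purely elastic cell;
  viscoelasticity, substrate feel-through on thin regions, and
  non-conical tip geometry are out of scope.
* The growing/quiescent trace classification is a range-threshold
  convenience for triage, not a measurement.
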