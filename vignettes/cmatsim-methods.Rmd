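---
title: "Simulating multipoint adaptive optics for mesoscale two-photon imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multipoint adaptive optics for mesoscale two-photon imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmatsim)
```

## The problem

Two-photon mesoscopes image fields of view of several millimetres while
resolving sub-cellular structure. Over such fields the optical aberrations are
strongly field-dependent: a wavefront correction calibrated at the centre of
the field (central adaptive optics, "CeAO") degrades rapidly off-axis, where
astigmatism and coma dominate. The multipoint strategy simulated here ("cmat"
mode) pre-calibrates a grid of correction points across the field and, during
scanning, loads the deformable-mirror (DM) pattern of the point nearest to the
current tile or region of interest.

`cmatsim` is a desk-scale digital twin of that instrument. It contains no
hardware control; every input is generated internally from seeds, and every
quantity the package reports is computed by the same code paths a user calls.

## Correction-point geometry

The correction points are the centres and vertices of a honeycomb of regular
hexagons of side $s = 577$ µm — equivalently, a triangular lattice of pitch
$s$. A hexagon centre and two adjacent vertices form an equilateral triangle
whose circumradius $s/\sqrt{3} = 333.1$ µm (conventionally quoted as 330 µm)
is the farthest any field position lies from its nearest correction point, so
the isoplanatic "effective compensation radius" of ~330 µm guarantees
coverage. With lattice points admitted inside a 3950 µm inclusion radius the
grid holds 163 points, 55 of them hexagon centres.

Two geometry notes, both visible in the code and its tests:

* **Admission radius.** The printed counts (55 hexagons, 163 points) require
  excluding the lattice ring at $4\sqrt{3}s \approx 3997.6$ µm while the
  nominal field radius is 4000 µm; any inclusion radius in roughly
  [3790, 3995] µm reproduces the counts, and 3950 µm is the package default.
  A consequence is that positions near the extreme rim of the field are
  farther than 333 µm from every admitted point: full triangle-circumradius
  coverage holds on a disk of radius `inclusion_radius - side`
  (about 3.37 mm), which is what `build_correction_grid()` asserts. Users who
  need coverage farther out can pass a larger `coverage_radius` and will get
  an explicit error naming the first uncovered location.
* **Orientation.** The hexagon-centre sublattice (pitch $\sqrt{3}s$) has a
  basis vector along $+x$; hexagon vertices then sit at $30° + k\,60°$ from
  each centre. All point counts are rotation-invariant; fixing the
  orientation makes ordering, nearest-point ties, and tests deterministic.
  Points are ordered by distance from the field centre, then by angle.

The overlap economics of the layout are closed-form: disks of radius $r$ that
just cover the plane sit at spacing $\sqrt{3}r$ on the triangular lattice
(pairwise overlap 5.77 % of a disk, 34.6 % over six neighbours) versus
$\sqrt{2}r$ on the minimal covering square lattice (18.17 % pairwise, 72.7 %
over four neighbours). `overlap_report()` evaluates the circular-lens area
formula; the percentages are scale-invariant.

## Optical model

The point-spread function comes from scalar Fourier optics: a uniformly
filled circular pupil (NA 0.5, water immersion, 920 nm excitation) with phase
$2\pi\sum_j c_j Z_j(\rho,\theta)$, where $Z_j$ are Noll-indexed Zernike
polynomials normalized to unit RMS over the pupil, so a coefficient in
wavelengths is directly its RMS wavefront contribution. Defocus to plane $z$
uses the exact high-NA phase $kz\sqrt{n^2 - \mathrm{NA}^2\rho^2}$ rather than
the paraxial $\rho^2$ term. The far-field amplitude $h$ is computed by
zero-padded FFT, and the two-photon effective PSF is $|h|^4$, normalized to
unit peak for the unaberrated system. At NA 0.5 the scalar model is accurate
to a few percent; the test suite bounds the unaberrated lateral FWHM against
an independent Debye-integral quadrature to 3 %.

Numerical choices worth knowing:

* The calibration metric (below) integrates $|h|^4$ over the focal plane.
  For any pad factor ≥ 2 this sum is *exact* — by Parseval it equals
  $N\sum|P\star P|^2$, the energy of the pupil autocorrelation, which is
  alias-free once the FFT grid is twice the pupil — so metric evaluation runs
  at pad 2 regardless of the rendering pad factor.
* Rendering uses pad factor 8 (0.115 µm focal-plane pitch), and `psf_2p()`
  refuses grids with fewer than 4 samples across the focal spot.
* The DM is modal: its state is a Zernike coefficient vector with a ±30
  wavelength stroke bound. A wavefront exceeding the stroke is rescaled as a
  whole (shape-preserving) with a warning, rather than clipped per term.
* DM coefficients add to the sample-path phase; perfect correction is the
  negative of the ground truth.

## Ground-truth aberration field

The "system aberrations" the calibration must discover are a seeded,
continuous field of Zernike coefficients over the object plane: astigmatism
growing as $(r/R)^2$ and oriented along the field azimuth, coma growing
linearly and pointing radially, spherical aberration growing as $(r/R)^2$,
plus a band-limited random component (~2 mm correlation length) per term.
The deterministic part vanishes at the field centre — the best-corrected
point of a centred optical train.

The default edge amplitudes (0.2, 0.15 and 0.08 wavelengths, random
component 0.02) put the whole field inside the capture range of modal
sensorless optimization, which we measured at roughly 0.3 wavelengths total
RMS (about 2 rad) for the 21-step sweep protocol below. That matches how a
working instrument operates: its calibration demonstrably converges in a few
rounds, which bounds how aberrated the real system can be. Even so, the
uncorrected edge of the simulated field retains less than 1 % of the
two-photon peak signal, so peripheral degradation without multipoint
correction is severe.

**Known limitation.** Aberrations much beyond ~0.3 wavelengths total RMS
exceed the capture range of per-term sweeps: the total-fluorescence metric
develops joint local maxima that coordinate-wise argmax cannot escape, no
matter the sweep range schedule. This is a property of the method, not of
the implementation; simulations of heavily misaligned systems need a
different optimizer and are out of scope.

## Sensorless modal calibration

Calibration at a point follows the sweep protocol: for each Zernike term in
Noll order (terms 4 onward — piston does not affect two-photon signal and
tip/tilt merely translate the field), evaluate the fluorescence metric at 21
equally spaced coefficient values spanning the current value ± a half-range,
record the argmax; repeat for 5 cycles and average the per-cycle argmax
values. One pass over all terms is a round; 4–8 rounds are run, stopping
early once the relative metric gain per round falls below 1 %.

The metric is the total fluorescence of a pollen-like calibration phantom —
for the plane-integrated two-photon PSF this factorizes into
(phantom brightness) × (plane-integrated $|h|^4$), so the noise-robust
`"total"` metric is evaluated without an explicit convolution; a `"peak"`
metric (image maximum, rendered) is available in the configuration.

The sweep half-range starts at 0.5 wavelengths. Rather than halving every
round on a fixed schedule, the half-range shrinks (by a factor 1.5) only
after a round whose updates all stayed interior to the sweep window: an
update railed at the window edge means the optimum is still out of reach,
and shrinking then strands the search. On benchmarks with coupled
astigmatism/coma fields the adaptive schedule converged in cases where fixed
halving stalled, and it reduces to the fixed schedule for small aberrations.
Five-cycle argmax averaging matters only under noise: with 5 % multiplicative
metric noise the variance of the averaged estimate is measurably below that
of a single cycle's argmax (a property test covers this).

Per-point calibration is independent; `calibrate_grid()` loops points in
grid-index order and persists the table as tab-separated text. A metric
collapse of more than 20 % below the round's starting value aborts with a
runaway diagnostic.

## Scanning

A full-field frame divides the FOV square into an $n \times n$ matrix of
half-open tiles (default 4×4 tiles of 2×2 mm² on the 8 mm field), scanned as
stripes top-to-bottom and left-to-right within a stripe. Each tile is
rendered with a spatially constant PSF evaluated at its centre — one DM state
per subregion, matching the instrument, at the cost of ignoring intra-tile
field variation — and the DM vector is the calibrated vector of the tile
centre's nearest correction point (`"cmat"`) or the field-centre vector
everywhere (`"ceao"`). One DM load event is logged per tile ($n^2$ per
frame), with the transition interval's data excluded (zero samples
retained). Tiles are rendered with a margin of half the PSF-kernel width so
mosaics are seam-free; a constant sample under zero aberration reproduces a
constant frame to numerical precision.

ROI scanning selects the single correction point nearest the ROI centroid
and holds it across the frame sequence, reproducing the instrument's
"jump-and-load" behaviour; the 1000×1000 px at 0.5 µm/px geometry used for
in-vivo recordings is the default request shape.

## Phantoms

All generators are pure functions of their specification and seed:

* **Beads** — anti-aliased spheres (0.5 µm for resolution, 10 µm for
  brightness comparisons), uniformly placed with centre separation at least
  two diameters; the sub-voxel limit degenerates to a single-voxel impulse
  carrying the sphere's integrated amplitude.
* **Pollen-like ball** — a spiky disk used as the calibration target.
* **Neuron scenes** — somata (bright disks), dendrites with spine bumps, and
  a smooth dim neuropil; ground-truth soma masks are returned in place of an
  external segmentation.
* **Calcium movies** — per-cell Poisson spike trains convolved with a
  single-exponential kernel (τ = 1.5 s, a GCaMP6s-scale decay; the indicator
  kinetics are configurable), a shared neuropil signal, contamination of the
  measured cell trace by a 0.3 neuropil fraction (so the 0.7-subtraction in
  the analysis is exercised meaningfully), and per-pixel Poisson photon
  noise. Defaults follow the in-vivo acquisition: 15 Hz for 300 s (4500
  frames). Spike times, clean traces, and masks are returned as ground
  truth.

What the phantoms deliberately omit: vasculature and motion artifacts (the
real pipeline's registration step is out of scope), depth-dependent
scattering, and photobleaching. Tests passing on these phantoms therefore
validate the geometry, optics, calibration and statistics — not robustness
to real-tissue nuisance structure.

## Evaluation statistics

* **Bead FWHM** — per bead, a 1-D Gaussian is fitted to the lateral line
  through the intensity maximum and to the axial profile, taken as the
  bead's per-plane peak within the lateral window (the usual way a bead's
  z-profile is read off a stack; it also captures the axial elongation of
  astigmatic PSFs, which a single z-column can miss). FWHM
  $= 2\sqrt{2\ln 2}\,\sigma$; failed fits and widths under 2 pixels are
  flagged and excluded from the site mean ± SD. Because residual spherical
  aberration shifts the best focus by several µm, `measure_bead_fwhm()`
  first locates the focal plane with a coarse axial scan, then samples the
  stack at the 0.27 µm acquisition step around it.
* **ΔF/F** — $F = F_{\mathrm{cell}} - 0.7\,F_{\mathrm{neuropil}}$; $F_0$ is
  the 25th percentile of $F$ over the whole recording (linear-interpolation
  percentile, `type = 7`); $\Delta F/F = (F - F_0)/F_0$. A non-positive
  baseline is an error, not a silent NaN.
* **SNR** — mean of the samples at or above the 90th percentile of ΔF/F,
  divided by the standard deviation (n−1) of the samples strictly below it.
  The phrase "top 10 % interval" admits a contiguous-window reading; both
  are implemented (`top = "value"` is the default, `top = "interval"` takes
  the best contiguous 10 % window).
* **Group comparisons** — Wilcoxon signed-rank for paired data, Mann–Whitney
  otherwise, two-sided; exact enumeration of the permutation distribution
  (mid-ranks under ties, zero differences dropped) for combined $n \le 12$,
  normal approximation with tie correction beyond. The exact branch is
  hand-enumerated because the reference implementation declines exact
  p-values under ties; tests cross-check both branches against independent
  oracles.

## The demonstration pipeline and problem sizes

`run_demo()` chains the stages — build grid, calibrate the needed points,
scan a frame in both modes, compare the modes at probe radii — from a single
serializable configuration whose hash tags every output. The desk-scale
defaults are 15 Zernike terms, a 64-sample pupil, and probes at 0, 2000 and
3900 µm. The package-level comparison experiment (`compare_modes_at()`) uses
a photon-limited calcium movie (baseline 8 photons/pixel/frame, 0.1 Hz
spiking, 60 s at 15 Hz) so that SNR differences reflect each mode's photon
collection, as they do in vivo; soma brightness uses a rendered neuron
scene, and resolution uses 0.5 µm beads on the acquisition grid. At these
sizes a single mode comparison (two calibrations included) takes seconds to
tens of seconds on one CPU; the directional experiment over 10 seeds runs in
a couple of minutes.

A thin command-line front end (`inst/cli/cmatsim.R`) exposes the same
functions as `tile`, `overlap`, `calibrate`, `scan`, `roi`, `analyze` and
`demo` subcommands; it adds no logic of its own.

## Design choices that were genuinely open

* "First 200 Zernike coefficients" fixes only the count: Noll indexing with
  unit-RMS normalization is the adaptive-optics default and makes RMS
  bookkeeping trivial. 200 terms are supported; 15 is the desk-scale
  default.
* "Maximizing the fluorescence intensity" does not say total or peak; total
  is the default for noise robustness, peak is a configuration option.
* Whether the per-cycle "peak" is the argmax coefficient or a
  metric-weighted value: implemented as argmax, following the wording
  "coefficient corresponding to the maximum intensity".
* The square-layout comparison uses spacing $\sqrt{2}r$ (the minimal fully
  covering square lattice) and 4 neighbours; the printed total (4 × the
  pairwise value) implies 4, not 8.
* The exact admission rule that yields 55 hexagons / 163 points is not
  derivable from first principles; the 3950 µm inclusion radius reproduces
  it and is configurable.
* Which higher-order terms were held fixed between points in the original
  procedure is unknown; the simulator simply optimizes all configured terms
  at every point.

## Reading the test suite

Exact geometry (point counts, circumradius, overlap percentages, scan-plan
structure, the 65 µm image extent) is asserted at printed precision.
Numerical physics (Debye FWHM agreement, Strehl bounds, Parseval, energy
monotonicity) is asserted at stated tolerances. Statistical procedures are
asserted against independently written oracles (brute-force enumeration,
direct-formula recomputation). The directional end-to-end experiment asserts
sign consistency — multipoint correction beats centre-only correction at the
field edge on lateral and axial bead FWHM, soma brightness, and calcium SNR
in at least 9 of 10 seeds — rather than any instrument-specific percentage,
which a desk-scale simulation cannot and should not reproduce.
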