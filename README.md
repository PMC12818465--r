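# cmatsim

A desk-scale digital twin of a large field-of-view two-photon mesoscope with
**multipoint adaptive optics**. Mesoscopes image ~8 mm fields at sub-cellular
resolution, but optical aberrations grow rapidly off-axis; a single wavefront
correction calibrated at the field centre ("CeAO") leaves the periphery badly
degraded. The multipoint strategy ("cmat") pre-calibrates a honeycomb grid of
correction points — the centres and vertices of 55 regular hexagons of side
577 µm, 163 points in all — and loads the deformable-mirror pattern of the
nearest point for every scan tile or region of interest, so that no position
is farther than the triangle circumradius $s/\sqrt{3} \approx 330$ µm from
its correction.

The package simulates the whole workflow with no hardware and no external
data:

* **hexgrid** — the correction-point lattice, nearest-point assignment,
  galvo-voltage mapping, and the coverage-overlap economics of honeycomb vs
  square layouts (disks at spacing $\sqrt{3}r$ overlap 5.77 % pairwise /
  34.6 % total; the minimal covering square lattice at $\sqrt{2}r$ wastes
  18.17 % / 72.7 %).
* **wavefront** — Noll-indexed, unit-RMS Zernike polynomials; scalar
  Fourier-optics PSFs (NA 0.5, 920 nm, water immersion) with exact high-NA
  defocus; the two-photon effective PSF $|h|^4$; a seeded field-varying
  ground-truth aberration model; a modal DM with a ±30-wavelength stroke.
* **calibration** — sensorless modal optimization: per term, 5 cycles of
  21-step coefficient sweeps maximizing total fluorescence, argmax values
  averaged; 4–8 rounds with an adaptive range schedule.
* **phantoms** — seeded bead fields, a pollen-like calibration target,
  neuron scenes with ground-truth masks, and GCaMP-like calcium movies
  (15 Hz × 300 s defaults) with known spikes.
* **scanner** — stripe-ordered 4×4 tiled scans (16 tiles of 2×2 mm², one DM
  load each) and ROI scans with nearest-point correction.
* **metrics** — Gaussian-fit bead FWHM (0.0542 µm pixels, 0.27 µm z-steps),
  line profiles, neuropil-subtracted ΔF/F
  ($F = F_{cell} - 0.7 F_{neu}$, $F_0$ = 25th percentile), top-decile SNR,
  and exact small-sample Wilcoxon / Mann–Whitney comparisons.

## Worked example

```r
library(cmatsim)

cfg <- run_config(seed = 1, n_terms = 8, rounds_min = 2, rounds_max = 4,
                  scan_n = 2, pixels_per_tile = 16,
                  probe_radii_um = c(0, 2000, 3900))
report <- run_demo(cfg)
print(report)
```

```
cmatsim demo report  (config 851304bc, seed 1)
grid: 163 points (55 centers), side 577 um, inclusion 3950 um
scan: 2 x 2 tiles of 4000 um, 4 DM loads/frame

mode comparison (cmat vs ceao):
 radius_um mode lateral_fwhm_um axial_fwhm_um soma_intensity mean_snr
         0 cmat       0.7162654      6.161753      73.678904 5.624308
         0 ceao       0.7162654      6.161753      73.678904 5.624308
      2000 cmat       0.7169917      6.159842      66.161176 5.033076
      2000 ceao       0.7894825      6.586473      27.436527 4.434046
      3900 cmat       0.7206102      6.254318      65.383627 5.491993
      3900 ceao       0.8569977     10.729405       4.316744 3.805203
```

Reading the table: at the field centre the two modes share the same
correction point, so they agree exactly. Moving outward, the centre-only
correction (`ceao`) loses lateral and axial bead resolution (FWHM in µm,
Gaussian fits on a simulated 0.5 µm bead stack), soma brightness (mean
rendered intensity inside ground-truth soma masks), and calcium-trace SNR
(photon-limited synthetic movies) — while the multipoint mode (`cmat`) stays
near the diffraction limit everywhere, because its residual aberration is
only the field variation across at most 330 µm plus the calibration error.

Single pieces are available directly:

```r
grid <- build_correction_grid()        # 163 points, 55 hexagon centres
overlap_report("cmat")$pairwise_pct    # 5.766889
hex_circumradius(577)                  # 333.13 -> "roughly 330"
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cmatsim.R tile --side 577 --fov 8000 --out grid.tsv
Rscript inst/cli/cmatsim.R overlap --scheme square
Rscript inst/cli/cmatsim.R demo --seed 1 --out demo_out
```

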