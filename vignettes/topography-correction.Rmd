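---
title: "Topography-aware ToF-SIMS processing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topography-aware ToF-SIMS processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TopoSIMS)
```

# The physical model

TopoSIMS treats the ToF-SIMS analyzer in an idealized form: a singly
charged secondary ion leaves the sample surface with negligible initial
velocity, is accelerated by the uniform field between the sample and the
biased extractor (default 2 kV across a 1.5 mm gap), drifts, and is
reflected by an ion mirror that is assumed to compensate the
kinetic-energy spread exactly. Under these assumptions:

* the substrate-level acceleration time is
  $t_{ac}(m) = \sqrt{2 h_{ex}^2 m / (U_{ex} e)}$;
* an ion emitted at height $\Delta h$ above the substrate spends
  $t_{ac}\sqrt{(h_{ex}-\Delta h)/h_{ex}}$ in the gap — its exit-velocity
  deficit is absorbed by the reflectron, but the shortened acceleration
  time is not, and appears as a topographic shift of the whole spectrum;
* all flight times scale as $\sqrt{m}$, anchored by one calibration
  point (K⁺ at 20.545 µs by default), giving the quadratic
  time-to-mass law $m = m_{cal}\,(t/T_{cal})^2$.

The $\sqrt{m}$ scaling has one crucial consequence: the *relative*
topographic shift $T(m,\Delta h)/T(m,0)$ is the same for every mass.
That is why a single per-pixel correction factor
$D(x,y) = T^{sub}_{ref}/T_{ref}(x,y)$, derived from one reference peak,
restores the substrate-level flight time of *every* species when each
pixel's time axis is multiplied by it, and why the reference shift can
be inverted in closed form into a height map,
$\Delta h = h_{ex}\,(1 - ((t_{ac}-\Delta T)/t_{ac})^2)$.

What is *not* modelled: extraction-field curvature above non-planar
surfaces, angular emission distributions, detector dead time,
reflectron geometry, non-uniform sputtering and shading on steep
features, and charging. These are real effects on real instruments; the
correction implemented here addresses the acceleration-path term only,
which is the dominant, systematic and invertible one.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `U_ex` | 2000 | V | extraction potential of the modelled analyzer |
| `h_ex` | 1.5e-3 | m | sample–extractor gap; sets both the shift scale and the height scale |
| `T_cal`, `m_cal` | 20.545e-6, 38.9637 | s, u | calibration anchor (K⁺ at substrate level) |
| `tof_bin` | 50e-12 | s | TDC bin; sets the ≈5 µm height-detection floor |
| `t_window` | 100e-6 | s | acquisition window; 2,000,000 raw bins |
| `threshold` | 1000 | counts | per-segment total-count floor; at 256×256 pixels ≈ one ion per 65 pixels |
| `minGap` | 40 | bins | zero-run below which nonzero runs merge (2 ns ≳ the K-scale shift), so a peak and its shifted copies stay in one segment |
| `pad` | 10 | bins | guard band around segments; see below |
| `minCounts` | 5 | counts | minimum reference counts per pixel for a valid track |
| `percentile` | 1.0 | — | substrate estimator: strict maximum; robust quantile optional |
| `nComponents` | 6 | — | retained PCA components |

**Threshold semantics.** The threshold applies to a segment's *total*
counts, not to single bins. This matches its interpretation as an
ion-per-pixel rate: 1000 counts over a 65,536-pixel image is one
detected ion per ~65 pixels, about the weakest signal worth mapping.

**The pad parameter deserves attention.** After correction, a peak
moves *up* the time axis toward its substrate-level position. If a
species is entirely confined to elevated regions — as every root-only
species is in the synthetic scene — its segment, found from the
*uncorrected* sum spectrum, may end below the substrate-level position,
and the corrected peak can leave the segment (the counts are then
dropped, counted and warned about). With real, resolution-broadened
peaks the default 10-bin pad is ample because the segment already
reaches up to the substrate position; with the simulator's noiseless
delta peaks it is not, and the tests use `pad = 120` (6 ns, covering
the full shift of a Cs₂-mass ion over ~200 µm relief) for noiseless
fixtures. The pad is deliberately a user-facing parameter.

# The synthetic scene

`makeRootScene()` emulates the study system the package is built
around: a dried seedling root on a flat oxidized-silicon substrate,
imaged over a 500 × 500 µm field. The topography is a half-cylindrical
ridge; its default footprint width is twice its 200 µm height, which is
the geometrically consistent width of a true semicircular cross-section
(400 µm, 0.8 of the field). Heights therefore span 0 at the footprint
edge to 200 µm at the centerline.

The default palette places Si⁺/Si₂⁺ on the bare substrate; Na⁺, Mg⁺,
K⁺, Ca⁺ and three organics (166, 212, 255 u, spaced ≥ 1 u so they stay
resolved at m/Δm = 7000) on the root; and Cs⁺/Cs₂⁺ everywhere, because
the sputter source implants cesium across the field. Yields are chosen
to reproduce the qualitative intensity structure of such a measurement:
Cs⁺ is globally the most intense peak (which is what makes it the
reference of choice), K⁺ is the dominant root peak, and the substrate
contributes a minor share of the total retained intensity — under which
the leading uncentered principal component reproduces the mean spectrum
and the substrate contrast appears in component 2.

Stochastic rendering draws Poisson counts per pixel (the conventional
shot-noise model for ion counting; the package's own choice) and adds
Gaussian timing jitter with $\sigma_t = T/(2R \cdot 2.3548)$, which maps
a FWHM mass-resolving power $R = m/\Delta m$ into the time domain via
$\Delta t/t = \Delta m/2m$. Times are floor-quantized to the TDC grid,
as a time-to-digital converter truncates; a guard of 10⁻⁹ bin
(5 × 10⁻²¹ s) keeps exact integer time/bin ratios — such as the
20.545 µs anchor on the 50 ps grid — stable against floating-point
representation. Noiseless mode deposits `round(λ)` counts at the
quantized centroid bin: fully deterministic, and deliberately the
hardest case for the correction stage, since a delta peak carries no
sub-bin information.

What the simulator does *not* emulate — and hence what passing tests do
not demonstrate about real data: matrix effects on sputter yields,
detector saturation and dead time (the "saturation" motivating K⁺
exclusion is reproduced only as high intensity), mass interferences and
isotope patterns, ion-gun shading on steep walls, charging, and any
correlation between chemistry and height beyond the binary
root/substrate split.

# Numerical choices

* **Bin-center convention.** The time of raw bin *i* (0-based) is
  $(i + 0.5)\,\tau$; with floor quantization this is the minimax
  estimate of the true arrival time.
* **Reference position by intensity-weighted centroid,** not argmax:
  sub-bin precision is what pushes the height floor to the few-µm
  scale implied by 50 ps timing. Pixels with fewer than `minCounts`
  reference counts are invalid and propagate as invalid through every
  later stage; no spatial interpolation is attempted.
* **Correction by axis scaling + overlap rebinning.** Each bin's time
  support $[t_i, t_{i+1})$ maps to $[t_i D, t_{i+1} D)$ and its counts
  are redistributed proportionally to overlap length. This conserves
  counts exactly in fractional mode; integer mode restores integrality
  per pixel by largest-remainder rounding, preserving per-pixel totals
  exactly. The package corrects the full compressed axis per pixel
  (not just segment-local peak positions), so downstream consumers see
  one coherent corrected cube.
* **Substrate reference level.** The default estimator is the maximum
  tracked reference TOF — the substrate is the lowest surface, so its
  ions fly longest, and for deterministic data the maximum is exact.
  For noisy data the maximum of thousands of per-pixel centroids is
  biased upward by extreme-value statistics (≈3σ of the centroid
  noise, ~15 µm of spurious height at typical reference intensities),
  so a robust quantile is exposed; with the substrate covering ≥ 20% of
  the field, the 0.9 quantile sits mid-plateau and estimates the
  substrate level nearly unbiasedly. The strict maximum remains the
  default; the robust option is used in the stochastic-recovery tests
  and the pipeline examples.
* **Height reconstruction clamps** shifts within one TDC bin of zero
  (centroid noise) to zero, and invalidates pixels whose shift reaches
  $t_{ac}$ (unphysical: the emission point would be above the
  extractor).
* **Degenerate inputs.** Empty segments, all-zero cubes, zero-count
  pixels, and empty (0-point) compressed spectra are all representable
  and handled explicitly rather than erroring mid-pipeline; see the
  test suite.
* **PCA** is a deterministic full SVD (fixture-scale matrices need no
  randomized solver), uncentered and unwhitened by default so that
  component 1 is interpretable as the mean spectrum; the eigenvector
  sign is fixed by making each one's largest-magnitude element
  positive. Per-pixel total-ion-count normalization exists but is off
  by default, since the modelled workflow does not prescribe one.

# Quantization and the correction residual

With delta peaks on a 50 ps grid, the corrected peak position inherits
the input quantization: the residual time error per pixel is
$\varepsilon_K + r(\varepsilon_{sub} - \varepsilon_{Cs})$ with
$|\varepsilon| \le \tau/2$ and $r = T_K/T_{Cs} \approx 0.54$ — up to
about one bin, i.e. up to ~2 × 10⁻⁴ u at mass 39 in the adversarial
worst case. Which phases actually occur depends on how densely the
scene's heights sample the profile: the acceptance computation runs on
the native 256 × 256 grid, where the half-cylinder's heights sample the
phase space finely. Real peaks are ~30 bins wide, so their centroids
carry sub-bin information and this quantization term largely vanishes;
the noiseless delta-peak setting is the floor-case stress test, not the
favourable case.

# Interfaces and formats

The cube container is a single-file, versioned, little-endian block
format (magic `TOPOSIMSCUBE`): JSON blocks for geometry, grids, segment
tables and logs; raw float64/int32 blocks for matrices and maps. Round
trips are lossless and version or truncation problems produce explicit
errors naming the block. Compressed cubes interchange as
continuous-mode imzML (shared m/z axis as float64, per-pixel float32
intensities, 1-based pixel coordinates, x fastest; the ibd UUID is
derived from the payload so exports are byte-deterministic); the
exported files parse with independent imzML readers. Spatial maps
export exactly as CSV; the 32-bit float TIFF export normalizes values
to [0, 1] and records the scale factor in a JSON sidecar, because float
TIFF samples outside [0, 1] are not portable across writers. All CSV
numerics use 9 significant digits with fixed column order, so identical
inputs give byte-identical files.

# Problem sizes

The test fixtures use 32 × 32 (noiseless) and 64 × 64 (stochastic)
grids with the full 2,000,000-bin raw axis held sparsely; these sizes
exercise every code path, including 65,536-pixel counting-statistics
checks, while the whole suite runs in about a minute. The acceptance
computation of the correction residual runs on the native 256 × 256
grid with the two species it concerns (K⁺ analyte, Cs⁺ reference).

# Known limitations

* Absolute height accuracy is limited by the uniform-gap idealization;
  field curvature over real topography is not modelled.
* The correction assumes one global substrate level; tilted or stepped
  substrates would need a spatially varying reference plane.
* Species absent at substrate level can lose counts past their segment
  boundary under correction if the pad is too small for their shift
  (warned and counted, never silent).
* PCA is the only decomposition shipped; the structure is in place for
  other factorizations, but they are out of scope here.
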