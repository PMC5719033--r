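# TopoSIMS

Topography-aware processing of time-of-flight secondary ion mass
spectrometry (ToF-SIMS) imaging data.

## The problem

A ToF-SIMS imaging run produces one time-of-flight histogram per pixel —
at a 50 ps time-to-digital converter over a 100 µs window that is two
million samples per pixel, and 256 × 256 pixels per image. Two things
make these cubes hard to interpret automatically:

1. **Volume.** Multivariate analysis over the raw axis is impractical;
   naive binning throws away spectral resolution.
2. **Topography.** An ion emitted from an elevated part of the sample
   (height Δh above the substrate) has a shorter acceleration path to
   the extractor and therefore arrives *earlier*. On samples with
   hundreds of micrometres of relief — here, a dried plant root on a
   flat substrate — every peak is smeared into a family of
   height-dependent copies, which corrupts peak areas and any
   decomposition run on top of them.

TopoSIMS is aimed at mass-spectrometry-imaging practitioners who want
these cubes compressed losslessly, corrected for topography, and mapped
chemically — and, as a by-product, want the sample's surface topography
reconstructed from the spectral shifts alone.

## The model

For a singly charged ion of mass *m* accelerated across a gap *h_ex*
under extraction potential *U_ex*, the acceleration time at substrate
level is

    t_ac = sqrt(2 h_ex² m / (U_ex e))     (≈ 30.2 ns for K⁺ at 2 kV, 1.5 mm)

and emission at height Δh shortens the total flight time *T* by

    ΔT(m, Δh) = t_ac(m) · (1 − sqrt((h_ex − Δh)/h_ex)).

Because both *t_ac* and *T* scale as √m, the *relative* shift is
mass-independent, so a single per-pixel correction factor

    D(x, y) = T_ref^sub / T_ref(x, y)

derived from one reference peak (Cs⁺, the most intense peak — implanted
everywhere by the sputter source) corrects every species at once:
T′ = T · D. Inverting the shift law gives the surface height per pixel:

    Δh(x, y) = h_ex · (1 − ((t_ac − ΔT)/t_ac)²),

with a detectability floor of ≈ 5 µm set by the 50 ps timing accuracy.

Around this core the package provides: threshold-based mass-segment
detection and lossless cube compression (2,000,000 bins → a few thousand
points at full resolution, with a point-index → m/z calibration map),
uncentered PCA with peak exclusion for chemical mapping, a forward
simulator with ground-truth topography and Poisson counting noise, a
binary cube container, continuous-mode imzML interchange, and a staged
command-line pipeline (`inst/cli/toposims`).

## Worked example

Simulate a root-on-substrate scene, compress, correct, reconstruct the
topography and map the chemistry:

```r
library(TopoSIMS)
geom  <- instrumentGeometry()       # 2 kV, 1.5 mm, 50 ps, K+ at 20.545 us
scene <- makeRootScene(nx = 64, ny = 64, seed = 11)
raw   <- renderScene(scene, geom)
#> RawSpectrumImage 64 x 64 px, 2000000 raw bins, 1798256 total counts

segments <- labelSegments(findSegments(sumSpectrum(raw), threshold = 1000),
                          defaultSpeciesTable(), geom)
cube <- compressCube(raw, segments)
#> CompressedSpectra 64 x 64 px, 2495 points in 11 segments (of 2000000 raw bins)

csSeg <- cubeSegments(cube)[which(S4Vectors::mcols(cubeSegments(cube))$label == "Cs")]
track <- trackReference(cube, csSeg)
field <- correctionField(track, estimateSubstrateTof(track, percentile = 0.9))
#> CorrectionField 64 x 64 px, t_ref^sub = 37.9444 us
#>   D range 0.99999448 - 1.0001067 (4096 valid px)

corrected <- applyCorrection(cube, field)
topo <- reconstructTopography(field, ionSpecies("Cs"), geom)
#> TopographyMap 64 x 64 px (Cs+ reference), 4096 valid
#>   height range 0 - 210 um

pca <- spectraPCA(excludeSpecies(corrected, c("K", "Cs", "Cs2")), nComponents = 6)
#> PCAResult: 6 components over 1634 points (uncentered)
#>   explained variance: 0.484, 0.0154, 0.00906, 0.00874, 0.00845, 0.00806
```

Reading the output: the raw two-million-bin axis collapses to 2,495
points in 11 segments with nothing lost inside them; the correction
factor D stays within ~10⁻⁴ of unity (a few nanoseconds over tens of
microseconds) yet encodes the full 200 µm ridge; the reconstructed
topography recovers the half-cylindrical root to ≈ 4 µm RMSE against the
simulator's ground truth; and after excluding the saturated K⁺ peak and
the implanted Cs⁺/Cs₂⁺ peaks, component 1 of the uncentered PCA is the
mean spectrum while component 2's loading map separates the silicon
substrate from the root.

The same flow runs from the shell:

```sh
Rscript inst/cli/toposims run-all --seed 11 --out-dir out/
```

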