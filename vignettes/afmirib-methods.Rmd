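---
title: "Methods: AFM-IR map and spectrum analysis for bacterial inclusion bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AFM-IR map and spectrum analysis for bacterial inclusion bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the problem

Atomic force microscopy-based infrared spectroscopy (AFM-IR, also called
PTIR) reads out local infrared absorption through the photothermal expansion
of the sample under a sharp probe, reaching ~10 nm lateral resolution --
far below the Abbe limit of conventional infrared microscopy. Applied to
thin sections of epoxy-embedded bacteria, it resolves inclusion bodies
(IBs): insoluble aggregates of misfolded protein that are enriched in
β-sheet secondary structure. In the amide I region, β-sheets absorb around
1620-1640 cm⁻¹ (and 1674-1700 cm⁻¹), while α-helices and disordered chains
absorb near 1654 cm⁻¹. Two quantities drive everything downstream:

* the **β-sheet ratio** of a pixel, the 1625/1650 cm⁻¹ IR-amplitude ratio,
  and the **β-sheet enrichment** of an IB, the mean ratio inside the IB
  divided by the mean ratio over its host cell's cytoplasm -- a
  ratio-of-ratios that cancels global intensity factors (laser power, probe
  contact quality);
* the **PLL frequency**, the laser pulse rate a phase-locked loop keeps at
  the tip-sample contact resonance; its local shifts report stiffness
  contrast (but not an absolute modulus).

An acquisition consists of co-registered channel maps (Height, Deflection,
IR Amplitude, PLL Frequency, IR Phase; IR channels in both trace and
retrace scan directions) at 1650 cm⁻¹ and then at 1625 cm⁻¹, plus point
spectra (800-1800 cm⁻¹ at 2 cm⁻¹) on IBs, cytoplasm, and the epoxy
background of each measurement session.

## Pipeline overview

```
spectra:  emission-normalised input -> / session epoxy mean
          -> min-max rescale over 1600-1800 cm^-1
          -> band quantification (1615-1635 integral, band means,
             Savitzky-Golay second derivatives, PLL reduction)

maps:     1625 registered onto 1650 (rigid -> affine, height-map NCC)
          -> PLL line-drift correction (epoxy line means, rolling mean)
          -> ratio map -> segmentation (cells, then per-cell triangle
             threshold + opening for IBs) -> per-IB features -> statistics
```

Every stage is exposed as a function (`epoxyNormalize()`,
`registerPair()`, `correctPllMap()`, `segmentCells()`, `segmentIbs()`,
`extractIbFeatures()`, ...), with `runPipeline()` and the `inst/cli/ibspec`
script tying them together.

## Spectral processing

Input spectra are assumed already normalised by the laser emission
spectrum. The chain divides by the pointwise mean of the session's epoxy
(background) spectra -- cancelling slow drifts of probe and laser within a
session -- and then min-max rescales so the minimum over 1600-1800 cm⁻¹ is
0 and the maximum 1. The affine rescale is applied to the **whole**
spectrum using the window extrema, so values outside the window may leave
[0, 1]; window endpoints are inclusive.

Numerical choices:

* **β-sheet content** is the trapezoid integral over 1615-1635 cm⁻¹ on the
  native grid. The band endpoints are odd wavenumbers and fall between the
  even grid points, so the integral is taken over the piecewise-linear
  interpolant; a unit-amplitude spectrum integrates exactly to the band
  width (20 a.u.·cm⁻¹). The grid (2 cm⁻¹) is fine relative to amide-I
  sub-bands, so no higher-order rule is warranted.
* **Band intensity** (`bandIntensity()`, e.g. "around 1628" or
  "around 1678 cm⁻¹") is the *mean* amplitude over an inclusive
  ±5 cm⁻¹ window, not an integral, so values are comparable across window
  widths. Both the integral and the band mean are provided because the two
  quantifications are used for different figures of merit and are not
  interchangeable; we do not unify them.
* **Second derivatives** use a Savitzky-Golay filter, default 9 points
  (16 cm⁻¹) and cubic order: wide enough to suppress noise, narrow enough
  to resolve 10-20 cm⁻¹ sub-bands. The filter is exact on polynomials up
  to the fit order, which the tests exploit. Absorption bands appear as
  negative minima.
* **PLL reduction** of a spectrum is the mean PLL frequency over
  1600-1650 cm⁻¹ minus the session epoxy PLL reference, in kHz.

## Registration

The 1625 cm⁻¹ scan is acquired after the 1650 cm⁻¹ scan; stage drift in
between displaces it, and drift *during* the slow scan shears it (rows are
acquired over minutes, so a drift velocity becomes a displacement
proportional to the row index). Registration estimates a pixel-coordinate
affine transform `M` mapping reference (1650) coordinates to moving (1625)
coordinates by maximising the normalized cross-correlation (NCC) of the
two Height (trace) maps:

1. **Rigid stage.** Integer translations are scanned by FFT
   cross-correlation (bounded by `maxShiftPx`, default 16 px) with
   quadratic subpixel peak interpolation, inside a coarse rotation grid
   (±3° at 0.5°); the best candidate is refined by Nelder-Mead over
   (θ, dx, dy).
2. **Affine stage.** All six parameters are optimised from the rigid
   optimum, with the singular values of the linear part constrained to
   1 ± 5% -- enough for scan shear of a few percent, while excluding
   degenerate contractions that trivially inflate the NCC.

The paper-level objective (height-map cross-correlation, rigid then
affine) is fixed; the optimizer is our choice. The final transform
resamples every 1625 channel bilinearly onto the reference frame; output
pixels whose source falls outside the frame are masked, and masks
propagate through all downstream operations. On noise-free phantoms the
recovered transform agrees with the planted one to ~0.02 px mean residual
over the cell support; the acceptance suite requires < 0.5 px for
translations up to 10 px and shear up to 3%.

Height maps are used for both stages: they are wavenumber-independent, so
the same structures appear in both acquisitions regardless of chemistry.

## PLL line-drift correction

The PLL frequency drifts slowly and the cantilever's state can jump
between scan lines, producing a per-line baseline on top of the stiffness
signal. The correction computes the mean PLL of epoxy pixels for each scan
line, smooths this profile with a centered rolling mean, and subtracts it
from the whole map. Choices:

* **Window 17 lines.** A window of about 16 lines suppresses per-line
  noise while following drift; a centered rolling mean needs an odd
  length, so the default is 17 (the nearest odd value).
* **Symmetric truncated windows at the edges.** Partial windows that stay
  symmetric around the target line reproduce any *linear* ramp exactly at
  every line, including the first and last; asymmetric partial windows
  would leave an O(slope·window) systematic residual at the map edges.
* Lines without epoxy pixels get their profile value by linear
  interpolation from neighbouring lines and are reported in a message.
* The epoxy mask precedes final segmentation, so the pipeline derives a
  provisional mask from the cell labels (everything ≥ 3 px clear of any
  cell).

Because the 1650 cm⁻¹ acquisition has the stronger IR amplitude, its PLL
map (corrected) is the one summarized per IB.

A note on verifying flatness: after *any* correction -- including
subtracting the true drift profile -- each line's epoxy mean still
contains that line's own noise mean, distributed N(0, σ/√n). A bound of
3 standard errors applied per line therefore fails for some line of a
512- or 128-line map in a sizeable fraction of realisations even for a
perfect correction. The acceptance suite tests the calibrated equivalent:
all lines within the family-corrected 3σ bound, and the RMS of
line-mean/SE at the pure-noise level (~1), against an uncorrected ramp
that sits tens of SE away.

## Segmentation

Pixels are classified into background, cell, and IB on the (registered)
1625 cm⁻¹ amplitude map.

**Cells.** The cell backend is pluggable: any function from an intensity
matrix to an instance label map (this is where an external deep-learning
segmenter would plug in). The built-in fallback is Gaussian smoothing
(σ = 1 px), a global triangle threshold, hole filling, a radius-2 opening,
and a distance-transform watershed split. Whatever the backend, each
instance is eroded by a disk (default radius 2 px) to discard membrane
pixels, instances touching the image border are discarded (partial cells
would bias geometry and polar positions), and labels are renumbered from 1.

**Triangle threshold.** The per-cell IB threshold builds a 64-bin
histogram of the cell's interior intensities, draws a line from the
histogram peak to the farthest non-empty bin, and returns the centre of
the bin maximising the perpendicular distance between histogram and line,
with both axes normalised (span to 1, counts to the peak). 64 bins are
stable for the 10³-10⁴ pixels of a typical cell. The construction is
invariant under affine rescaling of the intensities; ties in distance
(observed at the level of one floating-point ulp) resolve toward the bin
nearest the peak; if the peak is central, the farther tail wins, ties
toward the lower bin. Thresholding is per cell because intensity varies
between cells; a pooled mode exists for sensitivity analysis
(`pooled = TRUE`).

**IBs.** Supra-threshold pixels within each cell are cleaned by a binary
opening with a Euclidean disk of radius 2 px (the same pixel-set
definition the phantom uses to plant disks), pixels outside the eroded
cell mask are discarded, and connected components become IB instances with
recorded cell ownership. The opening imposes a minimum detectable radius
equal to the element radius: a radius-1 disk (5 px) erodes to nothing,
a radius-2 disk (13 px) survives exactly. Components clipped by the mask
edge are kept. Cells with fewer than 16 interior pixels are skipped (their
histogram is unidentifiable).

## Per-IB features

For each IB: area (px and nm², via the pixel geometry
`pixelSizeNm · width_px = 1000 · field_width_um`), equivalent radius
√(area/π) in nm, polar position, β-sheet ratios and enrichment, PLL
contrast (`pll_ib − pll_cp` from the corrected 1650 PLL map), raw
amplitude means, and a thickness proxy (mean height inside the IB minus
the mean epoxy height -- labelled a proxy because true section thickness
is not observable here).

* **Cell geometry** comes from the second moments (inertia tensor) of the
  mask: centroid, orientation, and the full extent of the mask projected
  on the major axis. Isotropic masks (disks) have no defined orientation
  and are flagged degenerate.
* **Polar position** is the signed projection of the IB centroid on the
  major-axis unit vector, normalised by the half extent and clipped to
  [−1, 1]. The axis vector is oriented so its image-x component is
  positive: the positive pole is simply the right-hand one; pole age is
  not observable, so the sign carries no biology. `pole_proximity` is
  defined as |polar_position| (large = close to a pole); the direction of
  this convention is stated in the output docs since either choice is
  defensible.
* **Cytoplasm** of a cell is its eroded mask minus *all* of its IB pixels.
  A cell fully covered by IBs has no cytoplasm; its IBs are flagged
  (`cytoplasm_defined = FALSE`) and excluded from enrichment statistics.
* **Edge-distance profiles** assign every pixel a signed Euclidean
  distance to the nearest IB boundary (distance transforms of the IB mask
  and its complement; positive inside), bin it (default one pixel), and
  report mean ratio and mean corrected PLL per bin with bootstrap CIs;
  outside the IBs only cell pixels contribute. `fitEdgeWidth()` fits a
  logistic transition and reports the boundary width as 4σ of the matched
  Gaussian edge blur (σ = 1.702 · logistic scale), the convention under
  which a sharp step blurred with Gaussian σ has width 4σ.

## Statistics

* **Test-selection tree** (`chooseAndRunTest()`): Shapiro normality per
  group and Bartlett homoscedasticity across groups decide between
  one-way ANOVA and Kruskal-Wallis. The pre-test p values are
  Bonferroni-adjusted over the pre-test family (k + 1 tests) before
  comparison with α = 0.05: without the adjustment the chance of an
  unwarranted switch to the nonparametric branch grows with the number of
  groups (~19% already at k = 3 under a true Gaussian null), and the
  screen would not be calibrated at α. `pretestCorrection = "none"` gives
  the uncorrected rule. The report records raw and adjusted pre-test p
  values, the branch taken, and the post hoc table.
* **Post hocs**: Tukey HSD (all pairs) or Dunnett (versus control, via
  multivariate-t) on the ANOVA branch -- both control the family-wise rate
  by construction, so their recorded extra-adjustment count is 1; Dunn's
  rank test with Bonferroni on the Kruskal-Wallis branch (the companion
  test is not named in the underlying protocol; Dunn is our choice and
  marked as such).
* **Bonferroni is uncapped by default**: adjusted p values above 1 (2.2,
  9, ...) are reported as such, keeping heavily corrected
  non-significances distinguishable; `cap = TRUE` clips conventionally.
  The adjustment count is always recorded so corrections are never
  silently stacked.
* **Bootstrap CIs** are percentile intervals (default 9999 resamples,
  seed-deterministic). Percentile rather than BCa matches the plain "95%
  CI by bootstrap" convention; for the near-symmetric statistics used
  here the difference is small.
* **Correlation matrices**: Pearson correlations between all property
  pairs are computed within each dataset; the per-pair set of
  correlations (one r per dataset) is bootstrap-resampled (9999) to test
  its mean against zero by a two-sided percentile test, Bonferroni-
  corrected over the number of pairs. Resampling the *set of r values*
  (rather than IBs within datasets) treats the dataset, not the IB, as
  the sampling unit. Constant properties within a dataset yield no r
  there and that dataset is excluded for the affected pairs.
* **PCA** is mean-centered with a deterministic sign convention (the
  largest-magnitude loading of each component is positive).
  `embedSpectra()` exposes a pluggable 2D embedding: built-in linear PCA
  and classical MDS backends, or any user function run under a fixed
  seed -- a nonlinear embedding (e.g. UMAP via an external runtime) plugs
  in without code changes.

## The phantom generator

`makePhantom()` builds scenes with full ground truth so every stage is
testable without instrument data. It emulates the *statistical* structure
the pipeline assumes:

* epoxy background plus elliptical cell cross-sections with uniformly
  random orientation (bacteria are sectioned at random 3D orientations,
  so 2D outlines are tilted ellipses of varying aspect);
* disk-shaped IBs at integer-pixel centres (so rasterised disks match the
  Euclidean disk definition shared with the opening element and the
  detection floor is exact), separated by > 2 px, clipped to their cell
  and flagged when clipped;
* β-sheet contrast: the 1650 map is flat over the cell, the 1625 map
  carries `ratioCp` in cytoplasm and `betaEnrichmentTrue · ratioCp` in
  IBs;
* optional Gaussian edge blur applied to both wavelength maps (a shared
  PSF), making IB boundaries diffuse;
* inter-map drift: translation plus scan shear applied to the 1625
  acquisition (the later scan), sampled from a padded scene so the
  drifted field of view contains real "sample", as on a real stage;
* PLL maps: base rate (880 kHz) plus the IB stiffness offset, a per-line
  drift ramp and per-pixel noise; Height maps carry elliptical dome
  relief (the registration signal); trace/retrace copies differ by
  independent noise.

Defaults are the acquisition geometry of a 20 × 20 µm, 512 × 512 px map
(39 nm pixels) with 12 cells; enrichment 1.15 (the imaging-mode scale of
enrichment values, which run lower than spectral ones), IB radii 2-6 px
around the ~85 nm scale, PLL offset 0.35 kHz (the observed IB-cytoplasm
stiffness contrast is a few tenths of a kHz), edge blur σ = 0.8 px
(≈120 nm boundary width at 39 nm pixels), drift (4, −3) px with 1% shear
(5-10 nm/min over minutes-long scans), 2% amplitude noise. Tests and the
acceptance script run 64-128 px scenes with the same 39 nm pixel -- the
package's choice of problem size; every property tested is
size-independent.

What the phantom does **not** model -- and hence what passing tests do not
show about real data: no photothermal forward physics or probe-shape
convolution (amplitudes are set, not derived), additive Gaussian noise
only (no scan-line artefacts, knife marks, or heavy-tailed outliers
beyond an optional flag), flat epoxy chemistry, and cells that never
overlap. Recovery results on phantoms certify the algorithms, not the
instrument.

## Verification design notes

* Enrichment recovery (slope of estimated on true enrichment across
  phantoms spanning 1.0-2.0) is evaluated on ground-truth masks: at true
  enrichment exactly 1.0 there is no contrast, so no detector can find
  the IBs -- the per-cell threshold correctly raises an error on a
  constant histogram. Detection-based recovery (counts exact, areas
  within ±15%, the ±15% covering edge discretisation plus the opening's
  erosion-dilation bias) is tested separately at enrichment ≥ 1.2.
* The registration-benefit check also uses ground-truth masks, which live
  in the reference frame: without correction the masks miss the drifted
  1625 signal and enrichment collapses toward 1; after correction it
  returns to the planted value (within 5%; bilinear interpolation softens
  one boundary ring, costing ~2%).
* The triangle threshold is verified against an independent brute-force
  implementation of the peak-to-tail perpendicular-distance construction
  (exact bin agreement on 100 random histograms), and the registration
  lag against an exhaustive integer-lag scan.

## Known limitations

* The fallback cell backend is intensity-based; on real data with touching
  cells or textured epoxy a trained instance segmenter should be plugged
  in through the backend contract.
* The affine registration assumes drift is well approximated by one global
  affine transform; strongly nonuniform drift within a scan is out of
  scope (no deformable registration).
* PLL-derived quantities are stiffness *contrasts*; no Young's modulus is
  estimated.
* Uncapped Bonferroni values are p-value transforms for reporting; they
  are not probabilities once above 1.
* The container format stores raw little-endian float64 arrays with a JSON
  manifest; it is deliberately trivial to parse anywhere, but it is not a
  hierarchical scientific container, and vendor instrument formats are not
  parsed (convert via TIFF/CSV).
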