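---
title: "laminscape: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{laminscape: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminscape)
```

## Scope

`laminscape` quantifies how perturbing the nuclear lamina reshapes genome
organization across scales: mesoscale chromatin folding read out from Hi-C
contact matrices, radial positioning of chromosomes, heterochromatin and
gene loci read out from fluorescence and localization microscopy, chromatin
mobility read out from spectroscopic interference time series, and
transcriptional consequences read out from differential-expression tables.
The package consumes processed inputs — balanced contact matrices, DamID LAD
interval tracks, segmented nucleus masks, localization tables,
spectral/temporal image cubes, DEG tables — and owns every statistic
computed on top of them.  Upstream steps (read alignment, matrix balancing,
domain calling, differential-expression model fitting, single-molecule
localization fitting) are deliberately out of scope; their outputs are
inputs here.

Because the raw microscopy and sequencing data behind such a study are far
beyond desk scale, every analysis stage is paired with a seeded synthetic
generator that plants known structure.  The package's validation story is
recovery: each statistic is tested for recovering its generator's truth at
a sample size where the test has power, plus exact identities (partition
sums, closed forms, brute-force oracles) where the mathematics allows.

## Contact-probability scaling

The probability of contact between two loci separated by `N` bp along the
chain is modelled as a power law `P(N) ∝ N^−s`; the exponent magnitude
`|s|` summarizes how fast contacts decay and is the primary mesoscale
folding statistic.  Lamina-associated domains (LADs) decay more slowly
(lower `|s|`) than non-LAD chromatin, so the package computes
segment-classified curves: a bin is labelled LAD when at least half of it
(configurable, `labelBins(minOverlap = 0.5)`) is covered by the merged LAD
intervals, and a bin pair contributes to the LAD curve when both anchors
are LAD bins, to the non-LAD curve when neither is, and to the cross curve
otherwise.  Anchors may lie in different LADs: the classification is a
two-class anchor partition, not a same-domain test.

For each separation, `P` is the total contact count over qualifying pairs
divided by the number of qualifying pairs, zero-count pairs included; the
diagonal is excluded.  Distances are pooled into log-spaced bins (8 per
decade by default).  Each bin is reported at the pair-weighted geometric
mean of its constituent separations rather than at the raw bin centre;
with bin-centre reporting a perfect power law would fit with a small
systematic bias (about 0.014 in `|s|` at 8 bins/decade), while the
weighted representative reduces that to under 0.001.  Setting
`distanceBins = "integer"` disables pooling entirely, which is what the
exactness tests use.  `fitExponent()` is ordinary least squares of
`log P` on `log N` over 1e5–1e6 bp, the window in which the power law is
cleanest; `|s| = −slope`.

The synthetic map generator draws Poisson counts around
`scale · d^−s_class` with independent exponents per segment class, then
rescales by one global constant so the grand total matches the requested
sequencing depth (a multiplicative constant, so fitted slopes are
untouched).  At the scale used throughout (1500 bins × 15 kb, ~5e6
contacts) the fit recovers the generator exponent to better than ±0.005,
comfortably inside the ±0.03 recovery band the tests assert.

Three auxiliary statistics share this module: per-chromosome LAD coverage
(merged LAD bp over chromosome length) with an exponential fit
`|s| = a·exp(−b·coverage)` (log-linear initialization refined by
nonlinear least squares); interchromosomal percent-change matrices (mean
trans contact frequency per chromosome pair, zeros included, with an
optional total-sum normalization guard); and the compartment eigenvector —
observed/expected transform with the expected value taken as the
per-distance mean over populated entries, Pearson correlation of O/E
columns, leading eigenvector by eigenvalue magnitude, sign oriented by a
user reference track or, failing that, by making the first nonzero entry
positive so repeated runs agree.  Domain calls (TADs) are inputs; the
package only classes them against LADs (≥ 50% of the domain length by
default) and summarizes sizes.

## Radial nuclear geometry

All radial statistics are defined through the Euclidean distance transform
of the filled nucleus mask, not through angles from the centroid, so
lobed and blebbed nuclei — common after lamin loss — partition sensibly.
The normalized radial coordinate is `ρ = 1 − d_b/d_b,ref`, with `d_b` the
distance to the nearest background pixel and `d_b,ref` its per-nucleus
maximum: `ρ = 0` at the deepest interior point, `ρ → 1` at the boundary,
and for a disk `ρ` agrees with `r/R` to within a pixel.

Three partitions are derived:

* **Rings** (`makeRings`): `K = 10` equal-`ρ` bins, ring 1 central, ring
  10 peripheral.  Under a circular idealization ring `k` has area
  proportional to `2k − 1`, so ring occupancy reports both the raw
  intensity fraction `f_k` and the area-normalized `g_k = f_k/(2k−1)`
  (plus a renormalized version for plotting).  Measured pixel areas are
  attached so users can substitute the empirical-area normalization; on a
  rasterized disk the two agree within 5%.
* **Ribbons** (`makeRibbons`): six boundary-anchored ribbons of fixed
  260 nm physical width plus a central remainder, the segmentation used
  for regional spectroscopic analysis.  Boundary distance is measured
  from the outermost foreground pixel ring (the raster distance transform
  assigns boundary pixels the value 1, so ribbons bin `(d_b − 1)·pixelSize`);
  at 130 nm/px each ribbon is exactly two pixels wide on a disk.
* **Periphery/interior** (`makePeripheryInterior`): the
  localization-microscopy convention — the 8-adjacency boundary contour
  dilated five times with a 5×5 all-ones kernel, clipped to the mask.
  Each pass grows the band by 2 px (Chebyshev), giving an 11 px inward
  extent from a straight edge.  Note the stated intent of this
  construction is a ~100 nm band, which at 26 nm/px it is not (11 px ≈
  290 nm); the construction is implemented as specified, and both the
  iteration count and kernel size are exposed so either reading can be
  configured.  This discrepancy is documented rather than resolved.

The centroid is the mean foreground pixel position and the equivalent
radius is `sqrt(area/π)`, the circular idealization used to normalize
focus-to-centre distances across nuclei.

## Spatial signal statistics

**Ring occupancy** divides per-ring intensity sums by the in-mask total;
across nuclei, conditions are compared by per-ring differences of means
with SEM (`ringOccupancySummary`).

**NSI** (normalized regional intensity for reconstructed localization
images) is the region's mean pixel intensity over the nuclear mean:
`NSI = (Σ s_i/A_mask)/(Σ s_j/A_nuc)`.  It is exactly 1 for uniform
signal, and for any disjoint partition of the nucleus the area-weighted
NSI values sum to exactly 1 — an identity the tests exercise on random
partitions, and a useful sanity check on real segmentations.
Localization images are reconstructed at 26 nm/px as count histograms;
an average-shifted-histogram mode (`m = 2` shifts per axis by default;
the original shift count is not published) is available, and both modes
conserve the event total.

**Coefficient of variation** is `σ/μ` over in-mask pixels with the
population (denominator-`n`) standard deviation by default, switchable to
the sample estimator; the same population convention is used everywhere
in the package so variance-derived quantities compare cleanly.

**Foci distances** are normalized per nucleus by the equivalent radius
(`d/r`); an area-normalized variant is reported alongside.  Normalizing a
distance "by the nuclear area" is dimensionally inconsistent, so the
package reports `d/sqrt(area)` as the meaningful reading and includes the
literal `d/area` column for completeness.  Distances between two locus
label sets are matched by greedy nearest-pair assignment (each focus used
once); the original analyses paired foci in the same focal plane without
specifying an assignment rule, so greedy is the default and an exhaustive
minimum-total-distance assignment is available behind
`method = "optimal"` for small sets.  Foci detection itself is out of
scope: foci arrive as coordinate tables from an external spot localizer.

## Spectroscopic chromatin dynamics

A spectral cube (500–700 nm at 2 nm steps by default) yields the
structural signal `Σ`: each pixel's spectrum is divided by a reference
(bare-substrate reflectance), the spectral mean is removed, and the
population standard deviation over wavelength is returned.  `Σ` is
proportional to nanoscale refractive-index — hence chromatin-density —
fluctuations.  The mapping from `Σ` to the chromatin packing scaling `D`
is instrument-calibrated and lives in dedicated optics literature, so it
is pluggable here: identity, affine, or a monotone tabulated curve
(`sigmaToD`).  The package never invents a calibration.

A temporal cube (single wavelength over time) yields the temporal
variance `Σ_t²` per pixel, converted to **fractional moving mass** by the
physical normalization

```
m_f = Σ_t² · (π ρ₀ / (2 Γ² k³ n_i)) · (NA_i/NA_c)² · (n₁/(n_m − n₁))²
```

with nucleosome dry density ρ₀ = 0.55 g/cm³, illumination wavenumber
k = 1.57e5 cm⁻¹, immersion RI n_i = 1.518, nuclear RI n₁ = 1.37,
nucleosome RI n_m = 1.43, and NA_i = 0.52 / NA_c = 1.49.  The Fresnel
intensity coefficient Γ deliberately has **no default**: it depends on
the reference interface of the particular instrument and no standard
value exists, so the constructor requires it explicitly and
`fresnelGamma(n_a, n_b)` computes the normal-incidence coefficient from a
user-supplied RI pair.  Silently inventing a physical constant would make
`m_f` values quietly non-comparable across instruments.  The prefactor is
attached to the result and verified in the tests against an independently
hand-evaluated constant.

**Diffusion** is summarized as the decay rate of the per-pixel temporal
autocorrelation: the normalized autocovariance is computed at the first
10 lags (configurable) and `exp(−t/τ)` is fitted by least squares on the
log of the positive leading ACF run, excluding lag 0 so uncorrelated
shot noise in the zero-lag variance cannot bias the slope.  Pixels whose
lag-1 autocorrelation is non-positive are noise-dominated; they are
flagged and excluded from regional means (with counts reported) rather
than contributing garbage rates.  Conversion from decay rate to absolute
diffusion units is again instrument-specific and exposed as a single
multiplicative constant.  Regional aggregation averages valid pixels per
ribbon, and paired designs report per-region percent change computed
from per-cell means (differencing per-cell means, not pooling pixels
across cells, which is the more conservative reading of a paired
regional comparison).

The temporal generator is an exact AR(1) discretization of an
Ornstein–Uhlenbeck process — stationary variance and `exp(−t/τ)`
autocorrelation are exact, not asymptotic — so recovery tests compare
against truth, not simulation folklore.  At 1e4 frames the whole-mask
mean `Σ_t²` recovers the generator variance within 5% and the median
decay rate within 10%; a spectrally synthesized series with exactly
exponential circular ACF pins the fitting step itself to 1%.

## Expression divergence

DEG filtering applies the strict thresholds adjusted `P < 0.01` and
`|log2FC| > 1` exactly as printed (boundary records are dropped).
Gene-vs-LAD classification uses any-overlap (≥ 1 bp, raisable) against
the merged LAD track, reporting overlap width, gap distance to the
nearest LAD (0 when overlapping, `Inf` flagged on chromosomes without
LADs) and the relative-distance statistic
`min(d_left, d_right)/(d_left + d_right) ∈ [0, 0.5]` against the flanking
LAD midpoints, whose histogram is flat with mean 0.25 for features placed
independently of LADs.

Transcriptional divergence is the Gini coefficient
`G = Σᵢⱼ|xᵢ − xⱼ| / (2n²x̄)`, computed via the equivalent sorted-rank
`O(n log n)` form and verified against the `O(n²)` double sum.  The
population variant is the default (the estimator used upstream is not
published); the sample variant (`n/(n−1)`) is a switch.  The lognormal
expression generator has the closed-form population Gini `erf(σ/2)`,
which sampled tables recover within 1% at n = 1e5 — the recovery test
anchoring this module.  Whether expression values are TPM, FPKM or
normalized counts is irrelevant to `G` up to the scale invariance the
tests assert; zero filtering is left to the caller and recorded in the
result's `n`.

## Synthetic-data design

Generators are deterministic given `(seed, parameters)` and restore the
caller's RNG state, so adding a call never perturbs earlier streams; a
scene-level counter scheme (`substream`) expands one global seed into
per-generator seeds.  Every stochastic generator has a noiseless
(expected-value) mode for exact tests.  Radial placement densities are
specified as the marginal density of `ρ` with the `2πρ` area weighting
explicit in the contract — a distribution uniform over the nuclear area
is `f(ρ) = 2ρ`, not a constant — avoiding the classic disk-sampling
bias; the uniform-area closed form (mean normalized distance 2/3) is
recovered within 2% at n = 1e4.

What the generators deliberately do not emulate: optical point-spread
functions, polymer-physics chromatin structure (loops and TADs beyond
segment-class power laws), localization drift or multi-emitter
artefacts, and mask segmentation error.  Passing recovery tests
therefore certifies the statistics, not robustness to those upstream
imperfections.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen so each
statistical check has power ≥ 0.9 at α = 0.01 while the whole suite
stays fast: contact maps of 1500 bins × ~5e6 contacts for exponent
recovery (and 80–120 bins for exact identities), 1e4–1e5 events for
localization and foci statistics, 1e4 frames for dynamics recovery
(1.6e4 for the exact-ACF construction), n = 1e5 for the lognormal Gini.
Ties and degenerate inputs are handled explicitly: empty rings, empty
ribbon centres, all-zero intensity, zero-mean CoV, constant matrices,
sub-3-bin fit windows and missing Γ all raise informative errors instead
of returning numbers.

Interval arithmetic is delegated to `GenomicRanges`/`IRanges`, image
morphology and distance transforms to `EBImage`, and nonlinear
refinement to `minpack.lm`; the statistics themselves are implemented in
this package.  The exported functions are the interface; the package is
an analysis library rather than a shell tool, so no command-line wrapper
is shipped — `scripts/acceptance.R` shows the intended scripting
pattern.

## Known limitations

* The Σ→D calibration and the decay-rate→diffusion conversion are
  configuration points, not built-in physics; results in `D` or absolute
  diffusion units are only as good as the supplied calibration.
* Ring geometry on strongly non-convex masks uses boundary-distance
  depth; the `2k−1` weight is a circular idealization, and for such
  shapes the measured-area normalization (also reported) is preferable.
* Greedy focus matching can exceed the optimal assignment cost on
  adversarial configurations; the exhaustive mode is limited to small
  sets.
* 2D only: z-stacks are expected to be maximum-projected before
  analysis, matching the upstream imaging convention.
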