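# laminscape

Quantitative analytics for studying how the nuclear lamina organizes the
genome — built for experiments that acutely deplete B-type lamins (or
similar lamina perturbations) and ask what happens to mesoscale chromatin
folding, radial nuclear organization, chromatin mobility and gene
expression.

The package is aimed at computational biologists who already have the
processed outputs of such an experiment — balanced Hi-C contact matrices,
a lamin B1 DamID LAD track, segmented nucleus masks and fluorescence
images, SMLM localization tables, spectroscopic (PWS) image cubes, and
DESeq2-style differential-expression tables — and need the downstream
statistics, each of which `laminscape` implements and tests:

* **Contact-probability scaling.** Contacts decay with genomic separation
  as `P(N) ∝ N^−s`. The package builds segment-classified P(s) curves
  (both anchors in LADs / both outside / one of each) and fits `|s|` by
  OLS on log–log over 10⁵–10⁶ bp, plus LAD coverage fractions, the
  exponential coverage–exponent relation `|s| = a·e^(−b·cov)`,
  interchromosomal percent-change matrices, compartment eigenvectors
  (first eigenvector of the O/E correlation matrix), and TAD-vs-LAD size
  summaries for externally called domains.
* **Radial geometry & signal.** Ten concentric rings of equal normalized
  radius with the `2k−1` area normalization for ring occupancy, 260-nm
  boundary ribbons for regional spectroscopy, the dilated-contour
  periphery/interior split for SMLM, NSI
  (`(Σsᵢ/A_mask)/(Σsⱼ/A_nuc)`), coefficient of variation `σ/μ`,
  average-shifted-histogram reconstruction at 26 nm/px, and
  focus-to-centroid / focus-pair distances normalized by the equivalent
  nuclear radius `√(area/π)`.
* **Chromatin dynamics.** Spectral-variance Σ maps, pluggable Σ→D
  calibration, temporal variance Σ_t², the fractional-moving-mass
  normalization
  `m_f = Σ_t²·(πρ₀/(2Γ²k³n_i))·(NA_i/NA_c)²·(n₁/(n_m−n₁))²`,
  ACF-decay diffusion maps, and per-ribbon regional means with percent
  changes.
* **Expression divergence.** Strict DEG filtering (padj < 0.01,
  |log2FC| > 1), gene-vs-LAD classification with coverage / closest /
  relative-distance semantics, within/outside-LAD tallies, and the Gini
  coefficient of transcriptional divergence.
* **Synthetic data.** Seeded generators for every input class
  (elliptical nuclei, radial intensity fields, foci, localizations,
  power-law contact maps with LAD layouts, AR(1) temporal cubes,
  spectral cubes, lognormal expression, planted gene/LAD layouts) with
  analytically known truth, so the full pipeline is testable with no
  data downloads.

## Worked example

```r
library(laminscape)

## 1. A LAD-like chromosome: slow contact decay, recovered by the fit
sim <- simCisContactMap(1500, 15000, rep(TRUE, 1500), list(lad = 0.862),
                        totalContacts = 5e6, seed = 7)
fit <- fitExponent(scalingCurve(sim$matrix, sim$labels, "LAD"))
#> fitted |s| = 0.862 (R^2 = 1.0000, 8 distance bins)

## 2. Radial occupancy of a peripherally enriched signal
nuc <- simNucleusMask(128, 128, 130, c(6500, 5200), id = "cell01")
#> NucleusMask 'cell01': 128x128 px @ 130 nm/px, area 6284 px (106.2 um^2)
rings <- makeRings(nuc)                      # ring 1 centre ... 10 periphery
img <- simRadialImage(nuc, function(rho) as.numeric(rho > 0.8), 1e5,
                      "poisson", seed = 2)
ringOccupancy(img, rings)[8:10, c("ring", "fraction", "weight", "normalized")]
#>    ring fraction weight normalized
#> 8     8   0.0000     15     0.0000
#> 9     9   0.5211     17     0.0307
#> 10   10   0.4789     19     0.0252

## 3. Transcriptional divergence of a lognormal expression table
g <- gini(simExpression(1e5, 1, seed = 5)$expression)
#> sample Gini = 0.5253 vs closed form erf(1/2) = 0.5205
```

Reading the numbers: the generated contact map decays with the planted
LAD-segment exponent and the segment-classified fit recovers it to three
decimals; the simulated signal confined to normalized radius > 0.8 lands
almost entirely in rings 9–10 (the nuclear periphery), and after the
`2k−1` area normalization the per-ring values become comparable across
rings; the sampled Gini coefficient of a lognormal(0, 1) expression table
matches its closed form `erf(σ/2)` within 1%.

## Package layout

S4 classes (`NucleusMask`, `RegionPartition`, `ContactMatrix`,
`ImageStack`, `OpticalConstants`) carry the data; camelCase functions
(`makeRings`, `ringOccupancy`, `computeNsi`, `computeSigma`,
`fractionalMovingMass`, `diffusionMap`, `scalingCurve`, `fitExponent`,
`classifyGenesVsLads`, `gini`, `sim*` generators) do the work.  See
`vignettes/laminscape-methods.Rmd` for the models, parameter defaults and
design decisions.
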