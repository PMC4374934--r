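---
title: "Models and methods behind rgcmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rgcmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ocular hypertension (OHT) induced by laser photocoagulation of the
limbal and episcleral veins kills retinal ganglion cells (RGCs) in two
characteristic spatial patterns: pie-shaped sectors with the apex at the
optic disc and the base at the retinal periphery (the signature of
axon-bundle damage at the optic nerve head), superimposed on diffuse
loss across the whole wholemount. Damage propagates centrally: the
retinotectal terminals innervating the contralateral superior colliculus
(SC) retract, measurable as a shrinking CTB-labelled area on serial
coronal sections. `rgcmap` implements the quantification chain for this
model — from raw frame montages to cohort-level percentages — together
with a synthetic generator that makes every stage testable without
microscopy data.

# Coordinate and orientation conventions

All retinal coordinates are millimetres relative to the optic disc
(origin). For a left-eye wholemount viewed from the vitreal side, +x is
nasal and +y superior. Azimuths are degrees measured from the temporal
axis increasing towards superior (temporal 0°, superior 90°, nasal 180°,
inferior 270°); the deepest radial relieving cut marks the superior
pole, which is how real preparations are oriented. Images use 0-based
top-left pixel origin with y increasing downward; `mm_to_px`/`px_to_mm`
are the single conversion point and are inverse-consistent to 1e-12.

# The synthetic wholemount

`generate_population()` draws an inhomogeneous Poisson pattern: the
realized count is Poisson with mean `target_total` and positions are
i.i.d. from the density profile by rejection sampling inside the
contour. Defaults state the experimental world:

* **Geometry** — a 2.2 mm disc. The adult C57BL/6 wholemount spans
  roughly 4.4 mm tip to tip; the radius is configurable because the
  source measurements never state retinal dimensions.
* **Population targets** — control group means: OHSt-traced RGCs 38,479,
  Brn3a+ RGCs 37,936, melanopsin RGCs 1,059, non-RGC ganglion-cell-layer
  nuclei 45,471.
* **Radial profile** — density declining linearly from centre to
  periphery with a 2:1 ratio. Only "central higher than peripheral" is
  documented; 2:1 is a conservative mid-range choice and is a parameter.
* **Melanopsin anisotropy** — a cosine bump centred on the
  dorso-temporal quadrant (azimuth 45°), 2:1 peak:trough, reflecting the
  documented dorso-temporal enrichment; again only the direction of the
  effect is documented, not its size.
* **Hard core** — `min_separation_mm` (default 0) optionally enforces a
  soma-exclusion distance by sequential rejection. Mouse RGC somata are
  ~8–15 µm wide, so two cells cannot sit 1 µm apart; image-rendering
  fixtures use 8 µm. The default stays 0 so the pattern is exactly the
  Poisson process the analytical expectations assume.

`apply_lesion()` removes each cell in a wedge with that wedge's loss
fraction (overlapping wedges compound as `1 − Π(1 − f_i)`), then removes
survivors independently with the diffuse fraction. Survivors keep their
exact coordinates, which gives the tests a machine-checkable subset
property. Whether diffuse loss is eccentricity-dependent is unknown;
both options exist (`diffuse_profile`), uniform is the default.

The renderer projects cells as Gaussian blobs (σ = 1.5 px) on a
background of 500 counts with amplitude 3,000, Poisson shot noise and
30-count Gaussian read noise, quantized to 16 bits. Frame size 0.45 ×
0.34 mm at 1.25 µm/px stands in for a 20× field; nothing about the real
camera is documented, so these are declared, realistic defaults chosen
once. What the generator does **not** emulate: uneven illumination and
vignetting, soma-size and brightness heterogeneity, debris and blood
vessels, focal-plane variation, and tracer leakage. A green detection
test therefore establishes correctness of the algorithmic chain on
clean-but-noisy data, not field robustness.

# Cell detection

The published counts came from an undisclosed commercial macro, so the
package ships a conventional, fully specified detector: band-pass
enhancement by difference of Gaussians at (σ, 1.6σ); Otsu threshold on
the positive response (the negative lobe is background by construction);
8-connected components; area band 3–400 px; intensity-weighted sub-pixel
centroids; peaks closer than 2 px merged to the larger integrated
intensity with lexicographic pixel order breaking exact ties, making the
pipeline deterministic. Blank or saturated montages warn and return an
empty map rather than erroring, since a montage with no signal is a real
possibility in a damaged retina. On the default synthetic world at
4,000 cells/mm² with an 8 µm hard core, recall and precision are both
≥ 0.95 (in practice 1.00 on the test fixture).

# Topography

**Isodensity maps.** Square 0.1 mm quadrats (the historical "quadrant
analysis" geometry is in prior literature, not restated; 0.1 mm gives
map granularity comparable to the published figures with stable per-bin
counts). Bins straddling the contour are normalized by the clipped area,
estimated on a deterministic 8 × 8 sub-grid of bin-centre probes — a
~1.5% worst-case area quantization that only affects rim bins. Bins
fully outside the contour are `NA`, never zero: absence of retina is not
absence of cells. The count matrix always sums to the in-contour count
exactly (conservation is asserted, not approximated). Colour scales are
linear with a saturating top bin: 0 → ≥ 4,800 cells/mm² for RGC
populations and 0 → ≥ 9,200 for GCL nuclei, 12 steps.

**Neighbour maps.** Closed-ball counting (ties at exactly r count) with
r = 0.165 mm, the radius used for melanopsin maps; the focal cell is
excluded — whether the original tool counted it is unknown, so the
choice is documented rather than claimed faithful. No edge correction is
applied, matching apparent original usage; analytical expectation checks
(mean ≈ λπr²) are restricted to cells ≥ r from the contour. Counts are
computed by grid bucketing in C++ and are verified exactly against an
O(n²) pairwise oracle.

**Wedge profiles.** 24 equal sectors (15° each) about the optic disc, so
a small pie-shaped sector still spans a wedge. Per-wedge loss is
`1 − n_exp/n_ctrl`, `NA` where the control wedge is empty (never
infinite). Sector detection uses an adaptive working threshold
`max(0.2, 0.5 × max wedge loss)` rather than a fixed high cut: a fixed
"few to none" threshold (≈ 0.8) cannot detect a 50%-loss sector, which
the recovery contract requires. The sector's loss fraction is estimated
from the interior wedges of the detected run (edge wedges are usually
only partially covered by the true sector and would bias the estimate
down), and its span from the total loss mass divided by the estimated
fraction, which is unbiased under partial edge coverage. Recovery on
38,000-cell patterns is within ±0.05 in f and one wedge width in span
across f ∈ {0.5, 0.8, 1.0}.

# SC volumetry

Labelled area vs Bregma is fitted with an order-5 least-squares
polynomial on usable sections only (≥ degree + 2 required). The
predictor is recentred to the midpoint of the observed range purely for
conditioning — a raw quintic in coordinates near −4 mm loses ~8 digits —
and coefficients are reported in both bases. r² is computed on the raw
response as `1 − SS_res/SS_tot`; a constant series (SS_tot = 0) is an
exact fit and reported as r² = 1. The observed quality regime in usable
preparations is r² > 0.78, so poorer fits warn (a flag on the result)
but are not rejected: fit quality is an observation, not a gate.

Volume is the closed-form definite integral of the fitted polynomial,
with negative excursions clipped to zero first (areas are physical):
the integration range is split at the real roots of the quintic
(`polyroot`, imaginary parts below 1e-7 relative) and only positive
sub-intervals contribute. Clipped integration matches composite Simpson
quadrature to 1e-6 relative, and unclipped noiseless recovery is exact
to 1e-8. The default integration range is the observed span of usable
sections, not the nominal −3.08..−4.72 mm: whether the original analysis
extrapolated over unusable end sections is unknown, and not
extrapolating is the conservative choice (configurable).

# Cohort statistics

Inclusion requires an IOP peak strictly greater than 25 mmHg within the
first 48 h (a peak of exactly 25.0 is excluded); animals without an IOP
record are excluded with an explicit reason. Summaries are mean ± sample
SD (n − 1). Percent loss is computed from group means, not the mean of
per-animal ratios — with only this convention do the Table-style control
and treated means reproduce the published 50% (2 weeks) and 62%
(4 weeks) headline losses. Published percentages are integers, so
reported values are rounded half away from zero (base `round()`'s
round-half-even would turn 49.5 into 50 but 62.5 into 62).

The Mann–Whitney U test is exact by full enumeration for combined
n ≤ 16 (the study's arms are 6–8 per group): the observed mid-ranks are
redistributed over all `choose(n, n_A)` group assignments, which handles
ties without approximation; the two-sided p is the probability of a U at
least as far from n_A·n_B/2 as observed. Larger samples fall back to the
normal approximation with tie correction and continuity correction.
Kruskal–Wallis uses the tie-corrected H with a χ²(k−1) p-value and
refuses fewer than three groups. Sidedness is not documented in the
source analyses; two-sided is the default, configurable. No
multiple-testing correction is applied (α = 0.05 per comparison),
matching the original presentation.

# Pipeline and determinism

Every generator takes an explicit seed and restores the caller's RNG
state; a single pipeline seed fans out to stage seeds through a Lehmer
step kept below 2³¹. Identical config + seed reproduce byte-identical
CSVs and identical manifest MD5 hashes. Tiles are stored as plain-text
16-bit PGM (P2) with a JSON sidecar — a lossless single-channel
container chosen because the environment provides no TIFF codec for R;
the round-trip is exact and tested.

# Known limitations

* The detector is a declared stand-in; its size/intensity cut-offs are
  not claimed faithful to the original macro's (undisclosed) criteria.
* Contour-clipped bin areas are sub-grid estimates, not exact polygon
  clipping; the error is confined to rim bins and below the Poisson
  noise of their counts.
* The demo cohort's inter-animal variability is purely Poisson +
  lesion-sampling; the real model's large inter-animal spread (SDs up to
  ~97% of the mean in treated groups) is not emulated, so simulated
  p-values are more optimistic than experimental ones.
* SC deafferentation percentages, cross-population r² values and IOP
  curves from the original cohorts cannot be reproduced without the
  original microscopy; the suite instead verifies the arithmetic chain
  on synthetic ground truth.
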