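---
title: "Minutia polygon models: method, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minutia polygon models: method, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfinger)
```

## The model

`polyfinger` matches fingerprints minutia by minutia. Each validated
minutia is represented by the set of all valid $n$-vertex polygons whose
vertices are neighboring minutiae surrounding it, and each polygon is
stored as the fixed-length vector

$$(e_1, \dots, e_n,\; a_1, \dots, a_n)$$

of its cyclic edge lengths (pixels) and the central angles at the
reference (degrees, summing to 360). Because the vector uses only
distances and relative angles, and its cyclic order is anchored at the
largest edge, it is invariant under any rotation and translation of the
print. Matching one minutia against another reduces to a nearest-neighbor
search between two small sets of such vectors; matching two prints reduces
to counting how many minutiae find a validated counterpart.

The working assumptions are those of minutiae-based verification
generally: the extractor finds mostly the same minutiae in two impressions
of one finger, the deformation between impressions is approximately rigid
at the scale of a polygon's neighborhood, and impostor prints rarely
reproduce the *local constellation* around many minutiae at once. The
redundancy of representing one minutia by many polygons is the method's
hedge against spurious and missed minutiae: a single surviving true
polygon suffices to validate the minutia.

## Pipeline stages and their parameters

**Enhancement** (`enhance_fingerprint`). Segmentation keeps 16×16 px
blocks whose standardized gray variance is at least `variance_threshold`
(default 0.1); normalization brings the image to mean 0, variance 1;
orientation is estimated per block by the least-mean-square gradient
method and smoothed in the doubled-angle domain (`smooth_sigma` = 1
block); ridge frequency comes from peak spacing of the profile sampled
perpendicular to the ridges, accepted only for wavelengths of 3–25 px
(plausible ridge periods at 500 dpi) and interpolated from valid neighbor
blocks otherwise; Gabor kernels use $\sigma_x = \sigma_y = 0.5/f$
truncated at $3\sigma$, are zero-mean, and are binarized at 0; thinning is
Zhang–Suen. Block size 16 and the Gabor parameterization are the standard
choices for 500 dpi imagery; the source method delegates this whole stage
to the classical enhancement literature without printing numbers, so every
preprocessing constant here is a package-level default, chosen once and
documented, not a reproduced value. Orientation is measured
counter-clockwise from the +x axis (columns) in the x-right/y-down pixel
frame, range $[0, \pi)$; coordinates are 0-based throughout.

**Extraction and validation** (`extract_minutiae`, `validate_minutiae`).
Crossing Numbers classifies each interior skeleton pixel; CN 1 and CN 3
become terminations and bifurcations. Validation applies, in order:

1. *Same-type distance* δ (default 10 px): every same-type pair closer
   than δ is removed — both members. The source describes exclusion
   without saying which member survives; we drop both because a tight
   same-type pair signals a spur or bridge artifact in which neither
   point is trustworthy.
2. *Region of interest* γ (default 10 px): the convex hull of the set is
   eroded γ pixels inward. We realize the erosion exactly as
   distance-to-boundary thresholding (equivalent to morphological erosion
   by a disk, with no rasterization error), so hull vertices always fall.
   The hull itself is computed by Andrew's monotone chain; the hull of a
   point set is unique, so the choice of construction algorithm does not
   affect the result.
3. *Cloud averaging* (`cloud_radius`, default = δ): connected components
   of the graph linking minutiae closer than the radius collapse to their
   centroid as a new "averaged" minutia. Components, rather than single
   pairs, so that chains collapse to one point. Averaged minutiae carry no
   type downstream — descriptors never use type.

**Polygon model** (`build_model`). The neighbor search grows a circle in
`r_step` = 5 px increments to at most `r_max` = 120 px, stopping at the
first radius holding at least $n+2$ neighbors with at least one per
axis-aligned quadrant (points exactly on an axis count toward the
lower-index quadrant). If the cap is reached, any set of at least $n$
neighbors is accepted with the quadrant condition waived — the stated
relaxation that increases how many minutiae register. Neither `r_step`
nor `r_max` is printed in the source; 5 and 120 px are our defaults
(120 px ≈ 40% of a 300 px print — a neighborhood still plausibly rigid).
A candidate $n$-subset is ordered counter-clockwise by angle around the
reference; it is a valid polygon exactly when the largest angular gap is
below 180°, which for angularly sorted vertices is equivalent to the
polygon being closed, simple, hole-free and strictly containing the
reference. Subsets with two vertices at identical angles are discarded
(only the subset, not the minutia). Counter-clockwise ordering means
mirror images produce different descriptors — acceptable, since rigid
motion of a print never mirrors it.

**Matching** (`match_fingerprints`). For a minutia pair, only the single
minimum-distance descriptor pair is validated; a farther pair that would
pass is never consulted. Validation is element-wise with OR semantics per
slot: relative error $100|a-b|/\max(a,b) \le$ THREL, *or* absolute
difference within THL (edges) / THA (angles). OR is the only reading
under which the method's own commentary is coherent — small edges fail
the relative criterion and are rescued by the absolute one, and
tightening THREL shifts work onto the absolute thresholds. The
denominator $\max(a,b)$ is symmetric and division-safe. Validated
candidates become one-to-one greedily by ascending distance with
deterministic index tie-breaks; one minutia can therefore never inflate
the count. The Euclidean distance itself mixes pixels and degrees
unweighted — it only ranks polygon pairs of the same minutia pair, while
all unit-aware thresholding happens in validation. Defaults THREL = 11,
THL = 5, THA = 10, TMC = 12 are the best configuration reported for
optical 500 dpi data.

**Evaluation** (`metrics`, `sweep_tmc`). Standard definitions:
precision TP/(TP+FP), recall TP/(TP+FN), F1 the harmonic mean,
FMR FP/(FP+TN), FNMR FN/(FN+TP); zero-denominator metrics are `NA`, never
silently 0. One published variant prints recall as TP/(TP+TN), which
contradicts its own prose definition; we treat it as a typo, implement
the standard form, and expose the literal form behind
`literal_recall = TRUE` for reproduction only. The threshold sweep
evaluates both error rates on all half-integer thresholds spanning
[min−1, max+1] of the observed counts (counts are integers, so this grid
captures every decision boundary) with match declared at count ≥ t, and
reads the EER off the crossing of the piecewise-linear interpolated
curves — hence real-valued equal-error thresholds like 9.5.

## What the synthetic generator does and does not establish

`generate_minutia_set` scatters k = 30 minutiae uniformly over a
300×300 px extent with a minimum pairwise spacing of 2δ = 20 px, so an
unperturbed set passes validation untouched; `perturb_minutia_set`
composes a rigid transform, Gaussian jitter, dropout and spurious
insertions (spurious points obey the same spacing rule, so they form
plausible false vertices). `run_benchmark` mirrors a
verification-competition protocol at desk scale: impressions of one
finger are genuine pairs, first impressions of different fingers impostor
pairs; non-first impressions receive a random rotation in ±30° and
translation in ±5% of the extent on top of the configured noise.
"Moderate perturbation" in the tests means jitter 1.5 px, drop rate 0.1,
spurious rate 0.1 — roughly the localization error and extractor
miss/false-alarm rates one expects from decent-quality optical captures.

The point-set path is the primary test surface for the polygon and
matching mathematics: it gives exact ground truth, which image-derived
minutiae never do. The ridge-image generator (plane sinusoids of known
orientation and wavelength, optionally noisy) tests the enhancement
estimators only. A green synthetic suite establishes the geometric and
algorithmic claims — descriptor invariance, alignment-free matching,
separability under moderate noise — but *not* performance on real
fingerprints: real prints add elastic skin distortion, wet/dry artifacts,
partial overlap and correlated extractor errors that the generator
deliberately does not model. Published error rates on the standard
competition databases are sampled from external data we do not ship, and
are therefore out of scope for this package's tests.

## Numerical choices and degenerate inputs

- Canonical rotation ties (several equal largest edges) resolve to the
  lexicographically largest full vector over the tying rotations —
  deterministic, and stable under the floating-point noise of rigid
  transforms at the 1e-6 comparison tolerance used everywhere.
- Angle sums are exact to 1e-6 by construction (gaps of sorted angles).
- Constant images cannot be normalized (error); images with no textured
  block raise "no fingerprint region found"; an all-invalid frequency
  field errors out rather than inventing a wavelength.
- Fewer than 3 non-collinear minutiae make the ROI hull degenerate
  (error); γ beyond the inradius empties the set with a warning.
- Empty models match nothing, with a warning and count 0.
- All randomness flows through explicit seeds; identical seeds give
  byte-identical benchmark reports.

## Known limitations

Pure-R image processing keeps the package dependency-light but is not
optimized for high-volume screening; the enhancement stage targets
300–500 px captures. No minutia orientation attribute is used (the
descriptor does not need it), no global rigid-consistency check is
applied across matched pairs, and no ISO/ANSI template formats are read.
Image I/O is limited to PGM/CSV because no image-decoding package is
assumed at install time.
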