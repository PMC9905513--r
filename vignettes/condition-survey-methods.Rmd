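---
title: "Methods: biodeterioration mapping and pigment arrangement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biodeterioration mapping and pigment arrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artefactscan)
```

This vignette is the package's account of its own science: the models, the
parameters that matter, the numerical choices, what the synthetic fixtures
emulate, and where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Biodeterioration mapping by correlation-coefficient matching

### Model

A template $R$ ($m \times n$) is slid over every same-size window of a
grayscale scene $I$ ($M \times N$); window $(r,s)$ is scored with the
normalized correlation coefficient, giving a map $C$ of dimensions
$(M-m+1) \times (N-n+1)$ (valid mode — no padding, so every score is
computed from full data). Scores lie in $[-1, +1]$; $+1$ means the window
is an affine intensity transform of the template.

**Per-window mean.** The mean subtracted from the scene side is the mean
of *each window*, not of the whole scene. This is the decisive choice: only
the per-window form is invariant to local brightness and contrast changes,
which is what makes the method usable on large fluorescence panoramas with
uneven illumination. The invariance is exercised directly by the test suite
(affine maps $aI + b$ leave $C$ unchanged to $10^{-5}$; $a < 0$ negates
it). The orientation contract is deliberate: matching is same-size,
same-orientation only, and a rotated plant of an asymmetric template is
*not* recovered (also tested).

**Zero-variance windows.** A flat window makes the denominator zero. It
carries no pattern evidence, so it scores 0 and is flagged rather than
producing NaN; flagged pixels can never fire a detection. "Flat" is decided
numerically: window sum of squared deviations $\le 10^{-6} mn$, i.e. a
window standard deviation below $10^{-3}$ intensity units — three orders of
magnitude below anything an 8-bit image can express as real texture.

**Numerics.** The production path computes the numerator with a 2-D FFT
(cross-correlation against the mean-subtracted template, whose zero sum
cancels the window-mean term) and the window means/variances with
summed-area tables; the scene is globally mean-shifted first to tame the
accumulated floating-point error of the prefix sums. The implementation is
algebraically identical to the double loop over windows; the test suite
keeps a literal brute-force transcription as an independent oracle and
requires elementwise agreement to $10^{-6}$ on 50 seeded instances. Scores
are not clamped; tests tolerate $\pm 10^{-6}$ beyond the exact bounds.

### From map to detected areas

Pixels *strictly above* the threshold are detection evidence. Two counting
modes exist because the natural reading of "one box per hot pixel" almost
always over-counts: a genuine match excites a small connected blob of
windows. The default `grouped` mode merges 8-connected above-threshold
pixels into one detected area anchored at the maximum-score pixel (ties
break to the smallest `(row, col)`); `raw` mode keeps one detection per
pixel for fidelity. Each detection carries a template-sized box and the
survey-grid label of the *box centre* — the physical spot one would swab.

### Threshold selection

`sweep_thresholds()` counts grouped detections from high to low threshold
(defaults 0.95 down to 0.40, step 0.01). Counts are non-increasing in the
threshold on every tested family; note this is an empirical regularity of
correlation maps, not a theorem — lowering the threshold can in principle
merge two areas into one.

`select_threshold()` formalizes "set the threshold where the count
increases drastically": it returns the lowest threshold whose next-lower
neighbour multiplies the count by at least `jump_factor` (default 6, the
observed blow-up factor in the motivating survey). The selected value is
the last stable threshold before the blow-up. A sweep with no jump is
flat-ish; the midpoint of the swept range is returned with a warning. When
no sweep is requested, the default working threshold is 0.675 — the
midpoint of the 0.65–0.70 interval in which the motivating survey found a
stable count of about ten areas.

`efficiency(n_detected, n_positive)` is simply
$100\,n_\mathrm{positive}/n_\mathrm{detected}$, reported unrounded and
rounded half-up to integer percent (18 detected, 2 positive → 11.11 → 11%).
The count of areas actually swabbed is carried but deliberately not ordered
against `n_detected`: surveys also sample beyond software hits.

### Survey grid

The grid is a configurable $P \times Q$ array of cells numbered row-major
from 1 at top-left, each cell split into subcolumns A–D and subrows 1–3, so
labels read like `63C3`. The original survey's cell count is not published,
hence the configuration; the labelling scheme itself (A–D, 1–3) is fixed.
A pixel exactly on an interior strip boundary belongs to the lower-indexed
strip — an arbitrary but total and deterministic rule, with
`gridref_to_box()` as its tested left inverse.

## 2. Pigment arrangement in micrograph mosaics

### Colour classification

Crystals are gated in HSV space. Defaults: blue 190–270°, yellow 40–70°,
red 330–20° (wrapping through 0°), all with saturation ≥ 0.3 and value
≥ 0.2 — matched to ultramarine, chrome yellow and vermilion on a dark
embedding medium. Specs are applied in list order and masks are mutually
exclusive. Light pigments on dark layers segment poorly; a class whose mask
covers < 0.05 % of pixels triggers a low-contrast warning naming the class,
surfacing that known weakness instead of silently returning sparse data.

### Segmentation and geometry

8-connected mask components of at least `min_area_px = 4` pixels become
crystals (smaller specks are sub-resolution noise). The centroid is the
unweighted mean of pixel centres (pixel $(r,c)$ has centre $(r+0.5, c+0.5)$
pixel units) converted by the required `scale` (px/µm — the calibration
must come from the microscope; it is never guessed); the area is the pixel
count divided by `scale²`.

Tiles sit on a stage-step lattice: step = tile extent × (1 − overlap), and
tile-local points lift to global µm coordinates by adding the tile origin.
An explicitly supplied step that contradicts extent × (1 − overlap) by more
than $10^{-6}$ relative is a geometry error.

### Overlap deduplication and the common-area index

Tiles are visited in raster order. A crystal from a later tile is dropped
only when (a) its centroid lies inside the field of view of the left or up
neighbour *and* (b) a same-colour crystal is already kept within
`match_radius_um` (default 2 µm — comfortably above centroid error, well
below the hardcore separation of real packings). Distinct crystals sharing
a strip are both kept. The *common-area index* reported alongside is the
mean pairwise overlap fraction (intersection area / tile area) over
4-adjacent tile pairs. The index construction is one plausible reading of
an under-specified original ("average common area between images, used to
decrease the error"); the reading is recorded here precisely because it is
a choice.

### Distance statistics

`pair_distances()` supports two pairing rules because the under-specified
original admits both: `nearest` (default) — for each crystal of class A,
the distance to its nearest distinct class-B crystal — and `all_pairs` —
every unordered pair once. All-pairs statistics are symmetric in the pair;
nearest-mode need not be (a tested, documented property). With
`neighbourhood = TRUE` candidates are restricted to the crystal's own tile
plus the four edge-adjacent tiles, matching how neighbouring photographs
are compared; crystals with no candidate there contribute nothing. The SD
is the sample SD, defined 0 for a single distance. Histograms use
half-open equal-width bins (last bin closed) so counts always sum to $n$;
default 10 bins over $[0, \max]$.

For a Poisson field of intensity $\lambda$ the nearest-neighbour mean
approaches $1/(2\sqrt\lambda)$; the suite verifies recovery within 5 % at
$n > 500$ (the tolerance covers Monte-Carlo spread plus the upward edge
bias of an uncorrected bounded window).

## 3. The synthetic worlds

Everything is a pure function of its recipe (one seed field, a private RNG
stream, caller state restored), so identical recipes give byte-identical
files.

**Scenes** (`make_scene`): planted exact template copies with per-plant
affine jitter ($a T + b$), optional smooth blotchy background, global
Gaussian noise, clamp and round to 8-bit. Default canvas 1024 × 1024 —
desk-scale stand-ins for ~26,000 × 13,700 panoramas; default template sizes
123 × 156 and 83 × 95 mirror the survey's two reference patterns.
Placement is rejection sampling with a `10 × k` attempt budget that fails
loudly rather than under-planting. What the generator does *not* emulate:
real colony morphology, craquelure, varnish fluorescence gradients beyond
affine jitter, or stitching seams — so a green recall test establishes the
detector's contract (affine-invariant recovery of planted patterns under
pixel noise), not field performance on real paintings.

**Knee scenes** (test fixture): the threshold-selection behaviour — about
ten areas stable across 0.65–0.70, then a roughly six-fold jump — needs a
population of "almost-matches" with controlled scores. The fixture plants
10 exact copies plus 60 mixtures built by Gram–Schmidt: template direction
with weight $\rho = 0.63$ plus an orthogonalized rough pattern, giving
*exactly* $\rho$ at the anchor. A rough (iid) orthogonal pattern matters:
a smooth one lets windows shifted a few pixels off an anchor score ~0.02
above $\rho$, blurring the knee. The sweep for this fixture uses step 0.05,
mirroring the coarse exploration implied by a range quoted as 0.65–0.70.

**Mosaics** (`make_mosaic`): a hardcore point process (minimum centre
separation `min_sep_um` across all colours) rendered as filled ellipses
with per-crystal hue/saturation/value jitter kept inside the class gates,
on a dark background. Defaults: blue density 0.01 crystals/µm² (the
observed ~20 crystals per 2000 µm² packing), `min_sep_um = 4`, semi-axes
0.8–1.6 µm. Note 0.01/µm² *cannot* coexist with a 20 µm hardcore distance
(even square packing at 20 µm caps at 0.0025/µm²); the generator's
rejection cap turns such recipes into an explicit feasibility error, and a
test asserts exactly that. A crystal is rendered in a tile only when its
full extent fits inside that tile's field of view: real micrographs clip
crystals at tile edges, but omitting partial views makes every duplicate an
exact re-observation — the property dedup conservation is defined against.
Consequently the fixtures do not exercise clipped-crystal centroid bias;
that is a stated limitation, not an oversight.

**Station logs** (`make_station_log`): sinusoidal diurnal cycles plus
Gaussian noise. `peak_hour` names the clock *hour* of the maximum — the
60-minute bin `summarize_log()` reports — so the continuous sinusoid peaks
at that hour's centre; peaking at the boundary instead would leave two bins
equidistant from the peak and the recovered extremum noise-limited.
Recovery tests use 14 days at 5-minute sampling, a scaled-down stand-in for
a roughly two-month campaign, which keeps the hourly bin-mean noise several
standard deviations below the signal margin. Defaults (23.5 °C, 72.7 %,
570 ppm, maxima at 15:00, minima at 03:00) emulate the monitored room;
means and extrema are recovered by the tests, not asserted as constants.

Spore concentration is plain arithmetic: count / (flow × duration / 1000)
m³, with a multiplicative correction hook defaulting to 1 (no
trap-efficiency correction).

## 4. Known limitations

* TIFF support is a built-in baseline codec (uncompressed, 8-bit, chunky);
  compressed or 16-bit TIFFs are rejected with a clear error. PNG is
  delegated to the png package; 16-bit PNGs are rescaled with a warning.
* Matching is translation-only by design: no rotation, scale or deformation
  invariance, and no colour-channel matching (scenes are converted to
  grayscale with BT.601 weights, rounded half-up).
* Grouped-count monotonicity in the threshold sweep is empirical, not
  guaranteed; pathological maps could merge areas faster than new ones
  appear.
* The published inter-crystal means for the original sample (29/31/41 µm)
  cannot be recomputed here — the raw micrographs are not distributed — so
  the distance pipeline is validated by planted-truth recovery instead.
* Dedup assumes re-observations of a crystal land within `match_radius_um`
  of each other; heavy stage miscalibration would defeat it and is not
  modelled.
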