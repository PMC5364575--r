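---
title: "Slope-difference-distribution segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slope-difference-distribution segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddseg)
```

This vignette is the package's account of the science it implements: the
threshold-selection model, the morphological machinery around it, the
parameters that matter, and the decisions taken where the method leaves
room for interpretation.

## The threshold-selection model

The model assumes a single-channel image whose histogram is approximately
a mixture of a small number of intensity classes — one background class
and one or more object classes, each roughly unimodal (the working
assumption is a Gaussian mixture).  The pipeline works on the image
rescaled to integer gray levels `[0, 255]` (`rescale_to_255()`, rounding
half-up), with the histogram normalized by its modal count so the largest
bin is exactly 1.

Hard truncation of the histogram's DFT spectrum (`dft_lowpass()`, keeping
coefficients `0..W` and their conjugate mirror, then the pointwise
magnitude of the inverse transform) smooths the histogram while leaving
the positions of its features essentially unchanged — unlike FIR/IIR
smoothing, which shifts them.  We use the standard self-inverse
length-256 DFT pair, so that the full band (`W = 128`) reproduces a
non-negative signal exactly; this identity anchors several tests.

At each gray level `i`, straight lines are least-squares fitted to the
`N` smoothed-histogram points immediately left and immediately right of
`i`, giving slopes `a1(i)` and `a2(i)`.  The **slope difference
distribution** is

```
s(i) = a1(i) - a2(i),   i = N + 1, ..., 255 - N.
```

With this orientation a histogram mode — rising on the left, falling on
the right — is a positive local *maximum* of `s`, so SDD **peaks mark
cluster centers**, and the shoulders where a cluster meets the flat
remainder of the histogram are negative local *minima*: SDD **valleys
mark candidate thresholds**.  (The sign convention is chosen precisely so
that these two statements hold; with the opposite sign the roles of
peaks and valleys would swap.)  For a known class count `K_c`, the `K_c`
largest peaks are the real cluster centers and the threshold for a
requested separation is the deepest valley strictly between the two
bounding peaks.

Three properties drive the design, and all three are exercised by the
test suite:

* the valley position drifts monotonically as `N` grows, while peak
  positions move at most a bin per step — so `N` is a calibration knob
  that fine-tunes the threshold without destabilizing the cluster
  centers;
* peaks identify cluster centers, valleys thresholds (above);
* a large `N` merges or suppresses small peaks — the basis of the
  benchmark-free calibration.

### Real versus pseudo extrema

Spectral truncation rings: on long flat histogram stretches next to a
dominant spike, the smoothed histogram carries small harmonic ripples
whose SDD extrema are spurious.  The worst-case relative amplitude of
this ringing is governed by the first sidelobe of the rectangular
(Dirichlet) spectral window, about 0.22 of the main response.
`classify_extrema()` therefore keeps an extremum as *real* when its
magnitude is at least a quarter (`frac = 0.25`, configurable) of the
largest same-sign extremum — just above the sidelobe bound, so harmonics
always fall below the cut while clusters of comparable mass stay above
it.  A fraction as low as 0.1 demonstrably misclassifies ringing valleys
as real on spiky histograms.

On the package's noise-free three-class fixture (flat background at gray
50 and two large flat objects at 120 and 220, each contributing a
histogram spike of comparable height) this rule reports exactly 3 real
peaks — at the three gray levels — and 6 real valleys: each spike's
smoothed bump contributes a valley at each foot.

### Identifying the background and the separation cases

The method itself never states which cluster is background.  We take the
real peak nearest the smoothed histogram's argmax (backgrounds dominate
the pixel count in this class of images).  Case 1 separates the
background from the adjacent object class — when the background peak is
interior, the side holding more real peaks; an exact tie is an error
rather than a silent guess.  Case `m >= 2` separates object classes
`m - 1` and `m` in ascending intensity.  When several valleys lie
between the bounding peaks, the most negative one wins (pseudo valleys
are much smaller, so this choice is stable).

### When the threshold is meaningful

The threshold tracks the minimum-misclassification cut of a two-Gaussian
mixture only in the *overlapping* regime, where the two modes are close
enough (up to roughly 3.5–4 standard deviations apart) that the
histogram has a genuine valley.  For near-disjoint classes the histogram
floor between the modes is flat and empty; any cut in the gap separates
the classes, and the deepest SDD valley settles at the dominant mode's
shoulder — a perfectly good segmentation threshold, but not the midpoint
crossing.  The package's accuracy tests therefore sample mixtures with
modes 2.5–3.5 sigma apart (sigma 14–20, weights 0.4–0.6, 20 000 pixels),
the regime the mixture model actually speaks about, and compare against
an exhaustive scan of all 256 cut points on the generating densities.

## Calibration

With ground truth available, `calibrate_grid()` scans `N` in `[3, 60]`
and `W` in `[2, 50]` (step 1) and keeps the pair maximizing the mean
mask F-measure; ties break toward the smallest `W`, then the smallest
`N`, so featureless score surfaces give a deterministic answer.  The
F-measure as implemented (`2PR/(P+R)` with the printed precision/recall
pair) reduces algebraically to the Dice coefficient
`2|A∩M|/(|A|+|M|)`; the tests assert this identity to within
floating-point rounding.  When the intensity and gradient thresholds are
both calibrated, each is scored against its own ground truth (cell
regions for `S_I`; the 1-px-dilated contour band for `S_g`), since their
optima need not coincide.

Without ground truth, `calibrate_rational()` exploits peak suppression:
starting from the defaults `N = 15`, `W = 10`, it raises `N` until the
SDD shows exactly `K_c` dominant peaks, and fails loudly if no
`N <= 60` does.  `W` is held fixed during this scan; varying both
parameters without a score to rank them would be underdetermined.

## Morphological stages

**Noise blob filter.**  `N_l` erosions followed by `N_l` dilations with
the radius-1 4-connected diamond (default `N_l = 3`) — a morphological
opening.  Pixels outside the image are background, per the literal set
definition; the test suite checks the implementation against a
brute-force oracle that applies that definition pixel by pixel, and
asserts idempotence and anti-extensivity.  Threadlike structures of
half-width below `N_l` vanish; note that opening restores only shapes
that are *open* with respect to the element — a square, for instance,
loses exactly the four corner triangles the diamond cannot reach.

**Boundary smoothing filter.**  Contours are extracted by Moore-neighbor
tracing with the walk-state stopping rule: outer contours of 8-connected
components (clockwise, starting at the topmost-leftmost pixel) and
contours of 4-connected interior holes (counterclockwise).  Coordinates
are 0-based `(row, col)` at pixel centers.  Contours of length
`<= T_sn` are removed — a removed outer contour deletes its blob, a
removed hole contour fills the hole (holes of deleted blobs disappear
with them).  By default `T_sn` is a quarter of the mean outer-contour
length of the current mask's blobs; it is a blunt statistic — long
threadlike debris, if not removed beforehand, inflates it until genuine
small cells are deleted, which is exactly why the noise blob filter
precedes this stage.  Surviving contours' coordinate sequences are
low-pass filtered as periodic signals (the histogram filter generalized
to period `N_j`, taking the real part of the inverse), rounded to the
grid, and refilled by even-odd scanline rasterization plus the contour
pixels themselves; with unfiltered contours this rebuild inverts the
tracing exactly, an identity the tests assert on random hole-free masks.

The contour bandwidth default is `W_b = 20`.  A smoothed contour cannot
represent features sharper than about `N_j / W_b` consecutive points, so
too small a bandwidth rounds away the sharp concave notches where two
touching cells meet — visually harmless, but it thickens the contact
neck and delays the erosion split on which counting relies.  `W_b = 20`
suppresses pixel-scale jaggedness while leaving those necks intact;
`W_b = 10` was observed to weld touching pairs together.  The `k = 0`
DFT coefficient is untouched, so smoothing conserves each contour's
centroid exactly (up to final rounding).

## Quantification

`iterative_erosion_quantify()` alternates a harvesting step and one
diamond erosion.  At the start of each iteration, every connected
component whose area is already below the gate `S_0` is moved, whole, to
the seed set and removed; the rest of the mask is then eroded once.
Components therefore leave the loop the moment they are small enough —
an isolated small cell is harvested intact at iteration 1, while a
merged pair of touching cells keeps eroding until its neck severs, after
which each lobe shrinks below the gate and yields its own seed.  Erosion
strictly shrinks every nonempty component, so termination is guaranteed.
The structuring element is the same radius-1 diamond as the noise
filter: it is the one element the morphological stages define
operationally, and an identity element would make the loop
non-terminating.

`S_0` defaults to the mean component area after `pre_erosions = 3`
erosions of the blob image (falling back to the uneroded mean if nothing
survives): pre-eroding first discards thin structures that would drag
the mean down.  Centroids are arithmetic means of seed pixel
coordinates, 0-based.

## Scoring

`score_quantification()` implements the per-cell counting metric: for
each ground-truth cell region, the number of detected centroids whose
(rounded) pixel falls inside it — exactly one is a true positive, more
than one a false positive, zero a false negative.  Each truth cell is
classified exactly once, so the three counts partition the truth set and
the rates are percentages of the truth-cell count.  Detections landing
outside every truth region are reported separately (`n_spurious`) rather
than folded into the rates: in sparse fields, unlike confluent tissue
where every pixel belongs to some cell, background debris would
otherwise be invisible to a purely region-based false-positive count,
and conflating the two conventions would make rates incomparable across
field densities.

## The synthetic generators

`make_three_class()` renders the trimodal demonstration image: a flat
background at gray 50 and two large flat rectangles at 120 and 220, each
covering about 27% of the image, so all three histogram spikes have
comparable height and the real SDD extrema dominate the smoothing
harmonics.  `add_gaussian_noise()` and `iterative_blur()` (seeded,
clipped; box kernel with replicate borders) derive the noisy and blurred
variants used to probe pseudo-extremum behavior.

`make_cell_field()` builds the end-to-end fixture: bright, mildly
roughened circular cells on a dark background in a 384×384 field, with
ground-truth labels, centroids, region mask and contour band.  Its
geometry is stratified by role so that each optional filter has a
deliberate, mechanistically understood job:

* **small singles** (radius 6.5–7.5 px): counted correctly by the full
  pipeline, but their contours are shorter than the thread-inflated
  automatic `T_sn`, so disabling the noise blob filter makes the
  boundary stage delete them (false negatives);
* **touching pairs** (radius 16.5–17.5 px, centers overlapping by
  0.5 px): the largest blobs in the field, so the merged component stays
  above `S_0` until erosion severs the ~7-px contact neck and each
  member seeds separately;
* **vacuole cells** (radius 15–16 px) carry a central dark vacuole
  (radius 6) holding a bright core blob (radius 3.5).  The core's short
  contour falls below `T_sn` and is deleted by the boundary filter;
  without that filter it survives the opening (it contains the
  erosion-stable diamond of radius 3) and is harvested as a second seed
  inside the truth region (false positives).  The central vacuole itself
  is harmless either way — an annulus never fragments under erosion;
* **threadlike noise**: 12 polylines of 16 segments (step 80 px),
  2 px thick, kept 2 px clear of every cell; removed outright by the
  default opening;
* **roughness**: a 13-wave radial sinusoid (amplitude 2 px, capped at
  20% of the radius; pairs are rendered smooth so their neck is clean).

Intensity noise defaults to sigma 3 on a 160-level contrast.  This is
deliberate: the selected threshold sits at the background mode's
smoothed foot, a fixed offset in *bins* set by the DFT kernel width, so
a larger sigma would place the threshold within ~2.5 sigma of the
background and sprinkle speckle blobs — legitimate noise, but it would
swamp the mean-based `T_sn` statistic and blur the single-artifact
attribution the fixture exists to provide.

What the generator does **not** emulate: optical point-spread blur, shot
noise, uneven illumination, intensity gradients within cells, confluent
tissue where cells tile the image, and cell shapes beyond perturbed
circles.  Passing the end-to-end tests therefore demonstrates that the
pipeline's stages interact as designed under the stated failure modes —
not that the default parameters transfer to any particular real imaging
setup, which is what the calibration procedures are for.

## Numerical conventions and degenerate inputs

* Rescaling rounds half away from zero; all-zero images are an error.
* SDD extrema are located at sign changes of the forward difference;
  plateaus resolve to their leftmost index.
* Valleys are local minima with negative value; non-negative local
  minima are never thresholds.
* `binarize()` uses `>= T` for bright cells and `< T` (the exact
  complement) for dark ones.
* Contours: Moore tracing, clockwise outer / counterclockwise holes,
  single-pixel components trace to themselves; rasterization is even-odd
  at pixel centers with the (rounded, clamped) contour pixels added, so
  degenerate one-pixel-wide polygons still rebuild correctly.
* Empty masks pass through every filter unchanged; a pipeline whose
  filtered mask is empty reports zero cells rather than failing.
* All randomness is opt-in through explicit `seed` arguments, which save
  and restore the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
256×256 and 384×384 images, 100-mask oracle comparisons at up to 32×32,
50 mixtures of 20 000 samples, and three full pipeline runs on the
384×384 cell field.  These sizes keep a full check-out in the order of a
minute on a single CPU while leaving every mechanism — including the
erosion race between neck severance and the area gate — at realistic
scale.

## Known limitations

* Case selection (1/2/3) and polarity are user inputs, never inferred
  from the image.
* The automatic `T_sn` is a single global statistic; fields mixing very
  large and very small genuine cells can push small cells below it.
  Supply a fixed `t_sn` in such settings.
* The per-region metric needs truth *regions*; centroid-only ground
  truth would require a matching-radius variant that the package does
  not implement.
* Iterative-erosion counting separates touching cells only when the
  merged component's area stays above `S_0` until the neck severs;
  heavily overlapping cells (necks comparable to the cell radius) are
  counted as one.
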