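---
title: "Counting hepatocyte nuclei: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting hepatocyte nuclei: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hepaquant quantifies hepatocyte nuclei in RGB images of BrdU-stained rat
liver sections and reports the BrdU labeling index — the fraction of
nuclei that belong to proliferating (dividing) cells. This vignette is
the package's account of the science: what each stage assumes, which
parameters matter and why they have the defaults they have, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## The measurement problem

After partial hepatectomy the rat liver regenerates, and the kinetics of
that process are read off the fraction of proliferating hepatocytes.
BrdU immunohistochemistry marks nuclei of dividing cells red and
non-dividing nuclei blue. In an RGB photograph of such a section at
200-fold magnification, *all* hepatocyte nuclei appear dark in the red
channel, while only the proliferating ones are dark in the blue channel.
Counting is therefore run twice — once per channel — and the labeling
index is the ratio of the two counts.

Two structures complicate the count. First, nuclei touch and overlap, so
region counting undercounts; the package counts *circles*, not regions.
Second, images from liver zones 1 and 2 contain venous structures
(portal tracts, central veins) whose lumen holds blood cells of roughly
nuclear size and stain — a false-positive factory unless the vessel
region is excluded. Whether an image contains such structures is
signalled by the `PT`/`CV` token in its filename, a convention carried
over from how the regions of interest are cropped per liver zone.

## Stage by stage

### Edge-preserving smoothing

Each channel is first denoised with a bilateral filter, which weights
neighbours by spatial distance (Gaussian, std `sigma_s` pixels) and by
intensity difference (Gaussian, std `sigma_r`, expressed as a fraction
of the 0–255 range). Texture inside nuclei and background is averaged
away while the nucleus-background step, being many `sigma_r` tall,
survives. Two variants are provided:

* `bilateral_chain()` — three direct passes with spatial stds
  `sigma_s/4`, `sigma_s/2`, `sigma_s`. The coarse-to-fine chain removes
  progressively larger detail while each pass preserves edges. The pass
  schedule is this package's choice; three octaves reproduce the
  intended "remove fine detail, keep coarse edges" behaviour and the
  exact internals of chain formulations differ between implementations
  anyway. Kernels truncate at 3 spatial sigmas; borders reflect-pad so
  no dark frame biases the histogram.
* `fast_bilateral()` — the bilateral-grid approximation: splat into a
  coarse (x, y, intensity) grid at sampling rates
  `(sigma_s, sigma_r·255)`, blur the grid with a unit-sigma Gaussian,
  slice back by trilinear interpolation. Orders of magnitude faster and
  the default in the pipeline; its mild distortions are absorbed by the
  shape filtering (a regression test holds the two variants within 1.5
  intensity levels mean absolute difference on synthetic fields, and
  their detection counts within 5%).

Defaults: `sigma_s = 16`, `sigma_r = 0.15` for the red channel;
`sigma_s = 50`, `sigma_r = 0.10` for the blue channel. The much stronger
blue smoothing deliberately washes out the brighter non-proliferating
nuclei so that a *two*-class threshold suffices there.

### Histogram thresholding by EM

The smoothed channel is rounded back to integer levels and summarized as
a 256-bin histogram. Pixel intensities are modelled as draws from a
mixture of 2 Gaussians (nucleus, background) or 3 (nucleus, background,
vein — only when the filename signals venous structures), and the
mixture is fitted by expectation-maximization *on the histogram*: every
intensity level enters the E- and M-step sums weighted by its count.
This is an exact reformulation of pixel-level EM — all pixels sharing a
level share a responsibility vector — and the test suite verifies
equality with an independent pixel-level implementation to 1e-6.

Initialization follows a deliberately simple rule: split the histogram
into `n` equal parts and take each part's mean intensity as the initial
class mean; set every initial standard deviation to the maximum
intensity present in the image (a very flat start, but convergence is
unaffected); set proportions to `1/n`. Iteration stops when the
log-likelihood moves by less than `tol = 1e-4`. Numerical guards:
responsibilities use log-sum-exp; standard deviations are floored at
0.5 levels so spiky histograms cannot collapse a class to a singularity;
a class pinned at the floor with proportion under 1e-4 is frozen and
reported. `max_iter = 500` is a pure safety bound — typical fits take
10–40 iterations.

Class boundaries are the intersections of the proportion-weighted
densities: each level goes to the class with the highest weighted
density, and the levels where the winner changes are the cuts. With very
unequal standard deviations the per-level argmax can interleave classes;
the boundary between two adjacent (by mean) classes is then repaired to
the outermost density crossing between their means, keeping the
threshold set monotone, which the mask construction requires.

Otsu (`otsu()`) and three-class Otsu (`multilevel_otsu()`) are provided
as baselines; both are exhaustive searches, verified in tests against
independently coded within-class-variance minimizers, with ties broken
at the midpoint of the optimal plateau. Their weakness, and the reason
EM is the default, is the non-representative-class case: when the
nucleus class is tiny next to background and vein (low proliferation
images), Otsu's criterion happily splits the background instead. EM
degrades more gracefully — the small class is lumped with the vein, and
after vein exclusion the cut still isolates the nuclei. For the blue
channel of vein images the vein mask found in the red channel is
*excluded from the histogram before fitting* (and those pixels take part
in no class), which is precisely what rescues the negligible
proliferating class.

### Connected-component shape filtering

The nucleus-candidate mask is cleaned in the order: erode → fill holes →
label → area and equivalent-diameter filter → dilate → form-factor
filter. Erosion (disc radius 2) severs the thin bridges between weakly
connected regions; dilation afterwards restores sizes. Filling holes
makes regions simply connected. Components are measured by area `A`,
boundary-trace perimeter `P`, equivalent diameter
`d_eq = sqrt(4A/pi)` and form factor `F = 4*pi*A/P^2` (1 for a circle,
near 0 for elongated debris). Defaults: `A` in [700, 8000] px, `d_eq` in
[35, 200] px, `F >= 0.2`.

Conventions that needed fixing: labeling is 8-connected; the perimeter
is the length of the outer boundary trace with unit steps for axis
moves and `sqrt(2)` for diagonal moves, width-1 structures counting
both sides and an isolated pixel assigned `P = 4` (such specks are
rejected regardless, but `F` stays finite); `F` can marginally exceed 1
on a coarse raster, so the raw value filters and a clamped value is
reported. The size criteria are checked before dilation and the
roundness criterion after — with a radius-2 structuring element the
difference is small, and this ordering matches the narrative order of
the processing chain. A structuring radius of 2 separates bridges
without destroying nuclei of the expected size; it is config-exposed.

Note a consequence of these published ranges: after erosion by radius
2, a lone circular component survives `d_eq >= 35` only if its original
radius is at least ~19.5 px. The filter window thus *defines* the
nucleus population the pipeline targets, which the synthetic generator
respects (below).

### Vein exclusion

The brightest class of a three-class thresholding is the vein
candidate. How it becomes an exclusion mask depends on its
fragmentation ratio — the largest connected component's share of the
total vein area:

* ratio ≥ 0.95 (or `mode = "fill-only"`): the vein is one major
  component whose enclosed blood cells appear as holes; filling holes
  suffices.
* otherwise: blood separates the vein into fragments and hole-filling
  cannot reach the blood between them. The 0/255 mask raster is
  smoothed with the fast bilateral filter, re-binarized at a quarter of
  the foreground level, united with the original vein pixels and
  hole-filled, merging the fragments into one region. A quarter rather
  than a majority threshold is essential: on a binary raster the
  smoothed value tracks local vein density, and the blood gaps that
  this branch exists to bridge only ever reach moderate density — a
  majority criterion provably never reconnects a ring of fragments
  whose surroundings are background. The quarter threshold accepts
  pixels with roughly one-third local vein density, which also absorbs
  the immediate perivascular margin (non-parenchymal in real tissue).

The qualitative rule "smooth according to the ratio" is realized as a
continuous monotone map `sigma_s = base_sigma*(1 - ratio) + min_sigma`
(defaults 30 and 5): the more fragmented, the stronger the smoothing.
The map, and the permissive range std (`sigma_r = 1.0`) used on the
binary raster — reconnecting fragments *requires* the range term to be
weak — are this package's choices; only the monotone principle is
inherited. The exclusion mask is subtracted from the red-channel
nucleus mask; for the blue channel it is excluded in the thresholding
step instead, and the pipeline asserts that no proliferating detection
lies inside it.

### Circle Hough detection

Counting overlapping nuclei is delegated to a circle Hough transform
over radii 14–50 px (step 2). Design choices here were the most
consequential of the build:

* **Compact, normal-directed voting.** Each boundary pixel of the
  candidate mask estimates its inward normal from the local mask
  content and casts one vote per candidate radius `r` at the point `r`
  pixels along the normal. Full-circle voting (every boundary pixel
  voting on the entire circle of possible centers) was implemented
  first and measured: with the accumulator smoothing below, arcs of
  *different* nuclei interfere so strongly that five planted discs
  yield dozens of detections; direction-informed voting removes the
  interference and is the reason compact formulations are the standard
  for overlapping-nuclei counting.
* **Accumulator smoothing and completeness normalization.** Each
  (x, y) plane is smoothed with a Gaussian of std `acc_sigma = 10`
  (amplitude-one kernel, so a value approximates the
  proximity-weighted vote count) and divided by the circumference
  `2*pi*r`. The score then approximates the *fraction of the circle's
  boundary present in the mask*, comparable across radii. Without the
  normalization a peak's height is proportional to its radius, and
  with radii spanning 14–50 the stopping rule below would discard
  every small nucleus as soon as one large nucleus exists.
* **Radius re-estimation.** The circumference normalization biases the
  plane-argmax toward small radii (neighbouring planes receive
  ring-shaped vote residues), so after a peak's center is found its
  radius is re-read from the best-supported plane of the raw vote
  column at that center.
* **Relevance stopping.** Circles are extracted greedily from the
  global maximum; extraction stops when the current maximum is no
  longer strictly above `relevance` times the first maximum
  (`relevance = 1` thus returns exactly one circle). The default 0.5
  sits in the empirically favourable 0.5–0.6 window of the ROC-like
  sweep that `roc_sweep()` reproduces.
* **Suppression.** After each extraction a cylinder across all radius
  planes is zeroed around the peak. Suppressing only the minimum search
  radius (the obvious choice) measurably re-detects large nuclei from
  residual ring structure just outside that radius; the suppression
  radius is therefore the detected circle's own radius, floored at
  `r_min`. Genuinely overlapping neighbours survive because their
  centers sit further apart than one radius.

The post-filter then (a) drops circles whose center is off the image or
off the candidate mask, and (b) resolves groups of circles lying close
together — center distance below `F_cl*(r1 + r2)`, with `F_cl = 0.5`
for the total channel and 0.75 for the proliferating channel — keeping
the member with the largest disc-mask overlap (ties to the higher
score), greedily in score order. The closeness formula is a
reconstruction from the quantities involved (two centers, two radii,
one dimensionless factor); it is the only dimensionally consistent
combination of them.

### Pipeline and batch

`process_image()` wires the stages per the two-channel flow;
`process_batch()` maps it over files with one shared configuration — no
per-image adjustment — and never lets a failing image abort the run,
since unattended whole-section processing is the point. Everything is
deterministic: identical inputs and configuration give bit-identical
result tables. Degenerate inputs (blank channels, empty histograms,
all-one-class thresholds) surface as a `failed` row, not a crash.

## Validation toolkit

Detections are scored against *point* ground truth (experts mark
nuclei, they do not outline them). A point may match a circle only if
it lies inside it; the assignment is one-to-one, greedy by ascending
center-point distance — a reconstruction of the informal "overlay"
rule, documented as such. Sensitivity is `TP/(TP+FN)`; the false
positive fraction is `FP/Detected`. True negatives are deliberately
not computed: the bundled inter-observer table shows experts disagree
by ~30% on what a "non-hepatocyte" even is, so specificity would
validate against noise.

`interobserver()` summarizes expert dispersion as the per-image
relative standard deviation (100·sd/mean, *sample* standard deviation)
averaged over images. The (n−1) form is used because it reproduces the
published summary values of the bundled count table (15.02% for total
and 20.92% for proliferating hepatocytes) where the population form
does not. Those dispersion figures calibrate expectations: an automatic
count within ~15% of an expert is inside the expert band itself.

The bundled reference tables ship with a caveat the tests encode: their
printed sensitivity/FPF columns were typeset with an inconsistent mix
of rounding and truncation (both occur, provably, in different rows),
and one row's `Detected` disagrees with `TP + FP`. The raw counts are
authoritative; printed-value regressions accept either rounding rule at
each cell's printed precision.

## The synthetic generator

`synth_generate()` produces seeded, bit-reproducible images with exact
ground truth, emulating the features each pipeline branch exercises:
dark nuclei of both stain classes on a lighter parenchyma (background
≈ 210, nuclei ≈ 80, vein ≈ 245 pre-noise, i.i.d. Gaussian noise std 8),
overlapping nucleus pairs at a prescribed center distance, a connected
vein with enclosed blood holes, a fragmented vein whose blood channels
carry nucleus-sized clumps (false-positive bait), and a second
"staining batch" rendition with shifted levels (190/110/240). Default
canvases are quarter-scale (644 × 483) with *full-scale* nucleus radii,
so every published parameter applies unchanged while tests stay fast; a
full-scale preset exists. Nucleus radii default to 20–30 px — inside
the Hough search range and, after erosion, inside the `d_eq` window,
i.e. the population the published filter settings describe.

What the generator does **not** emulate: real chromatin texture,
staining gradients, necrosis, bile-duct proliferation, out-of-focus
blur, or JPEG-era acquisition artifacts. Passing the synthetic suite
therefore demonstrates that the implementation is faithful and the
geometry/statistics of the method work as designed; it does not certify
performance on degraded real slides, where published experience shows
morphological abnormalities can raise the false positive fraction
substantially.

## Problem sizes used by the shipped experiments

The test suite and the reproduction script run: 10 seeds of the clean
preset (50 nuclei each) for end-to-end sensitivity/FPF; 5 seeds × 10
planted pairs for overlap resolution; 5 fragmented-vein seeds processed
with and without exclusion; 10 + 10 EM parameter-recovery replicates at
5·10^4 samples; 100 random histograms against the Otsu oracles; and a
9-point relevance sweep. These sizes were chosen so the whole study
runs comfortably on a laptop core while every claim is still measured,
not assumed.

## Known limitations

* Vein presence is taken from the filename convention; there is no
  automatic vessel detection.
* The Hough stage reports conservative radii (counting, not sizing, is
  the goal); radius estimates inherit a ±1 step quantization and the
  re-estimation described above.
* Whole-slide formats, tiling and stitching are out of scope; inputs
  are single cropped regions of interest.
* The EM model assumes per-class Gaussian intensities after smoothing;
  heavily bimodal backgrounds (e.g. bright vessel lumen in an image
  *not* flagged as venous) violate it and typically surface as a
  degenerate-threshold failure row rather than silent miscounts.
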