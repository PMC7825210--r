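---
title: "Segmenting and quantifying OCTA microvascular networks with octavca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and quantifying OCTA microvascular networks with octavca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(octavca)
```

## The problem

En-face OCTA (optical coherence tomography angiography) renders blood flow as
bright, branching structures on a darker static-tissue background. Clinically
useful morphometry of a neovascular complex — its cumulative vessel length and
mean caliber — requires a segmentation that (i) captures the full connected
network even where speckle briefly interrupts a vessel, (ii) excludes the
"tail" artifacts that smear below vessels, and (iii) rejects isolated bright
speckle clusters that are neither connected to nor shaped like vessels.

octavca implements a vascular connectivity analysis (VCA) built around exactly
those three needs: region growing with a small gap tolerance, global
intensity thresholding that assigns artifact-level signal to background, and a
skeleton-graph filter that removes components whose branch geometry does not
look like a vessel.

## The pipeline

`segment_angiogram()` runs six stages; `cmd_segment()` writes each stage to
disk, which is also the recommended way to inspect a segmentation visually.

1. **Pre-processing.** The image is cropped to a caller-supplied rectangular
   region of interest (the package never guesses one) and converted to
   grayscale with Rec. 601 luma weights (0.299 R + 0.587 G + 0.114 B).
   Intensities are normalized to [0, 1] on read; every threshold below is
   expressed on that scale. Coordinates are (row, col) with the origin at the
   top-left pixel.

2. **Starting-point detection** (`detect_starting_points()`). A pixel is
   *effective* when its intensity reaches the effective-intensity threshold —
   by default the Otsu threshold of the whole region of interest. Through
   each effective pixel we lay `start.line_length` = 7-pixel probe lines in
   four directions (horizontal, vertical, both diagonals); a line is *empty*
   when it contains no other effective pixel. A pixel whose fraction of empty
   lines is below `start.empty_line_proportion_max` = 0.5 sits inside locally
   coherent bright structure and becomes a starting point. The criterion is a
   pure per-pixel predicate: the boustrophedon scan order in which pixels are
   visited cannot change the resulting set, so the scan is computed in
   vectorized form. Probe lines are cropped at the image border.

3. **Connectivity growth** (`grow_network()`). The network is the closure of
   the starting points under the relation "effective pixel whose minimum
   Euclidean distance to a network member is at most `grow.d_max` = 2 px".
   For that radius, the admission neighborhood is the 5×5 window minus its
   four corners, so one- and two-pixel speckle gaps are bridged but wider
   gaps are not. Growth iterates to a fixed point (a full pass that admits no
   pixel), computed by frontier expansion; the result provably equals
   breadth-first closure and is therefore order-independent. Candidate pixels
   must themselves be effective — admitting arbitrary pixels within 2 px
   would flood the image.

4. **Rotation merging** (`extract_network()`). Because region growing is
   sensitive to where starting points are found, detection and growth are
   repeated on the image rotated by 0°, 90°, 180° and 270°, each grown set is
   mapped back through the exact coordinate bijection, and the four sets are
   united. Quarter turns are lossless, so this merge is exactly equivariant:
   rotating the input permutes the four runs and the merged network of a
   rotated image equals the rotated merged network, pixel for pixel. (The
   later thinning stage is *not* exactly equivariant — parallel thinning
   deletes in directional subpasses — so skeleton length may differ by a few
   pixels between orientations; network and area do not.)

5. **Binarization** (`otsu_threshold()`, `binarize_network()`). The Otsu
   threshold maximizes the between-class variance ω₀ω₁(μ₀ − μ₁)² over a
   256-bin histogram of the full region of interest, with ties broken toward
   the lowest qualifying bin edge and foreground defined as intensity ≥
   threshold. The threshold is computed on the whole ROI rather than the
   grown network so that it does not depend on growth parameters; the binary
   vessel mask is the intersection of the network with the thresholded
   image. A constant image has no meaningful split and raises a
   degenerate-histogram error; the pipeline catches it and returns an empty
   segmentation with zero length.

6. **Skeleton analysis and filtering** (`skeletonize()`, `skeleton_graph()`,
   `filter_pieces()`, `mask_from_graph()`). The mask is thinned to unit width
   with Zhang–Suen parallel thinning followed by a sequential
   connectivity-preserving cleanup: a pixel with at least two neighbors whose
   foreground ring forms a single 8-connected component is redundant (a
   "staircase" remnant on diagonal runs) and is deleted in raster order until
   stable. Without this cleanup, roughly a third of skeleton pixels on
   diagonal vessels carry spurious junction counts, which would poison the
   ratio filter below. The skeleton graph then classifies every pixel by its
   8-neighbor count — breakpoint (endpoint) = 1 neighbor, bifurcation ≥ 3 —
   and traces maximal branches between node pixels; branch length is the
   branch's pixel count including both end pixels.

   Filtering applies two rules. First, terminal branches (endpoint into
   junction) shorter than `filter.min_branch_length` = 5 px are pruned
   iteratively, rebuilding the graph after each pass, until stable — this
   removes tail-artifact spurs that attach below vessels. Second, any
   component whose total length divided by its node count (bifurcations +
   breakpoints) falls below `filter.min_ratio` = 3 is removed: compact noise
   blobs skeletonize to dots, tiny bars or small rings with low
   length-per-node, while genuine vessel trees have long runs between nodes.
   The node count is clamped to at least 1, so a closed loop (which has no
   nodes) is kept whenever its circumference passes the length rules, while
   isolated single pixels (ratio 1) are removed; components whose *total*
   length is below `min_branch_length` are removed outright, which also
   catches the small rings that speckle occasionally punches out of a noise
   blob. Both thresholds are deliberate defaults, exposed in the
   configuration; sensible values depend on pixel pitch and noise level.
   Finally `mask_from_graph()` restricts the binary mask to the 8-connected
   components that still contain skeleton, so area is only counted for
   surviving vessels.

## Quantification and monitoring

`measure_vessels()` reports pure pixel accumulation: length = skeleton pixel
count, area = mask pixel count, width = area / length. No √2 weighting is
applied to diagonal steps by default; a diagonal-weighted arc length is
available behind `diagonal_weighted = TRUE` for comparison. An optional
`mm_per_px` calibration (e.g. 6 mm / scan width) is applied only at reporting
time. Note one consequence of pixel-count length: an 8-connected diagonal run
has fewer pixels per unit arc than an axial run, so the width of a diagonal
tube measures up to √2 times its perpendicular caliber. Estimates should
therefore be compared against a ground truth defined by the *same*
convention, which is what the synthetic generator records.

`monitor_study()` summarises a (subject × day) table of metrics: per-day
cross-subject arithmetic mean and standard deviation, percent change of the
day-7 mean relative to the day-1 mean (negative = reduction; a companion
column reports day 7 as a percent of day 1), and a two-tailed two-sample
t-test per parameter. Welch's correction is always applied — never the pooled
test — to avoid a data-dependent switch on a variance-equality pretest. The
comparison is unpaired even though subjects repeat across days, matching how
such monitoring data are conventionally summarised; a paired alternative is
available via `paired = TRUE`. Labels follow the usual convention: `**` for
p < 0.01, `*` for p < 0.05. `autoplot()` draws the mean ± sd trajectory per
parameter.

## The synthetic angiogram generator

No study images ship with the package, so `generate_angiogram()` provides
test data with exact ground truth. It emulates the qualitative phenomenology
of en-face OCTA: bright branching trees of varying caliber, multiplicative
speckle, downward tail artifacts, and isolated bright clusters.

Trees grow as random walks: branches advance `step_len` = 2 px per step with
the heading perturbed by `tortuosity` = 0.15 rad, spawn children with
probability `branch_prob` = 0.08 per step (children are shorter and spawning
stops at depth 4, so the branching process is bounded), and carry calibers
drawn from `width_range` = 3–7 px with children tapering toward the minimum.
Each branch claims a corridor one pixel wider than its tube and terminates on
entering another branch's corridor, so tubes never overlap and the recorded
centerline corresponds one-to-one to the rendered mask — without this, the
"true" length would be unrecoverable from the image by any method. A child
escaping its parent's tube stamps mask but not centerline until it leaves the
parent's corridor, keeping junctions connected without double-counting.

The render is `background_level` = 0.08 off-vessel and `vessel_intensity` =
0.85 on-vessel. Tail artifacts leak a decaying smear (factor 0.75 per pixel,
random 3–10 px extent) downward from every vessel pixel at
`tail_artifact_strength` = 0.4 of vessel brightness — visible clutter that a
global threshold assigns to background, as tails are speckle-level rather
than flow-level signal. Six noise clusters of radius ≤ 3 px are placed at
least 10 px from every vessel *and from each other*: clusters that merge form
elongated blobs that no fixed shape rule could reject, whereas isolated
clusters are exactly what the piece-by-piece filter is designed to remove.
Finally each pixel is multiplied by (1 + 0.15 · N(0, 1)) and clipped.

Generation is fully deterministic given the integer seed (R's Mersenne
Twister, applied locally without touching the caller's RNG state), and
`write_truth()` round-trips the object through plain-text formats: masks as
0/255 PNG (exact), the image as 32-bit-float TIFF (exact to single
precision), scalars in a key=value manifest.

What the generator does *not* emulate: physically realistic OCT speckle
statistics (Gaussian multiplicative noise stands in for Rayleigh-like
speckle; the stages under test are distribution-agnostic), flow decorrelation,
3-D projection artifacts, or vessels crossing in projection. Tests passing on
these images show the pipeline's logic is correct under the stated
phenomenology; they do not certify clinical accuracy on device data.

## Numerical and design choices

* **Effective intensity.** "Effective" is defined as intensity ≥ threshold,
  with the Otsu value of the ROI as default; the detection, growth, and
  binarization stages share one threshold unless overridden.
* **Ties and degeneracy.** Otsu ties resolve to the lowest qualifying
  threshold; constant images raise an error from `otsu_threshold()` but
  produce an empty segmentation in the pipeline; empty masks propagate as
  empty skeletons and zero-length metrics with `defined = FALSE`.
* **Admission metric.** d ≤ 2 Euclidean, implemented by neighborhood offsets
  but contractually equal to brute-force minimum distance (tested against a
  queue BFS oracle).
* **Termination.** Growth adds at least one pixel per sweep or stops; the
  sweep count is hard-bounded by the pixel count and asserted.
* **Pruning order.** Branch pruning runs before the component ratio test and
  iterates to stability; the ratio test is applied once. Filtering is
  idempotent and monotone (never adds pixels), both property-tested.
* **Simulation sizes.** The test suite and the acceptance script use 256×256
  images (a few are 96–128 px for speed), 6–20 images per property, and a
  14-subject two-day simulated study — sizes at which every stage's behaviour
  is already stable and a full run stays interactive.

## Known limitations

* Thresholds are global; images with spatially varying noise floors would
  need local thresholding, which is out of scope.
* The skeleton stage is not exactly rotation-equivariant (directional
  thinning subpasses); length differences of a few pixels between
  orientations are expected.
* Length is a pixel count, not arc length; see the width discussion above.
* The filter's two thresholds are fixed per run; a single setting cannot be
  optimal for images with multiple noise regimes.
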