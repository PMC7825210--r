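# octavca

Segmentation and morphometry of microvascular networks in en-face OCTA
(optical coherence tomography angiography) images, built for monitoring
neovascular regression — e.g. a neovascular complex in proliferative diabetic
retinopathy shrinking under anti-VEGF treatment.

OCTA angiograms show flow as bright branching vessels over a darker
background, contaminated by multiplicative speckle, shadow-like "tail"
artifacts below vessels, and isolated bright noise clusters. octavca
implements a gap-tolerant **vascular connectivity analysis (VCA)**:

1. **Starting points** — a pixel above the effective-intensity threshold
   (default: the Otsu threshold of the region of interest) is a starting
   point when fewer than half of the 7-px probe lines through it in four
   directions are empty of other effective pixels.
2. **Connectivity growth** — the network is the closure of the starting
   points under "effective pixel with minimum Euclidean distance ≤ 2 px to a
   network member" (equal to breadth-first expansion; 1–2 px speckle gaps are
   bridged), repeated on the image rotated by 90°, 180° and 270° and merged
   through the exact coordinate bijection.
3. **Binarization** — the Otsu threshold maximizing the between-class
   variance ω₀ω₁(μ₀ − μ₁)² over a 256-bin histogram, intersected with the
   grown network.
4. **Skeleton-graph filtering** — Zhang–Suen thinning to a unit-width
   skeleton, classification of breakpoints (1 neighbor) and bifurcations
   (≥ 3 neighbors), iterative pruning of terminal branches shorter than
   5 px, and removal of every component whose total length per node
   (bifurcations + breakpoints) falls below 3 — the piece-by-piece rule that
   eliminates noise clusters and artifact stubs.
5. **Quantification** — by pixel accumulation: length = skeleton pixels,
   area = surviving mask pixels, **width = area / length**.
6. **Monitoring** — per-day cross-subject mean ± sd of length and width,
   percent change between two days, and unpaired two-tailed Welch t-tests
   (`**` p < 0.01, `*` p < 0.05).

A synthetic-angiogram generator with exact ground truth (vessel mask,
centerline, per-pixel noise-cluster bookkeeping) makes the whole pipeline
testable without any study data.

## Worked example

```r
library(octavca)

truth <- generate_angiogram(synth_params(seed = 42))
truth
#> <synthetic_angiogram> 256x256, length 679 px, area 4025 px^2, mean width 5.93 px, 98 noise-cluster px

seg <- segment_angiogram(truth$image)
seg
#> <vca_segmentation> 256x256 image, threshold 0.4648
#> # A tibble: 1 × 4
#>   length_px area_px2 width_px defined
#>       <dbl>    <dbl>    <dbl> <lgl>
#> 1       692     4027     5.82 TRUE

glance(seg)
#>   length_px area_px2 width_px defined threshold n_components_kept n_components_removed
#> 1       692     4027 5.819364    TRUE 0.4648438                 3                    6
```

Against a ground truth of 679 centerline px and mean width 5.93 px, the
pipeline reports 692 px (+1.9%) and 5.82 px (−0.11 px); the six injected
noise clusters are among the removed components (`n_components_removed`),
and `sum(seg$mask[truth$noise_cluster_pixels])` is 0 — no cluster pixel
survives. `autoplot(seg)` shows the stage rasters (input, network,
binarized, skeletons, final mask); `tidy(seg)` gives the per-component
keep/remove table.

For longitudinal data, build a `(subject_id, day, length_px, width_px)`
table (or let `cmd_monitor()` segment a manifest of images) and call:

```r
mon <- monitor_study(metrics, day_from = 1, day_to = 7)
glance(mon)   # percent changes, Welch p-values, significance labels
autoplot(mon) # mean ± sd trajectory per parameter
```

A command-line front end is installed at
`system.file("cli", "octavca", package = "octavca")` with subcommands
`segment`, `monitor`, `synth`, and `config` (exit codes: 0 ok,
2 validation, 3 I/O, 4 internal).

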