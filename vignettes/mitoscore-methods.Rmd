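---
title: "Methods: how mitoscore separates stains, counts nuclei, and scores mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mitoscore separates stains, counts nuclei, and scores mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscore)
```

## The problem and the statistic

Immunohistochemistry (IHC) for a mitochondrial inner-membrane marker such
as COX4 stains essentially every cell: there is no meaningful positive /
negative cutoff per cell, so classical scores built from "percent positive
cells" (H-score and relatives) are uninformative. What does vary between
cells and tissues is *how much* granular DAB signal each cell carries.
The Mito-score therefore quantifies abundance per cell:

$$\text{Mito-score} = \frac{\#\{\text{DAB-positive pixels}\}}{\#\{\text{nuclei}\}}.$$

Both quantities are measured on the same brightfield RGB tile. The
numerator comes from color thresholding, the denominator from a
distance-map peak count. When a region contains no nuclei the score is
undefined and flagged (`NaN`), never silently dropped — in whole-slide
tiling, background tiles are the norm, not the exception.

## Stain separation in HSV space

The RGB image is converted with the standard hexcone transform
(`grDevices::rgb2hsv`); hue is expressed in degrees on $[0, 360)$ and
saturation/value on the 8-bit scale $[0,255]$, because the published
windows are stated on those scales. A pixel belongs to a stain class when
its hue lies in any of the class's hue windows *and* saturation and value
lie in the class windows, all bounds inclusive:

| class            | hue (deg)              | saturation | value    |
|------------------|------------------------|------------|----------|
| IHC (DAB brown)  | [0, 60] and [320, 360) | [60, 255]  | [0, 160] |
| nucleus (hematoxylin) | [200, 320]        | [20, 255]  | [10, 220]|

The brown hue range wraps around 0 degrees and is represented as two
closed intervals. Because the two hue ranges are disjoint, the two masks
are disjoint on any image — a property the test suite asserts on random
HSV images against an independent per-pixel brute-force check. The three
criteria commute (pure intersection), so they are applied in a single
vectorized pass; the value window doubles as the background eliminator
(near-white background has $V > 220$ and falls outside both windows).
Endpoint inclusivity is a choice this package fixes explicitly, since
"0–60" alone does not determine it; inclusive bounds are the simplest
reading and make the monotonicity property (widening a window can only
add pixels) exact.

What is deliberately *not* done: color deconvolution (Ruifrok–Johnston),
spectral unmixing, or cross-scanner stain normalization. The window
thresholds are parameters (`channel_profile`, YAML-serializable) exactly
so that a different scanner or staining protocol can be accommodated by
re-tuning rather than re-coding.

## Nucleus counting

Counting runs in five deterministic stages on the hematoxylin mask:

1. **Otsu binarization.** The HSV value (brightness) plane, restricted to
   the nucleus-colored pixels, is thresholded at the split maximizing
   between-class variance; the dark side is kept, since nuclei are the
   darkest objects in a brightfield field. The threshold is computed in
   closed form from histogram cumulants and is exhaustively equivalent to
   scanning all 255 split points (the test oracle does exactly that
   scan). A constant histogram (possible on synthetic input where every
   nucleus pixel has one color) is degenerate: the mask is returned
   unchanged with a warning rather than inventing a split.
2. **Denoising.** Dilation with a disc of radius `dilation_radius`
   (default 1, once) smooths ragged edges; closing with a disc of radius
   `closing_radius` (default 2) fills holes smaller than the element;
   8-connected components below `min_nucleus_area` (default 20 px², well
   under any nucleus at 0.23 µm/px but above stain specks) are dropped.
   The defaults are the smallest elements that visibly act at 40×
   magnification; the operators are named by the method, their sizes are
   this package's choice.
3. **Distance map.** Each foreground pixel gets its exact Euclidean
   distance to the nearest background pixel (EBImage's distance
   transform, with the mask padded by one background ring so that the
   image border counts as background — otherwise a component touching the
   edge would have unbounded depth). Verified against an $O(n^2)$
   brute-force scan on small masks.
4. **Apex counting.** The support is first eroded `erosion_iters` times
   (disc radius 1; default once) to peel boundary pixels, then local
   maxima of the distance map are taken on the 8-neighborhood. A plateau
   of equal maximal values yields exactly one apex (the plateau pixel
   nearest the plateau centroid, ties broken by row then column). Kept
   apexes must be pairwise at least `min_apex_separation` px apart
   (default 7): candidates are visited strongest-first and absorbed by
   any already-kept stronger peak closer than the floor. Everything is
   deterministic; there is no randomness anywhere in the pipeline.
5. **Centers of gravity.** Each apex also reports the centroid of its
   8-connected mask component, since downstream users may want either the
   peak position or the center of gravity; both are returned.

**Crowded-cell fallback.** Touching nuclei fuse into one component whose
distance map may carry spurious maxima near the neck. When the field
looks crowded — mean component area exceeding `crowding_area_factor`
(default 3) times the median area of components holding exactly one
apex — the apex stage is rerun once with one extra erosion and the
separation floor lowered by 2 (floor 3), and the result is flagged
`fallback_used`. A single deterministic retry keeps results reproducible;
if no single-apex component exists the criterion is undecidable and the
fallback does not fire.

## Granule morphometry

DAB-positive 8-connected components are measured as granules: pixel area
and circular-equivalent diameter $2\sqrt{A/\pi} \cdot s$ where $s$ is the
pixel size in µm (default 0.23, the 40× scan calibration). The
equivalent-diameter convention is this package's choice of a single
scalar size for irregular blobs; at 0.23 µm/px the 1–2 µm size of a
mitochondrion corresponds to equivalent radii of about 2.2–4.3 px, so the
resolution suffices to see single granules of that scale.

## Regions, tiles, heatmaps

Polygon annotations use the Labelme JSON dialect (`shapes` with `label`
and `points = [x, y]`, 0-based). Polygons must be simple; self-
intersection is rejected by an exhaustive segment-pair test. Pixel
membership is even-odd ray casting with pixel centers, boundary pixels
counting as inside — deterministic, and additive across regions with
disjoint interiors. IHC pixels are counted inside the polygon; a nucleus
belongs to a region iff its *apex* is inside (single assignment, no
double counting of straddling components). Masks are always computed on
the full image; since thresholding is pixelwise this equals per-region
computation, a property the tile tests assert exactly.

Large images are covered by a row-major grid of `tile_size` × `tile_size`
tiles (default 2000 px, one field of view at 40×), edge tiles truncated.
Per-tile scores are rendered as a heatmap raster (viridis ramp; undefined
tiles in neutral grey; a color bar labelled with the numeric min/max is
drawn with a built-in bitmap font so no graphics device is needed and the
output is byte-reproducible), and the numeric grid is written as CSV that
round-trips to the same matrix.

**Coordinates.** Inside R everything is 1-based `(row, col)`, matching
matrix indexing. Every file the package reads or writes (CSV, JSON) is
0-based with half-open rectangles; the conversion happens only at the I/O
boundary. This is stated on every I/O function.

## The synthetic generator: what it does and does not emulate

`generate_synthetic()` renders the study conditions the pipeline is
designed for: a 512×512 px, 0.23 µm/px field with near-white background
(RGB (245,242,238)), hematoxylin-like elliptical nuclei (RGB (60,70,150),
mean radius 6–10 px, aspect ratio ≤ 1.2) and DAB-like granule disks (RGB
(130,80,40)). Granule radii are drawn uniformly from 2.25–4.2 px so that
the rasterized (center-in-disk) equivalent diameters span the 1–2 µm
mitochondrion scale at this calibration — note that a disk of true radius
exactly 2 px is only 0.92 µm across, so the lower default sits slightly
above 2 px by arithmetic necessity, not tuning. `overlap_fraction`
controls the fraction of nuclei placed as touching pairs (center distance
0.92 × the sum of mean radii), emulating the crowded-cell failure mode.

Rendering is hard-edged — a pixel is painted iff its center falls inside
the shape — so the painted pixel sets *are* the ground truth and mask
fidelity can be asserted as exact equality, not approximately. Placement
uses bounded rejection sampling (500 tries per object, then a packing
error); a fixed seed gives a byte-identical image, and the caller's RNG
state is left untouched.

The generator deliberately does **not** emulate: stain intensity
gradients and texture inside nuclei, partial-volume (anti-aliased) edges,
scanner noise and JPEG artifacts, overlapping granule-on-nucleus signal
(off by default to keep counts exact), macrophages/stromal cell mixtures,
or out-of-focus regions. Consequently, passing recovery tests demonstrate
the geometry and bookkeeping of the pipeline — thresholds applied as
specified, apexes found where the distance map says — but say nothing
about robustness to real staining variability; on real slides the HSV
windows and denoise parameters are exactly the knobs one is expected to
re-tune per facility.

Two synthetic idealizations interact with the pipeline in ways worth
knowing. First, single-color nuclei make the within-mask histogram
degenerate, so the Otsu stage warns and passes the mask through; Otsu's
discriminating behaviour is therefore tested on constructed bimodal
histograms rather than through the generator. Second, with no background
tissue tint the nucleus mask is exactly the painted ellipses, so count
errors isolate the apex logic (fused pairs) rather than thresholding.

## Numerical choices and degenerate inputs

* Ties in the Otsu objective break toward the smallest threshold;
  plateaus in the distance map yield one apex as described; apex ordering
  is by decreasing peak value, then row, then column — all total orders,
  hence deterministic outputs.
* 8-connectivity everywhere (components, local maxima), the blob-analysis
  convention; the labeling is EBImage's 4-connected labeling plus a
  union-find merge of diagonal adjacencies.
* Zero nuclei ⇒ flagged undefined score; empty masks propagate to empty
  results, not errors. A zero-area polygon is an error (empty region).
* All file outputs are written to a temporary name and renamed, so a
  failed run leaves no partial CSVs; inputs are parsed and validated
  before the first byte of output is written.
* Problem sizes in the test suite (512 px scenes, 20 seeds per recovery
  experiment, 32×32 oracle comparisons) were chosen so the whole suite
  exercises every stage, including brute-force oracles, in well under a
  minute of compute on one core.

## Known limitations

* The HSV windows are calibrated to one staining protocol and scanner
  family; they are parameters, not universal constants.
* Apex counting undercounts heavily fused clusters (three or more nuclei
  sharing one convex blob) and can overcount dumbbells whose neck is
  nearly as thick as the lobes; the fallback mitigates but does not
  eliminate this. On touching-pair scenes the residual error is about one
  miscount per 20 nuclei (measured by the acceptance suite).
* Only counts, apexes and centroids are produced — no instance
  segmentation masks.
* Plain raster tiles only (PNG/TIFF); pyramidal whole-slide formats must
  be exported to tiles upstream.
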