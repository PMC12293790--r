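---
title: "Annotating multicellular spots from immunofluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating multicellular spots from immunofluorescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcall)
```

## Why spot-level annotation is hard

Spatial transcriptomics platforms capture RNA in fixed-diameter multicellular
spots (55 µm on Visium slides), while immunofluorescence reports protein
state per cell or subcellular structure. To compare gene expression between
marker-positive and marker-negative tissue regions, every spot must first be
labelled from the image. Manual labelling is subjective whenever marker
expression is non-uniform: different trained observers produce materially
different label sets, and the disagreement propagates into
differential-expression results. `spotcall` makes the labelling a
deterministic function of the image and a small set of explicit parameters,
and provides the agreement statistics (percent agreement, Fleiss' kappa)
needed to quantify observer variability in the first place.

## The segmentation model

Nuclei in a 20x whole-slide scan touch and overlap, which defeats
single-threshold labelling. The pipeline exploits one property of nuclear
counterstains: DAPI intensity is highest at the nucleus center and falls
toward the rim. Segmentation therefore *peels* the image iteratively:

1. Delete every pixel whose nuclear-channel value is below the current
   threshold (value ≥ threshold survives; ties kept).
2. Label the surviving pixels into 8-connected components.
3. Accept as single nuclei the components with `area ≥ min_area_px` and a
   boundary-pixel count (members with a 4-neighbor outside the component)
   no larger than `perimeter_max`; record their pixels and erase them.
4. Raise the threshold by `range_increment` and repeat, until the threshold
   passes `dapi_upper_limit` or the tile is black.

A fused pair of nuclei has a joint boundary longer than one nucleus's, so it
is held back until a higher threshold severs it at the dim junction — each
core is then accepted separately. Components are processed in raster-scan
order of their first pixel, so the procedure has no randomness at all: two
runs on the same inputs produce byte-identical output files.

Connectivity is 8-connected for components with 4-neighborhood boundaries, a
standard pairing that avoids checkerboard ambiguities; the same convention is
used by the brute-force flood-fill reference the test suite compares against
on hundreds of random tiles.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `dapi_start_threshold` | 40 | 8-bit intensity | first peel; below this is background |
| `range_increment` | 10 | intensity | threshold step per iteration; finer steps resolve heavier overlaps |
| `dapi_upper_limit` | 255 | intensity | last threshold considered |
| `perimeter_max` | 120 | boundary px | largest boundary a single nucleus may have |
| `min_area_px` | 20 | px | noise floor for accepted regions |
| `dilate_px` | 0 | px | optional grow-back of accepted cores before marker quantification |

All thresholds live on the 0–255 scale; 16-bit input is linearly rescaled to
8 bits at load time. The defaults suit 0.5 µm/px scans of tissue with
7–10 µm nuclei; `perimeter_max` should be set near the boundary length of
one typical nucleus at the start threshold, and is deliberately isolated
behind one predicate (`boundary_length()`) so an alternative perimeter
definition could be swapped in. Accepted pixel sets are the *cores* at the
acceptance threshold — eroded relative to the full nucleus footprint. Marker
statistics are therefore computed over core pixels; the `dilate_px` option
grows cores back (without overlap, in acceptance order) for users who prefer
fuller footprints, and is off by default because the core behaviour is
simpler to reason about and recovered every ground-truth quantity in
validation.

A nucleus belongs to a spot when its pixels lie inside the spot disk; since
segmentation runs on the masked tile, all accepted pixels (and hence the
centroid, by convexity) are inside the disk by construction. Tiles at image
borders are clipped and out-of-image area counts as background.

## Marker quantification and calling

A pixel is marker-positive when every channel satisfies
`rgb_min[c] ≤ value[c] ≤ rgb_max[c]` (closed on both ends — the thresholds
are minima and maxima). The default `rgb_min = (100, 0, 0)` with vacuous
maxima targets a red fluorophore such as Texas Red: red must be bright, and
the blue counterstain underneath does not disqualify the pixel. A cell is
positive when the positive fraction of its nucleus pixels reaches
`cell_positive_pixel_fraction` (default 0.10, boundary inclusive); a
fraction is the default because it is invariant to nucleus size, but an
absolute-count mode is available.

Spot intensity is the mean main-channel value over pixels that are both
inside a segmented nucleus and marker-positive, 0 when no such pixel exists.
Restricting to nuclei is the package's deliberate reading of the two
plausible scopes ("within the spot" vs "within the nuclei"): red blood cells
autofluoresce brightly in red but contain no nucleus, so a whole-spot mean
can call tissue positive on pure confounder signal, while the
nuclei-restricted mean cannot. `intensity_scope = "spot"` restores the
looser scope for comparison.

The final call excludes spots with fewer than `min_cells = 10` nuclei, then
applies strict `>` comparisons (`intensity > 60`, `percent > 10` under the
default `both` mode). Strict inequalities follow the published operating
point's wording ("above 60", ">10%") even though the manual criterion it
replaced was "10% or more"; because the two readings differ only exactly at
the boundary, the comparison operator is a parameter (`comparison = "ge"`).
Excluded spots are kept in the results table (labelled `excluded`, so spot
counts reconcile) but omitted from the Loupe category export, which accepts
only scored spots.

## Agreement statistics

`fleiss_kappa()` implements the standard multi-rater formulation with pooled
category prevalences. Two identities are worth noting. First, for three
binary raters the per-subject agreement equals agreeing-pairs/3, so the mean
per-subject agreement *is* the average pairwise percent agreement; this
yields `fleiss_kappa_binary_from_summaries()`, which reconstructs kappa from
exactly the two summaries an agreement table reports (per-rater positive
proportions and mean pairwise agreement). The identity is exact when the
summaries are exact, and the test suite verifies it algebraically on random
matrices. Applied to printed, *rounded* summaries it is only as good as the
rounding: the uniformly-low-positivity column of a typical three-observer
study reconstructs to 0.912 on the nose, while higher-variance columns can
drift by ~0.005–0.013 from the value computed on the raw labels — an
input-rounding sensitivity, not a formula discrepancy, which is why only the
exactly-reproducing column is asserted in tests. Second, at R = 2 the
formula reduces to the pooled-marginal two-rater statistic (Scott's pi), not
Cohen's kappa; the cross-check oracle uses the pooled form.

Kappa is reported to 3 decimals and agreements to 2, matching the precision
such tables conventionally print. When every assignment falls in one
category the chance term saturates at 1; agreement is then perfect and 1 is
returned rather than 0/0.

## The synthetic-data generator

`render_slide()` produces slides with exact ground truth. Nuclei are clipped
2-D Gaussians in the blue channel (peaks 180–240, σ = 1.8 px at the default
0.5 µm/px scale), composed with per-pixel maximum so overlaps do not
artificially brighten — the minimal profile with the center-bright premise
the peeling algorithm needs. Centers are drawn from a jittered hexagonal
lattice inside each spot disk, guaranteeing a minimum separation so
ground-truth counts are recoverable while reaching tissue-like densities
(the standard scene's dense spots carry 25–60 nuclei, mean ≈ 42, matching
the per-spot cell counts reported for the glioblastoma sections this
emulates, range 11–88). Positive nuclei carry punctate red foci (3 disks of
radius 1.2 px at intensity 220 within 1σ of the center — comfortably above
both the pixel threshold and the 10% cell fraction); red-blood-cell
confounders are red disks with blue forced to zero, placed away from nuclei
so their effect can be tested in isolation. All randomness flows from the
single scene seed; identical seeds give byte-identical images.

The standard validation scene (`default_scene()`) is 20 spots — 8 positive
at 35% positive cells, 10 negative, 2 sparse (< 10 nuclei) — on a 650 × 520
px canvas. The pipeline recovers all 20 truth calls exactly, and the
dumbbell fixtures (two fused Gaussians whose joint boundary exceeds the
perimeter limit at the start threshold but whose cores separate as it rises)
demonstrate the property single-threshold labelling lacks: peeling finds 2
nuclei where one threshold finds 1 object.

What the generator does *not* emulate: point-spread blur, tissue
autofluorescence texture, uneven illumination, chromatic registration error,
and truly severed or crescent-shaped nuclei. Passing the synthetic suites
therefore shows the algorithmic machinery is correct and deterministic, not
that the default thresholds transfer to any particular microscope; on real
slides the segmentation and marker thresholds must be set against biological
controls, which is why every one of them is a config key.

## Numerical choices and degenerate inputs

- Spot radius uses round-half-up (`55 µm` at `1 µm/px` → 28 px); scales
  coarser than one pixel per spot radius are rejected.
- Disk membership is `(dx² + dy²) ≤ r²` on the integer lattice, matching the
  brute-force lattice count.
- Percent positivity is serialised with 1 decimal and intensity with 2; a
  spot with 11 cells, 1 positive prints `9.1`.
- Empty tiles yield 0 nuclei and measurements `(0, 0, 0, 0)`; an empty
  positive-pixel set yields intensity 0.
- Ratings tables are inner-joined on spot id; subjects missing from any
  rater are dropped with a message.
- Problem sizes in the test suite (a 20-spot slide, 200 random oracle tiles
  ≤ 32×32, 10⁴-subject ratings matrices) were chosen as the smallest sizes
  at which each property is meaningfully exercised.

## Known limitations

The segmentation is specific to nuclear stains with center-bright profiles;
cytoplasmic or membrane staining needs a different boundary model. The
perimeter criterion reads the historical "perimeter" parameter as a
boundary-pixel count on the accepted region; region-boundary conventions
differ across toolkits, so the predicate is kept swappable. No image
registration is performed — spot coordinates are assumed to already
correspond to the image, as they do for Loupe Browser exports matched to the
scanned slide. And kappa reconstruction from printed summaries inherits the
print precision of its inputs, as discussed above.
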