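# spotcall

Objective marker-positivity annotation of multicellular spatial
transcriptomics spots from immunofluorescence images.

## The problem

Visium-style spatial transcriptomics profiles RNA in fixed 55 µm capture
"spots", each covering tens of cells. Pairing that readout with an
immunofluorescence stain — e.g. γH2AX, a nuclear marker of unresolved
double-stranded DNA breaks — requires labelling every spot positive or
negative for the marker before comparing gene expression between the two
groups. Done by eye, that labelling is unreliable exactly where it matters:
on tissue with heterogeneous marker expression, trained observers agree on
as little as ~69% of spots (Fleiss' κ ≈ 0.35), and downstream
differential-expression results change with the annotator. `spotcall`
replaces the manual step with a deterministic, parameterised image-analysis
pipeline and quantifies interobserver agreement so the improvement can be
measured.

## What it computes

For each spot (barcode, center, fixed 55 µm diameter) on an 8-bit RGB
immunofluorescence image:

1. **Spot masking** — a disk of radius `round(55 / (2 · µm/px))` pixels is
   cut around the spot center; everything outside is background.
2. **Nuclear segmentation by iterative threshold peeling** — DAPI intensity
   falls from the nucleus center to its rim, so a rising threshold
   progressively splits touching nuclei. Starting at threshold *T₀*, pixels
   below *T* are deleted; surviving 8-connected regions with area ≥
   `min_area_px` whose boundary-pixel count (4-neighborhood) is ≤
   `perimeter_max` are accepted as single nuclei and erased; *T* increases
   by the `range` increment until 255 is reached or the tile is black.
3. **Marker quantification** — a pixel is marker-positive when every RGB
   channel lies inside a closed `[rgb_min, rgb_max]` range; a cell is
   positive when ≥ 10% (default) of its nucleus pixels are positive; spot
   intensity is the mean main-channel (red for Texas Red) value over
   marker-positive pixels *inside nuclei*, which makes nucleus-free red
   blood cell autofluorescence invisible to the measurement.
4. **Calling** — spots with < 10 cells are `excluded`; the rest are
   `positive` when spot intensity > 60 **and** percent positive cells > 10
   (defaults; each criterion, the mode and the comparison operator are
   configurable), else `negative`.

For annotation sets (two or more raters over the same spots) it computes
pairwise percent agreement, its average, and Fleiss' kappa

κ = (P̄ − P̄ₑ) / (1 − P̄ₑ),  P̄ᵢ = (Σⱼ n²ᵢⱼ − R) / (R(R−1)),  P̄ₑ = Σⱼ p²ⱼ,

plus a closed form that reconstructs κ for three binary raters directly from
the per-rater positive proportions and the mean pairwise agreement.

## Worked example

Everything below is generated in code — the package ships a synthetic-slide
generator with exact ground truth (center-bright Gaussian nuclei, punctate
red foci in positive nuclei, optional RBC-like red blobs):

```r
library(spotcall)

scene <- default_scene(seed = 42)   # 20 spots: 8 positive, 10 negative, 2 sparse
sim   <- render_slide(scene)
ann   <- run_pipeline(sim$image, sim$grid)
glance(ann)
#> # A tibble: 1 × 7
#>   n_spots n_positive n_negative n_excluded pct_spots_positive mean_cells ...
#> 1      20          8         10          2               44.4       39.9
```

All 20 calls match the generator's ground truth: the 8 spots seeded with 35%
positive cells are `positive`, the marker-free spots `negative`, and the two
spots with fewer than 10 nuclei `excluded`. Per-spot measurements, e.g.
`SPOT-002: n_cells 60, n_positive_cells 21, pct_positive 35.0,
spot_intensity 220.0, call positive`, are written with
`write_results_csv(ann, "results.csv")` (percent to 1 decimal, intensity
to 2) and exported for Loupe Browser with
`write_loupe_categories(ann, "categories.csv")`.

Agreement between annotation sets:

```r
fleiss_kappa_binary_from_summaries(c(0.094, 0.094, 0.113), 98.42)
#> [1] 0.9124719          # three observers, uniformly low-positivity tissue

rt <- make_ratings(2785, c(0.094, 0.094, 0.113), flip_rate = 0.005, seed = 1)
agreement_summary(rt)
#> <agreement_summary> 2785 subjects, 3 raters
#>   average pairwise agreement: 98.32%
#>   Fleiss' kappa: 0.907
```

A thin CLI wraps the same functions
(`exec/spotcall run|agreement|simulate`); see the script header for flags.

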