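---
title: "Methods: two-stage NETosis classification with interval-membership scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage NETosis classification with interval-membership scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netquant)
```

## The classification model

netquant treats a double-stained fluorescence image as two rasters sharing a
coordinate grid: a total-DNA channel (cell-permeable dye, all DNA) and an
extracellular-DNA channel (cell-impermeable dye, DNA outside intact
membranes). Objects of interest — neutrophils at successive NETosis stages,
NETs, bacterial clumps, artifacts — are bright connected regions on one of
the two channels, and the biology is encoded almost entirely in five
per-region statistics:

* `area` — pixel count;
* `mean_total` — mean total-DNA brightness over the region's own pixels;
* `mean_extra`, `std_extra` — mean and *population* standard deviation of
  extracellular brightness (the region describes itself, not a sample, hence
  the n-denominator);
* `mean_log` — mean Laplacian-of-Gaussian response on the total-DNA channel;
  compact bright blobs give strongly negative values, diffuse edge-less
  clumps (bacteria) values of small magnitude.

Two optional circularity ratios (`area/perimeter²`, `area/diameter²`) are
computed for completeness but excluded from every default class definition:
NETs can be as circular as cells, so the ratios carry no discriminative
signal for this task.

Classification runs in two stages. **Stage 1** (extracellular channel):
regions smaller than `min_net_area` are skipped — they are typically the
footprints of membrane-permeabilized (PER) cells and are counted once, at
stage 2, through the `mean_extra` feature of the matching total-DNA region.
Remaining regions are NETs when mean brightness and its standard deviation
both fall in user-set ranges; everything else is an "extracellular unknown"
artifact. The standard deviation is the load-bearing discriminator: NET
chromatin density varies across the region while background-level artifacts
are nearly uniform. **Stage 2** (total-DNA channel): regions lying mostly
inside the union of NET and artifact pixels are ignored (whether a cell
within a NET is permeabilized cannot be decided reliably); the rest are
scored against per-class feature intervals.

## The partial score and its margins

Hard interval tests make classification brittle at the boundaries a user
tunes by eye. The partial score softens each interval \([l, u]\) with
half-sine ramps over adaptive margins
\[
\Delta_l = s\,\frac{l\,(u-l)}{u+l}, \qquad
\Delta_u = s\,\frac{u\,(u-l)}{u+l},
\]
giving score 1 on \([l,u]\), 0 outside \([l-\Delta_l,\ u+\Delta_u]\), and
\(\tfrac12 + \tfrac12\sin(\pi\,(x-l+\Delta_l)/\Delta_l - \pi/2)\) on the
lower ramp (symmetrically above). Because the margins scale with both the
interval length and its boundary values, one dimensionless factor `s` works
for every feature regardless of units. A class score is the *product* of its
partial scores, so one clearly violated feature vetoes the class.

```{r partial-score, fig.width = 6, fig.height = 3}
plot_partial_score(10, 20, s = c(0.2, 0.5, 1))
```

The decision rule demands unambiguity: a label is assigned only when its
score is at least `assign_threshold` (default 0.8) **and** every competing
class scores at most `reject_threshold` (default 0.4). Both comparisons are
closed, so a competitor exactly at 0.4 does not block assignment; this is
the package's reading of an underspecified boundary case, chosen so the
documented default thresholds behave as limits rather than open bounds.
Anything ambiguous becomes `UNKNOWN_INTRACELLULAR`, with the reason
(`no_high_score` / `multiple_high_scores`) recorded: mislabelling is
costlier than abstention, and unknowns are surfaced for manual review
through the per-image quality score \(Q = 100\,(1 - U/S)\,\%\) (unclassified
ROI area over all retained ROI area; ignored-by-mask and skipped-small areas
enter neither term; an image without ROIs scores 100).

Degenerate margin cases are fixed as follows, all exercised in the tests:
an infinite bound drops its ramp and the surviving margin becomes
`s·|bound|` (an interval like "area ≥ 100, no upper limit" keeps a soft
lower edge); `l = u` or a zero bound gives a hard edge there, as the margin
formula forces; and intervals with negative endpoints — possible for
`mean_log` — use `|l|`, `|u|` in the margin formulas, keeping margins
non-negative while leaving the score formula untouched.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| segmentation `threshold` | per config | a.u. (native) | strictly-greater comparison; `0` excludes an exactly-zero background |
| `min_area` | 4 | px | suppresses single-pixel noise components |
| `connectivity` | 8 | — | standard for blob detection; 4 available |
| pre-filter | off | — | Gaussian (`sigma`, px) or median (`radius`, px), per channel |
| `log_sigma` | 2 | px | LoG scale matching cell-size texture; computed after any pre-filter |
| `s` | 0.5 | — | moderate margins; synthetic preset configs use 0.2 because their generating distributions are tight |
| `assign_threshold` / `reject_threshold` | 0.8 / 0.4 | score | the unambiguity rule's defaults |
| `min_net_area` | per config | px | above PER footprints, below real NETs |
| `mask_overlap` | 0.5 | fraction | a region is ignored when more than half its pixels are masked; 0 means "any overlap" |

Intensities are used in native camera units throughout — no bit-depth
normalization — because acceptance intervals are laboratory-specific anyway:
the package deliberately ships no default class ranges for real data.
Stage 1 uses hard interval tests by default (`mode = "hard"`); a soft mode
reusing the partial score with the global `s` exists for symmetry.
Artifact area counts as unclassified in \(Q\) by default, since artifacts
require the same manual inspection as intracellular unknowns; set
`quality_includes_artifacts = FALSE` to restrict \(Q\) to intracellular
unknowns.

## Numerical choices

Connected components are labelled over an explicit pixel-adjacency graph,
supporting both connectivities with one code path; labels are renumbered in
column-major first-pixel order so results are deterministic. The LoG kernel
is the analytic \(\nabla^2 G\) discretized on a \((2\lceil 4\sigma\rceil+1)^2\)
grid and recentred to sum exactly to zero, so constant rasters and affine
ramps give a zero response away from borders (borders use replicate
padding). The ROI diameter is the maximal pairwise pixel-centre distance,
computed on the convex hull; a single-pixel region has diameter 0 and its
`circ_diameter` is returned as `NA` (undefined) rather than infinite. Greedy
IoU matching breaks exact ties by (smaller prediction index, smaller truth
index), making reports reproducible; for continuously distributed boxes ties
have probability zero and the greedy matching is exactly the matching that
lexicographically maximizes the sorted IoU sequence (verified against an
exhaustive oracle). VOC-style annotation boxes are converted from 1-based
inclusive to 0-based half-open on ingestion so box areas equal pixel counts.

## The synthetic generator

`render_scene()` draws each class with the features that define it: PMN as
unions of 2–4 overlapping ellipses (lobulated) at moderate brightness; RND
as discs with the highest total-DNA brightness; RUP as larger, dimmer
unions of discs; PER as discs carrying extracellular signal over their
footprint; NETs as wobbly-edged blobs whose extracellular intensity is a
smooth random field standardized to a fixed standard deviation (guaranteeing
the heterogeneity stage 1 relies on); artifacts as near-uniform smooth
patches, optionally on top of a background gradient; bacteria as blurred
point scatters without defined edges (small `|mean_log|`). Background is
100 a.u. with additive Gaussian noise of SD 5 a.u. on a 16-bit scale; all
randomness flows from one seed, recorded in the truth tables, and scenes are
bit-reproducible. Placement is rejection-sampled to keep objects disjoint
(bounded retries, then an explicit placement error).

The preset configurations bracket these generating distributions with a
safety margin — including the measured `mean_log` separation between RUP
clouds (≈ −28 to −49 a.u./px² under the defaults) and bacterial clumps
(≈ −10 to −17) — which is what makes end-to-end recovery testable. The
generator emulates the *feature contracts* of real data, not its optics: no
point-spread function, no anti-aliased cell borders, no focal drift, no
channel bleed-through, no touching or overlapping cells. Passing recovery
tests therefore demonstrates that segmentation, features, scoring, masking
and bookkeeping compose correctly — not that any particular acceptance
intervals work on a given microscope's output, which always requires
per-laboratory tuning.

## Problem sizes used by the test suite

Unit tests run on rasters up to 40×40 and oracle comparisons on up to
32×32 masks (100 random rasters, both connectivities) and 200 random
matching instances of at most 6 boxes per side. End-to-end checks use
256×256 scenes over 20 seeds, and the batch contract runs 121 in-memory
160×160 scenes. These sizes exercise every code path while keeping the
suite fast; nothing in the implementation depends on them.

## Known limitations

Merged NETs from adjacent cells segment as one object — NET *area* is the
robust readout, NET *count* is not. There is no adaptive thresholding, no
watershed splitting, no 3D stacks, no time-lapse tracking, and no learned
calibration of ranges: tuning by eye, aided by the quality score, is the
intended workflow. Co-cultures with non-neutrophil host cells are out of
scope.
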