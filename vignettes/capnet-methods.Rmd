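---
title: "Quantifying endothelial Ca2+ activity in capillary networks with capnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endothelial Ca2+ activity in capillary networks with capnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
library(dplyr)
```

## The measurement problem

Intravital two-photon imaging of the skin capillary plexus records a GCaMP
Ca2+ reporter in endothelial cells (ECs) alongside a nuclear label
(H2B-mCherry) that identifies each cell. A typical homeostatic recording is
300 frames at 3.44 s/frame — 17 minutes 12 seconds — over a 0.3 x 0.3 mm
field holding 100–150 cells. capnet implements the full quantification
stack for such recordings: per-cell event calling, persistence detection,
multicellular cluster linking, longitudinal conservation statistics,
line-scan flow analysis, vessel morphometry and permeability readouts.
Because no raw microscopy ships with the package, a synthetic-data module
generates every input with planted ground truth, and all claims made by the
test suite are claims about those synthetic worlds.

## Event calling

The nuclear mask is used as the cell proxy: `extract_traces()` averages the
movie over each labelled ROI per frame, with no dilation into the
cytoplasm. Baseline Ca2+ levels differ between cells and drift within a
recording, so each trace is normalised in consecutive non-overlapping
100-frame windows to the minimum fluorescence of that window
(`window_minima()`). A frame is part of a Ca2+ event when its intensity
*strictly* exceeds 1.5x that reference — the 50 %-above-minimum rule —
and maximal runs of such frames are events (`call_events()`).

Numerical choices worth knowing:

* **Strict inequalities** at both the 50 % threshold and the 170/255
  persistence threshold. An excursion to exactly 1.5x the minimum is not an
  event; a cell sitting exactly at 170 is not persistent. Both boundaries
  are tested explicitly.
* **Window seams.** Supra-threshold runs crossing a window boundary are one
  event: splitting at an arbitrary seam would inflate event counts.
* **Censoring.** Events touching the first or last frame are kept, count as
  events, and contribute their observed (truncated) duration; they carry a
  `censored` flag. No censoring correction is applied.
* **Gap merging** is off by default (`gap_tolerance = 0`): two
  supra-threshold runs separated by a single sub-threshold frame are two
  events. The tolerance is exposed because the right choice depends on the
  sensor's decay relative to the frame interval.

Per-cell dynamics follow directly (`compute_dynamics()`): a cell is
*active* iff it has at least one event; frequency is events per minute of
recording; average duration is total signalling time over event count. At
300 frames x 3.44 s the recording lasts 17.2 minutes, so the lowest
attainable frequency of an active cell is 1/17.2 = 0.0581 events/min
(0.001 Hz). High-dynamics cells (`classify_dynamics()`) are those more
than one *sample* standard deviation (denominator n − 1; cell populations
are samples) above the mean of the active reference population — the
population itself by default, the day-0 population for revisits, the
control group for knockout comparisons. The reference is passed explicitly
so thresholds stay fixed across the comparison.

## Persistent activity

A cell whose Ca2+ stays high for minutes never crosses 1.5x its own
windowed minimum, so the event rule is blind to exactly the behaviour of
interest in gap-junction-deficient vessels. Persistence is therefore
detected on the raw 8-bit intensity scale: every frame above 170 (of 255)
counts as signalling (`detect_persistent()`). Two consequences shape the
package's design:

* The 170/255 rule is scale-bound. Intensities above `scale_max` are a hard
  error; 16-bit data must be linearly rescaled first.
* A minimum supra-170 duration (default 120 s, configurable) separates
  persistent cells from bright transients, reflecting the minutes-long
  (2–17 min) span of the persistent events this rule targets. Pure supra-170
  framehood would misclassify brief excursions of a bright cell.
* On the 0–255 scale, `persistent` and `n_events >= 1` are nearly disjoint:
  a 50 % excursion above a >170 baseline is unrepresentable. The merged
  summary (`summarise_cells()`) therefore marks a cell active if it has
  events *or* is persistent, which keeps the "persistent implies active"
  invariant without pretending the event detector saw anything.

## Multicellular clusters

The vessel surface is tiled into 0.0076 x 0.0076 mm grids anchored at the
image origin; a grid's trace averages its vessel pixels only, so the vessel
mask is partitioned exactly and background never dilutes the signal. Grid
events use the identical thresholding semantics as cell events. Two active
(grid, frame) entries are linked when their grids are identical or adjacent
and their frames differ by at most one (`link_clusters()`); clusters are
connected components of this relation, counted by distinct grids and, after
`count_cluster_cells()`, by distinct nuclear centroids inside the union of
member-grid bounds (half-open, so an edge-sitting centroid counts once).

Two open choices and how they were fixed:

* **Adjacency** defaults to 8-connectivity (vessels run diagonally across
  any square tiling); 4-connectivity is a switch, and cluster counts under
  both are worth reporting when the distinction matters.
* **Co-activity, not onsets.** Entries are linked whenever activity
  overlaps within the 1-frame tolerance, the weaker and more inclusive
  reading of "events at the same frame or one frame apart".

Persistently active clusters (`persistent_clusters()`) are those with at
least one grid active in the full recording span (fraction configurable).

## Longitudinal conservation

Cell correspondence across revisits is an *input* (the same cells are
re-identified by positional stability); the package does no registration.
`conservation_stats()` reports the maintained-status fraction.
`chi_square_conservation()` implements the published test verbatim: a
two-category goodness-of-fit (df = 1) whose expected maintained proportion
equals the day-0 active proportion (0.58 / 0.54 / 0.74 depending on the
revisit design). That null is *not* the independence null — if the two
days were independent draws at rate p0, the expected maintained proportion
would be p0² + (1 − p0)², e.g. 0.5128 at p0 = 0.58 — so the independence
version is always computed alongside and labelled. Fidelity first,
correctness annotated. Treatment effects are compared on the published
design: per-mouse means before and after, percent change per mouse, unpaired
two-tailed Student's t-test between conditions (Welch correction off by
default to match; normality assumed, not tested).

## Line-scan flow

Line scans acquire 600 lines over each 2-second block (300 lines/s);
unlabelled cells in fluorescent plasma appear as intensity valleys.
`detect_valleys()` finds local minima that pass four rules: prominence
(default 0.3x the median-minus-minimum of the profile), width at half
prominence within [2, 50] samples, a minimum separation (default 4
samples), and an intensity ceiling (default 0.6x the median) that rejects
shallow noise dips — the qualification the operator would otherwise tune by
eye, logged in the output attributes. Valleys are assigned to blocks by the
floor rule, flux is valleys per block duration, and blocks are labelled
`no_event`/`before`/`during`/`after` against a threshold of 1.5x the
minimum green block mean, with interior gaps between event runs split by
proximity (ties to `before`). The flux trend is a centred 5-point moving
average with shrinking edge windows; per-period flow change is last-minus-
first flux within each signalling or non-signalling run.

Valley counting has an inherent ceiling: when two transits overlap within
roughly a valley width, their dips merge and any counter sees one cell. At
the homeostatic mean flux (~29 cells/s) this undercount is large; the
recovery guarantees in the test suite are therefore stated for regimes
where transits are resolvable (exact counts with separated valleys; ±5 %
mean flux at ~3 cells/s with collisions allowed). A baseline-shift QC
(`qc_baseline_shift()`) flags vessels whose per-block median range exceeds
30 % of the global median, mirroring the exclusion of drifting fields.

## Morphometry and permeability

Fully enclosed loops are connected components of the vessel-mask complement
that avoid the border (4-connectivity for the background, so a one-pixel
diagonal gap in a wall does not leak). Area is the pixel count; perimeter
is the Moore boundary-contour length with sqrt(2) diagonal steps — the
estimator is documented and fixed because perimeters are only comparable
within one estimator; the equivalent diameter is sqrt(4A/π). Nuclei snap to
the nearest skeleton pixel and are retained only when strictly under 10 µm
away (ties go to the lexicographically smaller pixel). Segments are
skeleton paths between branch points (>2 8-connected neighbours) and
endpoints; under 8-connectivity the pixels around a crossing all exceed
degree 2 and collapse into one node cluster, so segment lengths exclude
node-internal steps. Geodesic length sums 1/sqrt(2) pixel steps; linear
density is reported per 100 µm. Nuclei snapped to a shared branch pixel are
credited to the first incident segment in deterministic order — an
arbitrary but fixed rule, flagged here.

Permeability normalises the per-frame mean intensity outside the vessel
mask (dilated by 2 px by default, to keep partial-volume bleed at vessel
edges out of the "extravascular" region; 0 restores the literal reading) to
the average extravascular intensity of the pre-dextran recording. The
normalisation is scale-invariant by construction.

## The synthetic world

`generate_recording()` renders label masks (disjoint ellipses with a 2 px
margin), per-cell traces and movies on the 0–255 scale. Its defaults are
the homeostatic conditions: 300 frames at 3.44 s, 52.4 % active cells,
0.445 events/min and 8.36 s mean duration in active cells, baseline 100,
events at 2x baseline, Gaussian noise at 5 % of baseline, no bleaching.
The event-duration and inter-event distributions in vivo are unknown, so
they are parameters (exponential durations, uniform placement with a 2-
frame separation), not claims. Persistent cells are held at 180 for the
whole recording; the knockout dialect raises `persistent_fraction` to
about 0.19. Event placement is a censored Poisson process: boundary-
truncated events are kept and flagged, because detector boundary behaviour
is itself under test. Noise is Gaussian clipped to [0, 255]; Poisson shot
noise, optics, motion and spectral bleed-through are deliberately out of
scope. A green test against this world therefore establishes algorithmic
correctness — exact recovery of planted structure under stated noise — not
robustness to real-microscopy artefacts.

`generate_linescan()` plants triangular dips (depth 120, half-width 3 by
default) at per-block counts of `round(flux x 2 s)`; `generate_vessel_geometry()`
builds square annular loops, straight/diagonal one-pixel skeleton segments
and nuclei at exact pixel-realised offsets; `generate_revisit_pair()`
draws day-0 statuses at 0.58 and maintains them with probability 0.711 by
default, with an independence option for null calibration. Every generator
is bit-reproducible under its seed.

## Known limitations

* Masks and movies are consumed as arrays; nuclear/vessel segmentation of
  real imagery, projection and motion correction happen upstream.
* The chi-squared conservation test inherits the published null, which is
  not an independence null; both are reported but the headline follows the
  publication.
* Valley counting undercounts at high flux (see above).
* The grid tiling anchor (image origin) is a convention; the original
  analysis does not state one, and a different anchor shifts grid indices
  without changing the statistics materially.
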