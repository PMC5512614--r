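---
title: "Quantifying C. elegans larval development from long-term time-lapse movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying C. elegans larval development from long-term time-lapse movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrace)
library(dplyr)
```

## The measurement problem

*C. elegans* larvae develop from hatchling to adult in roughly 40–48 hours,
molting four times (the L1–L4 ecdyses). Confined to a hydrogel microchamber
with food, a larva can be imaged every 20 minutes over that whole period —
but it keeps moving and bending, so nothing about the raw camera frames is
comparable between time points. The analysis strategy this package
implements makes frames comparable by re-expressing everything in *body
coordinates*: a position is described by `s`, the arc length along the
animal's centre line from the head (the anteroposterior or A–P axis), and
`t`, the signed perpendicular distance from the centre line (the
dorsoventral or D–V axis, negative on the ventral side). On top of that
coordinate system sit four analyses: developmental staging from molt times,
seam-cell lineage statistics, distal-tip-cell (DTC) migration kinematics,
and oscillatory reporter-gene quantification.

Because live recordings are large and annotation is manual, the package
ships a fully ground-truthed synthetic movie generator
(`generate_movie()`, `generate_cohort()`). Every analysis path is exercised
against data whose true geometry, event times and intensities are known by
construction; the test-suite and the acceptance script report nothing that
is not recomputed from such data at run time.

## Body-axis geometry

`fit_body_axis()` interpolates the 10–20 manually annotated centre-line
points with a natural cubic spline (no smoothing: the annotation is
authoritative, and an interpolating curve is exactly testable), then
reparameterizes it by arc length through a dense polyline (400 samples per
control segment). The curve-length integral of the reparameterized curve is
the body length. The dense grid bounds the precision of the arc-length map;
at the default resolution equal steps in `s` produce equal chord lengths to
well within 0.1%, and the camera↔body round trip is accurate to below
1 µm × 10⁻⁶.

`to_body_coords()` projects a camera point onto the curve: `s` minimizes the
Euclidean distance, `|t|` is that distance, and the sign of `t` is fixed by
a ventral marker (the annotated gonad position in L2–L3, the vulva in
L3–L4): the normal is the +90° rotation of the tangent, globally flipped so
the marker side is negative. Numerically, the projection is bracketed on
the dense polyline, refined with Brent's method, and polished by iterating
the stationarity condition `(p − c(s))·T(s) = 0`; the polish is a
contraction whenever `|t|` is below the local curvature radius and is
discarded if it ever increases the distance (points beyond the curvature
centre, where the nearest-point problem is genuinely ill-conditioned).
Ties — points near the medial axis of a bend — resolve to the smallest `s`
with a warning. Points beyond the head or tail clamp to `s = 0` or `s = L`.

`straighten_image()` resamples a frame onto the regular (s, t) grid with
bilinear interpolation, filling 0 outside the camera field. Column `c` maps
to `s = c·pixel_size`; row `r` maps to `t = (r − r0)·pixel_size` with `r0`
the axis row, so ventral is at the top of the matrix; the mapping is
exposed by `straightened_s_axis()`/`straightened_t_axis()` rather than
being a convention users must remember. One geometric caveat is inherent to
all worm straightening: the area element of the transform is
`(1 − t·κ(s))`, so integrated intensities are conserved only where the bend
is gentle relative to the off-axis distance of the signal
(`|t·κ| ≪ 1`). For seam-cell nuclei, which sit within a few micrometres of
the centre line, the distortion is at the percent level; quantitative
intensity work on strongly bent frames should use `|t|`-near-axis signals
or camera-frame integration (`total_intensity()` integrates in the camera
frame for exactly this reason).

## Staging

`developmental_timeline()` records the hatch and the four ecdysis times —
ecdysis is an instantaneous annotated event, the appearance of a shed
cuticle. Stages are half-open intervals `[hatch, ecd1) → L1`, …,
`[ecd4, ∞) → adult`, so an ecdysis time itself belongs to the following
stage; this makes `assign_stage()` deterministic at boundaries.
`ecdysis_fraction()` histograms molt events over a cohort, normalizing by
the total number of animals (not by animals still imaged; with sub-stage
bins the distinction is irrelevant and the total-N convention keeps the
event-count identity `sum(fraction)·N = #events` exact).

## Seam-cell lineage statistics

A lineage is a table with one row per seam cell: name
(lineage H1/H2/V1–V6/T, side L/R, and an `{a,p}` sublineage suffix per
generation, e.g. `V2L.pp`), larval stage, division class
`d ∈ {0: none, 1: symmetric — two seam daughters, 2: asymmetric — one seam
daughter}`, and division time. The stage of a record is the annotated
stage, not `assign_stage()` of its time, so molt-boundary divisions follow
the annotator.

`relative_division_time()` centres each division time on the mean over all
divisions of the same animal and stage (all nine lineages, both sides);
`division_time_variability()` gives the across-animal mean and sample s.d.
per named cell.

`lineage_error_probability()` compares mutant lineages to a reference: for
every cell present in *both* the reference and a mutant animal, it scores
`1 − δ(d_wt, d_mut)` and averages within each (lineage, stage) over all
(animal, cell) pairs, pooling body sides. Pooling over pairs (rather than
averaging per-animal means) matches the exhaustive-enumeration oracle the
test-suite checks against exactly. Errors are scored only at the first
point of deviation: a cell created by an upstream error does not exist in
the reference name space, so the name intersection excludes its whole
subtree automatically, and a failed division (d = 0) is itself the scored
error while its missing descendants contribute nothing. Cells with no
shared observations yield `NA`, never 0 — absence of evidence is reported
as such. `tidy()`, `glance()` and `autoplot()` expose the result as a long
tibble, a one-row summary, and the standard lineage × stage heatmap.

## DTC migration kinematics

Trajectories are tibbles of (time, s, t) samples at a nominal 20-minute
cadence. Three corrections/conventions come before any kinematics:

* `correct_ap_offset()` removes the animal's A–P displacement between the
  Z-slice containing the cell and the reference slice, measured as the mean
  displacement of anatomical markers (pharyngeal bulbs, vulva, anus) seen
  in both slices. With no shared marker the correction is skipped with a
  warning rather than guessed.
* `reference_origin()` puts `s = 0` at the midbody (midpoint of posterior
  pharyngeal bulb and anus) in L1–L3 and at the vulval invagination from
  L3–L4 on; the synthetic animal plants these so the two definitions agree
  within 2 µm, as they do in real animals.
* Outward-positive sign: `v_AP = sign(s)·ds/dt`, so the anterior and
  posterior DTC share one convention in which outward migration is
  positive.

`smooth_trajectory()` applies a centred 1-hour sliding average with uniform
weights over in-window samples, truncated (not padded) at the ends —
padding would invent data. `trajectory_velocity()` differentiates with
central differences on the actual timestamps (gaps are respected; one-sided
at the ends). Both operators are linear, so they commute on interior
points, the velocity of a linear ramp is its slope exactly, and a smoothed
sinusoid is attenuated by exactly the boxcar factor `sinc(T/P)` — all
frozen as tests. `detect_midline_crossing()` reports the first
ventral-to-dorsal sign change of the smoothed `t` series, linearly
interpolated between samples. `align_to_event()` plus `average_aligned()`
re-time per-animal series to hours from an ecdysis and average across
animals with per-bin s.e.m., which is what makes the tight coupling of the
dorsal turn to the L3 molt visible despite animal-to-animal jitter in
absolute molt times.

## Expression quantification

`build_kymograph()` averages fluorescence over a D–V window `|t| < 60 µm`
and bins A–P position as a percentage of body length (100 bins of 1%), so
animals and time points of different lengths align. `regional_trace()`
integrates 5%-of-body-length regions centred at 25, 50 or 75%.
`total_intensity()` integrates over the body band in the camera frame and
subtracts a per-frame background (the median intensity outside the band),
making the readout invariant to constant offsets; whether published
whole-animal traces are background-subtracted is not always stated, so this
choice is explicit and configurable by its `half_width` argument.

`nuclear_mean_intensity()` implements Otsu segmentation of a 5 µm × 5 µm
ROI around each annotated nucleus and returns the mean intensity over the
mask; nuclei change size and shape over development, which the
per-timepoint mask absorbs. The Otsu threshold is computed exactly — every
midpoint between consecutive distinct intensities is scored by
between-class variance — rather than on a binned histogram, so the result
is exact for float images too and testable against exhaustive search; on
8-bit data it agrees with EBImage's histogram implementation to within a
bin.

`detect_stage_peak()` smooths a trace with a Gaussian filter and takes the
per-stage argmax. The filter's "width of 1 h" is interpreted as σ = 1 h
(the conventional reading; configurable), truncated at ±3σ with
renormalized edge kernels. A maximum on the first or last in-stage sample
is flagged as a boundary hit — such a pulse may be truncated. Peak
detection is invariant to affine intensity rescaling by construction.
`peak_relative_to_event()` re-expresses peaks as hours before the ecdysis
ending the stage; on cohorts this is the statistic that shows molt-locked
timing (small relative s.d.) despite large absolute jitter.
`trace_correlation()` computes Pearson's R over shared time points, pairing
within animal and pooling across a cohort; zero-variance traces give `NA`
with a warning rather than a fabricated number.

## The synthetic worm and what it does (not) emulate

`worm_config()` fixes the study conditions once; defaults are the field's
standard numbers: stage durations 11.1, 7.3, 7.1, 10.2 h (L1–L4) with
per-stage s.d. 0.2, 0.2, 0.3, 0.4 h; a centre-early/ends-late division
sequence (V5 first, V3 0.4 h early, T 0.5 h late) with 0.3 h cell-level
timing noise; the L2 symmetric doubling round for H1, V1–V4 and V6; DTC
outward migration at 5.5 µm/h on the ventral side, a dorsal crossing
starting 3 h before the L3 ecdysis and lasting 3 h (anterior DTC leading by
0.4 h), inward return at 7 µm/h from the molt; one expression pulse per
stage peaking 1.1 h before the animal's own ecdysis; and a mutant error
model converting asymmetric divisions to symmetric or suppressing them
(default rates 62/456 and 9/456 when enabled). Imaging is rendered at
1 µm/pixel on a 160 × 300 frame every 20 min: a sine-bent midline whose arc
length follows the growth law, re-posed every frame (random phase,
amplitude and rigid jitter), nuclei as Gaussian spots on the side nearest
the objective, a dark body band in the transmitted channel, Gaussian read
noise, and a planted inter-Z-slice A–P shift for testing the marker
correction. A given seed reproduces every frame and table bit for bit.

Deliberately *not* emulated: optics (no PSF, scattering, or the real
side-dependent visibility), 3-D anatomy (the axis is planar per frame, as
in the annotation protocol), bacterial food, animal flipping at molts, and
photobleaching. Tests passing on this generator therefore validate the
geometry, statistics and signal processing — not robustness to optical
artefacts of real microscopes.

Simulation sizes used throughout the tests and the acceptance script — one
full rendered movie (~110 frames), cohorts of 16–20 table-only animals, 200
seeded peak-recovery runs, 100 randomized lineage-oracle cases — were
chosen as the smallest sets for which the statistical checks have
comfortable margins.

## Numerical choices and edge cases, collected

* Interpolating (not smoothing) spline; natural boundary conditions.
* Projection ties → smallest `s`, with a warning; beyond-endpoint points
  clamp; polish step rejected if it increases distance.
* Straightening: bilinear interpolation, zero fill, ventral-at-top row
  order; intensity conservation only where `|t·κ| ≪ 1` (see above).
* Half-open stage intervals; ecdysis belongs to the next stage.
* `P(l, s)` undefined (NA) entries stay out of row/column means.
* Sliding average truncated at ends; Gaussian filter σ-parameterized,
  ±3σ support, renormalized at edges.
* Otsu ties resolve to the lowest threshold; degenerate (constant) ROIs
  are an error ("no contrast for segmentation"), not a silent mask.
* All randomness flows through explicit seeds; cohort animal `i` derives
  its seed from the configuration seed and `i`.

## A worked example

```{r example, eval = FALSE}
mv <- generate_movie(worm_config(seed = 1))
save_annotations(mv$annotations, "annotations.json")
ann <- load_annotations("annotations.json")

# geometry: per-frame body length
annotation_body_lengths(ann)

# lineage: relative division timing and a mutant comparison
rel <- relative_division_time(ann$divisions)
tl <- ann$timeline
mut <- generate_lineage(worm_config(seed = 2), tl, "m1", p_symmetric = 0.14)
autoplot(lineage_error_probability(ann$divisions, mut))

# migration: smoothed velocities aligned to the L3 molt
traj <- annotation_dtc_trajectories(ann)
traj |>
  dplyr::filter(cell == "posterior") |>
  smooth_trajectory() |>
  trajectory_velocity() |>
  align_to_event(tl, "L3_ecdysis") |>
  average_aligned("v_ap_um_h")

# expression: kymograph and molt-locked peaks
axes <- annotation_body_axes(ann)
ky <- build_kymograph(mv$frames_fluor, axes, ann$pixel_size_um, mv$times_h)
tr <- regional_trace(ky, 50)
peak_relative_to_event(detect_stage_peak(tr, tl), tl)
```

## Known limitations

* The body axis is two-dimensional; Z-structure enters only through the
  marker-based inter-slice correction.
* Straightened intensities are not Jacobian-corrected (standard practice,
  but see the curvature caveat).
* The wild-type seam division program is the stylized textbook pattern;
  real lineages have stage-specific exceptions that a user-supplied
  reference table can encode.
* `ecdysis_fraction()` normalizes by total N, which understates fractions
  if animals leave the recording early.
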