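---
title: "Quantifying plasma membrane repair, calcium clearance and ER fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasma membrane repair, calcium clearance and ER fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrq)
```

## Scope and data model

`pmrq` quantifies the live-cell time-lapse assays used to characterise
plasma membrane repair (PMR) and its calcium-dependent machinery in
cultured muscle cells:

* **dye-entry repair kinetics** — after focal laser injury, a lipophilic
  FM dye enters the wounded cell until membrane resealing stops it; the
  ΔF/F time course and a repaired/failed call per cell are the readouts;
* **cytosolic Ca²⁺ clearance** — Fluo-4 transients summarised by peak,
  time to clear 75% of the peak, and area under the curve (AUC);
* **ER fragmentation** — the fraction of the cell's longest axis from the
  injury point over which tubular ER has turned punctate
  ("beads on a string");
* **FRAP mobility** — mono-exponential recovery fits giving the mobile
  fraction and recovery time of ER membrane proteins;
* **bead-injury population counts** — injured (green-dextran⁺) and
  failed-to-repair (green⁺red⁺) cells, with failure expressed as a
  percentage of injured cells;
* **two-group statistics** — unpaired Student's t or Mann–Whitney
  rank-sum comparisons with automatic selection.

Every assay has a synthetic generator that produces image stacks or traces
together with machine-readable ground truth, so the whole pipeline is
testable without microscope data.

Conventions used throughout: images are `T × C × Y × X` arrays of integer
detector counts (AU) in `[0, 65535]`; coordinates are **1-based (row, col)
pixel centres** (the natural convention for R arrays; it is stated once
here and obeyed everywhere); times are seconds **relative to the injury or
bleach frame**, which sits at time 0. ΔF/F is `(F − F₀)/F₀` with `F₀` the
mean over a pre-injury baseline window — by default every frame strictly
before the injury frame (at least two frames). Background correction
(subtracting the per-frame mean of a background ROI) is optional,
disabled by default, and recorded in the trace metadata, since published
protocols rarely state whether it was applied.

## The synthetic generators and their noise model

The generators emulate the *study conditions* of a typical confocal
laser-injury experiment, and their defaults are fixed accordingly:

| assay | sampling | geometry / signal | noise defaults |
|---|---|---|---|
| dye influx | 2 s/frame, 90 frames, injury at frame 10 | ellipse cell, baseline 100 AU, influx 5 AU/s | read σ = 2 AU, shot noise 0.5 AU/photon |
| Ca²⁺ transient | 0.2 s/frame (5 frames/s), 960 frames, injury at 10 s | baseline 100 AU, peak +50 AU | additive σ = 1 AU |
| ER field | single- or multi-frame, 112×112 px | ridges period 6 px, spots r = 1.2 px | read σ = 4 AU |
| FRAP | 1 s/frame, 100 frames, 5 pre-bleach | bleach depth 0.8 | σ = 2% of baseline |
| bead field | single frame, 384×384 px | discs r = 5–9 px, 150 cells | noise-free by default |

The influx model is piecewise linear: flat baseline, a rise at
`influx_rate` from the injury frame, and a hard plateau `repair_time`
seconds after injury for repairing cells; non-repairing cells rise until
the detector clips. This reproduces the qualitative dye-entry shapes
(entry stopping within a minute in repairing cells, continuing beyond two
minutes otherwise) with the fewest parameters. The Ca²⁺ transient is a
difference of exponentials renormalised to the requested peak amplitude —
the standard transient shape; its `rise_tau → 0` limit is a step followed
by a pure exponential decay, which is the analytically convenient case
used in the tests. FRAP recovery is
`baseline·(1 − depth + mobile·depth·(1 − e^{−t/τ}))`.

Camera noise is Poisson shot noise (parameterised as AU per photon) plus
additive Gaussian read noise, then quantisation to integer counts —
the standard CMOS/EMCCD model. With both noise terms at zero, generated
pixels equal the analytic model exactly, which is what makes the
noise-free acceptance checks exact rather than approximate. Generators
are bit-deterministic for identical spec + seed.

What the generators deliberately do **not** emulate: optics (no PSF
beyond the Gaussian spot profile), dye diffusion or Ca²⁺
electrodiffusion physics, cell movement, focus drift, photobleaching of
the dye-entry signal (published dye-entry analyses apply no bleaching
correction either), or overlapping/touching cells in the bead assay.
Passing tests therefore demonstrate correctness of the *quantification*
given clean geometry and a realistic noise floor — not robustness to
segmentation failure modes real data can present. For real bead-assay
images with touching cells, a watershed split would be needed ahead of
the counting step; the validated path keeps cells separated.

## Repair classification

A cell is called repaired when its smoothed ΔF/F trace plateaus: the
least-squares slope over some sliding 20 s window starting within 120 s
of injury falls below 0.5% ΔF/F per second (Gaussian smoothing, σ = 2
frames). The verbal criteria in the literature are "entry stops within a
minute" versus "entry continues beyond two minutes"; the defaults sit
between the two and every threshold surfaces in the result's `params`.

The plateau *onset* is then refined with a hinge fit: a
ramp-then-flat model is least-squares fitted over the post-injury trace
for every candidate corner frame and the best corner taken (ties go to
the earliest frame, so an uninjured all-zero trace reports plateau time
0). The hinge fit localises the corner exactly on noise-free traces,
which window-based detection alone cannot do through the smoothing.

Traces that plateau because the detector clipped are a known failure
mode (saturation mimics repair); when the clip level is supplied via
`saturation_dff`, such traces are flagged `saturated` and not called
repaired.

## Calcium metrics

The peak is taken from the smoothed trace (σ = 2 frames), with standard
3-point parabolic vertex interpolation around the discrete maximum so the
peak time is not quantised to the frame grid. Clearance-75 is the first
post-peak time at which the smoothed trace falls to 25% of the peak,
linearly interpolated between frames; for a pure exponential decay of
constant τ this equals τ·ln 4, and the implementation recovers that
within one frame interval for τ from 5 to 40 s at 5 frames/s. The AUC
uses the **raw** trace (trapezoidal rule, injury to 180 s, negative
excursions clipped at zero — clipping is togglable): integrals are
noise-tolerant, threshold crossings are not, so smoothing is applied only
where it is needed. Cells whose transient has not cleared by the window
end are flagged `right-censored` and excluded from cohort clearance
means (with a censored count reported); all-zero traces are flagged
`no-transient` and carry no numeric metrics.

## ER fragmentation score

The injury axis is the straight segment from the injury point to the
farthest cell-boundary point (always a polygon vertex; distance ties are
broken towards the polygon's principal axis). For every pixel position
along the axis, a texture score is computed from the band of in-mask
pixels within 6 px of the axis and 4.5 px of the position (window 9 px).

The score is **1 minus the structure-tensor orientation coherence** of
the window's intensity gradients (central differences after light
Gaussian pre-smoothing at a fraction of the tubule scale). Intact
tubules vary essentially in one direction, so their gradients share a
single orientation and the score is near 0; punctate texture has
isotropically distributed gradients and scores near 1. On the synthetic
textures the two classes sit at ≈0.02 and ≈0.93. A per-window
coefficient of variation was evaluated first and rejected: sinusoidal
ridges are themselves high-contrast, and the measured class means (0.29
vs 0.31) gave no separation. The coherence score is invariant to
rotation and to global intensity scaling by construction, which the test
suite verifies directly.

The tubular/punctate threshold is not a magic constant: it is calibrated
as the midpoint of the mean scores of pure-tubular and pure-punctate
synthetic fields generated at matched noise
(`calibrate_fragmentation_threshold()`), and must be recalibrated when
texture parameters change. The fragmented length is the maximal
contiguous run of above-threshold positions starting at the injury point
(fragmentation is measured as a single length from the injury site);
isolated distal punctate stretches are reported separately. Windows
whose band loses more than half its pixels to the mask boundary — as
happens at the tapering cell tips — are flagged invalid and inherit the
nearest valid classification, so a tip cannot spuriously start or break
a run. The per-position score profile is lightly smoothed (σ = window/4)
before thresholding so that single-window noise cannot truncate a run.
Pixels whose gradient stencil touches the mask boundary are excluded so
the strong cell-edge gradient cannot contaminate the texture statistics.
Whether to score a single post-injury frame or the whole time course is
left to the user: both operators exist, and frames are scored
independently (no temporal smoothing).

## FRAP fitting

Traces are normalised to a pre-bleach mean of 1; an optional whole-cell
reference trace divides out acquisition bleaching (a reference identical
to the measured trace cancels it and is flagged degenerate). Recovery is
fitted as `y0 + M·(1 − e^{−t/τ})` on the post-bleach points
(Levenberg–Marquardt via `minpack.lm`), and the mobile fraction is
`M/(1 − y0)`. All three parameters are free in the fit: fixing `y0` at
the mean of the first two post-bleach frames — a common convention —
systematically overestimates the post-bleach floor because the second
frame already contains recovery (≈2% bias at τ = 15 s, 1 s frames), so
the two-frame mean serves as the starting value and is reported
separately as `post_bleach_level`. Noise-free recovery is then exact. A
flat post-bleach trace short-circuits to mobile fraction 0 (`no-recovery`
flag) since τ is unidentifiable; fits outside [−0.05, 1.05] are flagged
`implausible`. A mono-exponential is the simplest model adequate for
comparing recovery curves; no diffusion-equation model is attempted
because spot geometry is typically unreported.

## Bead-assay counting

Cells are detected as connected components (≥ 20 px) of the per-pixel
maximum across the two channels; each detected cell is scored positive
per channel by comparing its mask-mean intensity against the channel
threshold. Detection on the channel maximum (rather than green alone)
makes the operation symmetric: swapping the channels swaps every cell's
flags exactly, and a hypothetical red-only cell is still detected and
reported as an anomaly rather than silently missed.

Automatic thresholds use a half-maximum rule — channel median (the
background, since cells are sparse) plus half the range above it. An
Otsu threshold restricted to cell masks was considered and rejected: it
degenerates when a channel has all-positive or all-negative cells (it
then bisects a unimodal mode), and such compositions are entirely
legitimate (an experiment where every injured cell repaired has zero red
cells). The half-maximum rule returns +∞ for a featureless channel, so
nothing is called positive there, and both thresholds can be overridden
manually. The failure rate is `100 · n_failed / n_injured`, undefined
(with a flag) when no cell is injured.

## Statistics

`compare_groups()` mirrors the conventional selection procedure:
Shapiro–Wilk normality on each group and a median-centred Levene
(Brown–Forsythe) equal-variance check, Student's unpaired t when all
pass at α = 0.05, Mann–Whitney otherwise; the chosen test and the check
p-values are recorded in the result. All tests are two-sided, and no
multiple-testing correction is applied by default (apply
`stats::p.adjust` downstream if needed). The Mann–Whitney p-value is
exact by complete enumeration of group assignments (midranks for ties)
when both groups have ≤ 8 observations — small-n exactness matters at
typical per-experiment cell counts — and the tie-corrected normal
approximation otherwise. Identical constant samples yield p = 1 with a
zero-variance warning. The simulated type-I error of the full
auto-selection procedure on normal nulls (n = 20 per group) sits near
the nominal 0.05, which the acceptance checks verify by simulation.

`render_summary()` produces the standard presentations (per-group
mean ± SEM time courses; bar-plus-jitter group summaries annotated with
the selected test) and writes every plotted number to CSV alongside the
figure.

## Interfaces, problem sizes, reproducibility

The package's interface is its exported functions; analyses are a few
lines of R (see the README's worked example), so no shell entry point is
shipped — `scripts/acceptance.R` shows the whole pipeline driven
end-to-end from `Rscript`. Stacks are written as 16-bit multi-page TIFF
(multi-channel data as channel-interleaved single-plane pages, because
grayscale+alpha pages do not round-trip integer data through libtiff);
ROIs and ground truth are JSON sidecars with a documented schema rather
than binary ImageJ ROIs, for transparency and testability.

The validation suite exercises the documented study conditions at sizes
chosen to keep a full run in the low minutes on one core: repair
cohorts of 100–200 cells rendered as full 64×64 stacks, 20 ER fields per
fragmentation level, 100 FRAP replicates, 50 randomized bead specs plus
200 binomial replicates, and 1000 null replicates for the test-size
simulation. All randomness flows from explicit integer seeds.

## Known limitations

* ROIs are inputs; there is no automatic segmentation for the
  single-cell laser-injury assays (matching the per-cell workflow these
  experiments use), and no watershed splitting of touching cells in the
  default bead path.
* Physical units (µm) appear only when a pixel size is supplied;
  nothing in the pipeline depends on it.
* Fluo-4 intensity is not converted to absolute [Ca²⁺] (no calibration
  model), and FRET-based ER Ca²⁺ sensors are out of scope.
* The fragmentation score is validated on synthetic tubular/punctate
  textures; real ER images with strong lamellar sheets or out-of-focus
  light may need recalibrated texture parameters.
* Proprietary microscope formats (ND2, CZI, OIB) and OME-XML are not
  read; convert to TIFF first.
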