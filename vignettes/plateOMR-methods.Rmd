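---
title: "Methods: plate-based activity and optomotor response measurement"
author: "plateOMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based activity and optomotor response measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateOMR)
```

## The measurement problem

Zebrafish larvae at 5 days post-fertilization are a standard system for
small-molecule behavioral screening. Two readouts carry most of the signal:
**activity** (how often a larva moves) and the **optomotor response** (the
innate tendency to swim in the same direction as a moving visual pattern,
which requires an intact visual system). plateOMR implements an imaging
pipeline that extracts both from time-lapse photographs of up to four
96-well plates: one high-resolution RGB frame every 6 seconds, larvae in
shallow wells (7.15 mm diameter, 3.25 mm depth) that act as effectively
two-dimensional arenas, and red stripes projected through the translucent
plate bottoms as the visual stimulus.

Because no public image series exists for this assay, the package ships a
full simulator that renders synthetic recordings with known per-larva
parameters, so every pipeline stage can be validated by parameter recovery
rather than by eye.

## The assay timeline

A recording is divided into 10-minute **periods** (`period_schedule()`):
periods 1–2 show a blank background; periods 3–12 show stripes that
alternate direction, moving *down* in odd periods (3, 5, 7, 9, 11) and *up*
in even periods (4, 6, 8, 10, 12). A 1-hour acclimation precedes recording;
if acclimation frames appear in an input series they are tagged period 0 and
excluded from every score. The stripes are 1 mm thick, separated by a 7 mm
gap, and travel at 7/8 mm/s. "Separated by 7 mm" is read edge-to-edge, so
the pattern pitch is 8 mm and the pattern position repeats every 64/7 s;
the alternative center-to-center reading is one `stimulus_spec()` parameter
away.

## Detection: subtractive analysis

The detector (`run_detection()`) works on a single color channel chosen so
that the moving stimulus is invisible to it: the channel in which stripe
pixels and background pixels have the most similar mean intensity
(`select_channel()`, ties broken red–green–blue). On the physical rig the
projected colors — background RGB(191,191,191), lines RGB(255,0,0) — are
deliberately exposure-matched so that the red channel satisfies this; the
simulator reproduces the captured appearance with a configurable
`line_render_color` (default RGB(196,60,50)) for the same reason. Rendering
the projected pure red literally would make the stripes flash through every
difference image at |255−191| = 64, well above threshold, which is exactly
what the rig's calibration prevents.

Consecutive frames are subtracted as absolute differences, so static
structure (well walls, plate edges) cancels and displaced larvae remain as
a dumbbell of their old and new positions. Within each well region the
detector counts pixels at or above the intensity threshold (default 25 of
255), takes the unweighted centroid of all suprathreshold pixels (no
connected-component selection — the dumbbell as a whole is the measurement),
and flags a **movement** when the area reaches 20 pixels. A difference row
is attributed to the later frame of its pair, i.e. to the time the movement
is observed. The alternative **background mode** differences each frame
against the per-pixel median of the series and therefore sees motionless
larvae too; it is intended for sparse plates where a clean median exists.

Two conventions are deliberate and documented rather than derived: a
centroid exactly at the well center classifies as "down" (a measure-zero
tie), and intervals with no suprathreshold pixels contribute nothing to the
up/down denominator (an optional carry-forward mode inherits the last known
position instead, off by default).

## Well geometry

Rows are outlined by the user (the rig's plates are not auto-detected), and
each row outline is divided into equal-width well regions
(`partition_row()`); when the outline width is not divisible, the leftover
pixels go to the leftmost regions, so regions tile the outline exactly and
deterministically. Rectangles are half-open `[x0,x1)×[y0,y1)` with the image
origin top-left and y increasing downward; "up" in a well is smaller y.
Measurement uses the full rectangle by default, matching region-based
measurement of a thresholded selection; an inscribed circular mask (7.15 mm
diameter, requires the pixel scale) is available as an opt-in refinement.

## Scores

**Activity** ("lmpi", larval movement per interval) is the percentage of
scored intervals with a movement flag. The headline activity value is the
first 10-minute period after acclimation, the assay's reference window.

**E-O** is the visual-response statistic: the mean percentage of intervals
spent in the upper half of the well during even (stimulus-up) periods minus
the same during odd (stimulus-down) periods. It ranges over ±100 percentage
points, is antisymmetric under relabeling the period parity, and has
expectation 0 for a stimulus-blind larva. Larvae below an activity floor
(default 5%) are flagged `eo_valid = FALSE`: too few position fixes for a
reliable vision measure. The floor is applied per larva — a stricter,
well-defined version of the assay's group-level 5% rule — and is
configurable.

Because the default schedule gives every period the same number of frames,
computing up% per period and averaging equals computing it over pooled
frames; the per-period route is used so that unbalanced custom schedules
remain well-defined.

## Group statistics

Scores are not normally distributed, so the workflow is unconditionally
nonparametric: scores are binned and groups compared by Pearson chi-squared
(no continuity correction). Activity uses quartile bins (0–25, 25–50,
50–75, 75–100; upper-open except the last, so 25.0 falls in the second
bin), E-O uses terciles (<0, 0–10, >10; the middle bin closed on both ends).
The written ranges carry no edge rules, so these conventions are chosen to
be total and are documented here. Bins empty in both groups are pruned
before testing (they would give 0/0 expected counts); a bin empty in only
one group is kept, because that asymmetry is signal. E-O values are also
tested against the 50–50 sign null (goodness-of-fit, 1 dof), with E-O = 0
counted as non-positive, consistent with its tercile placement.

Significance uses the Bonferroni-corrected thresholds 0.05/n and 0.01/n for
n comparisons in a contrast family. When an experiment is repeated on
separate days, each day is tested against its own internal control and the
**median** per-day p-value is reported.

## The simulator

Each larva is a stochastic agent updated once per frame interval
(`step_larva()`): with probability `p_move` it displaces by `step_length_mm`
along the unit vector of `(1−g)·u + g·s`, where `u` is a uniform random
direction, `s` the stimulus direction, and `g ∈ [0,1]` the **optomotor
gain** — `g = 0` models blindness, `g` near 1 strong stimulus-following.
During blank periods the direction is purely random. Each larva draws from
its own L'Ecuyer-CMRG substream keyed by (seed, plate, row, col), so
simulations are bit-reproducible and independent of iteration order.

Choices that matter:

* **Wall handling.** A step that would exit the confinement circle is
  reflected off the wall: the outward component of the direction is flipped,
  the full step re-taken, and any residual radial excess clamped to the
  wall. A naive radial fold (`r → 2b−r`) was rejected because a larva pushed
  steadily against the wall by a strong stimulus then oscillates with
  near-zero net displacement, becomes invisible to frame differencing, and
  breaks parameter recovery at high gain; the specular bounce keeps every
  displacement at essentially full step length. The confinement radius is
  the 7.15/2 mm well radius minus the body's minor semi-axis, so the
  rendered body stays inside its well region.
* **Body model.** A rigid ellipse (default semi-axes 1.1 × 0.6 mm) rotated
  to the heading, rendered at dark gray RGB(60,60,60) on the 191-gray
  background — the high-contrast head/yolk silhouette of a roughly 4 mm
  larva; tails are translucent and rarely cross the threshold, and 6-s
  snapshots cannot resolve kinematics anyway. The contrast |191−60| = 131
  clears the threshold of 25 by a wide margin, as on the real white plates.
* **Step length.** 1 mm per moving interval. The assay does not constrain
  larval speed between 6-s snapshots; this is a simulator convention, not a
  measured quantity.
* **Rendering scale.** Default 5 px/mm (the rig resolves ≈20.7 px/mm at
  48.3 µm/px). At 4–5 px/mm the moved-larva dumbbell is 30–80 px, safely
  above the 20 px cutoff; large studies in this package's own tests render
  at 4 px/mm for speed.
* **Noise.** Additive Gaussian intensity noise is available
  (`render_spec(noise_sd=)`) but defaults to 0, because the validation
  suite asserts *exact* agreement between detection and ground truth where
  the geometry guarantees it.

What the simulator does **not** emulate: swim-bout kinematics within an
interval, body pigmentation changes, eye morphology, water-surface optics,
illumination gradients, or pharmacokinetics — presets such as `"immotile"`
and `"blind"` model treatment *endpoints* (e.g. full anesthesia, suppressed
vision), not drug action. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated, not that real larvae behave like
the agent model.

## What the validation shows

All quantities below are computed by the test suite
(`tests/testthat/`) and the acceptance script (`scripts/acceptance.R`) at
run time; problem sizes were chosen as the smallest that make the checks
statistically meaningful:

* Sweeping synthetic blobs recovers the operating constants: 20 px is the
  smallest area flagged as movement, 25 the smallest foreground intensity;
  the standard four-plate layout partitions into 384 wells.
* The rendered stripe pattern travels 70 px in 8 s at 10 px/mm (7 mm),
  recovered by row-profile cross-correlation.
* Parameter recovery: with 24 larvae per group over twelve 5-minute
  periods, measured activity lands within 3 SEM of 100·`p_move` at every
  gain in {0, 0.25, 0.5, 0.75, 1}, and group-mean E-O is strictly
  increasing in gain.
* Null calibration: with gain 0 and 384 larvae over a full 2-h assay, the
  fraction of positive E-O values is 50% within binomial error, and the
  homogeneity test's type-I error over 200 identical-parameter replicates
  is within 5% ± 3.5%.
* Detection equals ground truth on noise-free renders: no false positives
  at all, and every net displacement ≥ 0.5 mm is detected. Sub-resolution
  displacements (wall grazes) fall below the 20 px cutoff by design — that
  cutoff exists precisely to ignore sub-threshold motion.

## Degenerate inputs and numerical conventions

Empty wells produce area 0, undefined centroids, and are excluded from
up-percentage denominators; larvae below the activity floor keep their
activity score but not their E-O. Unreadable frames flag their frame pairs
`valid = FALSE` rather than being dropped silently. Images are processed in
8-bit; higher bit depths are rescaled on load with a warning. All CSV output
uses fixed `%.6g` formatting so identical (config, seed) runs are
byte-identical.

## Known limitations

Identity is positional: the pipeline never tracks larvae across wells, and
a well is one larva by design. The E-O statistic quantifies vertical
stimulus-following only; orientation, swim distance, and habituation
metrics are out of scope. The chi-squared tests rely on the usual
large-sample approximation; with very small groups (n < ~10 per group)
binned counts are sparse and p-values approximate.
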