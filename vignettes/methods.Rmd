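---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvasleep)
```

This vignette is the package's own account of the quantitative methods it
implements: the models, their assumptions, the tunables that matter, and
the choices made where the underlying assay descriptions leave the design
open.

## Larval activity classification

Larval sleep is scored from grayscale time-lapse video of single animals
in arena wells, acquired at 0.87 frames/s. The per-frame activity
statistic is a *changed-pixel count*: frame $t$ gets
$s_t = \#\{\,p : |I_t(p) - I_{t-1}(p)| > \delta\,\}$ over in-well pixels,
with noise floor $\delta$ (`noise_floor`, default 10 on the 8-bit scale).
Counting changed pixels rather than summing absolute differences makes the
statistic insensitive to static illumination gradients and to the overall
contrast of the animal; only *how many* pixels moved matters. Frame 0 has
no predecessor and copies frame 1's score, so a recording never opens with
an artificial state transition.

A frame is *active* iff $s_t > \theta$, strictly; equality classifies as
inactive, a deliberate conservative tie-break toward quiescence. The
threshold $\theta$ is calibrated per recording: without labels, by Otsu's
criterion on the score histogram (ties between equally good candidates
resolve to the lowest, keeping the result deterministic); with labels, by
an exhaustive scan of candidate midpoints maximising frame accuracy. No
temporal smoothing is applied by default — the 12-frame bout criterion
already suppresses single-frame flicker — though a 3-frame median filter
is available behind a flag.

Assumptions: one animal per well; the animal is darker than the substrate;
camera and illumination are static. The classifier makes no attempt to
distinguish behaviors beyond the binary active/inactive dichotomy.

## Sleep bouts and derived metrics

Sleep is an inactive run of at least `min_sleep_frames = 12` consecutive
frames (≈ 13.8 s at 0.87 fps). The threshold is counted in frames, not
seconds, because the criterion is defined on the acquisition grid; the
seconds value is derived, never configured. Bouts are 0-based, half-open
frame intervals, which makes adjacency arithmetic unambiguous
(`end − start` is the length; abutting intervals share an endpoint). Runs
truncated by the recording edges count when they meet the threshold —
discarding them would bias short recordings toward wake. Sleep latency
with no bout is `NA`, not 0 and not the window length; both substitutions
would silently distort group medians.

`sleep_metrics()` guarantees the partition identity
`total_sleep_s + total_wake_s = window length` exactly (wake is computed
as the complement, not independently).

Wake-gated locomotion speed divides centroid travel distance by wake time
while excluding sleep from both numerator and denominator; each
inter-frame displacement belongs to its destination frame and is dropped
(together with its time) when either endpoint was not validly tracked.
This makes the speed estimate invariant to inserting or removing sleep:
slower average motion in a sleepy genotype cannot be an artifact of the
time spent asleep.

Centroid tracking uses a per-pixel temporal median over a sliding
101-frame window as background, reinforced by the pixelwise maximum with a
per-column spatial median. The temporal model alone fails for an animal
quiescent longer than half the window (it becomes part of its own
background); since the substrate is always the bright component, taking
the brighter of the two estimates restores it without disturbing tracking
of moving animals.

## Deprivation schedule and indices

`deprivation_schedule()` encodes the standard protocol: a 3600 s
unstimulated baseline, then a 3600 s session of repeated LED cycles, ON
90 s / OFF 30 s (30 full cycles, 2700 s of stimulation at the defaults); a
final partial ON interval is truncated at the session end. The
light-response index is ON-phase sleep normalised to the 1 h OFF baseline;
the rebound index is post/pre sleep, with both returning `NA` (with a
warning) on a zero baseline rather than an arbitrary number. The rebound
ratio is a declared convention of this package — the assay literature
reports rebound without fixing a formula.

## Adult DAM scoring

Adult sleep bouts are maximal runs of 1-min bins with zero beam crossings,
of length ≥ `adult_min_gap_min = 5`. The criterion is read as "≥ 5 silent
minutes", the conventional adult-fly criterion, rather than a strict
"> 5 min" (which would demand 6 bins); the threshold is configurable for
users who prefer the strict reading. Monitor rows whose DAM2 status is not
the valid code break silent runs and are never imputed as immobility —
missing data must not fabricate sleep. Day/night splits label each bout
minute by clock time under the LD cycle (lights on 09:00, off 21:00 by
default), so a bout crossing lights-off contributes to both phases; two
recording days are summarised as two 24-h windows aligned to lights-on.

## Cell quantification

The nuclear localization index of a translocation reporter is
$\mathrm{NLI} = (F_{nuc} - F_{cyto}) / (F_{nuc} + F_{cyto})$, where
$F_{nuc}$ and $F_{cyto}$ are *region-mean* reporter intensities over the
nuclear and cytoplasmic (cell minus nucleus) masks, background-subtracted
and floored at zero. A subtractive reading of the cytoplasmic term
("whole-cell minus nuclear signal") is dimensionally inconsistent for
means and can push the index outside $[-1, 1]$; the region-mean
convention keeps it bounded, and an integrated (summed) mode is provided
behind a flag for comparison. Background defaults to the median intensity
outside the cell mask of the same image, since no separate background
protocol is specified for these assays. ROIs come from two-pass Otsu
segmentation of the activity-insensitive reference channel (cells vs
background, then nucleus vs cytoplasm within each cell; components under
`min_cell_area_px = 30` are dropped) — an automated stand-in for manual
ROI drawing. Cells, not brains, are the statistical unit: pooling is
concatenation with brain provenance retained, never per-brain averaging.

Food intake is the ratio of dye-stained to total body area: body = largest
connected component darker than the white background on luminance; stain =
body pixels whose red excess $R - (G+B)/2$ exceeds a configurable
threshold.

## Group statistics

Mann–Whitney U uses midranks; with both groups ≤ 8 and no ties the
two-sided p value is exact — full enumeration of all
$\binom{n+m}{n}$ rank assignments, doubled one-sided tail capped at 1 —
otherwise a normal approximation with tie correction and a 0.5 continuity
correction. Exact enumeration under ties is not attempted (the
tie-corrected approximation applies). Kruskal–Wallis uses the
tie-corrected $H$ with a $\chi^2_{k-1}$ tail; when every value ties the
statistic is undefined and returned as `NA` with a warning. The chi-square
test is Pearson's statistic without continuity correction. Bonferroni
multiplies by an explicitly declared family size (the planned comparisons
of one panel) — the family is never inferred silently. Quartiles use the
linear-interpolation (type 7) convention; the choice is documented because
assay reports rarely state one, and it matches R's default.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated against
known truth; its defaults are fixed study conditions, not tuning knobs.

- **Behavior**: alternating wake/sleep bouts with geometrically
  distributed frame counts (memoryless — the simplest law with a free
  mean). Defaults: mean wake 90 s, mean sleep 60 s, plausible bout scales
  for a quiescence assay at this frame rate and convenient for analytic
  checks (stationary sleep fraction 0.4).
- **Video**: the larva is an ellipse (length 15 px ≈ 1.5 mm at the default
  0.1 mm/px calibration, width one quarter of length) with sinusoidal
  length modulation (±2 px) as a peristalsis proxy, crawling at
  0.3 mm/s along a correlated random walk (heading SD 0.5 rad/frame)
  during wake and exactly frozen during sleep; wall collisions reflect,
  preserving step length. Intensities: substrate 200, larva 80, additive
  Gaussian sensor noise (SD 2) clipped to 8 bits, and a static ±5 % linear
  illumination gradient. An optional ≤ 1 px jitter during sleep can stress
  thresholding; it is off by default.
- **DAM series**: silent scheduled minutes; wake minutes draw
  zero-truncated Poisson counts (mean 5), so the programmed schedule is
  exactly the set of zero bins.
- **Cell images**: hard-edged discs (cell radius 18 px, nucleus 8 px)
  with a fixed total reporter signal split so that the nuclear share is
  the requested fraction $f$; the true index is $2f - 1$ by construction.
- **Dyed larva**: an ellipse body whose most anterior pixels are stained,
  covering the requested area fraction.

All randomness flows through one explicitly passed seed; identical
arguments give bit-identical output, and no generator touches global
random state (callers' RNG state is restored).

What the generator does *not* emulate: real larval postures and
head-sweep kinematics, occlusions and reflections at well rims, focus
drift, flicker, multi-animal wells, out-of-focus fluorescence or uneven
staining. Passing the synthetic benchmarks therefore demonstrates the
correctness of the algorithms under controlled conditions — scores,
thresholds, bout logic, index formulas — not robustness to every artifact
of real recordings; the classifier accuracy figure on synthetic truth
plays the role that manual-annotation agreement plays for real video.

## Problem sizes and numerical conventions

The validation suite uses sizes chosen to make sampling error negligible
relative to the tolerances tested: ten 1044-frame videos (seeds 0–9) for
classifier accuracy; 10⁴ random traces against an independent run-length
oracle; 20 render seeds per nuclear fraction across
$f \in \{0.1, \dots, 0.9\}$ with a ±0.05 recovery tolerance on the
median; 10⁴ null simulations at $n = 15$ per group for the 5 % ± 1 %
type-I check; and a 10-well cohort for end-to-end recovery of a programmed
30 %-sleep condition within 5 percentage points. Floating-point identities
(window partition, schedule arithmetic) are asserted exactly; physical
recoveries (speed, NLI) at the stated tolerances.

Coordinates are 0-based `(row, col)` with half-open intervals throughout;
violations are treated as bugs, not conventions. Distances are reported in
mm when `pixel_size_mm` is supplied and degrade to px (flagged in the
output) when the optics are uncalibrated, since no universal mm-per-pixel
calibration exists for these rigs.

## Known limitations

- The published assay does not disclose its exact pixel-change statistic
  or threshold; this implementation fixes both (changed-pixel count,
  Otsu/accuracy calibration) and treats the ~90 % frame-accuracy floor on
  ground-truthed video as the fidelity contract.
- Feeding-movement handling in the original immobility threshold is not
  quantitatively reproducible; the synthetic benchmark does not model
  feeding postures.
- Exact Mann–Whitney p values with ties, arousal-threshold assays, and
  circadian/periodogram analyses are out of scope.
- Video container decoding is not provided; frames are expected as
  multi-page TIFF or image sequences.
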