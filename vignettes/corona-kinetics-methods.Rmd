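---
title: "Quantifying aerotactic ring migration: models, estimators and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aerotactic ring migration: models, estimators and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronakit)
```

## The measurement problem

When a dense drop of *Dictyostelium discoideum* cells is confined under a
coverslip, the cells' own oxygen consumption creates centripetal hypoxia.
Within about an hour the colony self-organises into three density regimes: a
dense core of rounded, nearly immobile cells; a sparse intermediate zone of
elongated random walkers; and a dense circular front — the *corona* — that
migrates persistently outward toward higher oxygen. The quantities that
characterise this behaviour are all extracted from bright-field time-lapse
imaging:

* the ring **formation time** `T*` (first persistent peripheral density
  peak),
* the ring **initial speed** `v_i` (average over the first 140 min after
  formation) and **late speed** `v_f` (ordinary-least-squares slope of
  radius versus time over 10–24 h),
* the ring **width** `L(t)` and **density**, compared against the
  area-conservation prediction `L(t) = L0 R0 / R(t)` for a ring that keeps
  its cell number and density while growing in radius,
* the unconfined colony's **expansion velocity** `v_NC` (threshold sweep on
  the density border),
* single-cell **radial directionality** `v_r/|v|` as a function of distance
  from the colony centre, and the **von Mises concentration** `kappa` of
  step headings about the outward radial direction,
* **spontaneous motility** (mean instantaneous speed of uniformly seeded
  cells).

This package implements the full measurement pipeline and, because no
public raw data exist for this assay, pairs it with an agent-based
synthetic-colony generator whose ground truth is known exactly. Every
estimator is validated by *parameter recovery*: simulate a colony with
prescribed kinetics, render image stacks, run the pipeline end to end, and
compare the estimates with the generator's configuration.

## The synthetic colony generator

### Geometry and placement

A colony is seeded as a truncated two-dimensional Gaussian (`sd = 0.6 *
drop_radius`, truncated at `drop_radius`): the areal density is a smooth
dome decreasing monotonically from the centre, as in a freshly seeded drop.
We deliberately do not draw the *radial coordinate* itself from a
half-Gaussian — that superficially similar law concentrates mass as `1/r`
near the origin, which is unphysical and makes "central density" references
(used by the expansion-velocity threshold sweep) meaningless.

The default scaled-down geometry is a 1.2-mm drop of 5,000 cells (confined
presets); the experimental assay uses a ~2.8-mm drop of 50,000 cells. All
speeds are kept at their experimental values, so a 24-h confined run ends
with a ring at about 2.85 mm and the confined presets render a 6.1-mm field
(1024 px at 6 µm/px). Analyses that need sub-pixel centroids (single-cell
tracking) re-render at 2–2.5 µm/px.

### Motility model

Time advances in 1-min steps. Each moving agent takes a step of exact
length `speed * dt` with a heading drawn once per step from a von Mises
distribution centred on the outward radial direction; positions are
interpolated linearly to sub-step frame times. Redrawing headings once per
minute gives the cells an effective directional persistence of one minute —
the experimentally realistic scale — and means a 1-min velocity sample
recovers the configured speed exactly rather than a random-walk-shortened
fraction of it.

* **Rounded** cells do not move.
* **Elongated** cells move at `base_speed` (default 3.9 µm/min, the
  measured spontaneous motility) with heading concentration 0 (unbiased) —
  or a weak outward bias in unconfined mode (below).
* **Corona** cells move with heading concentration `ring_kappa = 0.5`.
  Since the mean cosine of a von Mises deviate is `A1(kappa) = I1/I0`, and
  `A1(0.5) = 0.2425`, a corona cell's *per-step radial directionality* is
  0.24 — the value observed for ring cells — and its mean radial drift is
  `A1(0.5) * speed`.

In kinematic mode the cells in the outermost shell (1,000–1,200 µm) at
`ring_formation_time` become a conserved cohort whose speed is set to
`v_ring(t) / A1(ring_kappa)`, so the cohort's mean drift equals the
prescribed ring speed *exactly*, with no tethering or artificial forcing:
the detected ring position is an emergent density peak of freely walking
agents. Seeding the cohort at the drop edge matters: a cohort seeded deeper
inside rides on a dense static background whose superposition biases the
detected peak inward early on and depresses the recovered `v_i`.

States are assigned once at seeding in kinematic mode (core cells rounded,
the rest elongated). Re-deriving them from the current radius each step
would freeze every random walker that strays into the core and pile cells
up artificially at the core edge.

### Prescribed ring trajectory (kinematic mode)

`R(t)` is continuous piecewise-linear: flat at `ring_start_radius` until
`ring_formation_time`, then `ring_speed_initial` until
`speed_crossover_time`, then `ring_speed_late`. The shipped presets are
calibrated to the wild-type and mutant kinematics the pipeline is meant to
recover: `AX2-confined` (formation 60 min, 2.2 µm/min until 600 min, then
0.67 µm/min), `catA-confined` (formation 28 min, initial 2.5 µm/min).

### Oxygen model (mechanistic mode)

A radial field `C(r, t)` (fraction of air saturation) obeys

    dC/dt = D * (1/r) d/dr (r dC/dr) - a * rho(r, t) * C / (C + Km)

solved by explicit finite differences on a 10-µm cell-centred grid
(zero-flux at the centre, `C = 1` at the outer boundary; the explicit
stability bound `dt <= dr^2 / 4D` is enforced and sub-stepped
automatically). `rho` is the live agent density normalised to the initial
central density. Agent states follow local oxygen: below `c_round = 0.02`
cells round up; between `c_round` and `c_crit = 0.10` they climb the
gradient (heading concentration `corona_kappa = 2`, the aerotactic
orientation strength — hypoxic cells in a steep gradient orient much more
sharply than the ring's *effective* 0.5); above `c_crit` they random-walk.
The ring emerges where outward-biased cells pile up at the stalling
`c_crit` contour.

No oxygen kinetics are reported for this assay, so `D = 600 µm²/min` (a
scaled-down effective diffusivity for the reduced geometry) and the
consumption rates are calibration constants: `a = 0.05/min` reproduces a
wild-type formation time of ~52 ± 4 min (target 60 ± 20), and the
catalase-null preset's faster hypoxia response is modelled
phenomenologically as `a = 0.16/min`, reproducing T* ≈ 28 ± 3 min. The
thresholds `c_round`, `c_crit` are free parameters of the model, not fits
to measurements — the assay they would be fitted against was never done.

### Unconfined and uniform modes

The `NC-spreading` preset emulates the unconfined control: all cells
elongated at 3.9 µm/min with a *weak* outward heading bias
`nc_bias_kappa = 0.16` (per-step directionality `A1(0.16) = 0.08`, the
maximum directionality observed anywhere in unconfined colonies) and
division on with an 8-h doubling time (typical axenic growth). The border
expansion speed is emergent — outward drift (~0.31 µm/min) plus
division-driven density growth pushing each density contour outward —
and lands near the 0.8 ± 0.3 µm/min reference band. `uniform-motility`
scatters cells over the whole frame with no bias, for the
spontaneous-motility assay.

### Division and rendering

Division duplicates an agent in place under a fresh id (probability
`division_rate * dt`; no mechanics of mitosis). Frames are rendered as
radially symmetric Gaussian bumps (sd = half the 5-µm render radius,
support truncated at 2 sd) on a dark background with additive Gaussian
noise (sd 6) and 8-bit clipping; identical parameters (including the seed)
give bit-identical stacks.

## The measurement pipeline and its numerical choices

**Binarization** follows the adaptive-mean rule `I > local_mean(block) -
offset` (51-px block). The offset convention matches OpenCV's
`adaptiveThreshold` constant; the default here is `offset = -20`, i.e. a
pixel must exceed its local mean by 20 intensity units. With the render
noise at sd 6 this keeps background false positives below 0.1% while cells
(peak ≈ 180 above background) are always caught. A small positive offset —
a common choice for other imaging modalities — would mark most of a
pure-noise background as foreground here.

**Radial profiles** are per-annulus foreground fractions (half-open 30-µm
bins, pixel-centre membership). Annuli clipped by the frame boundary are
normalised by the pixels actually present, so edge bins are unbiased.

**Corona detection** smooths the profile (3-bin moving average) and takes
the outermost local maximum beyond half the colony radius whose prominence
clears a noise floor. The floor is the largest of: (i) twice the sd of
first differences over the outermost empty annuli (measurement noise);
(ii) an absolute 0.5 density-percent minimum; and (iii) six binomial
standard errors of the smoothed peak estimate. Term (iii) is essential:
density fluctuations of the *cell field itself* are static, recur in every
frame, and therefore pass any persistence filter — they must be rejected
statistically. Annuli less than 90% complete (corner bins beyond the
inscribed circle) are excluded. The reported radius is the density-weighted
centroid of the region above half the peak prominence: the ring bump is
broad and, at late times, shallow (≈1% density), so the raw argmax is
quantised to the bin width and wanders by ±60 µm, while the centroid
tracks the ground-truth radius with ≈18 µm rms error. Finally, the trace
drops any detection more than 150 µm from a 5-point running median — an
isolated detector failure otherwise latches onto an interior density
feature millimetres away and a single such frame corrupts the late-phase
OLS slope.

**Formation time** is the first time the ring is detected in 3 consecutive
frames; the detection latency quoted with it is the persistence window plus
the time the cohort needs to carve a visible bump out of the colony flank
(about half the cohort width divided by the initial speed — ~15 min for the
confined presets, which is why a preset configured to form its ring at
60 min is typically *detected* at 70–80 min while `v_i`, measured from the
detected onset, is unaffected).

**Speeds.** `v_i` is the mean of per-interval velocities over
`[T*, T* + 140 min]`. The 2-h window sometimes quoted for the early phase
is supported via the `window` argument; 140 min is the default. `v_f` is
the unweighted OLS slope over 10–24 h.

**Ring width/density** uses a contiguous region around the peak above a
floor (default: baseline plus half the peak height above the
intermediate-zone baseline), resampled to 6-min cadence and binned five
measurements per reported point (mean ± sd).

**Expansion velocity** locates, per threshold, the outermost radius where
the profile reaches the threshold (sub-bin linear interpolation of the
crossing), averages 1-min border displacements over the first 5 h, then
averages over a sweep of nine thresholds (10%–50% of the initial central
density in 5% steps — the threshold choice is arbitrary, so a range is
used).

**Spot detection and linking** are Crocker–Grier style: 3×3 boxcar noise
suppression, boxcar background of about twice the 10-µm feature size,
local maxima of the difference above a percentile threshold (floored at 8×
the band-passed noise scale, estimated from the upper quartile so sparse
signal cannot inflate it), sub-pixel centroids over a circular window,
duplicate merging. Linking is greedy nearest-neighbour in global distance
order within a `10 µm/min × dt` search radius, deterministic, no gap
closing. Tracking analyses use 30-min windows at 3 frames/min.

**Velocity samples** are taken over non-overlapping 1-min windows anchored
to the absolute minute grid. Anchoring matters: a track that restarts
mid-minute otherwise contributes samples straddling two heading draws, and
the average of two outward-biased directions is *more* concentrated than
either — unanchored sampling inflated the measured directionality by
about 0.03. The ratio `v_r/|v|` is reported only for samples faster than
0.5 µm/min (the direction of a near-zero step is noise; set the floor to 0
to reproduce the convention in which quiescent cells contribute zero
ratios). Sliding-window profiles use a 150-µm window stepped by 25 µm with
at least 20 samples per window; extremum statistics (the profile maximum,
or its value at one radius) instead require thousands of samples per
window, because the maximum over ~50 overlapping windows of means estimated
from a few hundred angular samples each is dominated by selection noise
rather than biology. For the unconfined maximum — an extremum of a nearly
flat profile — the validation analyses additionally pool the velocity
samples of several replicate runs before windowing, the same way replicate
experiments are averaged; a residual upward bias of order 0.005–0.015 on a
true value of 0.08 is inherent to a maximum statistic at these sample
sizes.

**Tracking-window placement.** The confined directionality analysis tracks
at t = 720 min, mid-run, when ring cells move at 2.76 µm/min — an order of
magnitude inside the 10 µm/min linking search radius. Tracking during the
fast initial phase puts per-frame displacements at ~90% of the search
radius; the resulting censoring of large detected displacements biased the
directionality ratio upward by ~0.03 in our measurements.

**Von Mises fits** use the closed-form MLE: free mean — circular mean plus
`A1^{-1}(Rbar)`; fixed mean — `A1^{-1}(mean cos)` with the boundary value 0
when the mean cosine is non-positive. `A1` inversion is by bracketed
bisection to 1e-8; `kappa` is capped at 500, at which point the sampler
treats the distribution as a point mass.

## What the synthetic data do and do not establish

Passing recovery tests shows the estimators are unbiased and correctly
implemented *for data matching the generator's assumptions*: radially
symmetric colonies, constant per-state speeds, one-minute heading
persistence, Gaussian render noise, no cell–cell mechanics. Real
bright-field data add optical artifacts (uneven illumination, halos, focus
drift), cell-shape variability, contact interactions and crowding, none of
which are emulated; the binarization offset, spot-detection mass threshold
and prominence floor would need re-tuning on real images. The simulator's
corona also *diffuses* radially as it travels (its width grows slowly),
unlike the experimental ring, which thins as `1/R` at conserved density —
the area-conservation model is therefore exercised as a prediction overlay
here, not reproduced by the agent dynamics. Aggregation-stage behaviour
(streaming, cAMP signalling) and mechanical interactions are out of scope
by design.

## Problem sizes

The shipped analyses and validation runs use desk-scale colonies: 5,000
agents, 1024²–2048² px frames, 1-min steps over up to 24 simulated hours,
with density frames every 5 min for ring kinetics, every 1 min for
formation-time and expansion measurements, and 3 frames/min over 30 min
for tracking. A full 24-h confined run with profile extraction completes
in well under a minute per simulated day on a single core; the complete
multi-target validation suite runs in minutes.
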