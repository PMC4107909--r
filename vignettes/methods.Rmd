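---
title: "vnoca: models and methods for VNO-slice calcium response profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vnoca: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vomeronasal sensory neurons (VSNs) are profiled by time-lapse GCaMP
imaging of acute VNO slices: stimuli (urine, sulfated steroids, a
depolarizing control) are washed over the slice in timed epochs, and a
cell "responds" when its fluorescence transient exceeds a fractional
change threshold.  The scientific outputs are population summaries —
what fraction of cells responds to a stimulus, how responder sets
overlap between stimuli (e.g. sulfated estrogens vs estrus urine),
dose–response curves, and tuning panels — plus nonparametric statistics
on behavioral endpoints scored from mount-event tables.

vnoca implements this entire analysis path as a reproducible pipeline:

1. **register**: rigid alignment of every frame to frame 1;
2. **detect**: per-stimulus (local) ROIs from a pixelwise
   signal-to-noise score, filtered by shape gates;
3. **merge**: local ROIs integrated into one global list;
4. **trace/call**: per-ROI baseline-corrected ΔF/F and a responder flag
   at the 30% threshold;
5. **profile**: overlap (Venn) statistics, percent responding with
   optional co-label gating, normalized tuning panels, dose–response;
6. **behavior**: mount scoring, Mann–Whitney U and Kruskal–Wallis tests.

Because no raw recordings are published for this kind of experiment, a
forward simulator with complete ground truth is a first-class module:
every downstream stage is validated by recovery.

## The forward model

A synthetic slice is a set of `n_cells` disk-shaped somata with
non-overlapping footprints (centers re-drawn until each rim clears its
neighbours by `min_separation_px`; up to 1000 draws per cell).  Pixel
intensity is

```
F(x, t) = sum_cells 1[x in disk_i] * B0_i * exp(-t / tau_bleach)
          * (1 + sum_events a_ie * k(t - t_onset_e))  +  N(0, sigma)
```

with `k` a difference-of-exponentials transient normalized to unit peak
(rise 1 s, decay 8 s — generic GCaMP2-like kinetics, a design choice
since the source experiments report none), single-exponential
photobleaching shared across cells (`tau_bleach` = 600 s), per-cell
baseline brightness `B0` uniform in 400–1200 (16-bit scale) and additive
Gaussian noise (`sigma` = 15).  Optional rigid drift accumulates along
the image diagonal at `drift_per_frame` pixels per frame (default 0: a
mechanically stable slice; the registration tests switch it on).

Tuning structure is configurable as classes: each class has a fraction
of the population, a per-stimulus response probability and amplitude.
The default population encodes the headline biology: a fraction
`se_tuned_fraction = 0.10` of cells is tuned to sulfated estrogens
("SE"), and an SE-tuned cell co-responds to estrus urine ("EU") with
probability 0.65 and to non-estrus urine ("NEU") with probability 0.05.
Dose series scale a responder's amplitude by a Hill function
(`EC50 = 10 nM`, coefficient 1) of the event concentration;
concentration-free stimuli (urine, KCl) are unscaled.

Two deliberate idealizations:

* **Non-overlapping somata.**  ROI detection does not split touching
  cells (by design — that is a segmentation problem, not a response
  quantification problem), so the synthetic world states a focal-plane
  monolayer.  A green recovery test therefore establishes correctness of
  detection/quantification, *not* robustness to overlapping somata.
* **The depolarizing control.**  Activity-based detection only sees
  cells that respond to something.  Statistics with an "all cells"
  denominator (e.g. percent of VSNs responding to SE in a control slice)
  therefore require a stimulus that recruits the entire viable
  population; the simulator treats the label given by
  `depolarization_label` ("KCl", i.e. a high-K⁺ pulse, standard practice
  in slice imaging) as responded to by every cell with probability 1.

Other unmodeled features of real data: shot noise, optics (PSF, scan
artifacts), non-rigid tissue deformation, perfusion transients, and
focal drift.  Green tests say nothing about these.

## Registration

Each frame is translated by the integer-pixel shift maximizing its FFT
cross-correlation with frame 1, searched within ±10% of the image size
(larger drifts are out of scope by design: they indicate a failed
recording).  Exposed borders are filled with the frame median.  The
original analysis used a vendor "elastic" registration that cannot be
reproduced; slice drift in this preparation is predominantly
translational, and subpixel interpolation is declined so that ROI pixel
sets stay exact.  All-constant frames (undefined correlation) warn and
report zero shift.

## ROI detection

For a stimulus event, every pixel gets the score

```
score = (mean F over [onset, offset] - mean F over the 30 s before onset)
        / robust SD of the pre-event residuals
```

where residuals are about a per-pixel *linear* trend of the baseline
window — without detrending, photobleaching would inflate the noise
estimate — and robust SD is `1.4826 * median |residual|`.  Pixels with
score ≥ 5 (inclusive) form 8-connected components; components pass to
the candidate filter.  The original authors used unpublished
"signal-to-noise criteria" plus manual inspection; the filter replaces
the inspector with two reproducible gates: area within
`[min_area, max_area]` = [10, 400] px and isoperimetric circularity
`4πA/P² ≥ 0.5`, with the perimeter estimated as the 4-connected boundary
edge count scaled by π/4 (the taxicab→Euclidean correction, which makes
a digital disk score ≈ 1).

Local ROI sets from all stimuli are merged: pairs with IoU ≥ 0.3
(inclusive) are unioned under transitive closure; each global ROI
remembers its contributing stimuli.

Known consequence of the late-session bleaching in long schedules: a dim
cell's absolute transient shrinks with `exp(-t/tau_bleach)` while the
noise floor does not, so detection sensitivity decays over the session.
The benchmark protocols place the critical events early; real protocols
should too.

## ΔF/F and response calls

A global ROI's trace is the per-frame mean over its pixels.  The
baseline is fit on frames *outside* all response windows (onset to onset
+ 60 s) as `B0 exp(-t/tau)` by nonlinear least squares (log-linear
start); the fit falls back to a linear trend, then a constant (median),
when it fails, yields `tau ≤ 0`, `tau > 100×` the trace duration, or a
non-positive prediction.  The peak is the maximum of a centered 3-frame
moving average over the response window (single-frame noise maxima are
not peaks), and

```
dF/F = (peak - baseline(t_peak)) / baseline(t_peak)
```

so the bleach correction is applied *at the peak time* — the stated
purpose of baseline modeling.  A cell is a responder when dF/F ≥ 0.30,
inclusive.  The 60 s window and inclusive comparisons are conventions
the source description leaves open; they are documented and tested.

Numerical notes: at the default 0.5 s frame interval the 3-frame
smoothing biases a 1 s-rise/8 s-decay transient peak down by ~1% (at 1 s
sampling it would be ~4%, which motivated the default); the maximum-
over-window operator adds a small positive noise bias (~2.5 smoothed-
noise SDs for a 120-frame window).  Both are far inside the 5% fidelity
tolerance at realistic SNR.

## Population summaries

* **Overlap**: a cell is "in A" when it responds to any member of the
  label set (multi-sample classes like "female urine" use any-responder
  semantics); `pct(B|A) = 100 n_AB / n_A`, undefined (flagged) at
  `n_A = 0`.  Slices pool by concatenating response matrices with
  slice-qualified ROI ids.
* **Percent responding**: denominator is either all global ROIs or the
  co-label-positive subset (mean second-channel intensity ≥ threshold;
  default threshold = half the channel maximum).
* **Tuning panels**: each cell's dF/F vector over a stimulus panel is
  normalized by its own maximum (bounded by 1, comparable across cells);
  cells with non-positive maxima are excluded and counted.
* **Dose–response**: per-concentration responder fraction and mean dF/F
  over a fixed cell set; the threshold concentration is the lowest
  tested dose with ≥ 1 responder ("as low as" semantics), with a
  fraction-based criterion available; a 3-parameter Hill curve
  (`ymax`, `EC50`, coefficient) is least-squares fitted when ≥ 2
  concentrations exist.
* No multiple-testing correction is applied anywhere, matching the
  source analyses.

## Behavior statistics

Mount events are scored per animal into count, total duration, and
latency; animals that never mount get latency = session length (a
sentinel the plots need; the source leaves the case undefined).  The
Mann–Whitney U uses midranks; p is exact by full enumeration of all
`C(nx+ny, nx)` labelings when the combined n ≤ 12 with no ties, and a
tie-corrected normal approximation with 0.5 continuity correction
otherwise (two-sided throughout; the exact path is also available as a
permutation test over midranks).  Kruskal–Wallis uses pooled midranks
with tie correction and a χ² reference, with a seeded permutation null
as an option.  A Kruskal–Wallis gate before pairwise tests is available
but not enforced.

## Benchmarks the package ships

`run_overlap_experiment()` (3 slices, ~30 SE-tuned cells each,
co-tuning 0.65/0.05, full pipeline, pooled overlap),
`run_control_experiment()` (1000 cells across 3 slices at the default
10% SE-tuned fraction, SE + KCl schedule, all-ROI denominator),
`run_detection_benchmark()` (recall/precision vs ground truth at
0.4 dF/F) and `run_dff_benchmark()` (mean estimated dF/F at a known
amplitude).  The control benchmark shortens the inter-stimulus gap to
70 s — still comfortably beyond five transient decay constants — purely
to keep the 1000-cell run inside its runtime budget.  The test suite
asserts only quantities these benchmarks compute.

## Limitations

Integer-pixel rigid registration only; no splitting of touching cells;
one peak per stimulus epoch (no multi-transient quantification); no
spike inference; the simulator's noise is Gaussian and spatially white.
The original study's manual validation step has no computational
counterpart — the shape gates are a reproducible, but different, filter.
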