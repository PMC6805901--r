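---
title: "Quantifying contraction from transmitted-light video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contraction from transmitted-light video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myobeat)
```

## The method

Cardiomyocytes, engineered heart tissue or whole exposed hearts can be
filmed in ordinary transmitted light at high frame rates. `myobeat`
quantifies their contractility from such recordings without fluorescent
reporters, markers or sarcomere tracking, using nothing but absolute pixel
differences between 8-bit grayscale frames:

* **speed** — the mean absolute per-pixel difference between consecutive
  frames, `speed[n] = mean(|I_n - I_(n-1)|)`. It is large while the
  specimen moves, regardless of direction, and acts as the discrete
  absolute first derivative of the amplitude.
* **amplitude** — the mean absolute per-pixel difference against a fixed
  *reference frame* from the resting (diastolic) phase,
  `amplitude[n] = mean(|I_n - I_ref|)`. It measures deviation from rest
  and traces the familiar contraction waveform.

Both are means over the evaluated pixels, so they live on the 0–255
intensity scale and are comparable across frame sizes. They are
*arbitrary units*: the same motion produces different amplitudes in cells
of different size or optical density, so absolute times (below) are the
robust quantities for between-group comparison, while amplitudes are best
compared within one cell over a treatment time course.

### Regions of interest (the pretest)

Summing `|I_n - I_(n-1)|` over all transitions yields an **activity map**
that is bright exactly where movement concentrated. `detect_rois()`
binarizes its 8-bit rescale above `lower_threshold`, fills interior holes
(a pulsing cell moves mostly at its rim but should count as a solid
region), labels 8-connected components, and discards those smaller than
`cellsize` pixels. Each surviving region can then be evaluated through its
own mask, which removes static-background dilution: if motion is confined
to a mask covering fraction *f* of the frame, the unmasked amplitude is
exactly *f* times the masked one, so masking recovers the undiluted
per-pixel signal and makes multi-cell videos separable into independent
traces.

### Beat detection and the `detection` parameter

Extrema are found by a single forward scan with an excursion floor
`epsilon = (max - min) / detection` computed from the trace's global
range: a maximum is committed once the trace has fallen `epsilon` below
the running high, a minimum once it has risen `epsilon` above the running
low, and the two states alternate. `detection` is therefore an inverse
share of the full range — `detection = 5` recognizes peaks of roughly 20%
of the range, and raising it toward 80 recovers progressively smaller
local peaks (at some point also noise, which is the user's trade-off).
The scan starts in the seeking-maximum state, so the first committed
extremum is always a maximum; a beat whose rising phase precedes the
recording start has no committed onset minimum and is counted but not
timed.

### Dynamic thresholds, systole and diastole

For every beat — a committed minimum followed by its maximum — four
thresholds are placed at

```
T(level) = local_min + level * (local_max - local_min),   level = 10/20/50/90%
```

and recomputed for *every single* beat. This dynamic recomputation is the
load-bearing design choice: camera noise, illumination drift and floating
debris shift the amplitude baseline over a recording, and thresholds
frozen at the start then sit permanently above later valleys and "lose"
the trace, while per-beat thresholds track it. `compute_beats(static =
TRUE)` keeps the frozen-threshold variant purely for demonstrating this
failure mode.

Per beat and per level, the **systole** (contraction time) runs from the
first frame after the minimum whose amplitude reaches the threshold
(`>=`) to the maximum; the **diastole** (relaxation time) from the
maximum to the first frame whose amplitude falls back below the threshold
(`<`), searched up to the next minimum; the **peak time** is their sum,
and the **beat time** is the interval between successive maxima. If the
amplitude never falls back below a threshold, that diastole is reported
`NA` (incomplete) and excluded from summaries rather than guessed.

## Parameters that matter

| Parameter | Unit | Default | Role |
|---|---|---|---|
| `fps` | frames/s | from container | time base; ~40 samples per beat are needed for reliable systole/diastole statistics |
| `ref_frame` | frame index | `"auto"` | amplitude reference; auto-selection takes the center of the longest run of frames with speed at or below the 10th percentile |
| `lower_threshold` | 0–255 | 50 | activity-map cutoff for segmentation |
| `cellsize` | px | 100 | minimum region area ("particle size") |
| `detection` | – | 5 | inverse minimum peak share of the trace range |
| `levels` | fraction | 10/20/50/90% | threshold levels for timing decomposition |

## The synthetic generator

All validation is driven by generated videos, three of them analytic:

* `gen_alternating()` — all-white/all-black inversion: speed must be
  constantly 255 and the amplitude must flip 0/255 against frame 1.
* `gen_moving_bar()` — a 100×500 bar on a 500×500 white field moving
  1 px/frame: 1000 pixels invert per transition, so speed must be
  `1000/250000 * 255 = 1.02`, the amplitude must climb 1.02 per frame
  while the bar overlaps its reference position, and plateau at
  `100000/250000 * 255 = 102` once it has cleared it.
* `gen_uniform_function()` — uniform frames following `floor(clamp(f(n)))`,
  reproducing 8-bit quantization (22.9612 stores as 22) and the exact
  identity `speed[n] = |amplitude[n] - amplitude[n-1]|` when the reference
  sits at the function's minimum.

`gen_scene()` renders beating cells as discs whose radius follows a
piecewise-linear pulse (linear contraction over `rise_time`, linear
relaxation over `fall_time`), with optional per-beat amplitude schedules
(arrhythmia), linear illumination drift and Gaussian noise, and returns
ground-truth peak-contraction frames and masks. The pulse is deliberately
linear rather than sinusoidal so every threshold crossing is
hand-computable; the discs are rasterized by pixel-center inclusion so
areas are exact. What the generator does *not* emulate: cell texture,
organelle motion, focus drift, compression artifacts, or cells that
translocate — passing tests demonstrate correctness of the measurement
chain, not robustness to every property of real microscopy video.

```{r example}
cell <- cell_spec(center = c(60, 60), rest_radius = 30, period = 1,
                  rise_time = 0.2, fall_time = 0.3, phase = 0.1)
sc <- gen_scene(scene_spec(120, 120, fps = 100, duration = 3, list(cell)))
bundle <- evaluate_stack(sc$stack, myo_settings(detection = 5))
bundle$per_roi[["0"]]$extrema
subset(as.data.frame(bundle$per_roi[["0"]]$beats),
       select = c(beat_index, max_frame, systole_50, diastole_50, beat_time))
```

## Numerical choices and edge cases

* All arithmetic after frame differencing is double precision; nothing is
  re-quantized to 8 bit.
* Frames are numbered 1-based; frame `n` sits at `(n-1)/fps` s.
  `speed[1] = 0` by convention so all series share the stack's length.
* Color input converts with fixed BT.601 luma weights (0.299, 0.587,
  0.114), rounded half-up — fixed so results do not depend on the decoder.
* Crossing times have frame resolution; no sub-frame interpolation. The
  systolic crossing uses `>=`, the diastolic `<`, so plateaus that touch a
  threshold behave deterministically. If a rise dips back below a
  threshold, the *first* crossing within the minimum→maximum window wins.
* Plateau extrema commit at their earliest frame; trailing uncommitted
  candidates are discarded; a flat trace has no extrema.
* Degenerate beats (local min = max) carry equal thresholds and are
  flagged rather than dropped.
* The reference auto-selector uses *at or below* the 10th percentile of
  speed (strictly-below can be empty on constant-speed traces) and judges
  quietness on frames 2..n.
* Raising `lower_threshold` cannot increase the region count on unimodal
  blob-shaped activity maps (the realistic case), but can split an
  irregular component in two; `cellsize` filtering is monotone
  unconditionally.
* Uncompressed AVI round-trips bit-exactly; MJPEG is read/written by
  neither path (lossy codecs are deliberately out of the encoding scope),
  and TIFF/PNG stacks need an explicit `fps_override` because those
  containers carry no frame rate — it is never silently defaulted.

## Problem sizes

The test-suite scenes are 120–360 px frames at 100 fps for 3–6 s (300–600
frames), which keeps every ground-truth quantity exactly enumerable while
exercising all code paths; the analytic validations use the canonical
500×500 geometries at 50 and 325 frames.

## Limitations

* Cells are assumed stationary apart from contraction; translocating
  regions are not tracked.
* Amplitude units are arbitrary and field-of-view dependent in unmasked
  mode; compare absolute times between groups.
* Beats straddling the recording boundaries are counted but not fully
  timed (no extrapolation).
* 8-bit input only; 16-bit or floating-point video is out of scope.
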