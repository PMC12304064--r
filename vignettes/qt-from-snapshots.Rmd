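---
title: "Measuring QT and QTc from monitor snapshots: model, calibration, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring QT and QTc from monitor snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtsnap)
```

## The measurement model

A raster snapshot of a single-lead ECG trace carries no time axis of its
own: the horizontal pixel scale depends on the monitor's sweep speed, the
camera distance, and any cropping. The semi-automated measurement
implemented here recovers the scale from the image itself. An operator
places three markers — the onsets of two neighboring Q waves at columns
$x_{Q1} < x_{Q2}$ and the end of the T wave between them at $x_T$ — and
supplies the heart rate $\mathrm{HR}$ shown on the monitor. Because the two
Q onsets bound exactly one cardiac cycle,

$$\mathrm{RR} = \frac{60000}{\mathrm{HR}}\ \text{ms},
\qquad
\text{px/ms} = \frac{x_{Q2}-x_{Q1}}{\mathrm{RR}},
\qquad
\mathrm{QT} = \mathrm{RR}\,\frac{x_T - x_{Q1}}{x_{Q2}-x_{Q1}},$$

and Bazett's correction normalizes to a 60 beats/min heart rate,
$\mathrm{QTc} = \mathrm{QT} / \sqrt{\mathrm{RR}/1000}$.

Two properties follow immediately and are enforced as tests: QT is
invariant to scaling and to translation of all three marker coordinates
(camera zoom and crop cancel), and QTc equals QT whenever HR = 60. The
calibration is the only pixel-to-time conversion consistent with the
inputs the operator provides — the markers and the displayed heart rate —
and it makes the image content itself irrelevant to the arithmetic:
`measure_from_snapshot()` validates marker bounds against the image and
records provenance, nothing more. A single cycle is measured; no
multi-beat averaging is applied. The T marker denotes the *end* of the T
wave, since QT runs from depolarization onset to repolarization end. A T
end beyond the second Q onset is physiologically alarming but
arithmetically fine, so it produces a warning flag rather than an error.

### Error sources

With markers placed exactly on the true fiducials the reconstruction is
exact up to floating-point error (the ratio in the QT formula cancels the
common scale). Real error enters in two ways:

* **Quantization.** If markers snap to integer pixels, each span is off by
  at most one pixel, giving
  $|\Delta \mathrm{QT}| \le \mathrm{RR}\cdot 2/(x_{Q2}-x_{Q1})$ ms — about
  10 ms at the default 0.2 px/ms scale and HR 70. The bound is verified
  empirically across styles.
* **Placement.** Human marker placement adds noise and, for the T end —
  whose offset is notoriously hard to judge — possible systematic bias.
  A T-end bias of $b$ px shifts QT by exactly $b/(\text{px/ms})$; a bias
  common to all three markers cancels. This closed form is the lever the
  validation design uses.

## The synthetic snapshot generator

Validation needs images whose true QT is known exactly, so the beat
morphology is piecewise-analytic rather than a sum of Gaussians: raised
cosine P and T waves, triangular Q/R/S deflections, and flat PQ/ST
segments. Smooth bumps have no unambiguous onset or offset; segment
boundaries do. The ST segment absorbs whatever duration the requested QT
leaves after the QRS complex and T wave, so `t_end - q_onset` equals the
requested QT *by construction*, and the minimum representable QT is the
QRS-plus-T duration (270 ms under defaults).

Default morphology (adult lead II): P 80 ms / 0.15 mV, PQ segment 40 ms,
Q 20 ms / −0.10 mV, R 40 ms / 1.0 mV, S 30 ms / −0.20 mV, T 180 ms /
0.30 mV. The 120 ms P+PQ lead-in sits at the lower normal bound of the PR
interval, a deliberate choice: the whole beat (lead-in + QT) must fit
within one RR interval, and a short lead-in lets a 300 ms QT fit even at
140 beats/min (RR ≈ 429 ms). Heart rate is constant within a snapshot —
the marked RR is assumed representative of the displayed HR — and beats
are exact copies, so consecutive Q onsets are spaced exactly 60/HR s and
every beat's T-end-minus-Q-onset equals the true QT to machine precision
(about 10⁻¹³ s; one or two ulps are lost when the per-beat time offset is
added). Joint (HR, QT) sampling is constrained to pairs where the beat
fits: at high heart rates a 500 ms QT would exceed the RR interval
itself, which is outside this generator's sinus-rhythm scope.

### Rendering

The image convention is fixed once: origin top-left, column $x$ (0-based)
covers times $[x-0.5, x+0.5]/\text{px/s}$ around its nominal time
$x/\text{px/s}$, amplitude maps to row $\text{baseline} - \text{mV}\cdot
\text{px/mV}$ with y growing downward. The default *monitor* style is a
bright green trace on black at 200 px/s and 100 px/mV (0.2 px/ms); the
*paper* style is black-on-white with a pale red grid spaced one
millimeter of standard 25 mm/s ECG paper, i.e. 40 ms per division. These
are representational choices, not replicas of any particular monitor's
sweep or pixel geometry.

Each column is drawn as a vertical band covering the curve's extent over
the column's time window (supersampled at five offsets), padded by half
the line thickness, with anti-aliased partial-coverage ends — much as a
monitor pixel integrates the sweeping beam. Neighboring bands share their
window edges, so steep QRS slopes stay connected without any separate
join pass, and on flat or straight stretches the intensity-weighted
centroid of a column is exactly the sub-pixel trace position. Ground
truth fiducials are recorded as sub-pixel floats *before* rasterization
(`time × px/s`), which is what lets marker-placement error and pixel
quantization be studied independently. Optional per-pixel Gaussian
luminance noise is added last; all randomness is drawn from the caller's
explicitly seeded RNG — the package never consumes global random state
behind an API that looks deterministic.

### Trace extraction

`extract_trace()` is a validation instrument for closing the
synthesize → render → extract loop (a bedside app would overlay markers
on the raw snapshot). Pixels are scored by Euclidean RGB distance to the
trace color; the coverage estimate $1 - d/\text{contrast}$ inverts the
renderer's alpha compositing, grid-colored pixels are suppressed first,
and each column with any pixel above half coverage reduces to the
intensity-weighted centroid row. Columns without foreground are masked
invalid, never interpolated — gaps are the caller's decision. On clean
renders the centroid is exact over flat and straight stretches; the
residual round-trip error concentrates in the few steep QRS columns,
where a one-pixel-wide column genuinely cannot encode a 25 px vertical
sweep as a single sub-pixel position. At the default style this leaves an
RMS column error of ≈ 0.5 px and a signal correlation above 0.999.

## The simulated validation study

`simulate_study()` emulates a paired method-comparison design: one
snapshot and one measurement pair per subject, the reference being the
generator's exact QT (and its exact Bazett correction), the test value
obtained by actually rendering the snapshot, perturbing the true fiducial
columns with an observer model, and running the measurement. Defaults
describe an adult perioperative cohort in sinus rhythm: QT ~ N(385, 45²)
ms truncated to the representable range, HR ~ N(70, 12²) rounded to
integers (monitors display integers) and truncated to 40–140 beats/min.
The observer places each marker with 3.3 px of Gaussian noise and marks
the T end 2.8 px early; at 0.2 px/ms those choices yield a QT difference
distribution of roughly 14 ± 20 ms — the scale of disagreement reported
for snapshot-based QT measurement against careful manual reference
measurement. The T-end-only bias is deliberate: it is the only marker
bias that survives the calibration's translation invariance, and it
yields the closed-form check that the simulated mean difference equals
$-b/(\text{px/ms})$.

What the generator does *not* emulate bounds what passing tests show:
no arrhythmia or RR variability, no photographic distortion (perspective,
moiré, glare), no beat-to-beat morphology change, and QT drawn
independently of HR — so QTc differences here are slightly *wider* than
QT differences, whereas correlated real physiology can make them
narrower. Agreement on synthetic studies demonstrates the correctness of
the measurement arithmetic and the statistical pipeline, not the field
performance of snapshot QT measurement.

## Agreement analysis

Differences are taken as reference minus test, so a test method that
reads short gives positive bias. The Bland-Altman summary uses the sample
SD (n−1), limits of agreement $\text{bias} \pm 1.96\,\mathrm{SD}$, the
bias CI via $\mathrm{SD}/\sqrt{n}$, and the LOA CIs via the classic
normal-approximation standard error $\mathrm{SD}\sqrt{3/n}$, all with
z = 1.96. A t-based variant would widen the CIs by ~2% at n = 57;
published tables rounded to integer ms cannot discriminate between the
two, so the classic choice is documented rather than fitted.

Grading uses absolute differences — direction is already captured by the
bias — in half-open bins $[0,20)$, $[20,40)$, $[40,\infty)$ ms
(excellent / acceptable / unacceptable). The published thresholds
("< 20", "< 40", "> 40") leave the exact boundary values unassigned;
half-open bins make the three grades an exhaustive partition, with 20 ms
grading acceptable and 40 ms unacceptable. Percentages round half away
from zero to integers (and may therefore sum to 99 or 101); all display
rounding in the package is half-away-from-zero to match clinical table
conventions, while stored and serialized values keep full precision.
Clinical acceptability requires $|\text{bias}| \le 20$ ms and
$\mathrm{SD} \le 20$ ms.

```{r example}
ba <- loa_from_summary(13, 15, 57)
round_half_away(c(ba$loa_low_ms, ba$loa_high_ms))  # limits of agreement
round_half_away(ba$ci_bias)                        # CI of the bias
```

## Numerical and design notes

* **Problem sizes.** The test suite and the acceptance script use 100
  snapshots for the exactness sweep, 500 subjects for the bias-recovery
  study, and 10,000 draws for LOA coverage — large enough that Monte
  Carlo error is well inside the tolerances checked, small enough to run
  on a laptop in under a minute or two.
* **Degenerate inputs.** Markers with non-positive Q-Q span are
  calibration errors; a T marker at (or before) the first Q is a
  marker-order error; a T marker just after Q1 legally yields a
  near-zero QT. Heart rates must be positive but need not be integers at
  the API level.
* **Serialization.** Truth sidecars and reports are written at 17
  significant digits so write/read round trips are bit-lossless; the
  study CSV does the same.
* **Known limitations.** Only Bazett correction (no Fridericia or
  Framingham); single-cycle measurement by design; automatic Q/T
  detection is out of scope; the digitizer assumes an axis-aligned
  screenshot-like image, not a photograph of a screen.
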