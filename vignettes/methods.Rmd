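---
title: "Methods: event-triggered analysis of fiber photometry recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-triggered analysis of fiber photometry recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpeta)
```

## The problem

Fiber photometry records bulk fluorescence from genetically encoded sensors
(calcium indicators such as GCaMP, or neurotransmitter sensors) through an
implanted optical fiber while an animal behaves. The analysis question is
almost always the same: *how does the fluorescence signal change around
repetitions of an event* — a tone, a lever press, a bout of wheel running?
Answering it requires a chain of unglamorous steps: importing
heterogeneous acquisition formats, separating overlapping fluorophores,
correcting photobleaching, aligning behavioral streams recorded on their own
clocks, turning indicator channels into lists of events, cleaning those lists,
normalizing each event against its own baseline, and finally averaging.
`fpeta` implements that chain as composable functions plus a batch front end,
with a synthetic-recording generator so every stage is testable without any
instrument data.

## Data model and time conventions

A recording (`fp_recording`) is a set of named channels sampled uniformly:
sample *i* (1-based) sits at `start_offset + (i-1)/rate` seconds on a global
clock. All windows — events, peri-event intervals, slices — are half-open
`[start, end)`. The half-open convention is load-bearing: unions of adjacent
windows partition the samples with no duplication, which makes alignment,
export and the interval algebra exactly testable. The recording span is
`[start_offset, start_offset + n/rate)`, so the final sample owns one
sampling period and a run of ones reaching the last sample closes at the
span end.

Files with an explicit but jittery time column are resampled by nearest
neighbor onto the uniform grid at import (and the resampling is logged in
the recording's provenance); the rest of the package assumes exact
uniformity. Missing values propagate through transforms and are dropped,
with counts logged, from normalization statistics.

## Spectral decomposition

Spectrally resolved systems deliver a full emission spectrum per time frame.
With reference spectra $R \in \mathbb{R}^{W \times K}$ (one max-normalized
column per fluorophore), each frame $y_t$ is decomposed by least squares:

$$\hat c(t) = \arg\min_{c \ge 0} \lVert y_t - R c \rVert_2$$

Non-negativity is the default because fluorophore contributions are
physically non-negative; the unconstrained solution is available behind a
flag. Computationally, all frames are first solved unconstrained in one QR
factorization; only frames with a negative coefficient are re-solved by
non-negative least squares (if the unconstrained minimizer is feasible it is
also the constrained minimizer, so the fast path is exact). Collinear
reference spectra are a hard error naming the offending fluorophores.

The alternative "summary ratio" path reduces each frame over two
user-chosen wavelength bands (closed intervals on the recorded grid; no
interpolation at band edges, for reproducibility) with AUC, mean or median,
forms numerator/denominator, and then detrends the ratio trace. Detrending
follows the ratio, not the raw bands. Whether such detrending should be
divisive or subtractive is genuinely open; we default to divisive
(`ratio / fit - 1`, which puts the trace in fractional-change units) and
expose the subtractive variant as an option.

## Photobleaching models

Bleaching is modelled as a decreasing function of time, either linear
$\hat F(t) = \alpha + \beta t$ or exponential
$\hat F(t) = a e^{-bt} + c$ with $a, b \ge 0$. The linear fit is closed
form. The exponential fit is Levenberg–Marquardt nonlinear least squares
initialized by regressing $\log(F - c_0)$ on $t$ with $c_0$ just below the
channel minimum, with two fallback starting points; a fit whose decaying
component is numerically negligible over the recording is flagged
degenerate rather than treated as an error (a constant channel is a valid,
if extreme, bleach state). Manually supplied parameters skip fitting.
Detrending returns residuals ($F - \hat F$), predictions ($\hat F$), or
fractional change ($F/\hat F - 1$), the latter erroring if the trend is not
strictly positive.

## Transforms

* **Alignment** of a behavioral stream uses nearest-neighbor sampling on the
  global clock; equidistant ties take the earlier sample, and target times
  outside the other stream's span become missing — values are never
  extrapolated or clamped.
* **Row-wise append** of two sessions preserves the second recording's clock
  offset; any gap is filled with missing samples so the result stays
  uniform, and the seam is logged. Overlap is an error.
* **Low-pass + downsample** uses an order-4 Butterworth magnitude response
  applied forward and backward (zero phase, so event onsets are not lagged
  — whether a causal or zero-phase filter is "correct" here is a judgment
  call; we choose zero phase and say so). Edge transients are suppressed by
  reflecting the signal about its endpoints before filtering. Interior
  missing samples are interpolated for the filter pass and restored to
  missing afterwards.
* **Linear scaling** is either explicit gain/offset or moment matching to
  another channel (equal mean and SD), the standard step before overlaying
  streams of different magnitudes.
* A **custom hook** (`apply_custom`) passes the channel table through a
  user function, replacing embedded-script execution with a documented
  functional contract.

## Events

Detectors turn a recording into an ordered series of half-open events:

* **binary / inverted** — maximal runs of ones (or zeros) of an indicator
  channel, rising edge to falling edge;
* **binned** — consecutive `[t, t+L)` bins, trailing partial bin dropped;
* **peak** — samples exceeding the trailing-window mean by more than `k`
  sample standard deviations (window includes the current sample; early
  samples use the partial window, minimum 2 samples; a zero-variance
  window flags nothing). Trailing windows are a deliberate choice: they are
  causal, so a detection never depends on future samples. The SD uses the
  n−1 denominator;
* **timestamped** — a manual list, clipped to the recording span.

Inclusion **conditions** evaluate a boolean expression over the channels at
every time step (a small safe grammar: comparisons, arithmetic,
and/or/not, a few elementary functions, channel names and `(time)`), in
*entire* mode (every sample of the event must satisfy it) or *any* mode (one
suffices).

**Filters** then modify the list in user order; order genuinely matters
(pad-then-drop ≠ drop-then-pad, regression-tested). The eleven kinds:
keep/drop first or last; constant time shift (clipped to the span); pad to a
minimum length (end-extension only — the onset is the scientifically
meaningful anchor); truncate to a maximum length; drop short; drop long;
aggregate events separated by at most a gap (a zero gap merges touching
events); coalesce overlapping events; minimum rate of occurrence; keep/drop
relative to a timestamp; and debounce (drop events starting within a dead
time of the last *kept* event, which makes the result order-stable).
"Minimum rate of occurrence" has no canonical formula; we read it as a
neighborhood count — keep events with at least `count` event starts
(including their own) within a window of `window` seconds centred on their
start — and flag that reading prominently here and in the function
documentation.

**Intervals** materialize peri-event windows by offsets from an anchor: the
event-signal start, its end, the raw signal itself, or a no-overlap start
variant that raises the interval start past everything claimed by preceding
events (their signals and their intervals) — the natural choice for long
baselines before closely spaced behavioral bouts.

## Normalization

Each event is normalized against its own reference interval (typically a
pre-onset baseline), per event, with reference statistics from that event
only:

* **z-score** $(x - \mu_\mathrm{ref}) / \sigma_\mathrm{ref}$, sample SD
  (n−1 throughout the package);
* **ΔF/F** $(x - \bar F_\mathrm{ref}) / \bar F_\mathrm{ref}$ — the z-score
  with the SD replaced by the mean; optionally ×100;
* **robust z-score** — percent change first,
  $p(x) = (x - \mathrm{med}_\mathrm{ref})/\mathrm{med}_\mathrm{ref}$, then
  $(p(x) - \mathrm{med}(p_\mathrm{ref})) / \mathrm{MAD}(p_\mathrm{ref})$
  with the raw (unscaled) MAD. Under this reading the reference median is
  exactly zero after normalization; the alternative reading that centres
  and scales raw values by the reference median/MAD is available via
  `robust_on_raw = TRUE`, and the 1.4826 normality constant via
  `mad_constant`. We default to the percent-change pipeline and the plain
  MAD, and do not claim the alternative is wrong — both are implemented so
  the choice is explicit.

Degenerate references (zero SD, zero mean, zero MAD, fewer than two
samples) raise named errors identifying the event and scheme rather than
producing silent NaNs.

## Event-triggered products

Aligned traces re-index every event so the event signal starts at
`t_event = 0` (baselines carry negative times), snapping times onto the
exact sample grid so equal peri-event times match across events. The mean
trace reports, per time point, the pointwise mean over the events that have
a sample there, a band of `multiplier` SDs or SEs, and the contributing
count `n(t)` — ragged edges are visible, never imputed. Heatmap matrices
order events chronologically, by length, or by trapezoidal AUC (full event
or a sub-window), ties broken chronologically; rows are padded with missing
values. Interval summaries reduce each event × interval to mean, median, or
AUC between two time points, the unit of box-plot comparisons.

## The synthetic generator

The generator emulates the structure the pipeline assumes:

$$F(t) = B(t)\,\bigl(1 + r(t) + \varepsilon_t\bigr), \qquad
  B(t) = a e^{-bt} + c,\quad \varepsilon_t \sim \mathcal N(0, \sigma^2)$$

where $r(t)$ sums difference-of-exponential transients
$(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$, normalized to unit peak and scaled by
a fractional amplitude, locked to each scheduled event onset. Modelling the
response and the noise as *fractions of the instantaneous baseline* (rather
than additive absolute terms) keeps the ΔF/F of the signal stationary
across the bleaching decay, so "the injected amplitude" is a single number
the full pipeline should recover — which is exactly what the acceptance
tests measure. A TTL channel carries the schedule; a behavior-stream helper
re-emits it at a different rate and latency; a glitch helper flips seeded,
isolated zero samples to one to emulate spurious pulses from video scoring.

The default scenario is a 900-second session at 20 Hz with five 10-second
tones (onsets 120, 270, 420, 570, 720 s; the spacing is a convenience
default), bleach $a = 2, b = 0.001, c = 1$ (≈59% decay over the session),
transient amplitude 0.2 (20% ΔF/F, τ-rise 0.5 s, τ-decay 2 s — a realistic
calcium-sensor shape) and fractional noise σ = 0.01. Peri-event analyses of
this scenario use a 3-s baseline and follow the signal to 5 s after tone
offset. Spectrally resolved variants mix Gaussian emission spectra
(e.g. peaks at 515 and 580 nm for a green activity sensor alongside a red
calcium-insensitive fluorophore) per frame from the true coefficient traces,
which are returned for ground-truth comparisons.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: motion and hemodynamic artifacts, isosbestic
reference channels, autofluorescence, non-exponential photoswitching,
correlated (non-white) noise, and detailed sensor kinetics. Tests against
the generator validate the *pipeline arithmetic*, not the biology.

## Numerical choices and degenerate inputs

* Sample SD (n−1) everywhere; plain MAD by default.
* Welch power spectra and spectrograms share one short-time core: Hann
  window, per-segment mean removal, one-sided scaling chosen so the
  integral of the spectrum approximates the signal variance. Defaults:
  segment length `min(n, 256·⌈rate⌉)`, 50% overlap. Autocorrelation is the
  literal per-lag Pearson correlation, not the biased FFT estimator,
  because each reported value should be interpretable as a correlation
  coefficient; the 1.96/√n white-noise band is attached.
* The exponential bleach fit bounds $a, b \ge 0$ (bleaching decreases),
  flags near-constant fits as degenerate, and reports the best residual sum
  of squares if all starting points fail.
* Zero denominators (channel ratios, ΔF/F references, summary-ratio
  denominators) are either logged missing values (elementwise ratios) or
  named errors (normalizations), never silent infinities.
* Sessions serialize to schema-versioned JSON with 17 significant digits,
  which round-trips IEEE doubles exactly; a version mismatch or truncated
  file is a refusal, never a partial load.

## Testing conditions

The test suite regenerates every fixture from code at fixed seeds. The
acceptance checks run the tone scenario at its native 18 000 samples; the
bleach-recovery study uses 200 seeded 900-s sessions at 10 Hz (9 000
samples each), where the fitted parameters recover the truth with a median
relative error well under 1% at ~1% noise; detector equivalence is checked
against literal per-sample reference implementations on 1 000 randomized
inputs. One statistical note: with five events, a pointwise ±3 SE band
around the mean baseline excludes zero at a few percent of time points for
a *correct* implementation (heavy t-tails at n = 5), so the baseline
flatness check asserts the exact centring identity of the averaged
reference plus a ≥90% pointwise coverage rate, rather than demanding every
single point cover zero.

## Known limitations

No workbook (.xlsx) reader or writer — exports are CSV per dataset, which
are diff-able and round-trip exactly. Proprietary lock-in acquisition
formats have no public byte layout; importing them means converting to
delimited text first (any tabular export the vendor software produces will
do). No isosbestic/motion regression correction is included, and the
condition grammar is deliberately small — the `apply_custom` hook is the
escape hatch for anything beyond it.
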