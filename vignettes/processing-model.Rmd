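---
title: "The gazeproc processing model: epochs, ROI gating, features and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gazeproc processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeproc)
```

## Scope and data model

`gazeproc` processes one wearable eye-tracking session at a time: parallel
CSV streams on a shared nanosecond session clock. Timestamps are carried as
doubles holding exact integer nanosecond counts; doubles are exact integers
below 2^53 (about 104 days of session clock), so every interval comparison
in the package is integer-exact and no drift can accumulate. Durations stay
in milliseconds as exported, and any recomputation from timestamps must
agree within 1 ms (`validate_recording()` flags violations rather than
silently "fixing" them). Pupil diameters are millimetres; when the export
carries left and right eyes, the per-sample diameter is their mean (one eye
alone is used as-is) — the symmetric default, overridable by supplying a
single-diameter column.

The export dialect is not stable across platform versions, so all files
pass through a tolerant header layer: lowercase, strip bracketed unit
annotations, collapse whitespace, then match against a per-stream alias
table. Malformed data rows are skipped with a counted warning rather than
aborting — field recordings are messy, and `validate_recording()` reports
the damage explicitly (non-monotone clocks, overlapping blinks, dangling
fixation references).

## Epoching

Events partition the analysis timeline. Event *i* opens the half-open
epoch `[t_i, t_{i+1})`; the final event is a pure terminator. Half-open
windows are the numerical choice that makes the tiling exact: a point
sample on a boundary belongs to exactly one epoch (the next one), and
*n* events always give *n − 1* contiguous epochs. Interval events are
assigned to the epoch containing their midpoint and are never split,
keeping counts integral: for any partition, per-epoch blink/fixation/
saccade counts and total durations sum exactly to the whole-recording
values, and the test suite asserts this over hundreds of random partitions.
A session whose events are only `start` and `end` is analysed as one
whole-recording epoch. Replacement event files (epochs driven by another
device, e.g. a stimulus program) fully overwrite the platform events — no
merging — because half-merged event streams are impossible to audit.

## ROI membership

Region-of-interest membership is consumed from the vendor's surface
mapping (the enrichment stream), never recomputed from geometry: the
enrichment is the product of marker- or reference-image-based mapping that
this package deliberately does not reimplement. Three policies cover the
three stream types:

* **Point samples (gaze, pupil)** take the flag of the temporally nearest
  surface sample within 25 ms. At the 200 Hz nominal rate that is five
  sample periods — wide enough to absorb jitter, narrow enough not to
  bridge real gaps. Samples beyond tolerance default to off-ROI and are
  counted in one warning.
* **Saccades** have valid gaze throughout, so membership is a majority
  vote of the surface samples overlapping the saccade window, ties broken
  by the status at onset.
* **Blinks** have no usable gaze while the lid is closed, so membership is
  read from the last surface sample up to 200 ms before onset, else the
  first up to 200 ms after offset, else FALSE with a warning.

Unknowns always resolve to off-ROI rather than missing so that downstream
sums stay well-defined, and every defaulted value is logged. Annotation
adds flags only; it never changes a stream's counts, timestamps or
durations, and flipping any off-surface sample on can only move interval
memberships toward on-ROI (a monotonicity the property tests exercise).

## Movements and the feature battery

Fixation and saccade *detection* belongs to the device; the package
segments the already-labelled gaze stream. Movement *k* is the sample run
strictly between fixation *k* and fixation *k + 1*; samples labelled as
blink are excluded (lid-closed gaze is noise), and samples before the
first or after the last fixation belong to no movement. "Absolute" metrics
are in scene-camera pixels; "relative" metrics are the same quantities in
surface-normalised coordinates via the enrichment stream. Both path length
and first-to-last displacement are reported, since either can be meant by
a "movement distance"; they satisfy `path_length >= displacement` with
equality only for monotone collinear runs.

All category summaries reduce through one descriptive-statistics core
whose standard deviation is the population form (divisor *n*). Empty
categories are empty-marked (NA), not zeroed — "no saccades" is not
"saccades of zero amplitude" — with two deliberate exceptions: counts are
genuinely 0, and `*_total` indices are 0, because totals are additive
across epochs and the partition-conservation contract (an epoch partition
must sum to the whole-recording value) is only satisfiable with a zero
contribution from empty epochs. The fixation "average position" is
unweighted; a duration-weighted variant was considered and rejected as the
default because the longest-fixation position is already reported
separately.

Trial exclusion removes epochs whose blink count strictly exceeds 5
(configurable). The rationale: typical blink rates are 15–20 per minute,
so a trial of a few seconds containing more than five blinks indicates an
acquisition artefact, not behaviour. The two-sample comparison is the
pooled-variance Student *t* by default — the conventional reading of
"independent samples t-test" — with `var_equal = FALSE` switching to the
Welch form; the degenerate identical-zero-variance case returns t = 0,
p = 1 instead of NaN.

## Pupil spectra

The pupil series is irregular (samples are dropped around blinks), so
spectral analysis first resamples linearly onto a uniform 200 Hz grid.
Linear interpolation through blink gaps avoids the spectral leakage of
zero-filling; the trade-off is artificial smoothness inside gaps, so gaps
longer than 1 s are flagged and the gap fraction is reported for the
analyst to judge. Welch's method uses Hann-tapered 256-sample segments at
50 % overlap with per-segment mean detrending — conventional defaults, all
configurable; detrending per segment (rather than once globally) also
suppresses slow drift. The estimator is scaled as a one-sided density, so
summing it times the bin width recovers the series variance (checked
against white noise within 10 %), and a planted sinusoid's peak lands
within one frequency bin of its true frequency (checked at 1 Hz). The
spectrogram reuses the identical per-segment estimator without averaging;
its time axis is the segment centre.

## Visualisation

Every figure is prepared as labelled numeric arrays before anything is
drawn; rendering performs no numeric transformation beyond axis mapping.
Colour semantics (green = on-ROI, red = off-ROI) live in annotations where
tests can assert them. The fixation cloud's Gaussian kernel density uses
the normal-reference (Scott-type) bandwidth per axis on a 256 × 256 grid
covering the point extent widened by three kernel standard deviations, so
grid quadrature recovers total mass 1 within 2 %; a degenerate axis
(coincident points) falls back to a small positive bandwidth. Histograms
use 30 equal-width bins by default — fixed for determinism, not optimality.
Saccade series are indexed by saccade order, and velocities are converted
to px/ms on the prepared axis.

## The synthetic-recording generator

The generator exists so that the whole pipeline is testable with no
hardware and no downloads, and its defaults are the study conditions the
package emulates: 200 Hz sampling; lognormal fixation durations with mean
300 ms and SD 150 ms; 50 ± 15 ms inter-fixation gaps, each carrying one
saccade whose amplitude is the centroid step and whose peak velocity is
1.6 × the mean (a monotone amplitude–velocity link, not a fitted main
sequence); Poisson blinks at 18 per minute (the middle of the
physiological 15–20/min band) with lognormal 150 ± 40 ms durations; and a
pupil model of 3.5 mm baseline + 0.05 mm/min drift + optional planted
sinusoid + 0.05 mm noise, with left/right written as d ± e (e ~ N(0,
0.05 mm)) so the mean-resolution rule is exercised and recovers d exactly.
Gaze and pupil samples inside blinks are omitted from the files, mirroring
device behaviour and forcing the blink ROI fallback policy to run.

What the generator does **not** emulate: oculomotor dynamics (no realistic
saccade velocity profiles, no microsaccades, no smooth pursuit), pupil
light/event responses, measurement noise structure, or enrichment dropouts
off-surface. Passing tests therefore demonstrate the *pipeline's*
correctness — parsing, epoching, gating, arithmetic, conservation — not
fidelity to any physiological model.

The packaged study preset (`mdmt_schedule()`) encodes a moral
decision-making session: 8 non-moral dilemmas plus 2 moral conditions
(personal/impersonal) × 3 observation variations (unobserved/media/
authority) × 8, i.e. 56 dilemmas, presented in seeded shuffled order as
ISI 1 s → audio ~ N(27.8 s, 3.00 s) → ISI 1 s → choice ~ N(4.34 s, 2.01 s)
truncated below at 0.5 s (rejection sampling; the truncation raises the
realised mean to ≈ 4.47 s, and the truncated-normal mean is the oracle the
recovery tests compare against), with a 30-s pause after every 7th
dilemma. The mid-session participant-resumed pause has no principled
duration, so the preset uses the same 30 s.

## Problem sizes and numerical choices

The test suite runs at desk scale by design: scripted fixtures use 12
fixations at 100 Hz over 4.8 s where exact equality is asserted;
conservation is checked over 200 random partitions of that fixture;
parameter recovery uses 200 seeds of one-minute recordings (blink rate,
fixation duration, ROI occupancy) and 200 scheduled sessions (epoch
durations), comparing recovered means within three standard errors;
spectral checks use 60-s series. The acceptance script pools 500 dilemma
epochs from consecutive seeded sessions. Tie-breaks and degenerate inputs
are fixed rather than undefined: stable sorts preserve file order between
equal timestamps, zero-width epochs are dropped, single-sample movements
are kept with zero metrics, and empty plot kinds render placeholders.

## Known limitations

* The enrichment stream is required; recordings without surface mapping
  are rejected (membership would otherwise need geometric ROI tests that
  belong to the vendor pipeline).
* No fixation/saccade detection from raw gaze; upstream labels are
  trusted as exported.
* No multitaper or wavelet spectra, and no pupillary response
  deconvolution.
* The independent-samples comparison is deliberately plain: no
  multiple-comparison correction, no mixed models.
* Video-synchronised rendering is out of scope (raw video is not parsed).
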