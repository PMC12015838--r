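# gazeproc

Headless processing and feature extraction for wearable eye-tracking
recordings exported in the Pupil Cloud Neon dialect.

Researchers in psychophysiology and cognitive psychology increasingly run
experiments on wearable eye trackers whose cloud platforms export a bundle
of parallel, time-stamped CSV streams — gaze samples, fixation/blink/saccade
intervals, pupil (eye-state) samples, events — plus a *surface-mapping
enrichment* that flags, for every frame, whether gaze fell on a tracked
region of interest (ROI), e.g. a stimulus monitor. The platforms stop short
of the summary statistics those researchers actually need per experimental
trial. `gazeproc` closes that gap: it loads and validates a recording
folder, cuts the timeline into named epochs from events, propagates ROI
membership to every stream, extracts a per-epoch battery of oculomotor and
pupillometric indices, applies blink-based trial exclusion, runs two-sample
comparisons, computes Welch spectra of the pupil series, and prepares the
standard figures — all scriptable, with no GUI and no hardware required.

## The processing model

**Epochs.** Events `(name_i, t_i)` define half-open windows
`E_i = [t_i, t_{i+1})`; the last event only terminates the final epoch, so
*n* events tile `[t_1, t_n)` into *n−1* disjoint epochs. Point samples
belong to the epoch containing their timestamp; interval events (blinks,
fixations, saccades) are assigned by midpoint and never split, so per-epoch
counts and totals are conserved under any partition. With only start/end
events the whole recording is one epoch.

**ROI membership.** Never recomputed geometrically — consumed from the
enrichment stream. Gaze and pupil samples take the flag of the temporally
nearest surface sample within 25 ms (else 0, logged). Saccades vote by
majority over their window (ties → status at onset). Blinks, whose gaze is
absent during lid closure, inherit the last surface status up to 200 ms
before onset, else the first within 200 ms after offset, else FALSE.

**Movements.** The gaze run strictly between the last sample of fixation
*k* and the first of fixation *k+1* is movement *k*, with duration, path
length `Σ‖p_{j+1} − p_j‖` and displacement `‖p_last − p_first‖`
(`path_length ≥ displacement` always), in both scene-pixel (absolute) and
surface-normalised (relative) coordinates.

**Indices.** Per epoch and category: blink count / total / average /
on-ROI ("surface") duration; fixation count, duration stats, position of
the longest fixation, mean position, consecutive-centroid distances;
gaze counts (total, per fixation, per movement) and movement
duration/distance stats; saccade duration, amplitude and velocity stats
with the overall peak; pupil first/last/max/min/average diameter (optionally
on-ROI only). Summary statistics use the population standard deviation
`σ = sqrt( (1/n) Σ (x_i − x̄)² )`. Trials (epochs) with more than 5 blinks
are excluded as acquisition errors — at a physiological 15–20 blinks/min, a
few-second trial cannot legitimately contain more. Group comparisons use
the independent two-sample *t*-test (pooled variance by default, Welch
option).

**Spectra.** The irregular pupil series is linearly resampled to 200 Hz
(gaps > 1 s flagged), then analysed by Welch's averaged modified
periodogram (Hann taper, 256-sample segments, 50 % overlap, per-segment
mean detrend) and a short-time spectrogram on the same estimator.

**Figures.** Every plot is prepared as numeric arrays first (testable) and
rendered thinly to PNG: ROI-coloured pupil trace (green = on ROI, red =
off), binary blink raster, saccade velocity/amplitude series, fixation
cloud with Gaussian kernel density (normal-reference bandwidth), absolute/
relative scan paths, histograms, periodogram and spectrogram.

**Synthetic recordings.** `simulation_config()` + `generate_recording()`
emit complete dialect folders with a ground-truth `manifest.json`:
lognormal fixations (300 ± 150 ms), Poisson blinks (default 18/min,
lognormal 150 ± 40 ms), one saccade per inter-fixation gap with a monotone
amplitude–velocity link, a pupil baseline + drift + optional planted
oscillation, a configurable ROI schedule, and device-like sample drops
during blinks. `mdmt_schedule()` packages a moral decision-making task
session: 56 dilemmas (8 non-moral + 2 moral conditions × 3 observation
variations × 8), each ISI 1 s → audio 27.8 ± 3.00 s → ISI 1 s → choice
4.34 ± 2.01 s (truncated at 0.5 s), with a 30-s break after every 7th.

## Worked example

```r
library(gazeproc)

cfg <- simulation_config(
  duration_s = 60, seed = 42,
  events = data.frame(name = c("baseline", "stimulus", "end"),
                      t_s = c(0, 30, 60)))
generate_recording(cfg, "demo_rec")

res <- run_process("demo_rec", participant = "P01", out_dir = "demo_out")
print(res$recording)
#> <gaze_recording> participant 'P01'
#>   span: 60.000 s (0 ns to 60000000000 ns)
#>   gaze 11651 | fixations 170 | blinks 14 | saccades 169 | pupil 11651
#>   events 3 | surface gaze 11651 | surface fixations 170

report_value(res$report, "blink", "count")
#> baseline stimulus
#>       11        3
report_value(res$report, "fixations", "duration_average")
#> baseline stimulus
#> 293.6794 312.5931
report_value(res$report, "pupillometry", "diameter_average")
#> baseline stimulus
#> 3.513142 3.537121
```

The two epochs average ~294 and ~313 ms per fixation (the generator plants
a 300 ms lognormal), the mean pupil diameter sits at the planted 3.5 mm
baseline, and the baseline epoch — 11 blinks in 30 s — is dropped by the
default "more than five blinks" exclusion filter, so `demo_out/P01_report.txt`
reports the surviving `stimulus` epoch plus an exclusion log.
`demo_out/` also holds the tidy `P01_features.csv`
(epoch × category × index × value × unit) and the figure set
(`P01_pupil_roi.png`, `P01_fixation_cloud.png`, `P01_periodogram.png`, ...).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/gazeproc.R simulate --out demo_rec --duration 60 --seed 42
Rscript inst/cli/gazeproc.R process  --folder demo_rec --participant P01
Rscript inst/cli/gazeproc.R validate --folder demo_rec
```

An external event table (CSV with `name,timestamp [ns]` columns, e.g. from
a stimulus-delivery program) can replace the recording's events with
`--events file.csv` or `replace_events()`.

## Canonical input files

| stream | file | key columns |
|---|---|---|
| gaze | `gaze.csv` | `timestamp [ns]`, `gaze x [px]`, `gaze y [px]`, `worn`, `fixation id`, `blink id` |
| fixations | `fixations.csv` | `fixation id`, `start timestamp [ns]`, `end timestamp [ns]`, `duration [ms]`, `fixation x [px]`, `fixation y [px]` |
| blinks | `blinks.csv` | `blink id`, `start timestamp [ns]`, `end timestamp [ns]`, `duration [ms]` |
| saccades | `saccades.csv` | `saccade id`, timestamps, `duration [ms]`, `amplitude [px]`, `mean velocity [px/s]`, `peak velocity [px/s]` |
| pupillometry | `3d_eye_states.csv` | `timestamp [ns]`, `pupil diameter left [mm]`, `pupil diameter right [mm]` |
| events | `events.csv` | `name`, `timestamp [ns]` |
| enrichment gaze | `enrichment_gaze.csv` | `timestamp [ns]`, `gaze detected on surface`, surface-normalised x/y |
| enrichment fixations | `enrichment_fixations.csv` | `timestamp [ns]`, `fixation detected on surface`, normalised x/y |

Headers are matched tolerantly: case, surrounding whitespace and bracketed
unit suffixes are ignored, and column order is free. The enrichment stream
is required in this version.
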