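---
title: "Methods: interictal patterns and unit firing in heterotopia microrecordings"
author: "pnhmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interictal patterns and unit firing in heterotopia microrecordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnhmicro)
```

## The problem

Periventricular nodular heterotopia (PNH) consists of ectopic gray-matter
nodules along the lateral ventricles that are frequently epileptogenic.
Hybrid macro–microelectrodes implanted for presurgical evaluation record,
from inside the nodules, local field potentials (LFP) and multi-unit spiking
activity. Three recurring interictal pattern (IP) classes structure the
nodular LFP:

* **PD+F** — trains of at least three periodic slow waves, each carrying a
  superimposed narrow-band fast-activity burst (60–200 Hz). A variant
  without slow waves (periodic fast activity, **PF**) occurs in one nodule.
* **SD+F** — isolated large slow waves (0.5–4 s) with prolonged superimposed
  fast activity.
* **ES** — brief sharp epileptic-spike transients, often followed by a slow
  wave, again with superimposed fast activity.

`pnhmicro` implements the quantitative chain used to characterize these
patterns and the units they recruit: event alignment, time–frequency
analysis, periodicity scoring, spike-train quality and baseline metrics,
peri-event firing statistics with cluster-based permutation inference, and
seizure-locked rasters — all exercised against a synthetic-recording
generator with known ground truth, since the underlying clinical recordings
are not publicly deposited.

## The synthetic generator

`generate_ip_series()` builds 1/f background noise (`generate_background()`,
spectral exponent 1, RMS 10 µV by default) and inserts rendered events.
Waveform primitives are deliberately simple and band-limited:

* slow deflections are raised-cosine lobes (positive-up convention, so that
  a unit firing *more* during a discharge correlates *positively* with the
  average LFP — matching the sign structure reported for activated versus
  suppressed units);
* fast activity is a Hanning-enveloped sinusoid at the preset's narrow-band
  frequency;
* the ES transient is a difference of Gaussians (~10/30 ms widths) followed
  by a 0.25 s after-going slow wave.

Per-nodule presets (`nodule_preset()`) carry the recorded narrow-band
frequencies — PD+F 92/135/106/81 Hz, ES 102/134/121/97 Hz, SD+F
96/111/77 Hz for nodules 1/2/4 — plus the intra-train period (0.511–1.723 s)
and a period-jitter fraction (0.176–0.206) read from the interval dispersion
of the recorded trains. Which nodules express SD+F is reported
inconsistently across published summaries, so the preset exposes
`sdf_fast_hz` as an override rather than hard-wiring the mapping; nodule 3
carries `NA` (no SD+F) and requesting it raises an error.

Inter-onset intervals are log-normal, parameterized by their **mode**
(the most frequent interval — the statistic reported for the recordings)
with `sigma_log` defaulting to 0.5. The recorded discrepancy between modal
(sub-second to a few seconds) and mean (tens of seconds) intervals implies
`sigma_log` near 1.5; such extreme clustering floods a desk-scale recording,
so the analysis drivers generate at `sigma_log = 1` with thinned modes and
state so. Same-kind events never overlap (intervals shorter than the
previous event's duration are redrawn, boundedly); different kinds may
interleave freely, as in the recordings.

Spike trains come from `generate_unit_spikes()`: thinning-based sampling of
an inhomogeneous Poisson process whose rate multiplies a baseline by every
overlapping event's gain curve, `lambda(t) = lambda0 * prod_k g_k(t -
onset_k)`. Thinning is performed chunk-wise against the local rate ceiling;
this is the same sampling law as global thinning but keeps the candidate
count bounded when gains stack multiplicatively. Gain archetypes mirror the
observed unit behaviors: phasic (ES-locked bump, up to ~20×), sustained
(SD+F-like plateau, up to ~100×), periodic-modulated (one bump per
deflection), inverse (gain below 1, down to complete suppression), and an
ictal plateau for seizures.

## Analysis chain

**Common timeline.** All analysis runs at 1 kHz. `downsample_to_1khz()`
applies a zero-phase 4th-order Butterworth low-pass at 400 Hz (preserving
the 60–200 Hz analysis band without phase distortion) before integer
decimation. Times are seconds from recording start; annotations are
half-open `[start_s, end_s)`; any analysis window overlapping an `artifact`
annotation is excluded everywhere.

**Alignment.** `epoch()` cuts one trial per annotation (ES: `[-1, +1]` s;
longer patterns: `[-2, +2]` s, each with an alignment pad), excluding trials
near the recording edges or overlapping artifacts. `align_trials()` refines
onsets by iterative template matching: the template is the current grand
average; each trial moves to the integer lag within ±150 ms (ES) / ±300 ms
(others) maximizing its Pearson correlation (mean-subtracted — robust to DC
offsets) with the template; iteration stops when no shift changes by more
than one sample (at most 10 iterations; non-convergence returns the best
iterate with a flag). Ties resolve to the smallest |lag|. Trial-to-average
(rather than trial-to-trial) matching keeps the procedure symmetric in the
trials, so shifts are invariant to trial order. No sub-sample interpolation
is attempted.

**Time–frequency.** `compute_tfr()` slides a Hanning taper every 5 ms —
200 ms long for ES, 400 ms for the longer patterns — and evaluates power on
a frequency grid at multiples of the taper resolution `1/window` covering
60–200 Hz (5 and 2.5 Hz bins respectively), avoiding interpolation. Windows
extending past the epoch are dropped. The trial-average map is normalized to
percentage change, `100 (P(f,t) − B(f)) / B(f)`, against the pre-event
baseline (ES: −1…−0.5 s; others: −2…−1 s); per-trial normalization is
available behind a flag. `peak_frequency()` averages the map over an
analysis window and takes the argmax (ties to the lowest frequency); the
default window hugs the event support — `[0, 0.25]` s for ES — the way
spectrum insets average power during the peak activity.

**Periodicity.** `periodicity_fraction()` scores a deflection train by the
fraction of inter-deflection intervals deviating strictly less than 25% from
the mean period; at least three deflections qualify a train as periodic. The
boundary comparison is evaluated as `|k·dt − S| < 0.25·S` (k intervals, sum
S) so exact-boundary cases are not decided by division round-off. The
denominator is the interval count (n−1); a per-deflection denominator is
available because summary counts of "conforming deflections" admit either
reading. Percentages round to the nearest integer (124/150 → 83%).
`interval_mode()` histograms inter-onset intervals (default 1 s bins; ties
to the smallest interval); it is deliberately unit-agnostic since the
reported modal statistics do not state their unit.

**Unit metrics.** `detect_spikes()` high-passes above 300 Hz (zero-phase),
estimates the noise scale as `median(|x|)/0.6745`, and takes one event per
contiguous negative excursion beyond `k ×` that scale (k = 6, or 5.5 for one
nodule in the source recordings), timestamped at the extremum; an
absolute-value polarity and an optional whitening step are out of scope
(the pipeline consumes spike times from any sorter). `rpv()` is the
percentage of inter-spike intervals below 2 ms. `classify_unit()` calls SUA
iff RPV < 1.0 (strict) and amplitude SNR ≥ 4 — thresholds are configurable
and always reported, because morphology-informed judgments cannot be
reduced to a fixed rule. `baseline_stats()` tiles the recording into 10-s
windows anchored at t = 0 (partial final window dropped), discards windows
overlapping any IP, seizure or artifact, and reports the mean firing rate
and CV2 — the *local* variability index `2|ISI_{i+1} − ISI_i| /
(ISI_{i+1} + ISI_i)` averaged over consecutive ISI pairs within a window
(1 for Poisson firing, 0 for clock-like), not the classic SD/mean.

**Peri-event firing.** `kernel_rate()` evaluates, at 1 kHz, the sum of
Gaussian kernels (σ = 10 ms for ES, 50 ms for longer patterns) centered on
each spike, truncated at ±4σ without reflection, per aligned trial.
`bin_rates()` averages each trial into 100 equal bins for inference.
`rate_lfp_correlation()` is the Pearson correlation between the average
time-locked rate and the average time-locked LFP. `modulation_percent()`
expresses the extreme significant-bin average rate as a percentage of the
pre-event baseline-window rate (up: `100 (max − b)/b`; down:
`100 (b − min)/b`, 100 = silence); a direction without a significant
cluster propagates as "n.s.", never 0. The baseline here is the pre-event
window (matching the time-locked statistics); a global resting-rate
baseline and a cluster-mean (rather than peak-bin) summary are available
behind flags. The peak-bin default matches the "maximal significant
increase" reading of the reported unit tables; its sampling error scales as
`sqrt(gain / baseline_rate) / sqrt(trials)`, so small gains in slow units
are overestimated — see *Limitations*.

**Cluster statistics.** `cluster_permutation_test()` subtracts each trial's
mean baseline rate from its bin vector, forms first-level one-sample
t-statistics per bin, merges bins with two-tailed p < 0.01 into contiguous
same-sign clusters, and refers each cluster's mass (sum of t) to a
Monte-Carlo null built by flipping each trial's difference vector with
probability ½ (10,000 draws by default), recording the **maximum absolute
cluster mass** per draw; cluster `p = (1 + #{null ≥ observed}) / (1 +
n_perm)`, read one-sided per direction at 0.05 against the common
max-|mass| null — which controls the familywise any-cluster rate at about
0.05 overall. The sign-flip scheme is the standard construction for a
one-condition-versus-baseline design, the only exchangeable null available
within trials; a paired bins-versus-baseline variant reduces to the same
flips. For ≤ 20 trials `exact = TRUE` enumerates all `2^n` sign
assignments, giving deterministic, trial-order-invariant p-values; on the
Monte-Carlo path the flip matrix is drawn once from the seed and attaches
to trial positions, so reordering trials perturbs p only within sampling
error. Zero-variance bins are excluded from cluster formation with a
warning.

**Seizures.** `seizure_raster()` re-references spikes to annotated seizure
onsets and reports pre/post mean rates. With a handful of seizures no
inferential statistics are attached, by design.

## Numerical and design choices

* Frequency grids snap to the taper resolution; time grids to the 1 kHz
  sample grid. No padding, no interpolation anywhere.
* The alignment template is the grand average (not a designated trial); lag
  ties break to the smallest magnitude, then the negative lag.
* The log-normal interval mode is mapped to parameters via
  `mu = log(mode) + sigma^2`.
* Periodicity tolerance is a strict inequality; the boundary is evaluated in
  a division-free form.
* The EDF writer stores one data record with a symmetric ±32767 digital
  range and the physical range exactly as printed in the header, so
  round-trips are exact to one digital step; raw float32 + JSON sidecar is
  the lossless path. Truncated files raise errors naming the defect.
* Reported p-values carry the +1 correction and can never be 0.

## What the generator does and does not emulate

It reproduces: narrow-band fast-activity frequencies per pattern and nodule,
periodic-train timing with realistic jitter, heavy-tailed event clustering,
event-locked rate gains spanning the observed range (including suppression
and silence), seizure epochs with sustained rate elevation, and 1/f
background. It does **not** attempt biophysical realism: no volume
conduction, no patient-specific waveform morphology beyond the spectral
peaks, no spike waveform shapes beyond a biphasic test template, no
nonstationary background. Passing tests therefore demonstrate that the
*analysis chain* recovers known ground truth under realistic event
statistics — not that it would resolve every ambiguity of clinical data.

## Problem sizes used in the test suite

Synthetic series for spectral recovery use ~100–180 events per pattern at
1 kHz (the fast-test synthesis rate; 32 kHz synthesis plus decimation is
exercised separately in the I/O tests). Cluster-test calibration uses 200
simulated units with 50 trials × 100 bins and 1,000 permutations; the
modulation ladder uses gains {2, 5, 20, 100}× at ~100 events. The analysis
drivers under `analysis/` simulate four 50-minute recordings.

## Limitations

* **Sign-flip calibration at desk scale.** The cluster test is exactly
  calibrated for sign-symmetric data (familywise rate 0.050 in the Gaussian
  simulation of the test suite). For sparse Poisson units at 50 trials it is
  anti-conservative, because the per-trial baseline mean estimated from a
  1-s window is right-skewed: simulated familywise rates run ~0.10–0.18 for
  baseline rates of 1.4–8 Hz, falling to ~0.02–0.03 at ≥10 Hz. With
  baseline rates drawn across the recorded cohort's range the pooled rate
  is ~0.10 rather than the nominal 0.05. The recorded patterns provided
  950–3,674 trials each, where this small-sample skewness effect
  disappears; at 50 trials it is a real property of the method, and the
  corresponding acceptance check is left failing rather than re-tuned.
* **Peak-bin modulation bias.** The default up/down percentages read the
  extreme significant bin; for a 2× gain in a slow unit at 100 events the
  extreme-value noise inflates the estimate beyond 15%. The recovery
  demonstration therefore uses a fast-firing unit (40 Hz, the top of the
  recorded range); the cluster-mean variant trades this bias for dilution
  by smoothing-transition bins.
* **Mixed recordings contaminate baselines.** When two patterns share a
  narrow-band frequency (one nodule's ES and PD+F sit 1 Hz apart), events
  of one class inside another's baseline window bias the percentage-change
  spectrum at the shared frequency; the analysis drivers flag this case.
  Single-pattern series recover every preset frequency within one bin.
* Deflection times for periodicity scoring come from annotations or the
  generator; automatic deflection detection from raw LFP is not included.
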