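---
title: "Local and global beta bursts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local and global beta bursts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each stage, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design decisions taken
where the procedure was genuinely open. It states no empirical result that
the test suite does not itself compute.

## 1. The measurement model

Beta-band activity in sensorimotor field potentials is treated as a point
process of discrete *burst* events rather than a continuous power signal.
On an electrode array a burst epoch is characterized by which channels
participate: epochs engaging a small spatially clustered set of channels
("local") are distinguished from epochs engaging most of the array
("global"), and the two classes are analyzed separately throughout.

### Per-channel burst detection

The raw LFP (3051.8 Hz) is decimated by 3 (anti-aliased, zero-phase),
bandpass filtered in the beta band with a Butterworth filter (order 3 by
default; some datasets use 4), and Hilbert transformed. With `amp` the
envelope of one channel over one session:

* `thresh  = median(amp)`
* `sigma   = sd(amp)` (population divisor)
* `thresh2 = thresh + sigma`

A burst is a maximal run of `amp > thresh` that lasts at least 100 ms and
whose maximum exceeds `thresh2`. The median/SD construction makes the rule
scale-free: multiplying a channel by any positive constant changes nothing
downstream (this invariance is tested). Note a consequence exercised by the
synthetic world: the rule's *precision* depends on bursts being prominent
enough to inflate the session SD; in a pure-noise channel, envelope
excursions above `median + sd` lasting 100 ms are not rare.

Burst features are the normalized amplitude
`(mean in-burst amp - thresh) / sigma`, the duration, and the mean
instantaneous frequency. Instantaneous frequency is implemented as
`diff(unwrap(phase)) * fs / (2*pi)`; the differentiated phase is taken over
the full series and averaged over the burst span.

### The local/global split

Per sample, the fraction of (non-excluded) cortical channels inside a burst
is computed. At timepoints where at least 3 channels burst, this fraction is
bimodal: a low mode (local epochs) and a mode near 1 (global epochs). A
two-component Gaussian mixture is fitted to the pooled per-day distribution
— each day's samples reweighted to equal total weight, the tractable
equivalent of fitting the average of the per-day histograms — and the
threshold is the crossing `w1 N(x; m1, s1) = w2 N(x; m2, s2)` between the
two means (closed-form quadratic root, dense-grid fallback). One threshold
is used for all days of a run. EM uses 10 restarts, tolerance 1e-6 and a
fixed internal seed; a collapsed mixture (means closer than a tenth of the
combined SDs) falls back to the midpoint with a warning and a flag.

Labels: 2 (global) iff `fraction > threshold`; 1 (local) iff
`fraction <= threshold` **and** at least 3 channels burst; else 0. Population
events are maximal constant-label runs of at least 100 ms; a direct
local-to-global transition terminates both runs, so every event is
label-pure. Excluded channels shrink both numerator and denominator of the
fraction, but the 3-channel gate stays absolute.

### Spatial clustering

For an event with per-channel activity fractions `fracact` (fraction of the
event's samples each channel spends bursting), the burst center is the
`fracact`-weighted mean of the channel coordinates, and `distcenter` is the
weighted mean Euclidean distance of channels to that center. The null model
shuffles whole columns (the channel vector at one sample) of the
concatenated event arrays, re-cuts at the original event lengths, and
recomputes the distances; this conserves the column multiset exactly, hence
the average number of active channels per burst and each channel's total
activation. 100 shuffles; the statistic of interest is
`distcenter - mean(null)`, negative when bursts are more clustered than
chance. Grid geometry is 8x8 with 0.5 mm column and 0.375 mm row pitch,
row-major channel order, origin at channel 1.

### Spike entrainment

Spikes are binned at 1 ms. For each unit-channel pair and burst class, the
phases of that channel at in-burst (and in-epoch) spike times give a
resultant vector length `r`. The null draws the same number of phases with
replacement from the channel's pooled in-burst phase samples, 100 times;
significance is `r` above the 95th percentile, and the modulation z-score is
`(r - mean)/sd` of the shuffle. Drawing *with* replacement is a pinned
choice — the pool is large and the draw is rate-matched, so the distinction
is immaterial in practice but must be fixed.

### Firing statistics and population dynamics

Rates use 10 ms bins. "Variability" is pinned as the SD of the binned rate
within an epoch (not the CV), trial-averaged. Burst conditioning assigns
each bin the majority label of the LFP samples it covers, ties going to the
lower code (conservative toward "no burst").

Population dynamics: `X_t = A X_(t-1)` on 50 ms binned rates from 0.5 s
before reach start to the first object lift, fitted by least squares on
within-trial consecutive-bin pairs; held-out trials are predicted one step
ahead with teacher forcing (each bin predicted from the *true* previous
bin), matching a reading of the model as predicting the next population
state from the current one. Per trial and burst category,
`R² = 1 - SSE/SST` over that trial's bins of that category, with SST taken
about the mean of those same true bins; categories with fewer than 2 bins
in a trial are not "valid" and yield NA. The fixed-budget protocol
subsamples 8 training trials and 12 units (defaults), 200 times.

### Behavior

Hand position is smoothed with a Gaussian kernel (11 frames, SD 1 frame at
50 Hz), speed taken by central differences (symmetric, so onsets are not
biased by the differencing direction). The crossing frame is the first
frame past the apparatus line; peak speed is searched within ±200 ms of it;
reach start is the last frame before the peak below 0.1 x peak, grasp start
the first frame after it below the same bound. Trials without a crossing
are flagged and carry no events. Reach epoch: reach start to grasp start;
grasp epoch: grasp start to reward, or door open + 10 s for unrewarded
trials. Trial time (reach start to reward; 10 s when unrewarded) normalized
by per-slot pre-stroke means gives the per-day recovery index
`1 - (mean_norm - 1) / (first_day_norm - 1)`: 0 on the first post-stroke
day, 1 at pre-stroke parity. The early/late session split threshold is 0.5
by default (0.8 for datasets where 0.5 leaves almost no early sessions).

## 2. The synthetic world

`generate_session()` produces one behavioral day with known ground truth:

* **Background**: per-channel `1/f^1.5` noise (unit variance) with a 20%
  shared common-mode component, so envelope medians are non-degenerate and
  channels are weakly correlated.
* **Bursts**: Hann-enveloped sinusoids added to the background. Global
  events (rate 0.25/s) hit all cortical channels at amplitude 2.0, last
  0.35 s on average at 21 Hz, and are accompanied by subcortical bursts
  with probability 0.9. Local events (rate 0.40/s) hit the channels within
  0.8 mm of a random center (typically 5-9 channels) at amplitude 1.2, last
  0.20 s at 27 Hz, with subcortical coincidence probability 0.1. Events
  never overlap (0.15 s separation), so classification accuracy is
  well-defined. The class asymmetries (global higher-amplitude, longer,
  lower-frequency, subcortically coincident) are the contrasts the analyses
  must recover — by construction, which is exactly what a directional test
  can and cannot establish (see below).
* **Amplitude scale**: 2.0 and 1.2 are in units of the background's
  broadband SD. They were chosen once so that bursts dominate the session
  envelope SD the way prominent bursts do in real recordings; with the
  median/SD detection rule this is what makes detection *precise* (a world
  with faint bursts fails the rule's precision no matter the
  implementation). They were not revisited after seeing test outcomes on
  other criteria.
* **Spikes**: inhomogeneous Poisson at base 10 Hz. Inside a burst the
  intensity is modulated by `exp(k cos(phase - pref)) / I0(k)` with
  `k = 1.5` for global and `0.5` for local bursts (preferred phases uniform
  per unit); inside global bursts the base rate is additionally halved
  (`global_rate_scale = 0.5`).
* **Kinematics**: 50 Hz frames; one Gaussian-bell reach per trial
  (peak 300 mm/s, width ~0.2 s), gentle 2 Hz manipulation movement during
  the grasp, rest between trials; positions are the trapezoidal integral of
  speed, so central-difference speed estimates are unbiased. Hand speed is
  multiplied by 0.35 inside global-burst intervals, and trials are
  lengthened in proportion to their global-burst overlap — planting the
  speed and occupancy/trial-length effects.

**What the generator does not emulate**: volume conduction and distance-
dependent channel correlations; non-stationary burst rates across a
session; spike waveform drift and sorting errors; camera tracking dropouts;
biophysical burst generation. A green test therefore establishes that the
pipeline recovers the stated statistical structure, not that it is robust
to every pathology of real recordings.

## 3. Numerical choices

* **Zero-phase filtering.** Only the filter order is conventionally
  reported; a causal filter would lag burst onsets by a band-dependent
  delay and corrupt burst-behavior timing, so all filtering is
  forward-backward (effective order doubles). This is a documented
  deviation risk if a reference analysis filtered causally.
* **Fused spectral path.** For long multichannel sessions the pipeline
  computes decimation + zero-phase bandpass + analytic signal in a single
  FFT pass per channel (`beta_series_fft()`): the squared-magnitude
  responses of the two filters are applied in the frequency domain,
  negative frequencies dropped, and the spectrum truncated to the decimated
  rate. Away from session edges this agrees with the time-domain reference
  (`decimate_lfp()` + `analytic_beta()`) to a fraction of a percent of the
  envelope scale (tested); the first/last 0.5 s are flagged unusable either
  way.
* **Instantaneous frequency** is `dphase * fs / (2*pi)`. A printed form of
  this normalization circulating with the procedure ("`* (1/0.5*pi) * fs`")
  is dimensionally inconsistent under standard precedence and was not
  implemented.
* **Strictness pins**: `>` for the envelope threshold crossing, `>=` for
  both the 100 ms duration and nothing-else; ties at exactly 100 ms are
  kept ("at least"). No gap-bridging between sub-threshold dips. Population
  SD (divisor n) for `sigma`.
* **Thresholds from trial windows.** Channel thresholds are computed over
  the union of trial segmentation windows ([-3, 10] s around reach start),
  mirroring per-day trial extraction; detection then runs over the full
  session so events between trials are still visible to burst-behavior
  alignment.
* **Artifact handling.** Manual trial/channel curation is replaced by a
  config-driven exclusion list plus an automatic rule (exclude channels
  whose envelope SD exceeds 5x the median channel SD) — manual curation is
  not reproducible.
* **Crossing line.** The generator expresses the apparatus line as a fixed
  offset from each trial's door-open hand position (half the unperturbed
  reach span); detection uses the same convention. On real data the line is
  one fixed image coordinate; the offset form is operationally identical
  for a pipeline whose positions are relative.
* **Epoch assignment of events** uses the epoch containing the event's
  onset. Event-to-category assignment for feature contrasts tags each
  channel burst with the population event containing its midpoint.
* **Degenerate inputs**: zero-variance envelopes give `sigma = 0` and a
  flagged (NA, warned) normalized amplitude; zero-spike unit-channel pairs
  are flagged undefined rather than scored 0; zero-variance true bins make
  the per-category R² NA.

## 4. Known limitations

* The 1/f exponent (1.5) and common-mode fraction (0.2) of the synthetic
  background are free parameters of the stated world, not fitted to any
  recording.
* The mixture threshold assumes a genuinely bimodal fraction distribution;
  on data without a global mode it degrades to the flagged midpoint
  fallback.
* The column-shuffle null conditions on the observed per-sample channel
  sets; it does not model temporal autocorrelation of channel membership
  within a burst.
* Statistical inference beyond descriptive summaries (mixed-effects models,
  multiple-comparison control) is intentionally out of scope: the pipeline
  emits the per-day/per-trial/per-unit tables such models consume.
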