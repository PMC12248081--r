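# betaburst

Detection and local/global classification of transient beta-band bursts in
multichannel cortical and subcortical field potentials, with downstream
analyses linking burst classes to spiking activity, population dynamics and
reach-to-grasp behavior.

## The scientific problem

Sensorimotor beta activity (~13-35 Hz) is not a continuous oscillation but a
sequence of brief high-amplitude *bursts*. On a multielectrode array, a burst
epoch can be **local** — confined to a small, spatially clustered set of
channels — or **global** — engaging essentially the whole array and tending
to coincide with subcortical beta bursts. The two classes behave differently:
global bursts entrain single units, suppress firing rate and firing
variability, degrade the one-step predictability of population dynamics, and
accompany slowed movements, whereas local bursts are a feature of healthy,
recovered motor behavior. `betaburst` implements the full analysis chain
needed to measure these effects, plus a ground-truthed synthetic-session
generator so every stage is testable without animal recordings.

## The core procedure

1. **Preprocess.** Raw LFP (default 3051.8 Hz) is decimated by 3 with an
   anti-aliasing lowpass, bandpass filtered in an animal-specific beta band
   (default 15-35 Hz, order-3 Butterworth applied forward-backward), and
   Hilbert-transformed. The envelope is `amp = |z|`, the phase `arg(z)`.
2. **Detect per-channel bursts.** For each channel, with `thresh` the session
   envelope median and `sigma` its SD: a burst is a maximal run of
   `amp > thresh` lasting at least 100 ms whose maximum exceeds
   `thresh2 = thresh + sigma`. Features: normalized amplitude
   `(mean(amp) - thresh) / sigma`, duration, and mean instantaneous frequency
   `dphase * fs / (2*pi)`.
3. **Classify timepoints.** The fraction of cortical channels bursting is
   computed per sample; a two-component Gaussian mixture fitted to the pooled
   per-day fraction distribution (at timepoints with >= 3 bursting channels)
   yields a threshold at the density crossing. Label 2 (global) when the
   fraction exceeds it, 1 (local) when at least 3 channels burst below it,
   else 0; population events are constant-label runs >= 100 ms.
4. **Quantify.** Spatial clustering via activity-weighted burst centers
   against a 100-fold column-shuffle null; spike entrainment via the
   resultant vector length calibrated against 100 rate-matched draws from
   the in-burst phase pool (significant above the 95th percentile; modulation
   z-score `(r - mean)/sd` of the shuffle); burst-conditioned firing
   statistics in 10 ms bins; one-step linear population dynamics
   `X_t = A X_(t-1)` in 50 ms bins with per-trial per-category R²; behavioral
   onset extraction by the 0.1 x peak-speed rule; normalized trial times and
   a per-day recovery index (0 = first post-stroke day's deficit,
   1 = pre-stroke parity).

## Worked example

```r
library(betaburst)

out <- generate_session(synth_config(session_duration = 60, seed = 11))
res <- run_pipeline(list(out$bundle), "results",
                    pipeline_config(dynamics_reps = 20))
#> Warning: fitting local/global threshold on a single day

res$threshold$threshold
#> [1] 0.3489456
table(res$sessions[[1]]$events$category)
#> global  local
#>     12     35
res$sessions[[1]]$cooccurrence
#>   category  fraction n_samples
#> 1    local 0.2442225      6707
#> 2   global 1.0000000      3843
round(res$sessions[[1]]$speed, 1)
#>   none  local global
#>   48.8   84.9   53.6
```

The channel-fraction threshold (~0.35) separates the two modes of the
bursting-fraction distribution; the session contains 12 global and 35 local
population events; global events coincide with subcortical bursting far
more often than local ones (1.00 vs 0.24 of in-event timepoints); and hand
speed during bursts is lower for global than for local events (53.6 vs
84.9 mm/s — the directional signature of movement slowing inside global
bursts; the "none" mean is dominated by the slow manipulation phase of the
grasp). Any rerun with the same seed reproduces these numbers exactly.

## Command line

```sh
Rscript inst/cli/betaburst simulate --out session.h5 --seed 1 --duration 300
Rscript inst/cli/betaburst run session.h5 --out results/
Rscript inst/cli/betaburst report results/
```

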