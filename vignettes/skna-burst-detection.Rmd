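---
title: "SKNA burst detection with the Teager–Kaiser energy operator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SKNA burst detection with the Teager–Kaiser energy operator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(sknaer)
```

## The signal and the problem

Skin sympathetic nerve activity (SKNA) is a microvolt-scale, high-frequency
(500–1000 Hz) signal that rides on ordinary body-surface ECG electrodes when
the lead is sampled fast enough (here 8 kHz). Sympathetic discharges appear
as *bursts*: transient episodes, typically hundreds of milliseconds long,
during which the band-passed amplitude rises well above baseline. Burst
counts, durations and energies are the quantities of clinical interest, so
the computational problem is segmentation: label every sample of the
recording `burst`, `baseline`, or `artifact`.

Two properties make this hard. First, the nerve signal shares its electrode
with a millivolt-scale ECG; even after band-passing to 500–1000 Hz, residual
high-frequency QRS energy survives and produces short false bursts locked to
the heartbeat. Second, the classical detector — integrated SKNA (iSKNA):
rectify, RC-integrate with τ = 0.1 s, threshold at μ + ρσ — smears burst
edges (the RC stage is causal and slow) and fires on every energetic
transient, QRS residue included.

## The detection pipeline

`skna_detect()` implements the following chain for `method = "tke"`:

1. **Band-pass** 500–1000 Hz, 4th-order Butterworth applied forward and
   backward (`signal::filtfilt`), so filtering is zero-phase and burst edges
   are not displaced.
2. **Teager–Kaiser energy (TKE)**: φ(n) = f²(n) − f(n+1)f(n−1), full-wave
   rectified. For a sinusoid A·sin(Ωn) the operator returns the constant
   A²sin²(Ω), i.e. it estimates amplitude *and* frequency energy jointly and
   reacts within two samples — the property that makes onset localisation
   sharp. Boundary samples copy their nearest interior value.
3. **Envelope**: a centred sliding maximum over n = 2 ms of samples. Two
   milliseconds is the minimum duration of a nerve action potential, so the
   envelope bridges sub-action-potential dips without hiding burst structure.
4. **Threshold**: eth = λ · S<sub>max</sub>, where S<sub>max</sub> is the
   maximum envelope over a burst-free baseline epoch and λ defaults to 1
   ("anything the quiet baseline never reached"). A candidate opens where
   the envelope crosses eth rising (env ≥ eth, positive slope) and closes
   where it falls away (env < eth, negative slope).
5. **Boundary refinement**: a short-window integral signal (centred moving
   mean over Δt = n/2) reflects local detail better than the sliding max.
   Each rough boundary moves to the integral minimum within ±L/10 of itself
   (L the candidate length); argmin ties break outward — earliest for the
   start, latest for the end — so refinement never truncates burst energy.
6. **Artifact rules**:
   - *QRS width*: a burst that contains an R peak and is narrower than that
     beat's QRS complex is residual ECG energy, and is relabelled
     `artifact`. QRS complexes are found with an integrated-derivative
     detector and delineated with a curve-length transform (below).
   - *Minimum duration*: bursts shorter than T<sub>s</sub> = 2 ms (one nerve
     action potential) are relabelled `artifact`.

The result is a classed `skna_detect` object whose `segments` table tiles
the recording exactly — every sample has one label — which is the invariant
the energy features rely on. `method = "iskna"` runs the classical
comparator through the same interface.

## Features

- **aSKNA** (µV): the mean of iSKNA decimated to one value per 0.1 s unit
  time (a 5-minute window averages exactly 3000 values). It is a plain
  amplitude average, so it scales with electrode gain and is disturbed by
  any energetic artifact.
- **SKNAER** (dB): 10·log₁₀(P_burst / P_baseline), where each P is the sum
  of squared band-passed samples over the correspondingly labelled region of
  the analysis window; artifact samples count toward neither. Because gain
  multiplies numerator and denominator identically, SKNAER is
  gain-invariant, which is the central argument for it over aSKNA. A window
  that is entirely burst or entirely baseline has no defined ratio: it is
  flagged `abnormal` and reported as `NA`, never ±Inf (optionally retried
  with a doubled window via `skna_features(abnormal_retry = TRUE)`).

Reference HRV features (SDNN; vLF/LF/HF band powers from a Lomb periodogram
on the uneven beat times, no resampling) are provided for the conventional
autonomic comparison. vLF is reported `NA` below 5 minutes of data.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `band_low_hz`, `band_high_hz` | 500, 1000 | Hz | analysis band |
| `rho` | 3 | – | iSKNA threshold multiplier (μ + ρσ) |
| `lambda` | 1 | – | envelope threshold multiplier |
| `n_env_ms` | 2 | ms | sliding-maximum window |
| `dt_ms` | `n_env_ms / 2` | ms | integral (moving-mean) window |
| `ts_ms` | 2 | ms | minimum burst duration T<sub>s</sub> |
| `rc_tau_s` | 0.1 | s | RC integrator time constant |
| `baseline_interval` | `NULL` (auto) | s | burst-free epoch for S<sub>max</sub> |
| `invert_qrs_width_rule` | `FALSE` | – | flip the QRS width inequality (see below) |

## Numerical and design choices

**Automatic baseline selection.** When no `baseline_interval` is given, the
record is cut into 1 s windows and every window whose envelope maximum is at
most twice the median window maximum is used as baseline. The screening
statistic is the window *maximum* — the same statistic the threshold is
built from — because a window clipped by the edge of a large burst can have
a quiet median while its maximum carries burst energy; and *all* non-outlier
windows are kept, because selecting only the very quietest windows would
bias the estimated baseline maximum downward and admit noise crossings. The
rule assumes bursts occupy a minority of the record; pass an explicit
interval for strongly activated recordings (the bundled scenario helpers
do).

**Envelope dilation and the minimum-duration rule.** A sliding maximum of
window n widens every suprathreshold event by n − 1 samples, so a single
noise spike already produces a segment of length ≥ n = T<sub>s</sub> and a
naive duration test can never fire. The pipeline therefore compares
L − (n − 1) against T<sub>s</sub>: the duration of the underlying event, not
of its dilated footprint. The exported `reject_short_bursts()` keeps the
plain contract (its `dilation_samples` argument defaults to 0).

**Sub-T<sub>s</sub> gap closure.** Two distinct sympathetic discharges
cannot be separated by less than one nerve action potential, so an
end/start boundary pair closer than T<sub>s</sub> is removed and the bursts
concatenated (`merge_close_bursts()`). Without this, a stochastic burst
carrier fragments at threshold crossings near its tapered edges.

**QRS width inequality.** The discrimination rule relabels a burst that
contains an R peak when its length L is *smaller* than the contained QRS
width W<sub>qrs</sub> (a genuine burst is longer than the complex it
overlaps). `invert_qrs_width_rule = TRUE` applies the inverted inequality for
comparison purposes.

**QRS delineation.** Onset/offset come from a curve-length transform: the
ECG is low-passed to 40 Hz (the QRS morphology band — at µV resolution,
broadband noise otherwise dominates the arc length), the per-sample
increment √(1 + Δy²) − 1 is accumulated over an 80 ms backward window for
the onset and a forward window for the offset, and the boundary is placed
where the accumulated length falls below 1% of the beat's total curve
length. Widths are clipped to the physiological 40–200 ms range; beats
within 250 ms of the record edge are dropped with a message. The subtraction
of 1 per sample removes the flat-baseline offset of the classical transform
so the threshold fraction acts on the morphology-driven part.

**Tie-breaking and conventions.** All segment tables use 0-based half-open
`[sp, ep)` sample intervals; annotations are in seconds. Thresholds use the
population standard deviation (the definition of the iSKNA rule). The first
and last 5τ of the iSKNA signal are excluded from its threshold statistics
(RC warm-up). Matching for evaluation is greedy one-to-one by descending
overlap — optimal or within one of optimal on the small instances property
tests compare against an exhaustive matcher.

## The synthetic generator: realism and limits

`skna_simulate()` builds a single surface lead as the sum of:

- a PQRST template of Gaussian bumps (R amplitude 1 mV by default) placed at
  75 bpm with ±3% uniform RR jitter. The template includes a small
  intra-QRS high-frequency component (default 4 µV RMS near 700 Hz, confined
  within the complex), because real QRS complexes retain energy above
  500 Hz — this is precisely the artifact the QRS-width rule exists for, and
  without it the rule would be vacuously satisfied;
- nerve bursts: white noise band-passed to 500–1000 Hz, Tukey-tapered
  (α = 0.25), scaled to a target RMS amplitude drawn uniformly from the
  configured range, with Poisson onsets thinned to a 50 ms minimum gap;
- white baseline noise (1 µV RMS default), plus optional mains interference,
  broadband EMG events (20–450 Hz) and step artifacts.

Ground truth (burst sample intervals, R-peak indices, injected artifact
intervals) is returned alongside. The generator restores the caller's RNG
state, so the same spec and seed reproduce a recording bit for bit.

Limits worth keeping in mind: bursts are stationary band-limited noise, not
physiological spike trains, so intra-burst structure is unrealistic; the
ECG template is stylised (no respiratory modulation, no ectopy); baseline
noise is white rather than 1/f; and electrode motion is reduced to step
artifacts. These simplifications make ground truth exact, which is what the
evaluation needs, but absolute performance numbers on synthetic data should
not be read as clinical performance.

## Worked example

```{r example}
spec <- sim_spec(duration_s = 60, burst_rate_per_min = 10,
                 burst_amplitude_uv = c(10, 80), seed = 1)
sim <- skna_simulate(spec)
fit <- skna_detect(sim$recording)
summary(fit)
evaluate_detection(fit, sim$truth$bursts)
skna_features(fit, window_s = 30)
```

```{r plot}
plot(fit, xlim = c(0, 15))
```

The artifact problem the pipeline solves is easiest to see on a recording
that contains an ECG but *no* true bursts: every detection is a false
positive. The iSKNA comparator fires on the residual QRS energy; the
pipeline's QRS-width and minimum-duration rules suppress it.

```{r comparator}
quiet <- skna_simulate(sim_spec(duration_s = 60, burst_rate_per_min = 0,
                                seed = 1))
c(pipeline_fp = nrow(bursts(skna_detect(quiet$recording))),
  iskna_fp = nrow(bursts(skna_detect(quiet$recording, method = "iskna"))))
```
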