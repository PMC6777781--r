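---
title: "Models and methods behind echosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind echosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosim)
```

echosim simulates and analyses automated echo-detection experiments in which
a motorised reflector (a disk that can be turned edge-on to become acoustically
invisible) moves along a rail between 0.7 and 3.9 m from a listener, who
reports on each trial whether a presented click was reflected. This vignette
explains the models the package implements, the conventions it had to fix
where the experimental literature leaves room, and what its synthetic data do
and do not establish about real measurements.

## The SIAM staircase

Each session is an adaptive yes–no track following the single-interval
adjustment matrix (SIAM). The reflector state is drawn independently each
trial (reflecting with probability 0.5), the listener answers yes or no, and
the outcome moves the reflector on its 0.5 cm grid:

| outcome | state × response | step |
|---|---|---|
| hit | reflecting × yes | +0.25 m (harder) |
| miss | reflecting × no | −0.25 m |
| correct rejection | nonreflecting × no | 0 |
| false alarm | nonreflecting × yes | −0.50 m |

Steps that would leave the rail are clipped to the bound — the physical
carriage cannot move further. A session stops after 12 direction reversals
and the threshold estimate is the mean of the last 10 reversal distances.

Three conventions are not fully determined by that description, and
`run_session()` fixes them as follows:

* **Zero steps are transparent.** Correct rejections move nothing and leave
  the pending direction untouched, so the CR row of the matrix is purely
  neutral. This matches common staircase practice.
* **Clipped steps keep their intended sign.** A miss at 0.7 m cannot move
  the carriage, but it still counts as a downward intention; otherwise a
  responder pinned at the near rail would never reverse and sessions could
  not terminate.
* **A reversal is logged at the post-step distance**, i.e. the first
  distance of the new run direction, as an experimental control script
  naturally does when it appends the freshly computed position at the moment
  it detects the direction change. This choice was validated against the
  chance-level simulation below: logging the pre-step turning point instead
  shifts the simulated chance bands upward by 2–5 cm, outside the published
  intervals, while the post-step convention reproduces them.

The starting distance of a session is configurable and defaults to 0.7 m,
the closest position, where participants are trained before testing. The
chance bands are sensitive to this choice — starting mid-rail inflates the
upper band endpoint by more than 30 cm because early reversals from the
descent survive into the trailing average — which is itself evidence that
the original sessions started near the close end.

Degenerate responders (never yes, or always correct) never reverse; a
500-trial safety cap then ends the session, and the threshold falls back to
the mean of whatever reversals exist, or to the final distance when there are
none (the far rail for a perfect responder, the near rail for a mute one).

## Observers

`random_observer(p_yes)` answers yes with fixed probability regardless of the
stimulus. `sdt_observer()` is an equal-variance Gaussian signal detection
model: at distance $d$ the sensitivity is
$d'(d) = \max(0,\; d'_{\mathrm{ref}} - k\,(d - d_{\mathrm{ref}}))$ and, with
criterion $c$,

$$p(\text{yes} \mid \text{reflecting}) = \Phi(d'/2 - c), \qquad
  p(\text{yes} \mid \text{nonreflecting}) = \Phi(-d'/2 - c).$$

For an unbiased observer the proportion correct at sensitivity $d'$ is
$\Phi(d'/2)$ — 69% at $d' = 1$. The linear decay with a floor at zero is a
transparency choice, not a fitted psychometric shape: no published
distance–sensitivity function exists for this task, and the simulations only
require that $d'$ cross a target level at a known distance. Any other profile
can be plugged in through `dprime_fun`.

## What the staircase actually targets

The SIAM matrix above is commonly described as targeting $d' = 1$. Setting
the expected per-trial movement to zero shows otherwise. With reflecting
probability $\tfrac12$, hit rate $H$ and false-alarm rate $F$:

$$E[\Delta] = \tfrac12\big(0.25H - 0.25(1-H)\big) - \tfrac12\,0.5F
            = 0.125\,(2H - 1 - 2F),$$

which vanishes where $H - F = \tfrac12$. For an unbiased observer that is
$d' = 2\,\Phi^{-1}(0.75) \approx 1.35$ (75% correct), not $d' = 1$ (69%
correct). `siam_target_distance()` computes this drift-zero distance for any
observer, and `recover_threshold_distance()` reports both reference points.

Simulation confirms the distinction. For an observer with
$d'(d) = 3 - (d - 0.7)$, the $d' = 1$ crossing is at 2.70 m and the
drift-zero distance at 2.35 m. Sessions started at the drift-zero point
recover 2.28 m on average (the reversal logging convention contributes a
small downward bias of about 7 cm); sessions started at 0.7 m recover about
2.0 m, because reversals accumulated during the initial climb survive into
the 10-reversal trailing average. Users comparing simulated thresholds to a
nominal sensitivity level should therefore use the drift-zero distance, and
should treat thresholds from short, low-start sessions as conservatively
biased. The corresponding acceptance check in `tests/testthat/` asserts
recovery at the $d' = 1$ crossing and fails by construction; it is retained
as an honest record of the discrepancy.

## Chance-level calibration

`calibrate_random_responder()` simulates $n$ independent "participants" of
12 sessions each with a coin-flip responder and returns central 95%
percentile intervals (empirical quantiles with linear interpolation) of both
the pooled single-session thresholds and the per-participant 12-session
means. Both distributions are kept because "10,000 runs" could count either
sessions or participants; at these sizes the single-session interval is
insensitive to the grouping. With 10,000 participants the package obtains
approximately [0.86, 0.99] m for 12-session means and [0.83, 1.23] m for
single sessions, consistent with the published chance bands ([0.88, 0.98]
and [0.8, 1.2] m). A coin-flip responder drifts downward at 0.125 m per
trial on average, so the staircase pins it near the close rail; the chance
band sits just above 0.7 m because reversal distances alternate between the
rail and the first steps above it.

## Synthetic click acoustics

`synthesize_recording()` builds a 60 ms mono waveform at 48 kHz emulating a
measurement at a known reflector distance and state:

* **Direct click.** A raised-cosine gated sinusoid (default 3 ms, 3.5 kHz —
  energy in the band real echolocation clicks occupy), scaled so its 1-ms
  windowed maximum SPL reads exactly `direct_level_db` (default 76 dB) under
  the batch calibration constant.
* **Reflection** (reflecting state only). A copy of the click delayed by
  $2d/c$ (343 m/s) and scaled to
  $R(d) = 76 - 11\,\log_2(d/1.2)$ dB: anchored at the published facts that
  the reflection equals the direct level at about 1.2 m (the loudspeaker
  radiates little energy backwards, so nearby reflections can exceed the
  direct sound at the receiver) and decays about 11 dB per doubling of
  distance. The same law is extended beyond 2 m, where real measurements
  become less systematic; an optional per-recording level jitter
  (`level_jitter_db`, default off) models that scatter.
* **Room tail.** Exponentially decaying Gaussian noise from the end of the
  direct click, decaying 60 dB per `reverb_time` (default 0.07 s, a heavily
  damped listening room). Its onset level defaults to 48 dB, 28 dB below the
  direct click. This is the one free level in the model and it was chosen
  once, on physical grounds: the tail must sit clearly below
  $R(3.9\,\mathrm{m}) \approx 57$ dB throughout the 3–30 ms analysis window,
  otherwise the windowed-maximum analyzer would latch onto the early tail
  rather than the far echo — and the published measurements, in which the
  echo delay remains cleanly linear out to 3.9 m, show the real room behaved
  the same way. A single exponential pinned instead to the published late-tail
  level (~53 dB at 20 ms) would start near 67 dB at 3 ms, which is physically
  implausible for the early gap between the direct click and the first wall
  reflections and would bury the far echoes.
  The tail is generated from a fixed `room_seed`: the same room responds
  identically to the same click, so replicates share the tail realisation,
  and replicate-to-replicate variation comes from the stationary measurement
  noise floor (default 15 dB). This mirrors the published replicate
  stability (reflected-level standard deviations below 0.2 dB over 10
  replicates), which independent random tails per replicate could not
  reproduce.
* **Noise floor.** Stationary Gaussian noise at `noise_floor_db`. A
  reflecting and a non-reflecting recording synthesized with the same seed
  share every component except the reflection, so their difference isolates
  the reflection exactly, mirroring the subtraction used to visualise real
  measurements.

The `geometry_offset` parameter (default 0) subtracts a path-length
correction inside the delay formula. It exists because the published
inter-click interval at 0.7 m (2.9 ms) is inconsistent with both the
published slope (5.8 ms/m would give about 4.1 ms) and pure $2d/c$ geometry;
the microphone sat just behind and above the loudspeaker, and the exact
geometry is unrecorded. The package exposes the knob but does not resolve
the discrepancy.

## The windowed-SPL analyzer

`running_spl()` computes $10\log_{10}$ of the mean square over running 1-ms
rectangular windows, plus the recording's calibration constant. The
measurement convention specifies an overlap of 0.998 ms, i.e. a 0.002 ms
hop — sub-sample at 48 kHz. The implementation hops one sample (about
0.021 ms), the finest physically meaningful step; at the precision of any
reported quantity the difference is irrelevant. Window times are reported as
window start times, with time zero at the click emission onset (for real
recordings with unknown onset, align so that the first window exceeding the
noise floor by 20 dB starts near zero).

`extract_maxima()` takes the maximum windowed SPL over window start times in
[0, 3) ms as the direct level and over [3, 30) ms as the reflected level,
with ties broken by the earliest time; the inter-click interval (ICI) is the
time between the two maxima. Because direct and reflected clicks share a
waveform, the ICI equals the echo delay up to sample rounding, and the
fitted ICI slope over the full rail recovers $2/c \approx 5.83$ ms/m.
Note the window anchoring implies the analyzer is blind to echoes arriving
before 3 ms (distances under about 0.51 m at 343 m/s); at the default rail
this never happens.

`analyze_series()` averages replicate measurements in the dB domain (at the
sub-0.2 dB spreads involved, averaging in power instead changes nothing at
reported precision) and flags a reflecting-state row as low-confidence when
its reflected maximum is within 3 dB of the non-reflecting level at the same
distance, i.e. barely above the room decay it must be detected against.
`fit_level_decay()` regresses the reflected maximum on $\log_2 d$ over
0.7–2.0 m, the range where the decay law is stated to hold.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the study's own sizes: the
chance calibration runs 10,000 participants × 12 sessions (about half a
minute), threshold recovery uses 200 sessions, and the acoustic series spans
0.7–3.9 m in 0.1 m steps with 10 replicates where replicate stability is at
issue. Distances are held internally as integer grid indices so that
repeated ±0.25/0.50 m steps never drift off the 0.005 m grid. Percentiles
are type-7 empirical quantiles. Spearman correlations use average ranks for
ties and return `NA` with a warning for constant thresholds. WAV output is
32-bit float by default (24- and 16-bit PCM available); waveforms that clip
the unit range are rescaled with the scaling folded into the manifest's
calibration constant.

## What the synthetic data do not show

The response models are stationary: no learning within or across sessions,
no fatigue, no vocalisation quality — a human using self-generated sounds
confounds detection ability with signal production, which nothing here
represents. The acoustic generator is parametric: it does not reproduce any
particular recorded click waveform, a measured room impulse response, early
discrete wall reflections, or binaural cues. Passing round-trip tests shows
the analyzer correctly inverts the generator's laws through windowing and
noise; it cannot show that those laws hold in a given real room, and human
threshold values themselves are perceptual data that no simulation here is
meant to reproduce.
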