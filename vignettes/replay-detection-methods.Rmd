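---
title: "Detecting sleep replay of a practiced motor sequence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep replay of a practiced motor sequence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepreplay)
```

## The scientific problem

Offline replay — the spontaneous recapitulation, during rest or sleep, of
neural firing sequences first expressed during behavior — is a central
candidate mechanism for memory consolidation. In a person using an
intracortical brain-computer interface (iBCI), motor cortical activity can
be recorded continuously across task practice and subsequent overnight
sleep, and the same decoder that drove the cursor during practice can be
re-applied offline as a dimensionality-reduction tool: if the motor cortex
replays the practiced sequence, the decoded "hypothetical cursor" should
retrace the task trajectory while the participant sleeps.

`sleepreplay` implements that analysis end to end:

1. **Decoding.** A steady-state Kalman filter is calibrated on cued
   center-out data and applied to the full recording, producing a 2-D
   trajectory from 192-channel binned neural features (spike-band power and
   threshold-crossing counts, 20 ms bins).
2. **Template matching.** Decoded trajectories of successful target-sequence
   trials are averaged into an X/Y template pair; a sliding Pearson
   correlation against the whole recording yields two correlation series,
   and bins where both exceed their thresholds are *simultaneous threshold
   crossing events* (STCEs) — putative replay events when they occur during
   rest or sleep.
3. **Threshold selection.** The integer percentile of the task-block
   correlation distribution maximizing Youden's J (sensitivity +
   specificity − 1) for identifying successful target trials.
4. **Sequence preservation.** A channel-level firing-order matching index
   `I_m = (m − n) / (m + n)` over channel pairs (equivalent to Kendall's
   tau on tie-free orders), against a 100,000-pair random-sequence control.
5. **Counting nulls.** Two bootstrap controls for overnight STCE counts:
   pseudo-templates cut from pre-task rest, and phase-randomized surrogates
   of the decoded trajectory.
6. **Temporal compression.** A sweep of the template dilation factor tau
   (cubic splines, 18 log-spaced values on [0.1, 10] including 1-4).
7. **Sleep staging.** A 95% frequency power limit (FPL) on the EEG
   spectrogram, thresholded between 2 and 6 Hz to label slow-wave sleep
   (SWS), with STCE-in-SWS enrichment statistics.
8. **Cortical ripples.** Per-channel ripple detection (60-100 Hz RMS above
   the 90th percentile, peak-count confirmation), simultaneity counts, and
   STCE-ripple temporal alignment.

No participant recordings ship with the package. Instead, the
`synthdata` generator produces complete sessions with *known ground truth*
(injected replay at chosen speeds and amplitudes), so every stage of the
pipeline is verifiable.

## The synthetic session generator

`synth_config()` fixes the session structure: a 5 min radial-eight
calibration block (with the stepwise 0.9 → 0 error-attenuation schedule;
this schedule shapes only the simulated closed-loop cursor and is never
consumed by the offline analysis), a 30 min pre-task rest, ten 16-trial
blocks of the sequence-matching memory game (12 target-sequence and 4
distractor trials per block; each trial is a 3 s cue demonstration
followed by four 1 s movement legs), a 30 min post-task rest, and an
overnight segment. Within sleep, slow-wave and lighter epochs alternate
(default 20 min SWS / 10 min non-SWS).

Features follow the simplest generative model consistent with a linear
decoder: each channel has a preferred direction `d_c`; spike-band power is
`baseline + depth * (d_c . v) + Gaussian noise` and threshold crossings are
Poisson with a rate linear in the same projection (rectified at zero).
Medial-array channels carry full tuning depth; lateral channels are
attenuated 10-fold, mirroring the sparser task involvement of the lateral
implant. Background rates, depths, and noise SDs are free parameters of the
generator (no published values exist for them); the defaults place the
per-feature movement signal at about one background SD.

Replay is **injected additively** onto the sleep features: the noise-free
feature footprint of one clean target-sequence execution is resampled in
time by `1 / tau`, scaled by an amplitude in background-SD units, and added
at scheduled times. Addition (rather than replacement) preserves background
statistics outside the events, and the exact injected times form the ground
truth. The default schedule holds 20 events alternating tau = 1 and
tau = 2 at amplitude 3, placed inside SWS epochs.

The EEG channel is band-filtered Gaussian noise whose composition differs
by stage (slow-wave epochs dominated by 0.5-2 Hz power so the FPL falls in
the 2-3 Hz range; wake and light sleep dominated by 8-30 Hz power), with a
three-tap artifact at the start for clock synchronization. Synthetic LFP
(for the ripple module) is generated natively at 1 kHz: a slow (< 30 Hz)
Gaussian background plus 80 Hz bursts of ~120 ms coupled to injected replay
events on a random subset of channels.

**What the generator does not emulate.** Real recordings contain
nonstationary firing rates, correlated noise across channels, movement and
EMG artifacts, electrode drift, genuine sleep microstructure (spindles,
K-complexes, REM), and replay whose amplitude and timing are themselves
unknown. Passing the recovery tests therefore demonstrates that the
*pipeline* is correct and sensitive under its own assumptions — not that
those assumptions hold for any particular recording.

## Decoder design

The published analysis defers the state model to its references, so the
package fixes the open pieces explicitly:

* State = 2-D velocity; `A = 0.96 I`. `W = w I` with
  `w = (1 − a²) · Var(intended velocity)`, so the stationary state prior
  matches the cue kinematics.
* `Q` is diagonal (independent residual noise per feature). Residual
  variances are floored at `1e-6` times the mean feature variance so that
  exactly-linear (noise-free synthetic) features keep the innovation
  covariance invertible.
* Feature selection ranks all features by regression R² against intended
  direction and keeps the top 40, ties broken by index. If fewer than 40
  carry real modulation the set is still filled by rank and a warning is
  raised.
* The steady-state gain comes from iterating the discrete Riccati
  recursion to `1e-12` on `K` (`steady_state_gain()`); calibration uses a
  `1e-9` tolerance because the floored-noise case can limit-cycle in
  roundoff below that.
* Offline positions are produced without the online rescaling, smoothing
  or recentering. Over hours, a pure integrator drifts unboundedly, so the
  position stage uses **leaky integration**
  (`p_t = λ p_{t-1} + Δt · v_t`, λ = 0.995 per 20 ms bin) as the minimal
  mechanism yielding bounded traces; λ is exposed and reported. This leak
  is a surrogate for whatever keeps real offline traces bounded and is
  flagged as such.

## Template matching and thresholds

Trial segments are **mean-centered per trial** before resampling to the
median trial length and averaging: sliding Pearson correlation is
offset-invariant, and the raw decoded position carries an arbitrary slow
offset under leaky integration, so centering changes nothing statistically
while keeping the template well-defined.

"Cross-correlation" is implemented as the sliding-window Pearson
correlation (bounded in [−1, 1]); zero-variance windows are assigned 0
rather than NaN, which prevents spurious matches in flat segments. The
correlation at time `t` refers to the window `[t, t + L)`; an STCE is
stamped at the first bin of a contiguous supra-threshold run and marks the
*start* of the following L-bin trajectory.

Threshold percentiles are computed over the concatenated task-block
correlation series. When classifying STCEs against trials for the Youden-J
sweep, an event identifies the trial whose span contains the **midpoint of
its L-bin footprint**. Containment of the start bin itself proved too
brittle: windows beginning one or two bins before trial onset still
correlate above 0.99, and under start-bin containment essentially every hit
was misclassified as a stray false alarm. The footprint midpoint is the
natural anchor of the trajectory the event denotes; events whose midpoint
falls in no trial count as false alarms. Ties in J resolve to the higher
percentile.

Dilated templates are cubic-spline interpolants evaluated on
`round(L / tau)` bins spanning `duration / tau`; the default sweep grid is
18 log-spaced values on [0.1, 10], adjusted to contain the speeds 1-4
exactly.

## Firing-order matching

For each event, the peak-firing bin of every medial-array channel within
4 s of onset is found on a 100 ms rate grid (the rate bin is not specified
by the source analysis; 100 ms balances rate estimation against order
resolution over a 4 s window, and is configurable). Ties in peak time are
excluded from both the concordant and discordant counts, which keeps
`I_m` identical to Kendall's tau on tie-free orders; silent channels are
flagged. The random control draws pairs of independent 96-element
permutations; its per-pair SD matches the Kendall null SD
`sqrt(2(2M + 5) / (9 M (M − 1)))` and its mean is statistically
indistinguishable from zero.

## Bootstrap nulls and their p values

**Pseudo-template control.** One hundred windows of template duration are
cut at uniformly random positions from the pre-task rest trajectory. For
each, the full matching procedure is repeated — including recomputation of
the percentile thresholds on the task-block span, the faithful reading of
"repeating the template-matching procedure" — and overnight STCEs are
counted. The observed count is compared with the null counts by an exact
two-sided Mann-Whitney test; for one observed value against `n` counts the
observed rank is uniform over `n + 1` gaps, giving the floor
`2 / (n + 1)` (0.019802 at `n = 100`). Ties are counted conservatively.

**Phase-randomized control.** The decoded trajectory is split into 5 min
segments (a final partial segment is randomized on its own); per segment
and per dimension, every positive-frequency Fourier coefficient is rotated
by an independent uniform phase (the Nyquist term by a random sign) and
conjugate symmetry restored, preserving each segment's amplitude spectrum
and mean exactly while destroying temporal sequence structure. STCEs are
counted per surrogate with the true template and session thresholds.

Two p values are reported. `p_t` is the one-sample t test of the null
counts against the observed value — the conventional report for this
procedure. It is, however, strongly anticonservative when the observed
value is exchangeable with the surrogates: the t statistic then has
variance of order `n + 1`, not 1, because the dominant variability is the
observed draw itself, which the one-sample formulation treats as a fixed
constant. The package therefore also reports `p_empirical`, the two-sided
empirical rank p `2 · min(1 + #{counts ≥ obs}, 1 + #{counts ≤ obs}) /
(n + 1)` (capped at 1), which is exactly calibrated under exchangeability;
the type-I-error property below uses it, and reports should prefer it.

## Sleep staging

The spectrogram uses 30 s Hann windows with 50% overlap (standard
sleep-epoch scale; the source analysis states no parameters, so these are
package defaults recorded in the output), restricted to the 0.5-50 Hz
analysis band and normalized to unit power per step. The FPL is the first
frequency at which the cumulative normalized power exceeds 0.95; all-zero
steps are flagged rather than erroring. A step is SWS iff FPL < threshold,
for thresholds on the 2-6 Hz grid; label sets are nested across
thresholds by construction.

Enrichment assigns each STCE to the spectrogram step containing its
timestamp and, per threshold, compares the fraction of STCEs in SWS with
the fraction of the night spent in SWS, with a binomial 95% CI for the
proportional null. Across the grid, the observed-proportion and
expected-proportion curves are compared by a two-sample Kolmogorov-Smirnov
test. Which values constitute the two KS samples is ambiguous in the
source description; the curve-comparison reading is implemented, and the
per-threshold binomial test is reported alongside as the interpretable
companion.

## Ripple detection

Per channel: downsample to 1 kHz, band-pass 60-100 Hz (zero-phase
fourth-order Butterworth), RMS over a 20 ms moving average, candidate
segments above the per-channel 90th percentile (computed over the full
series), gaps **shorter than 40 ms bridged** between neighboring segments,
and candidates of at least 40 ms kept. Bridging gaps is the only reading
of the merge rule consistent with a subsequent ≥ 40 ms duration filter.

A candidate is confirmed if the 120 Hz-lowpassed LFP contains at least
three distinct peaks within a single 40 ms window whose first and last
peaks are not both within 7 ms of the window's edges. Sliding the window
freely, such a window exists iff some consecutive peak triple spans at
most 40 − 7 = 33 ms: with triple span `s`, the two edge margins sum to
`40 − s`, so a margin ≥ 7 ms is available exactly when `s ≤ 33 ms`. The
package therefore tests consecutive triples against a 33 ms span. The rule
passes 80 Hz bursts (period 12.5 ms, triple span 25 ms) and rejects 30 Hz
oscillations (triple span 67 ms) and, notably, even strong 60 Hz bursts
(33.3 ms — marginally outside), concentrating detections near the 80 Hz
center of cortical ripples. "Distinct" peaks are local maxima with
prominence above 10% of the candidate's peak-to-trough range (no
prominence rule is stated in the source; this one suppresses roundoff
wiggles without touching genuine oscillation peaks).

Ripple magnitude is the number of channels simultaneously inside a
confirmed ripple, on a 1 ms grid, thresholded at 1/2/4/8/16 channels. The
STCE-ripple alignment shifts all STCE timestamps over −7..+7 s in 20 ms
steps and recomputes the in-ripple proportion per threshold, against the
night-wide baseline occupancy; on coupled synthetic data the curve peaks
at approximately half the template duration, as the trajectory's energy
(and hence the ripple burst) follows the event stamp. The cross-correlogram
analysis correlates the template-matching signal with the channel count in
±5 s windows around each event and reports the per-event peak lag and its
median; zero-variance count windows yield correlation 0 and no peak.

## Numerical choices

* Sliding correlations use an FFT cross-correlation for the window
  cross-products and cumulative sums for window means/variances; windows
  with variance below `1e-12` of the series scale give correlation 0.
  Agreement with the direct per-window Pearson computation is tested to
  `1e-10`.
* The velocity recursion is diagonalized through the eigenbasis of
  `(I − K H) A` into two scalar AR(1) filters (complex-safe), with a
  direct loop fallback for defective matrices.
* The clock offset between the EEG and intracortical streams is estimated
  from the first supra-threshold sample of each rectified envelope
  (threshold: median + 8 robust SDs, configurable), to the nearest sample;
  sub-sample alignment is pointless against the stated human-reaction-time
  margin of the tap synchronization.
* Event merging, percentile sweeps and rate computations are exact integer
  operations; per-stage child seeds are derived deterministically from the
  master seed and stage name.

## Problem sizes used by the tests

The shipped test-suite exercises the full pipeline at desk scale, chosen
as the package's own verification conditions: a complete session with all
192 channels and the full 10 x 16 trial structure, 10 min rests and a 1 h
sleep segment holding the default 20 injections (tau 1 and 2, amplitude
3 SD, fixed seed); compact 48-channel sessions for stage-level tests; a
type-I calibration of the phase-randomized control on 200 background-only
decoded trajectory pairs (a task-like reference for thresholds plus a
10 min night segment each, 40 surrogates, α = 0.05), on which the
empirical-p rejection rate is statistically compatible with 5%; and a
100,000-pair random matching control. On these conditions the pipeline
detects over 80% of injected events, the tau sweep peaks at the injected
speeds, and injected-event firing order matches task events far above the
random control.

## Known limitations

* The leak constant λ is a modeling surrogate; decoded position scale
  (and so template shape, though not correlation values) depends on it.
* The percentile reference span is the task blocks; whether rest epochs
  belonged in the reference distribution is unknowable from the source
  description (both are supported via the function arguments).
* The KS-over-thresholds enrichment construction inherits the ambiguity
  noted above.
* Synthetic LFP background is spectrally simple; ripple false-alarm rates
  on real 1/f neural background will differ and the RMS percentile may
  need the configurable sleep-only span.
* All stochastic guarantees (detection rates, type-I calibration) are
  statements about the generator's assumptions, not about any real
  recording.
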