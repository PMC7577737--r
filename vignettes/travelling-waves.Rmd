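---
title: "Quantifying cortical travelling waves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical travelling waves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticalwaves)
```

This vignette documents the model behind the package, the choices made
where the method leaves room, and what the synthetic-data tests do and do
not establish about real recordings.

## The measurement model

A travelling wave on an ordered electrode array appears as an oblique
stripe in a time×electrode map: the oscillation's phase advances
systematically along the spatial axis. In the 2D discrete Fourier transform
of such a map, a plane wave
$\cos(2\pi f t - 2\pi \nu x)$ with $\nu > 0$ (posterior→anterior
propagation in our stacking order, posterior electrode first) concentrates
its power in the quadrant with *negative* spatial and *positive* temporal
frequency, plus the point-symmetric mirror; propagation in the opposite
direction occupies the other quadrant pair. The per-window statistics are
the maximum power over each quadrant's nonzero-frequency bins within the
1–45 Hz analysis band (`quantify_window()`), and the net wave amount

$$W_{dB} = 10\,\log_{10}(W / W_{ss}),$$

where $W_{ss}$ is the mean of the same quadrant maximum over 100 uniform
shuffles of the electrode order. Shuffling destroys spatial organisation —
including direction — while preserving each channel's temporal spectrum
exactly, so $W_{ss}$ measures how large a quadrant maximum the data's
temporal structure alone can produce. 0 dB therefore means "no net wave
beyond chance", and window values can be tested against zero directly.

Key conventions:

- **Quadrant orientation.** Which signed quadrant is "forward" depends
  jointly on stacking order, transform sign and axis layout. The convention
  is pinned by a unit test that generates a posterior→anterior plane wave
  with `gen_plane_wave()` and asserts it lands in the FW quadrant; no
  runtime branch depends on it.
- **Zero-line exclusion.** Bins with zero spatial frequency (spatially
  uniform activity is directionless) or zero temporal frequency (DC is not
  an oscillation) never enter a quadrant maximum; sign-ambiguous Nyquist
  bins are excluded likewise. Because the common average reference only
  moves power into the zero-spatial-frequency line, the statistic is
  invariant to re-referencing by construction.
- **No tapering or detrending.** Windows enter the transform raw; the
  zero-line exclusion already removes the components a detrend would, and
  any taper would smear power across spatial bins.
- **Spatial axis as-is.** A five-electrode array gives spatial frequencies
  ±1/5 and ±2/5 cycles/electrode; no zero-padding or interpolation is
  applied to the spatial axis.
- **Exact symmetries by construction.** The forward side of every quantity
  is computed by running the positive-spatial-frequency code path on the
  electrode-flipped map (equal in exact arithmetic to reading the negative
  quadrant), and surrogate spectra are computed from row-reindexed data
  with a fixed summation order. Two useful properties then hold *bitwise*,
  not merely to tolerance: reversing the electrode order swaps all
  forward/backward outputs, and a map whose rows are identical yields
  exactly 0 dB for any seed. Both are asserted in the test suite.
- **Surrogate draws.** Shuffles are drawn uniformly *with replacement* from
  all $5! = 120$ orderings (identity permitted); an exhaustive mode
  averages all 120 for deterministic tests. Draws are redrawn per window
  from a per-window seed derived from the master seed, so any single
  window can be reproduced in isolation. The same drawn sequence serves
  both directions of a window.

A small negative bias of order $-0.1$ dB is intrinsic to the statistic
under a pure-noise null: the observed maximum is one draw from the same
ensemble whose *mean* forms the denominator, and the logarithm is concave.
The white-noise calibration test bounds the observed mean against three
standard errors of zero at 100 windows, which accommodates this bias
without recentring anything.

## Preprocessing

The analysis chain mirrors standard resting-EEG practice: a zero-phase
band-pass (4th-order Butterworth high-pass at 1 Hz and low-pass at 45 Hz,
each applied forward–backward via `signal::filtfilt`), common average
reference, array selection, then 1-s windows sliding by 0.5 s. Zero-phase
filtering matters because any phase-distorting filter would bias the
cross-channel phase gradients the statistic measures. Interactive artifact
screening and independent-component cleanup are outside the package's
scope; `clean_windows()` provides an automated amplitude-threshold window
rejection in their place. Window or step lengths that do not give whole
sample counts are rejected rather than rounded.

## Frequency decomposition

`per_frequency_waves()` replaces the single quadrant maximum with one
maximum per temporal frequency (surrogates computed from the same
shuffles), and `peak_band_histogram()` counts window peaks in half-open
bands δ = [1, 4), θ = [4, 8), α = [8, 13), β = [13, 30] Hz. The band edges
tile the axis so every 1-Hz bin belongs to exactly one band; δ starts at
1 Hz because the analysis band-pass (and the 1-s window resolution) makes
lower frequencies unobservable.

## The synthetic study generator

`gen_study()` emulates the structure of a 13-subject, two-session
(placebo first, drug second) eyes-closed pharmaco-EEG experiment: 32
channels at 1000 Hz, recordings from 5 min before to 20 min after
injection, minute-wise subjective intensity ratings on a 0–10 scale, 20
end-of-session visual-analogue-scale items, and doses 7/14/18/20 mg
assigned to 3/4/1/5 successive subjects.

Each session's midline channels carry, per minute, a three-component
carrier mixture at one band-dependent frequency (δ 2 Hz, θ 6 Hz, α 10 Hz,
β 20 Hz — even integers so that every 1-s window holds a whole number of
cycles and the 0.5-s hop preserves phase): a forward plane wave, a backward
plane wave, and a fixed scattered-phase "diluent" that sets the surrogate
floor. A deterministic calibration routine (`calibrate_amplitudes()`,
damped Newton on the log-amplitudes against the exhaustive-permutation
response, averaged over the amplitude-modulation cycle) solves the mixture
so that the pipeline recovers prescribed forward/backward decibel levels;
the noise-free round-trip is tested to ±0.05 dB. Default decibel targets
are the group means of the post-injection block (forward: −0.20 placebo,
+0.19 drug; backward: +0.51 placebo, +0.18 drug; between-subject SDs 0.29
and 0.25), with pre-injection baselines reusing the placebo-post values
(placebo leaves the pre/post pattern unchanged). The drug effect follows a
piecewise profile: linear ramp to full effect over minutes 0–2, plateau to
minute 5, then exponential decay with a 5-minute half-life (half effect by
minute 10).

Choices the study design leaves open, fixed here once:

- **Antiphase modulation.** Forward and backward amplitudes are modulated
  in antiphase by a slow sinusoid (depth 0.12, period 40 s), which produces
  the negative moment-by-moment forward–backward coupling; the calibration
  objective averages over the modulation cycle so targets stay unbiased.
- **Spectral shift.** Each minute's carrier band is drawn from a mixture
  that moves from α-dominant (76 % α) at baseline toward δ/θ-dominant
  (38 % δ, 27 % θ) at full drug effect — re-weighted band components
  rather than any attempt to match unreported histogram heights.
- **Ratings.** The intensity rating for minute *m* is a clipped affine map
  of that minute's simulated forward effect (1 dB of effect spans the
  0–10 scale) plus Gaussian noise (SD 1); VAS items load positively
  (uniform loadings in [0.5, 1.5]) on the subject's mean post-injection
  forward effect with item noise SD 0.3. Any bounded monotone map would
  serve; correlation signs, not magnitudes, are the tested claims.
- **Noise.** Midline channels receive 1/f noise at RMS 0.2 relative to the
  unit diluent; other channels carry 1/f background at RMS 1. Calibration
  guarantees refer to the noise-free signal path.
- **Saturation at the physical envelope.** The three-component mixture
  cannot realize every decibel pair — in particular, both directions far
  below their null simultaneously is structurally impossible (shuffling
  redistributes, it does not create, spatial power). Rare tail draws
  outside the reachable set are saturated along the segment toward a
  reachable anchor; group-level conclusions are unaffected because the
  envelope comfortably contains the default targets.

What the generator deliberately does not emulate: volume conduction and
sensor geometry, eye/muscle artifacts, non-stationary alpha bursting, and
any biophysical source model. Passing the recovery tests therefore shows
that the *pipeline* is correct and well-calibrated — that the statistic
detects what it claims to detect and its null behaves as advertised — not
that real EEG satisfies the generator's assumptions.

## Study-level statistics

Minute-wise one-sample t-tests against zero are corrected by
Benjamini–Hochberg FDR *within* each direction-by-condition series (the
analysis that matches per-panel significance marking); window-to-minute
assignment puts a window in the bin containing its start time, and the
pre/post comparison blocks are the 5 minutes on either side of injection.
The forward–backward coupling is the Pearson correlation of per-window
forward and backward decibels over post-injection minutes 2–5, when both
directions are reliably present. Group Bayesian ANOVA machinery is out of
scope; `jzs_bf10()` supplies a default-prior (Cauchy scale 0.707)
one-sample Bayes factor by numerical integration of the noncentral-t
likelihood over the prior, for testing subject-level aggregates against
zero. `two_sample_power()` evaluates the two-sided two-sample noncentral-t
power exactly (both rejection tails, so equal means give exactly α).
Per-minute across-subject rating correlations are reported uncorrected and
BH-adjusted side by side, since with small samples none need survive
correction.

## Problem sizes used by the tests

The pipeline-scale tests and the acceptance script run the simulated study
at a reduced size chosen to keep the full suite fast while preserving every
structural feature: 250 Hz sampling, the five midline channels only, 2 min
pre- and 6 min post-injection, with 2-minute pre/post comparison blocks
standing in for the 5-minute blocks (decibel targets are then defined on
the 2-minute block). Unit tests use single windows (1 s) or short
recordings; oracle-equivalence tests use 5×16 maps where the literal
double-sum DFT is affordable. Full-scale sessions (32 channels, 1000 Hz,
25 min) are supported by the same code path; `gen_study(out_dir = ...)`
streams them to single-file containers on disk, and `run_study()` loads
such sessions one at a time, since holding all 26 in memory is not
reasonable at full scale.

## Known limitations

- The method measures *net* directional wave energy along a fixed
  one-dimensional array; it does not localize sources, estimate speed, or
  handle two-dimensional propagation patterns.
- Quadrant maxima are extreme-value statistics: they inherit the small
  negative log-ratio bias discussed above, and their window-to-window
  distribution is skewed. Aggregation across windows uses arithmetic means
  of decibel values (not decibels of mean ratios), keeping windows
  exchangeable.
- The EDF and BrainVision readers cover the common continuous,
  equal-rate, multiplexed cases used for resting EEG; annotation channels,
  variable-rate signals and vectorized orientations are rejected
  explicitly rather than guessed at.
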