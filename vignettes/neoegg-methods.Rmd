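---
title: "Methods: gastric rhythm analysis of neonatal EGG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gastric rhythm analysis of neonatal EGG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoegg)
```

## The measurement problem

Cutaneous electrogastrography (EGG) records gastric myoelectrical activity
from electrodes on the abdominal wall. The gastric slow wave occupies
0.5–9 cycles per minute (cpm) and is conventionally split into three rhythm
bands, half-open on the right:

* bradygastria, 0.5 ≤ f < 2 cpm (0.008 ≤ f < 0.033 Hz),
* normogastria, 2 ≤ f < 4 cpm (0.033 ≤ f < 0.067 Hz) — the healthy rhythm near 3 cpm,
* tachygastria, 4 ≤ f < 9 cpm (0.067 ≤ f < 0.15 Hz).

In preterm neonates the question is whether EGG-derived features track
gastrointestinal maturation across gestational age (GA) and respond to
enteral feeds. `neoegg` implements two families of features around each feed:

1. **Band-mean spectral power (mPSD)** — the arithmetic mean of the Welch
   power spectral density over each rhythm band, in µV²/Hz, per sub-feeding
   window, then averaged between the two feeding epochs of a session.
2. **Percent time in rhythm (%T)** — the fraction of whole minutes whose
   dominant rhythm, judged from a continuous wavelet transform (CWT)
   spectrogram, falls in each band.

Cohort-level analysis consists of one-way ANOVA with Tukey contrasts across
the pre-/during-/post-feed phases within each GA group, and ordinary
least-squares regression of each feature on gestational age.

## Analysis chain and its parameters

### Signal conditioning

Raw voltage (nominally 2000 Hz) is processed by:

1. keep-every-k-th decimation (default factor 4, 2000 → 500 Hz). No
   anti-alias filter is applied — a deliberate fidelity choice mirroring the
   plain `downsample` convention; the analysis band sits below 0.15 Hz and a
   1 Hz low-pass follows immediately, so aliased slow-wave content is
   negligible.
2. order-3 polynomial detrending fitted over the *entire* recording. The
   time axis is rescaled to [−1, 1] before fitting (orthogonal polynomial
   basis), which keeps the normal equations well conditioned on multi-hour
   records; residuals are identical to a raw-time fit. Leakage of a 3-cpm
   tone into a cubic fit scales as 1/(f·T) and is below 1% for records of an
   hour or more — one reason the package detrends whole recordings, not
   windows.
3. a zero-phase low-pass at 1 Hz: order-3 Butterworth applied
   forward-backward (effective order 6, zero phase). The filter family and
   order are the package's choice; Butterworth was picked for its monotone
   passband.

Zero-phase filtering is implemented with odd-reflection padding plus
steady-state initial conditions (the history of a constant input equal to
the first padded sample). This keeps DC exactly invariant and confines edge
transients to the discarded padding; a naive zero-initial-state
forward-backward pass leaves a visible transient at the start of multi-hour
records when the filter's time constant is long.

### Sub-feeding windows

Each session contains two feeds. During-feed windows equal the recorded
administration intervals. Pre-feed 1 is up to 30 min before feed 1; post-feed
2 is up to 30 min after feed 2; the inter-feed interval is halved at its
midpoint, post-feed 1 hugging the end of feed 1 and pre-feed 2 hugging the
start of feed 2. When the halving rule and the 30-min nominal duration
disagree (gap ≠ 60 min) the package defaults to `halves_mode = "capped"`:
each half contributes at most 30 min adjacent to its feed boundary. This
reading preserves both the halving rule and the nominal duration, and keeps
shorter-than-nominal windows (flagged `truncated`) rather than discarding
them. `halves_mode = "full"` uses the complete halves instead; both are
exposed because the boundary convention is genuinely ambiguous. Windows are
half-open minute intervals converted to sample indices by flooring.

`segment_feeds(allow_single_feed = TRUE)` additionally accepts a one-feed
schedule and returns the three Feeding-1 windows; phase summaries then pass
single-window values through (flagged `n_windows = 1`). This expresses the
single-epoch design used throughout the validation studies below.

### Welch band means

`welch_psd()` uses 240-s windows with 120-s overlap (50%) and a Hamming
taper, one-sided density scaling, giving a frequency resolution of
1/240 ≈ 0.004 Hz. Sanity identities: a unit tone's density integrates to
0.5, and white noise of variance σ² sits at σ²/(fs/2) µV²/Hz. Windows
shorter than 240 s are analysed with a single full-length window and a
warning (degraded resolution); below 125 s the bradygastria band no longer
contains a full bin and the segment is rejected. Per-window means are not
re-detrended by default (`detrend_windows = FALSE`) because global
detrending precedes segmentation.

mPSD is the unweighted mean of density over the bins whose *centre* falls in
the half-open band — an average density, not an integral, which is what
keeps its unit µV²/Hz. Computation stays in µV²/Hz; divide by 10⁶ for
mV²/Hz if preferred for plotting.

### CWT percent time

The conditioned signal is band-passed 0.5–15 cpm with a zero-phase order-3
Butterworth filter. Because those edges are tiny fractions of a clinical
sampling rate, the signal is first decimated to the 4 Hz working rate (its
content is already below 1 Hz) and the filter is designed there; at 500 Hz
the same design is numerically singular. The CWT then runs at 4 Hz on a
logarithmic grid of 12 voices per octave spanning 0.4–16 cpm.

Two analytic wavelet families are provided: Morlet (ω₀ = 6, the default)
and generalized Morse (γ = 3, β = 20, time-bandwidth 60). Amplitude (L1)
normalisation is used so a sinusoid of amplitude A attains |W| ≈ A at its
own frequency *regardless of scale* — essential here, because dominant-band
classification compares power across bands. The cone of influence is the
e-folding time of the wavelet envelope (√2·ω₀/(2πf) for Morlet; measured
once from the synthesized mother wavelet for Morse), and masked cells are
excluded from numerator *and* denominator of every mean.

One spectrogram is computed per feeding epoch — the contiguous
pre/during/post span, as in a feeding-epoch time–frequency plot — so the
cone of influence falls at the epoch edges, not at every internal window
boundary. Minutes are then attributed to sub-feeding windows.

Per whole minute, power is averaged over each band's rows and the minute's
columns; each band mean is divided by the mean over the full 0.5–9 cpm
range for that minute, and the largest ratio wins. The ratio denominator is
shared across bands, so using a mean rather than a sum cannot change the
ordering. Ties resolve to the lower-frequency band (deterministic;
probability zero on real signals). Minutes with no valid cells are
`unclassified`; trailing partial minutes are dropped. `percent_time()`
defaults to the whole-window minute count as denominator
(`denominator_mode = "total"`, the literal counting rule); with
`"classified"` the three percentages sum to exactly 100. Both are exposed
because the handling of COI-dominated minutes is not uniquely determined by
the counting rule.

### Statistics

`anova_phases()` wraps `stats::aov()` + `stats::TukeyHSD()`;
`regress_on_ga()` wraps `stats::lm()`. Repeated sessions of one subject are
averaged per subject before regression by default (`per_session = TRUE`
uses session-level points) — longitudinal sessions treated cross-sectionally
would otherwise pseudo-replicate. No multiple-testing correction is applied
beyond Tukey's adjustment, matching the analysis design; α = 0.05.

## The synthetic cohort

No public neonatal EGG corpus exists, so validation rests on a simulator
with known ground truth. Its defaults mirror the study conditions: 2000 Hz
acquisition, 6-h recordings, two 30-min feeds ~3 h apart, 51 subjects in GA
groups early/mid/term (< 29, 29–33, ≥ 37 weeks) of sizes 25/22/4.

The generative model is deliberately phenomenological, not a physiological
interstitial-cell model: the analysis stages only need realistic band
structure. Per minute, a Markov chain selects the active band; at each
minute boundary the state is redrawn from its stationary distribution with
probability 1/`mean_dwell_min` (default 2 min), so the long-run minute
fractions *equal* the target occupancy exactly. Within a dwell the slow
wave is a sinusoid with frequency drawn uniformly inside the band (phase
continuous across switches), amplitude 120/100/70 µV for
brady/normo/tachy. Gaussian noise (SD 20 µV) and motion-artifact bursts
(six per hour, 300 µV, 2–5 s low-frequency transients under a smooth
envelope) are added; artifacts are simulated because the analysis chain
claims robustness to them through Welch averaging, and they must exist to
exercise that claim.

Two maturational trends are injected:

* **occupancy**: %normogastria = 25% + 3.5 points per week above 23 weeks
  (clamped to [5, 92]%), remainder split 62/38 between brady- and
  tachygastria — so %normo rises and both others fall with GA;
* **feeding response**: during-feed amplitude gain 1 + 0.04·(GA − 23),
  so mPSD during feeding rises with GA.

The slope of the occupancy trend was sized by a power analysis of the
package's own validation design (51 subjects, single 30-min windows per
phase, trend test at α = 0.01 repeated over 50 cohort seeds): a pilot
estimate put the per-phase sampling noise at ~17 percentage points, so a
3.5 point/week slope (true r ≈ 0.6) gives roughly 98% joint power across
the three phases. The observed per-phase r² on synthetic cohorts
(~0.15–0.40) brackets the effect sizes typical of real neonatal cohorts.

What the simulator does *not* emulate: multi-channel electrode geometry,
harmonics and non-linear wave interactions, respiration and cardiac
contamination, electrode drift beyond a polynomial trend, and feed-type
covariates. Passing the validation suite therefore demonstrates that the
chain recovers band structure and injected trends from realistic
single-channel mixtures — not that it is robust to every artifact of real
clinical recordings.

## Problem sizes used in validation

Simulation studies in the test suite run 96-min single-feed recordings
(one full feeding epoch: 30 min pre, 30 during, up to 36 post) at a raw
rate of 16 Hz, decimated by the standard ×4 to a 4 Hz working rate. Since
every signal component lies below 0.25 Hz, the analysis path is identical
to the full-rate setting; the reduced sizes simply make 50-cohort
(2550-subject) recovery studies practical on a single core. The Welch
stage in smoke tests uses 120-s windows for the same reason. Full
2000 Hz/6-h generation remains the default of `sim_params()`.

## Numerical notes and edge cases

* FFT lengths for the CWT are 2–3-smooth sizes at least one low-frequency
  e-folding time beyond the signal, so circular wrap-around stays inside
  the masked cone.
* The CWT touches, per scale, only the FFT bins where the wavelet response
  exceeds ~1e-17 of its peak; the hot loop is compiled (RcppArmadillo).
* `egg_downsample()` requires exact rate divisibility; `cwt_power()` and
  `bandpass_gastric()` require the recording rate to be an integer multiple
  of the working rate.
* Degenerate inputs error early with named causes: overlapping feeds,
  gap ≤ 0, windows outside the recording, zero-length windows, segments
  under 125 s, recordings under 2 min for the CWT, constant regression
  predictors, ANOVA cells with fewer than two observations.
* All randomness is seed-controlled: a subject's recording is a pure
  function of (spec, seed); cohorts derive per-subject seeds from a master
  seed; pipeline outputs are byte-identical across reruns.

## Known limitations

* The 30-min cap versus true-half ambiguity in window derivation is
  resolved by configuration, not by evidence; results near the boundary
  depend on the choice.
* Band edges are hard half-open cuts: tones within ~0.1 cpm of an edge can
  classify to either side at wavelet resolution (documented edge blur).
* mPSD is amplitude-dependent by design; it is comparable across subjects
  only to the extent electrode impedance and placement are.
* The ANOVA/regression layer models neither longitudinal correlation nor
  covariates; a mixed-effects extension is out of scope.
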