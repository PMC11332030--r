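---
title: "Measuring auditory–motor synchronization with baseline-corrected phase-locking values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory–motor synchronization with baseline-corrected phase-locking values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvsync)
```

## The measurement problem

When a participant whispers or taps along with a stream of syllables or
piano tones, how well their motor output locks to the stimulus can be read
from the two amplitude envelopes: the stimulus envelope (from a loopback
recording) and the motor envelope (from a microphone over the tapping
surface or in front of the mouth). Both are reduced to 100 Hz amplitude
envelopes, band-pass filtered around the stimulus rate, and converted to
instantaneous phase with the Hilbert transform. The phase-locking value

$$\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T}
  e^{i(\theta_1(t) - \theta_2(t))}\right|$$

is 1 when the phase difference is constant — at *any* offset, so a fixed
motor lag does not count against the participant — and near 0 when the
phases are unrelated. We compute it in sliding windows (5 s with 2 s
overlap for ~4.5 Hz sequences, 11 s with 4.5 s overlap for ~2 Hz ones,
windows aligned to trial start, trailing partial windows dropped) and
average the window values into one raw PLV per trial.

### Why a permutation baseline

Raw PLVs are inflated by factors with no behavioural meaning: both signals
are rhythmic at roughly the same rate, so even an inattentive producer
shows some locking, and the amount depends on effector acoustics and trial
length. We therefore estimate chance-level locking per trial: the acoustic
envelope is cut into contiguous window-length segments, the segment order
is shuffled (identity permutations are rejected), filtering and phase
extraction are re-run on the shuffled envelope, and the windowed PLV
against the *unshuffled* motor phase is recorded. The normalized score is
raw PLV minus the mean over shuffles. Trailing samples beyond a whole
number of segments are dropped from both channels so raw and baseline are
computed on identical supports.

The number of shuffles is a precision knob, not a model choice: every
shuffle estimates the same chance distribution, and averaging only reduces
variance. `permutation_baseline()` defaults to 100 shuffles; the
whole-study driver `run_config()` uses 20 per trial, which keeps the
baseline's standard error well below the between-participant spread at a
fraction of the cost.

A property of this normalization worth knowing: when the envelope is
*strictly* periodic and the segment length is close to a whole number of
cycles — the slow preset's 11 s segments hold almost exactly 22 cycles at
2 Hz — shuffled segments remain partly phase-coherent and the chance floor
is high (about 0.53 for a noiseless synthetic burst train, so even a
perfect tracker scores about 0.47 after normalization in that condition).
Real envelopes, and synthetic ones with timing noise, are less strictly
periodic, and the fast preset's 22.5 cycles per segment decohere better.
Normalized PLVs are therefore comparable within a condition, which is how
they are used; they are not an absolute efficiency scale across rates.

## Envelope extraction and band choices

`extract_envelope()` implements a cochlear-style reduction: 32 log-spaced
band-pass channels spanning 180–7246 Hz, half-wave rectification, optional
power-law compression (exponent 0.3 by default; disable it to make the
extraction exactly linear in input amplitude), summation across channels,
10 Hz low-pass smoothing and resampling to 100 Hz. Channel count,
compression and smoothing are configurable; the defaults capture the
slow amplitude modulations the PLV needs without claiming equivalence to
any particular auditory-model toolbox.

The analysis bands are stored as presets: fast = 3.5–5.5 Hz and slow =
1.56–2.44 Hz, the fast band scaled by the rate ratio 2.0/4.5. Band-pass
filtering before phase extraction must be exactly zero-phase, otherwise
the filter's group delay would masquerade as a motor lag. We apply the
squared magnitude response of a 2nd-order digital Butterworth design
spectrally (the transfer function a forward–backward pass applies) to a
reflect-padded signal. This form is exactly symmetric under time reversal
— a property the test suite asserts at machine precision — and the padded
length is rounded up to a 2-3-5-smooth FFT size, with the two reflection
pads kept equal so the symmetry survives. The reflection pad is `3/lo`
seconds, enough for the band-edge transients of these narrow filters.

## Stimulus schedules

`make_accelerating_schedule()` builds the synchronization sequences: one
plateau per rate on an inclusive grid, each event's rate governing the
interval that follows it (the simplest reading of "the rate increases
every 48 tokens"; the choice only matters at plateau boundaries). The
canonical slow sequence — 240 tokens, 48 per plateau, 1.92 → 2.08 Hz in
0.04 Hz steps — sums to 120.096 s of inter-onset intervals, matching the
printed 120 s figure after rounding; the fast sequence (4.3 → 4.7 Hz by
0.1) computes to ~53.4 s, which we treat as exact since it follows
directly from the token and rate specification.

Perception blocks are balanced by construction (exactly half deviant), with
per-trial rates drawn from the multiplicative grid
`rate_center · (1 + 0.02k)`, k ∈ −2..2 — this reproduces the printed slow
grid 1.92–2.08 Hz exactly and stays inside the printed fast range — and
deviant shifts drawn uniformly from the stated ranges (28–34% of the IOI
for syllables, 12–18% for tones). Rates are drawn with replacement; the
draw scheme is a configurable detail with no effect on the balance
invariants.

## The synthetic study

Because group-level statistics need a cohort, the package generates one
with known ground truth.

**Synchronizer model.** `simulate_motor_response()` is an error-correcting
phase oscillator: each cycle the producer predicts its next event one
intrinsic period ahead, then corrects a fraction `coupling` ∈ [0, 1] of
the gap to the nearest stimulus onset (plus a constant lag), with Gaussian
phase noise per event and an optional random-walk drift of the intrinsic
rate. Correction references the *nearest* onset rather than an event
index, so the model re-anchors gracefully on accelerating sequences and
after missed events. Coupling 1 with no noise reproduces the stimulus
onsets exactly; coupling 0 free-runs. Events are rendered as Gaussian
bursts — 30 ms FWHM for taps, 120 ms for whispered syllables, defaults
chosen for clear separability rather than calibrated to any recording
corpus. (For deterministic periodic trains the burst width shows up in the
harmonic structure of the envelope spectrum, not in the width of the
fundamental line, which is duration-limited; the test suite asserts the
harmonic-ratio ordering.)

**Population model.** A participant's eight condition couplings are
`base + L z + ε` clipped to [0, 1], with three latent components: one
loading on all four fast conditions and two effector-specific slow ones.
Clipping rather than a logistic squash keeps the latent-to-coupling map
affine where valid, which makes recovery tests interpretable. The default
operating point is `base_coupling = 0.35` with loadings of 0.18 and
condition noise 0.05: the coupling → normalized-PLV map saturates above
roughly 0.6, so this places the population in the responsive regime where
latent differences survive into the measured scores. With these defaults a
200-participant study yields exactly three eigenvalues ≥ 1 and each
condition's largest varimax-rotated loading on its generating component.

**Perception model.** Responses come from a logistic psychometric
function, `P("deviant" | shift s) = guess + (1 − guess − lapse) ·
logistic(slope (s − threshold))` with guess fixed at 0.5; standards are
answered at the false-alarm rate implied by s = 0. Default thresholds make
syllables relatively easier at fast rates and tones easier at slow rates,
the direction of the rate-by-stimulus interaction the design is built to
detect.

What the generator does *not* emulate: real whisper/tap acoustics (bursts
stand in for both), auditory feedback loops, attention lapses during
synchronization, or session-level drifts. Passing recovery tests therefore
show the *pipeline* is faithful — couplings in, ordered scores out — not
that the oscillator model is a model of human synchronizers.

## Statistics

**Component analysis.** `pca_varimax()` standardizes the eight condition
scores, eigen-decomposes the correlation matrix, retains components by the
Kaiser–Guttman criterion applied inclusively (λ ≥ 1 — the inclusive
reading matters when a component sits exactly at 1), varimax-rotates the
retained loadings (Kaiser normalization, tolerance 1e-6) and fixes each
component's sign so its largest loading is positive. Rotation preserves
per-condition communalities to 1e-8, which the suite asserts.

**Bayes factors.** `jzs_bf_paired()` computes the two-sided JZS Bayes
factor by adaptive quadrature of the Cauchy-prior (r = 1/√2 default)
marginal likelihood against the point null. The quadrature is centred on
the likelihood peak δ = t/√n before the infinite-range transformation —
without this, adaptive quadrature wastes two orders of magnitude more
evaluations at large |t|. Agreement with a dense-grid trapezoid oracle is
at 1e-6 or better across the tested range. `bfda()` draws paired
differences from a unit-variance normal (the standardized-effect
convention of design-analysis tooling), so with n = 62, threshold
BF₁₀ > 6 and 10,000 replicates the exceedance proportions are ~100%,
~84.9% and ~10.5% at d = 1.05, 0.5 and 0.2; the Monte-Carlo standard
error at p ≈ 0.85 is ~0.36 percentage points.

## Quality control

The consistency screen regresses each condition's second-trial score on
its first and flags participants whose second trial falls outside the 99%
**prediction** interval at their first-trial value. We deliberately use
the prediction interval for a new observation, not the mean-response
confidence band: the latter narrows as 1/√n and would flag nearly every
participant in a large sample. The mean-response variant remains available
(`interval = "confidence"`) for sensitivity checks. The chance screen
excludes participants at or below 0.5 accuracy in any stimulus × rate
cell — *at or below*, so a cell at exactly 0.5 excludes — and reports
participants with missing cells separately rather than excluding them.

## Numerical choices and scales

- Problem sizes in the test suite are the study's own: 240-token
  sequences, 8 conditions × 2 trials, 200-participant recovery runs,
  10,000-replicate BFDAs. Per-trial baselines use 20 shuffles in the
  whole-study driver and 5 in the densest sweep tests.
- All generators and analyses are pure functions of (parameters, seed);
  the study driver derives per-stage seeds from one root seed via a fixed
  affine scheme (`derive_seed()`), so one integer regenerates a study.
- Spectral-peak search excludes DC (the envelope is mean-subtracted first)
  and breaks amplitude ties toward lower frequency; FWHM is measured by
  linear interpolation to the half-height crossings, truncated and flagged
  at the search boundary, and floored at one frequency bin.
- Degenerate inputs: silent audio yields a zero envelope; envelopes
  shorter than one analysis window raise an invalid-input error; a single
  permutation segment triggers a warning and an identity baseline
  (normalized PLV 0); a constant condition column aborts the PCA naming
  the column.

## Known limitations

- The cochlear filterbank is a pragmatic stand-in at the fidelity the PLV
  needs; equivalence with any specific auditory model's envelopes is not
  claimed.
- The permutation chance floor depends on stimulus periodicity (see
  above); comparisons should stay within condition.
- Mixed-effects modelling of the condition tables is intentionally out of
  scope; the package exports long-format tables for lme4-style tooling
  downstream.
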