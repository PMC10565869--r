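---
title: "Simulated unilateral crosstalk cancellation for bone conduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated unilateral crosstalk cancellation for bone conduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A bone-conduction transducer does not stimulate one cochlea: skull vibration
carries its signal to both inner ears. For users of two bone-conduction
hearing devices this "crosstalk" mixes the left and right signals at both
cochleae and erodes the interaural level and phase cues that binaural hearing
depends on. Psychoacoustic compensation methods work above roughly 1 kHz but
break down below it, where interaural phase ambiguity confuses the
lateralization judgments they rely on — yet the low frequencies are exactly
where binaural cues matter most.

The approach implemented here borrows the *zone of quiet* idea from active
noise control. An error sensor (a probe microphone in the ear canal or an
accelerometer on the mastoid, in the physical setup) sits close to one
cochlea. The contralateral transducer's signal reaches it through the
*primary path* `h_RL`; the ipsilateral transducer can drive the same point
through the *secondary path* `h_LL`. A crosstalk-compensation (CTC) filter
`w_RL` feeds the input signal, suitably filtered, to the ipsilateral
transducer so that the two arrivals cancel at the sensor. Because the zone of
quiet grows as frequency falls, cancellation designed at the sensor can
plausibly extend to the cochlea at low frequencies — which is also why the
toolkit's working band is 224–1122 Hz, the third-octave edges of the
250–1000 Hz target range.

`ctcsim` reproduces the whole measurement-and-evaluation chain in
simulation: nothing here touches hardware, and a synthetic-head generator
supplies the transfer paths that a physical rig would measure.

## The synthetic head

`head_config()` / `generate_paths()` produce the two paths as sums of
exponentially damped sinusoids — a modal picture of skull transmission. One
set of modes (frequencies uniform in 200–3000 Hz, decay constants 1–5 ms,
random phases) is drawn per head and shared by both paths, as cranial
resonances are; each path then applies its own arrival delay and a mild
per-mode amplitude perturbation, and the primary path is rescaled so its
energy sits exactly `transcranial_attenuation_db` below the secondary's.

Defaults: 16 kHz rate, 512 taps (32 ms), secondary delay 0.1 ms, primary
delay 0.4 ms, 10 dB transcranial attenuation, 6 modes, sensor noise at
−90 dB re 1 V RMS. The delays and attenuation are round numbers of the order
reported for transcranial transmission; no published tap data exists for
these paths, so the generator aims at qualitative realism: causal, decaying,
band-limited responses with distinct arrivals.

What the generator does *not* emulate: nonlinear transducer distortion,
occlusion acoustics (the occlusion effect is modeled only at the
threshold level, in the psychoacoustics module), head-to-head variability
statistics of real skulls, and sensor placement effects. A green test suite
on this fixture therefore demonstrates correctness of the *algorithms*, not
performance on real heads.

`generate_transducer()` supplies a separate fixture for the equalization
stage: a 200–4000 Hz band-limited response with two mild mechanical
resonances (700 and 2500 Hz) and a seeded perturbation small enough that any
two realizations differ by well under 1.5 dB — mimicking a matched pair of
audiometric transducers. Its in-band dynamic range (~8 dB) is deliberately
moderate: a response with deep in-band notches cannot be flattened by a
regularized inverse without giving up the boost limit that regularization
exists to enforce.

## Impulse-response measurement (TSP)

`generate_tsp()` builds the optimized swept sine in the frequency domain,
`H(k) = exp(-i 4 pi m k^2 / N^2)` with Hermitian completion; its magnitude
spectrum is exactly flat, so the conjugate spectrum is an exact circular
inverse. Defaults follow the measurement protocol: `N = 32728` samples
(2.05 s at 16 kHz; `N = 32768` works equally), stretch `m = N/8`, playback
at −20 dB re 1 V RMS, left/right sweeps staggered at 1 s and 5.1 s, a
100 Hz high-pass on the recording, and 512-tap extraction.

One numerical choice deserves a note. Convolving the *recording* with the
circular inverse only collapses to an impulse under circular (synchronized,
periodic) processing; on a linear lag axis the sweep's time-domain tails
wrap and leave artifacts around −30 dB. `deconvolve()` therefore inverts the
convolution exactly: it reconstructs the sweep spectrum from the inverse
(the two are conjugate, constant-magnitude spectra), zero-pads past the
recording length so linear convolution becomes invertible, and divides. The
padded sweep spectrum's magnitude varies by only a factor ~2.5, so the
division is well conditioned; embedded responses come back at machine
precision in the noiseless case, and each response appears at its sweep's
onset offset.

Because the protocol high-passes the recording at 100 Hz, the recovered
responses are by construction band-limited above the cutoff; round-trip
accuracy is judged against the equally band-limited ground truth (the raw
truth, if the high-pass is disabled, returns at ~1e-10 relative error).

## Transducer equalization (Kirkeby inversion)

`kirkeby_inverse()` computes `C(w) = conj(T) / (conj(T) T + eps(w))`. The
frequency-dependent regularization `eps(w)` is parameterized by
`reg_profile()`: a floor `eps_min` inside the equalized band (200–4000 Hz by
default), `eps_max` outside, raised-cosine ramps over half an octave in
log-frequency. Values are relative to `max |T|^2`, with defaults
`eps_min = 1e-4` and `eps_max = 1`; the original description shows the
profile only graphically and "adjusted manually", so these are package
choices, exposed as configuration. At every bin `|C| <= 1/(2 sqrt(eps))` —
the boost limit that protects a transducer from being driven hard where it
is weak. The time-domain filter is made causal by an `n_fft/2` circular
modeling delay (`n_fft = 4096`, at least twice the 512-tap responses, so
nothing wraps).

`flatness_metric()` quantifies the outcome: max-minus-min smoothed magnitude
(third-octave smoothing) over the band. The equalized fixture lands under
2 dB of ripple; applying the left transducer's filter to the right
transducer (they differ by <1.5 dB) degrades that by less than the pair
difference.

## CTC-filter estimation (FxLMS)

`estimate_ctc_filter()` runs the filtered-x LMS loop sample by sample, as
the update equations are written: with band-limited noise `s_R` as input,

* anti-signal: `anti(n) = w(n)^T s_R(n)`,
* sensor error: `e(n) = (s_R * h_RL)(n) + (anti * h_LL)(n)`,
* update: `w(n+1) = w(n) - mu e(n) s_Rf(n)`, where `s_Rf = s_R * c_LL` is
  the filtered-x signal and `c_LL` is the secondary-path estimate (equal to
  `h_LL` in simulation, replaceable for mismatch studies).

Coefficients start at zero; `p = 512` taps; the input is 224–1122 Hz
Gaussian noise; the protocol duration is 60 s. The inner loop is compiled
(Rcpp) — 60 s of 16 kHz signal against 512 taps is ~10^9 multiply-adds.

The printed update is scale-sensitive, so the default step is
power-normalized, `mu / (||s_Rf||^2 + delta)`. The raw rule is retained
(`normalized = FALSE`). Two numerical findings shaped the defaults:

* **Stability.** The filtered-x loop's gain margin is set by the delay and
  dispersion of the secondary path. On these modal paths the normalized
  update destabilizes near `mu ≈ 0.05–0.08` depending on the head
  realization. The default is `mu = 0.02`, roughly a factor three inside the
  worst edge observed; a run whose block error energy grows by 10^6 raises a
  divergence error naming `mu`.
* **Convergence depth vs. time.** With in-band-only excitation, modes at
  spectral dips of `h_LL` converge slowly; cancellation depth grows by a few
  dB per doubling of adaptation time. Ten seconds of signal reaches roughly
  −25 dB in-band residual on an exactly cancellable fixture; the protocol's
  60 s goes deeper. Tests that only need a *working* filter use 10 s.

`check_convergence()` flags the earliest time the per-block relative
coefficient change stays below a tolerance for five consecutive blocks. The
steady-state change floor (gradient noise) sits near 0.2–0.7 % per block at
the default step, so the default tolerance is 1 % — "negligible change" in
the sense that the filter has stopped moving beyond its stochastic jitter.

`ctc_wiener()` provides closed-form references. `method = "ls"` solves the
causal FIR Wiener problem exactly through the Toeplitz normal equations
(weighted by the adaptation-noise spectrum) — the true optimum for a 512-tap
causal filter, and the upper bound the adaptive filter is compared against.
`method = "division"` is the textbook regularized spectral division
`-H_RL conj(H_LL) / (|H_LL|^2 + lambda)`, truncated to causal taps; it is
the natural frequency-response reference, but its truncation discards the
unconstrained solution's acausal energy, so it *under*-performs the adaptive
filter in cancellation depth — which is why the ordering test uses the LS
solution.

## Verification

`measure_reduction()` replays the verification experiment: 6 s of band
noise through the crosstalk path, with and without the anti-noise through
the secondary path, band-limited levels over the steady state (first and
last 100 ms excluded — the analysis window is not specified in the source
protocol, so the package defines it), reported in dB re 1 V RMS, broadband
and per third-octave at the seven evaluation centers. The zero filter gives
exactly 0 dB by construction. `reestimate_if_shifted()` implements the
recovery rule: below 10 dB of reduction — the effectiveness criterion — the
filter is re-estimated on the current paths.

## Simulated subjective evaluation

The psychoacoustics module replaces human listeners with a standard
psychometric observer: correct-response probability
`p(L) = g + (1 - g - lapse) * logistic((L - threshold)/slope)` with guess
rate `g = 1/3` for the three-interval forced-choice task. The
2-down/1-up staircase starts at −20 dB re 1 V RMS, steps 4 dB until the
fourth reversal and 2 dB after, stops at 12 reversals, and averages the last
8 reversal levels — bit-exactly, as the trial log re-derivation test
checks. Reversal bookkeeping follows the standard transformed up-down
convention: a reversal is logged at the trial where the prescribed movement
direction flips; the consecutive-correct counter resets on every level
change and on every incorrect response; the small step applies from the
first change after the fourth reversal. The 2-down/1-up equilibrium is the
70.7 %-correct point; `staircase_target_level()` computes it by root
finding, and the estimator's mean over seeds lands within a dB of it for
steep observers.

Bracketing audiometry (`run_bracketing()`) models the manual procedure:
descend in 10 dB steps from a clearly audible start until the tone is
missed, ascend in 5 dB steps until heard, repeat; the threshold is the
lowest level detected at least twice (the "2-of-3" rule — the package
counts detections across ascents, which is the observable the rule needs).
Detection is a yes/no task, so the forced-choice guess rate does not apply.
Frequencies run 1000 Hz first, then ascending, on the 5 dB grid.
`occlusion_effect()` differences occluded and unoccluded audiograms at the
audiometric frequencies with the conventional sign (positive = occlusion
lowers the BC threshold).

`build_3ifc_stimulus()` assembles the actual waveforms: 800 ms third-octave
masker centered at the probe frequency, 500 ms probe tone temporally
centered (onset 150 ms), 75 ms raised-cosine (cos²) fades on both — the fade
window is unspecified in the source protocol and cos² is the psychoacoustics
convention. The faded tone segment is rescaled so its RMS sits exactly at
the nominal probe level.

## The end-to-end pipeline

`run_pipeline()` chains everything: generate a head → measure its paths with
staggered sweeps → design equalization filters for the transducer fixtures →
adapt the CTC filter on the *estimated* paths → verify on the *true* paths →
run per-frequency staircases with and without cancellation. All stage seeds
derive deterministically from one master seed; two runs with the same
configuration produce byte-identical outputs.

The "with cancellation" condition models the cochlear benefit as a
per-frequency attenuation of the masker equal to the sensor-measured
third-octave reduction times a derating factor (default 0.35), capped at the
masker sensation level (default 30 dB). The derating acknowledges what the
physical experiments found: sensor-side reduction exceeds the perceptual
benefit severalfold, because the sensor is not the cochlea. Both numbers are
configuration, not physics; the default ratio matches the reported
relationship between ~14–16 dB sensor reductions and ~4–5 dB threshold
improvements.

## Problem sizes and reproducibility

The test suite and the acceptance script run at reduced-but-faithful sizes
chosen as the package's own defaults for desk-scale work: full-length
(32,728-sample) sweeps where the protocol prints them; 10 s of FxLMS
adaptation where only a working filter is needed and the protocol's 60 s
where convergence itself is under test; 6 s verification probes; 200
staircase replications for estimator statistics. Every random quantity is a
pure function of explicit seeds; the RNG state of the calling session is
never touched.

## Known limitations

* The synthetic head is a modal caricature; absolute reduction figures on it
  do not predict performance on real skulls.
* Cancellation depth at short adaptation times is limited by slow modes at
  secondary-path spectral dips; an exactly cancellable fixture reaches about
  −25 dB in-band residual after 10 s at the default step, not the textbook
  "arbitrarily deep" limit.
* The spectral-division Wiener reference is not the causal optimum; use
  `method = "ls"` when comparing cancellation depth.
* Unilateral only: one error sensor, one compensated direction. Bilateral
  (two-sensor) cancellation, real-time operation and frequency-domain
  closed-form CTC design are out of scope.
* Levels are electrical (dB re 1 V RMS) throughout; no SPL/force-level
  calibration is attempted.
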