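---
title: "Methods: brain states, spindles and imaginary-coherence connectivity in sleepcoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain states, spindles and imaginary-coherence connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `sleepcoh`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices taken where more than one reasonable option existed.

## The analysis problem

Chronic rodent EEG studies of neurodevelopmental models ask three linked
questions: whether the distribution of brain states (wake, NREM, REM) is
altered; whether discrete events — sleep spindles and spike-and-wave
discharges (SWDs, the correlate of absence seizures) — change in rate or
shape; and whether functional connectivity between cortical sites differs,
both tonically within a state and dynamically around spindles. `sleepcoh`
implements this analysis chain for 32-channel skull-surface grid recordings
with an accelerometer, in 5 s scoring epochs.

## Electrode geometry

The packaged layout is a synthetic planar grid built to the published
summary geometry of a commercial 32-channel rodent surface probe: 4 columns
(ML ±0.65 and ±1.95 mm) by 8 rows spanning sqrt(178) mm of AP, which fixes
the shortest inter-electrode distance at exactly 1.3 mm and the longest at
13.9 mm. Coordinates are planar (AP, ML relative to bregma) and distances
are plain Euclidean: the probe is a flat grid, and skull curvature over the
spanned area is ignored (a stated non-goal). Channels carry a hemisphere and
a rostral/middle/caudal class, giving 6 regional groups of 4–6 electrodes;
channel 18 (right somatosensory trunk region) is the default single-channel
analysis site. Distance thresholds partition the 496 unordered pairs into
"short" (distance ≤ t) and "long" (> t) sets; ties go to the short set, a
rule that never fires on the packaged layout (no pair sits on an integer
threshold) and matters only for user-supplied geometries.

## Hypnogram and bout statistics

A bout is a maximal run of identical non-EXCLUDED epoch labels. EXCLUDED
epochs terminate bouts and are removed from the percent-time denominator, so
percent times over the three states always sum to 100 where any scored time
remains. Epochs are atomic: an epoch partially covered by an artifact or
seizure interval is excluded whole. The artifact rule is a literal
per-sample amplitude test (|v| > 750 µV on any analysed channel).

The rule-based scorer is a convenience surrogate for visual scoring and is
validated only against synthetic ground truth: an epoch is NREM when the
accelerometer is quiet and delta (1–4 Hz) power exceeds 40% of 1–48 Hz
power; REM when the accelerometer is quiet, the epoch is not NREM, and the
theta/delta power ratio exceeds 1.5; WAKE otherwise. The movement gate is an
absolute accelerometer-SD ceiling (0.3 a.u.) rather than a percentile cut:
percentile cuts are undefined on recordings that never move (e.g. an
all-NREM segment), while an absolute gate handles them correctly.

## Spike-and-wave discharge detection

SWDs are periodic, so their power spectra show peaks at the fundamental
(5–10 Hz) and its integer harmonics. The detector slides a 1 s window in
0.5 s steps; a window is marked when its peak amplitude reaches the floor
(200 µV) and its harmonic score reaches the prominence factor (3). The
harmonic score takes the strongest in-band peak as the fundamental f0 and
returns the minimum, over harmonics k = 2..3, of the peak power within ±1
bin of k·f0 divided by the local median power (±4 Hz neighbourhood,
excluding the peak bins — a broad genuine harmonic must not inflate its own
reference level). Marked windows merge when they are within 0.5 s *and*
their fundamentals agree: merging across distinct trains would blend two
fundamentals into one event and corrupt its spectrum. Merged events shorter
than 1 s are dropped, and each surviving event is re-validated on its
whole-length Welch-averaged spectrum — single-window harmonic flukes in
theta-rich REM epochs do not survive this averaging, which is what keeps
precision high without raising the prominence factor. Because the score is a
power ratio, detection is amplitude-scale covariant above the floor.

## Sleep-spindle detection

The trace is band-passed to 12–17 Hz with a zero-phase windowed-sinc FIR
(1 Hz transition; linear phase removed exactly, preserving event timing for
coherogram alignment), and the analytic-signal envelope is smoothed with a
25 ms moving average. All thresholds are expressed as mean + k·SD of the
smoothed envelope over NREM samples of that channel: the bare k·SD form
would place the 1.5 SD boundary threshold *below* the envelope's own mean
(a Rayleigh-like envelope has mean ≈ 1.25σ), making boundary extension
ill-posed. Candidates require mean + 3 SD; boundaries extend to the
surrounding mean + 1.5 SD crossings; candidates closer than 0.2 s merge;
events must show peak-to-trough amplitude within 25–750 µV and must not
reach mean + 35 SD (noise exclusion).

The 0.2–3 s length window is applied to the span of the detection-threshold
(3 SD) crossing, while the reported event extent uses the boundary
crossings. The reason is band-limit physics: any burst, however brief,
spreads to roughly 1/bandwidth ≈ 0.2 s at the low boundary threshold after
12–17 Hz filtering, so the boundary extent cannot discriminate sub-minimum
bursts; the 3 SD core tracks the true burst duration much more closely. A
known limitation follows: a sub-0.2 s burst planted at several times the
background amplitude still measures ≥ 0.2 s and is kept — at plausible
spindle amplitudes the rule behaves as intended, and the tests exercise
both regimes.

Multi-electrode spindles group per-channel detections whose electrodes lie
within 2 mm and whose intervals overlap in time, by transitive closure
(union-find). Transitive closure was chosen over seed-channel nearness
because it is the simplest rule consistent with "the same spindle seen on
several electrodes"; the grouping is cross-checked in the tests against an
independent graph connected-components implementation.

## Spectral power

Per-epoch power uses a sine-taper multitaper estimate with 7 tapers.
Sine tapers are closed-form, so no large eigendecomposition is needed at
any sampling rate, and at K = 7 their spectral concentration is comparable
to the classical Slepian family at time–bandwidth 4. On 5 s epochs the
periodogram's native resolution is exactly the mandated 0.2 Hz, so the
240-bin 0.2–48 Hz grid is read off directly (other epoch lengths are
linearly interpolated). Values are log10 power per bin; state averages are
arithmetic means of log spectra over the state's non-excluded epochs, and
band summaries average the bins whose centres fall inside closed intervals
(delta 1–4, theta 5–10, sigma 12–17, beta 17–30, gamma 30–48 Hz; sigma is
the spindle band).

## Static connectivity

Signals are decimated (default ×8: 1 kHz → 125 Hz) behind an order-8
Chebyshev type-I anti-aliasing filter (0.05 dB ripple, cutoff 0.8× the new
Nyquist) applied forward–backward. Imaginary coherency is estimated per 5 s
epoch by Welch's method with 2 s Hann segments at 50% overlap — 2 s segments
give exactly the 0.5 Hz native resolution of the 99-bin 1–50 Hz grid, so no
spectral interpolation is involved. Per-epoch estimation (rather than
state-concatenation) was chosen because epochs of one state are generally
not contiguous, and concatenation would create artificial segment
boundaries; epochs shorter than one Welch segment after exclusion are
skipped. Epoch values are Fisher-z averaged per bin: tanh(mean(atanh v)),
with |v| clipped to 1 − 1e-12 under a warning. atanh is odd, so the sign of
the imaginary part — which encodes lead/lag direction — survives averaging.
Pairs are stored in canonical orientation (lower channel id first); swapping
the orientation negates every bin.

Distance-group spectra are arithmetic means of the member pairs' Fisher
averages. Regional spectra are different by design: member-channel voltages
are averaged *first* and one coherency is computed between the two regional
signals, matching the regional-averaging convention of dynamic-connectivity
analyses. The identical-members degenerate case therefore returns exactly
zero.

## Spindle-locked dynamic connectivity

Around each detected spindle start (the boundary-threshold crossing),
complex Morlet coefficients are computed at 11 components (12–17 Hz, 0.5 Hz
steps) with 7-cycle wavelets truncated at ±3 SD of their Gaussian envelope,
on the signal at its native rate, then sampled onto a 1 ms grid from
−500 to +1500 ms (2000 points). The per-pair coherogram is the imaginary
part of the trial-summed coherency; coherograms are averaged across the
< 2 mm pair set per animal *before* thresholding, and the high-connectivity
statistic counts bins whose magnitude exceeds 70% of that animal's
coherogram maximum (magnitude, because the sign of imaginary coherence only
encodes lag direction). The count is invariant under global scaling of the
coherogram. Trials whose padded window leaves the recording are dropped and
reported.

## Permutation statistics

The bin-wise group test permutes animal labels, using the difference of
group means as the statistic (labels are exchangeable under the null, so
studentization is unnecessary; the statistic is documented and swappable).
One-sided probabilities use the add-one convention
p = (1 + #{perm ≥ obs}) / (n_perm + 1); a bin is significant at p ≤ α/2
(group A above B) or p ≥ 1 − α/2 (below), the two-sided split rule, with a
union rule (p ≤ α or ≥ 1 − α) available by flag. Clusters are maximal runs
of same-direction significant bins with mass Σ|statistic|; the corrected
cluster p-value compares each observed mass with the permutation
distribution of the *maximal* cluster mass, each permutation thresholded at
the same per-bin quantiles — the standard cluster-based multiplicity
correction. When the label assignments can be enumerated (e.g. 4 + 4 gives
70), the test switches to exhaustive enumeration and p-values are exact
proportions. Family-wise calibration under the null is verified by
simulation in the test suite. Cohen's d and two-sided two-sample power use
the noncentral-t formulation (noncentrality d·sqrt(n/2), df 2n−2);
`stats::power.t.test` serves as an independent cross-check in the tests,
never as the implementation.

## The synthetic-data generator

The generator is the package's ground-truth instrument. Per channel it sums:

- **1/f² background**, scaled per state (wake 40, NREM 55, REM 45 µV RMS).
  The squared-exponent default reflects the steep spectral decay of surface
  EEG; it also keeps incidental 12–17 Hz background power low enough that
  envelope-threshold spindle detection is meaningful.
- **State oscillators**: independent narrowband noise per channel — delta
  (1–4 Hz, 80 µV) in NREM, theta (5–10 Hz, 50 µV) in REM. Wake is
  desynchronized (background only).
- **Lagged shared sources** per regional group: band-limited sources
  injected into each member channel with a per-channel lag (sigma 12–17 Hz
  at 2 ms steps and delta in NREM, theta in REM). A zero-lag mixture alone
  would produce no imaginary coherence, so the lag is what makes the
  planted coupling detectable — and conversely the estimator's blindness to
  zero-lag mixing is the volume-conduction control. Group membership stands
  in for distance-dependent gain: within-group channels are the < 2 mm
  neighbourhood.
- **Spindles**: Hann-enveloped constant-frequency bursts (12–16 Hz,
  0.4–1.2 s, 100 µV peak, 3 per NREM minute) planted on a seed channel and
  echoed on channels within 2 mm at gain 0.8 with 2 ms per-channel lags.
- **SWDs**: harmonic trains (fundamental 6–9 Hz plus 3 harmonics at halving
  amplitudes, 350 µV, 2–5 s, square envelope with 50 ms ramps) during wake,
  on all channels with per-channel gains 0.7–1. Discharges are
  rejection-sampled so they never superpose.
- **Artifacts**: biphasic 900 µV pulses during wake, 0.2/min, placed clear
  of discharges; the accelerometer is quiet in NREM (0.1), nearly silent in
  REM (0.02) and variable in wake (1.0), with bursts during artifacts.

State sequences are semi-Markov with geometric dwell at epoch resolution
(wake → NREM; NREM → REM with probability 0.35, else wake; REM → wake), so
REM is entered only from NREM. Dwell means default to wake 180, NREM 160,
REM 70 s. The mutant preset multiplies wake and NREM dwell by 1.6 — which,
over a fixed recording, also yields fewer bouts — attenuates sigma-band
shared-source gain and cross-channel spindle gain by 0.45, and multiplies
the SWD rate by 6. Event rates and amplitudes were fixed once, at values a
rodent electrophysiologist would call typical, such that the reference
detectors reach high recall on default settings.

What the generator does **not** emulate: biophysical volume conduction and
head geometry (coupling is injected, not propagated), spindle frequency
chirp, slow-oscillation coupling, inter-animal variance structure beyond
seed-to-seed sampling noise, electrode drift, or real artifact morphology.
Passing tests therefore demonstrate the correctness and calibration of the
algorithms under the stated generative assumptions, not detector
performance on real recordings.

## Numerical choices and degenerate inputs

- Fisher averaging clips |v| ≥ 1 to 1 − 1e-12 with a warning; bins with a
  vanishing auto-spectrum yield NA and are excluded from averaging.
- Coherogram bins with a zero denominator return 0 and are counted in a
  `zero_denominator_bins` flag.
- An all-EXCLUDED hypnogram returns NA percent times under an
  `all_excluded` attribute rather than an error.
- Seed discipline: one global seed expands into per-animal, per-stage
  sub-seeds via a Lehmer-style counter map (`derive_seed`), all below 2³¹;
  every stochastic function restores the caller's RNG state.
- Problem sizes in the shipped tests — 15-minute single-animal recordings at
  250 Hz for detector validation, 2-minute NREM segments at 1 kHz and
  n = 10 per group for direction-of-effect recovery, 400-permutation null
  replicates for calibration — were chosen as the smallest sizes at which
  the quantities under test are stable across seeds.

## Known limitations

- Sub-minimum spindle bursts at unrealistically high amplitude are smeared
  past the 0.2 s floor by band-limited filtering (see above).
- The rule-based scorer is not a substitute for visual or EMG-based
  scoring on real data.
- Regional coherency inherits the reference-dependence of voltage
  averaging; no re-referencing is performed.
- EDF output is 16-bit with per-file physical scaling over the observed
  range; amplitudes are quantized to range/65535.
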