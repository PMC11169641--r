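---
title: "Methods: acoustic assessment of Parkinsonian speech with pdspeech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic assessment of Parkinsonian speech with pdspeech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdspeech)
```

## The measurement problem

Hypokinetic dysarthria affects most people with Parkinson's disease:
phonation becomes unstable (higher F0 variability, more noise),
articulation undershoots (smaller vowel space, slower and less regular
syllable alternation), and prosody flattens and slows (longer pauses,
lower net speech rate). `pdspeech` turns four short recording tasks —
sustained /a/, /i/, /u/; fast /pa/ repetition; fast /i/-/u/ alternation;
and a 105-syllable read passage — into 29 interpretable features, then
provides the cohort statistics used to compare patients with controls,
track disease stage, and classify PD vs. healthy speech.

Everything below a feature is ordinary signal processing; the package's
contribution is a complete, automated, and *testable* implementation of
the battery: each analysis stage is paired with a seeded generator whose
ground truth the stage must recover.

## Signal-processing choices

**Framing.** F0 and intensity use 40 ms frames with a 10 ms hop. 40 ms
holds at least three periods of the lowest searched pitch (75 Hz), which
autocorrelation needs for a stable peak; 10 ms resolves syllable-level
dynamics. Formants use 30 ms frames (spectra are quasi-stationary at
that scale) with the same hop.

**Pitch.** Per frame we compute the exact normalized cross-correlation
(the FFT supplies the lagged products; cumulative sums supply the
segment energies), search 75–400 Hz by default, refine the best peak
parabolically, and call the frame voiced when the peak height reaches
0.45 and the frame's RMS is within 45 dB of the recording's maximum. A
second pass re-picks frames whose estimate sits at twice, half, or a
third of the voiced median — the classic octave-error correction —
while leaving legitimately variable pitch alone (only ratio windows
1.8–2.2 and 2.7–3.3 are touched). The search range is overridable per
recording, mirroring the per-recording constraint tuning done in
clinical practice.

**HNR.** The voiced-frame mean of $10\log_{10}\, r/(1-r)$, where $r$ is
the normalized autocorrelation at the pitch period — the standard
periodic-to-aperiodic energy ratio. On synthetic vowels the estimator is
accurate to a few tenths of a dB for targets up to ~20 dB and saturates
near 27–30 dB, where residual synthesis aliasing (not the estimator)
sets the ceiling.

**Formants.** The signal is downsampled to ~11 kHz (zero-phase FFT
resampling), pre-emphasized (0.97), Hamming-windowed, and fitted with an
LPC of order `2 + rate_kHz` via Levinson recursion; polynomial roots
with bandwidth under 400 Hz count as formants. The bandwidth cap rejects
spurious wide-band roots; the price is occasional frame dropouts, which
downstream medians and voiced-span conventions absorb.

**Envelope and events.** The amplitude envelope is the analytic-signal
magnitude low-passed at `1000/smooth_ms` Hz (default 20 ms, chosen so a
7 syll/s DDK train keeps distinct peaks). Syllables and F2 cycles are
local extrema with a *topographic prominence* threshold — DDK peaks need
a prominence of 25 % of the envelope maximum and 100 ms spacing; F2
extrema need 200 Hz after a 50 ms median filter. Onsets/offsets sit at
half-prominence crossings, so syllable duration (`DDKavp`) follows the
half-prominence convention.

**Pauses.** A frame is a pause candidate when broadband energy is 25 dB
below the speech level (90th percentile frame level) *and* low-band
(< 1 kHz) energy is equally low — the low band stands in for voicing at
the fine 10 ms / 5 ms grid needed for sharp boundaries, and the
broadband test keeps fricative/plosive consonants out of pauses.
Candidate runs are expanded by half a frame on each side and kept when
at least 30 ms long. `TotalDur` is measured after trimming
leading/trailing silence so recorder start lag never counts as reading
time.

**VOT.** Burst onset: first 1 ms frame where > 3 kHz energy rises 12 dB
above the high-band noise floor inside the syllable window. Voicing
onset: first subsequent rise of the < 1.5 kHz band (within 25 dB of the
syllable's own low-band peak, so burst leakage cannot trigger it),
cross-checked against the pitch track. Tying voicing onset to the pitch
frame grid instead would quantize VOT to the 10 ms hop, which is larger
than the effect of interest.

## Feature conventions worth stating

* `DDKcvp = 100·DDKsdp/DDKavp`: the period SD is normalized by the mean
  *syllable duration* (half-prominence), not the mean period — this is
  the construction consistent with published group values of these
  features (period SD ≈ 35 ms over duration ≈ 91 ms ≈ 36 %).
* `DDKjit` is the local-jitter analogue: mean absolute
  consecutive-period difference over the mean period, ×100.
* `DDKcvi` is read as the coefficient of variation of peak intensities;
  intensities are expressed in dB re 2×10⁻⁵ full scale (the speech
  convention that puts full scale at ~94 dB), which keeps a CV of dB
  values meaningful.
* `vAmp` uses linear envelope amplitudes (a CV of dB values is
  ill-defined); `Ampstd` stays in dB. Both are computed from the
  smoothed envelope sampled at voiced frames — frame RMS would ripple
  with the fractional number of pitch cycles per window (~1.5 % floor).
* `MPT` is the longest voiced segment (50 ms dropout bridging), not the
  file length.
* `F2reg` is the CV (%) of peak-to-peak cycle periods: lower = more
  regular, matching the clinical directionality of the feature.
  `F2rate` divides the cycle count by the voiced span, consistent with
  `DDKavr`'s task-duration denominator.
* `NSR` uses the trimmed task duration minus detected pauses; the rate
  denominator question (task duration vs. peak span) is resolved in
  favour of task duration for both DDK and reading.
* `VowelArea` is the shoelace area of the /a/–/i/–/u/ triangle in the
  F1×F2 plane, from per-vowel median formants.

## Statistics

Group comparison is the pooled-variance two-sample t-test (Welch behind
a flag), with Hedges' g using the usual small-sample correction
$J = 1 - 3/(4\,\mathrm{df} - 1)$. Features are z-scored per sex against
healthy controls only, so patient abnormality is expressed in
control-referenced units. Feature ranking orders by |g| and demotes any
feature correlated above 0.8 with an already-accepted one — the
automatable part of a selection that, in practice, also weighs clinical
interpretability; the six-feature preset (`DDKavr`, `NSR`, `DPI`,
`F0std`, `F2reg`, `VowelArea`) is available directly.

The classifier is Gaussian naive Bayes with stratified 5-fold
cross-validation: per fold, class priors and per-feature normals are fit
on training subjects only; pooled out-of-fold posterior probabilities
give the primary ROC/AUC (per-fold AUCs are reported alongside, since
the pooling convention is a genuine choice). A variance floor of
10⁻⁹ × the largest feature variance protects against constant features
within a fold. Folds are shuffled by an explicit recorded seed.

Partial correlations residualize both variables on the covariates by
OLS and use a t reference with $n - k - 2$ degrees of freedom; with no
covariates this reduces exactly to Pearson. Stage comparisons run a
one-way ANOVA over {HC, HY 1.5–2.0, 2.5, 3.0, 4–5}, Bonferroni-adjusted
stage-vs-control t-tests, and unadjusted (LSD) tests between patient
stages. Multiple-feature p-values get Benjamini–Hochberg adjustment.

## Networks

Connectivity is Fisher-z transformed Pearson correlation between node
time series, |r| clipped at $1-10^{-7}$ so duplicated nodes stay
finite. Because no thresholding convention is universal, binarization
keeps the top `sparsity` fraction of edges by |z| (default 0.2,
negative correlations compete by magnitude, deterministic tie-break) and
every report carries the sparsity used. NE is the mean inverse shortest
path length; NLE the global efficiency of the neighbour-induced
subgraph; aCp the mean nodal clustering; aEloc the mean NLE. All four
are checked against brute-force path and triangle enumeration in the
test suite.

## What the generators emulate — and what they do not

The source model is a Rosenberg glottal-flow derivative driven by a
phase accumulator (periods are exact, never quantized to whole samples),
synthesized 4× oversampled and band-limited down so the closure
discontinuity does not alias; resonators supply formants; calibrated
white noise sets HNR. Pitch variability is injected as AR(1)-correlated
per-cycle perturbation whose marginal SD is numerically inflated for the
shrinkage a 40 ms analysis frame applies, so the *frame-level* F0 SD
matches the requested target. DDK syllables are burst + VOT gap +
sharp-attack vowel; /i/-/u/ alternation sweeps the F2 resonator along a
saturated cosine (vowel targets are briefly held, as articulators do);
passages are contiguous syllables with specified silent pauses.

These signals have exact ground truth but are deliberately unnatural:
no coarticulation, no lexical tone, no breath noise or room
reverberation, no tremor or festination patterns, and cohort tables draw
features *independently* per group, whereas real acoustic features
correlate strongly. Passing recovery tests therefore demonstrates that
the measurement chain is correct, not that it is robust to every
clinical recording condition; and the cross-validated AUC on an
independent-feature cohort is an upper-bound-flavoured sanity check, not
a clinical performance estimate. Separately, published single-cohort
AUCs (≈0.93 on real, correlated features) are not reproducible from
summary statistics alone — which is why the acceptance script anchors on
effect sizes recomputable from printed group means/SDs.

## Numerical choices and degenerate inputs

Seeds are mandatory for every generator and recorded in every
classifier report; generation restores the caller's RNG stream.
Digital-silence envelopes are kept peak-free by an absolute floor
(10⁻⁶). Resampling and the analytic envelope zero-pad to 5-smooth FFT
lengths (a prime-length FFT in base R is quadratic). Degenerate inputs
fail loudly with named errors: empty audio, impossible F0 ranges,
zero-SD normalization strata, single-class folds, rank-deficient
covariates, constant node series, out-of-range sparsity.

## Problem sizes

The test suite synthesizes audio at 16 kHz — every feature of interest
lives below 3 kHz, and recovery tolerances are unchanged from 48 kHz —
with task durations of 4–10 s; generators default to 48 kHz/16-bit to
mirror the clinical recording protocol. Statistical calibration uses
1000 ANOVA replicates at n = 50, 400 t-test replicates at n = 40/80, 50
classifier seeds at n = 120, and 200 random graphs of ≤ 8 nodes against
brute-force oracles. The acceptance script uses the same sizes and runs
in seconds.

## Known limitations

* Fully automatic measurement: the package replaces the per-recording
  manual supervision used clinically with fixed (overridable) detector
  settings plus an annotation-sidecar convention; on noisy clinical
  audio, supervised correction would still be advisable.
* Two features beyond the 29 named ones are referenced in passing in
  the source literature but never defined there; they cannot be
  implemented and are omitted.
* Lexical-tone analysis of Mandarin is out of scope; running-speech F0
  statistics pool over tones.
* The HY-stage classifier is pairwise only; no multiclass model, no
  regularized or nonlinear classifiers.
* Graph metrics are for binary undirected graphs; weighted variants are
  out of scope, and the sparsity threshold is a reported configuration,
  not an inference.
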