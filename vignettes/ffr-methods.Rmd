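---
title: "Cross-level FFR analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-level FFR analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrtools)
```

# The problem

The frequency-following response (FFR) is a sustained neural potential
phase-locked to the periodicity of a sound — the fundamental frequency
(F0) of a voice and its harmonics. FFRs recorded at the scalp have long
been treated as a readout of subcortical pitch encoding, but intracranial
recordings show that auditory cortex also produces frequency-following
activity at low F0s. Deciding what each level contributes requires
analyzing the same responses at the scalp, at the cortical surface, and
across laminar depth with a common toolchain: phase-locking spectrograms,
pitch decoding, spectrotemporal comparison, current source density, and
source decomposition. `ffrtools` implements that chain, together with a
forward model that generates multi-level recordings with known ground
truth, so every analysis stage can be validated quantitatively.

# Stimuli

The four Mandarin tones are carried by the vowel /yi/: T1 high-level
(129 Hz), T2 low-rising (109–133 Hz), T3 low-dipping (89–111 Hz), T4
high-falling (140–92 Hz); 48 kHz, 250 ms, presented in both condensation
and rarefaction polarity. Only the endpoints and extrema of the natural
contours are documented, so the trajectory *shapes* are a design choice:

- T1 constant; T3 a piecewise-cosine dip from 105 Hz to its 89 Hz minimum
  at 60% of the duration, ending at 111 Hz.
- T2 and T4 are raised-cosine ramps rather than straight lines. Natural
  F0 movements flatten toward voicing boundaries, and the flattening also
  matters for measurement: a sliding autocorrelation window centred 20 ms
  inside the vowel reads approximately the window-mean F0, so a linear
  140→92 Hz fall would make the last analysis window read ~96 Hz — a
  value the stimulus never holds at its offset. With zero-slope endpoints
  the boundary windows read the printed endpoint frequencies (±2 Hz).

The spectral envelope is a minimal /i/: two Lorentzian resonances near
300 Hz and 2200 Hz over a 1/k harmonic stack. Downstream analyses depend
only on F0 and harmonics being present with a speech-like tilt.
Presentation level and calibration are irrelevant to the analyses and are
not modelled.

# The two-source forward model

`simulate_ffr_dataset()` draws trial-level epochs from two phase-locked
generators responding to the stimulus F0 contour:

| parameter | subcortical | cortical | why |
|---|---|---|---|
| latency | 3 ms | 15 ms | typical brainstem vs cortical FFR lags |
| roll-off knee | 150 Hz | 90 Hz | cortical phase-locking fails at lower frequencies |
| roll-off slope | 6 dB/oct | 18 dB/oct | cortical decline is steeper |
| onset transient | ×1 | ×3 | cortical onset response dominates the CSD sink |
| envelope-following component | none | ×1.5 | cortical sustained/envelope response |

Each source is a harmonic stack following the F0 contour, with harmonic k
weighted by `phase_locking_gain(k·F0)` — 1 below the knee, then a fixed
dB/octave decline. The cortical source additionally carries a sustained
envelope-following plateau; that component is real physiology (cortical
sustained potentials track the stimulus envelope) and it is also what
makes the two generators statistically separable: without it the two
deterministic harmonic stacks are strongly mutually correlated and no
independence-based decomposition can pull them apart.

Mixing: scalp channels weight the volume-conducted subcortical source
1.0 and the cortical source 0.35; the cortical-surface channel reverses
that (0.2/1.0); laminar contacts carry a flat 0.3 subcortical term plus a
negative-Gaussian cortical profile (SD 200 µm) centred at the granular
depth (default 900 µm), which yields a CSD sink there with opposite-sign
flanks. Noise is 1/f (exponent 1) at 2 µV RMS per trial against 1 µV RMS
signal — per-trial SNR ≈ 0.5, the regime in which trial averaging is
actually needed — plus 60 Hz line harmonics (0.5/0.25/0.125 µV) and a
0.2 µV stimulus artifact on scalp channels that flips sign with polarity,
which is exactly the component polarity averaging must cancel. Default
recording rate 8 kHz: high enough for MUA extraction (300–3000 Hz band)
and for ~2 Hz pitch-lag resolution near 110 Hz, small enough to keep a
full simulated session in memory.

What the generator does **not** emulate: trial-to-trial latency jitter,
adaptation across the session, correlated noise between channels beyond
the shared sources, species-specific head geometry (montage weights stand
in for it), and background oscillations. Passing tests therefore
demonstrate correctness of the analysis chain under a plausible
generative model, not performance guarantees on any particular species'
recordings.

# Preprocessing and statistics

Line noise is removed by least-squares sine/cosine regression at the line
frequency and harmonics — unlike a notch filter this leaves neighbouring
frequencies untouched. Filtering is third-order Butterworth applied
forward-backward (zero phase), defaulting to a 70 Hz high-pass: below the
lowest stimulus F0 (89 Hz) but above the low-frequency noise bulk.
Artifact rejection drops any raw epoch whose peak |amplitude| exceeds the
threshold (75 µV human sEEG, 35 µV human scalp, 250 µV animal), evaluated
per analyzed channel *before* any averaging. The fixed stage order is
line removal → filter → reject → polarity-balanced average.

The FFR SNR is `RMS(0–250 ms) / RMS(−25–0 ms)` of the averaged response.
Significance uses a trial bootstrap of the *studentized* paired statistic
on per-trial window RMS values: resample trials with replacement, compute
the paired t of (response RMS − baseline RMS), and report the fraction of
resamples at or below zero. The studentized form is approximately
pivotal; an unstudentized RMS-difference bootstrap is visibly
miscalibrated at n ≈ 24 trials (its p-values bunch in mid-range), which
the test suite's null-uniformity check would catch. Paired comparisons
between conditions use sign-flip permutation of the Wilcoxon signed-rank
statistic, enumerated exhaustively for n ≤ 12 pairs.

# ITPC

Each trial is decomposed with complex Gaussian-envelope wavelets, every
coefficient is normalized to a unit vector, unit vectors are averaged
across trials, and the resultant magnitude is the ITPC. The default grid
is 130 frequencies from 70–200 Hz. "Equal widths" across frequency is
read as equal *temporal* width (fixed σ_t = 15 ms, i.e. ~10.6 Hz spectral
SD) — the plainest reading — with constant-cycles Morlet available via
`width = "cycles"`. Coefficients below machine precision are excluded
from the resultant rather than becoming NaN unit vectors, and values are
clamped to [0, 1] against rounding. ITPC is exactly 1 for identical
trials and invariant to per-trial amplitude scaling; both are tested.

# Pitch tracking and decoding

Pitch is tracked by normalized autocorrelation in 40 ms windows stepped
by 10 ms, searching 80–180 Hz (the printed F0 span 89–140 Hz with
margin); none of these values are documented for the original analysis,
so they are package defaults chosen to hold ≥ 2 periods of the lowest
search F0 per window. Strength is the maximum correlation coefficient;
windows below 0.3 are unvoiced. Parabolic lag interpolation is off by
default so the reported F0s are grid-exact; when enabled it never moves
an estimate by more than one lag step.

The decoder trains one left-to-right hidden Markov model per tone on
(F0, ΔF0) feature sequences: 4 states, diagonal-covariance Gaussian
emissions, 20 Baum-Welch iterations, variance floor 1 Hz². This is the
minimal topology that tracks level, monotone and dipping contours. The
HMM and Infomax ICA are implemented in the package itself (R's installed
ecosystem here provides neither), and both are validated against
independent oracles in the tests rather than against other libraries.
Averaging size k (pseudo-trials = disjoint random groups of k trials,
polarity-balanced) trades trial count for SNR; accuracy is monotone
nondecreasing in k on simulated data. Cross-validation is leave-one-out
by default — no pseudo-trial ever contributes to both training and test —
with stratified k-fold as a faster option. Ties in log-likelihood go to
the lowest tone index and are counted.

# RSA

Similarity between confusion matrices is the Pearson correlation over
the 12 off-diagonal cells (diagonals removed, so only the *pattern of
confusions* counts), with significance from 10,000 cell-permutation
shuffles — permutation rather than a parametric t because n = 12 cells.
For the confusion-space picture, each matrix is embedded by classical MDS
of the symmetrized dissimilarity `1 − (c_ij + c_ji)/2` (one 2-D
configuration of the four tones per matrix), and all configurations are
Procrustes-aligned (rotation, scale, translation) to the first. Whether
the original analysis used metric or non-metric scaling is unstated;
classical (metric) MDS is used because a 4-point configuration gives
non-metric stress majorization too little data to be stable.

# Scalp-cortex spectrotemporal comparison

Welch PSDs (1024-point Hamming windows, 50% overlap) are averaged over
the four tones and normalized so the maximum — in practice the F0 peak —
sits at 0 dB, making harmonic decay directly comparable across levels.
Cross-spectral density magnitude (same Welch scheme) quantifies shared
power irrespective of latency; it is power coherence, not phase-locking.
Frequency-wise latency comes from cross-correlating the real parts of
Morse-wavelet band signals (γ = 3, β = 20, the common time-bandwidth
default; only the wavelet family is documented) with the Pearson
(per-window-normalized) correlation form. Lags are searched within
±30 ms — wide enough for every plausible scalp-cortex latency gap, narrow
enough to limit cycle-slipping — and any |lag| of one period or more at
that frequency is flagged period-ambiguous rather than silently trusted.
Positive lag means cortex lags scalp.

# Laminar CSD

The LFP is smoothed along depth with a Gaussian (SD 250 µm at 150 µm
spacing; 125 µm for 60 µm-spaced alternate contacts) and the CSD is the
negative second spatial finite difference, so sinks are negative — the
convention is stated in the object's print method because sign ambiguity
is the classic CSD reading error. Edge contacts are dropped rather than
padded: the no-padding estimator is the only one whose value at every
reported depth is a pure function of measured data. The earliest
post-onset sink is the first crossing below k = 3 baseline SDs (no
numeric criterion is documented; 3 SDs is the conventional detection
threshold) that *stays* below threshold for ≥ 1.5 ms — the duration
requirement suppresses single-sample noise excursions that would
otherwise always win "earliest". On noiseless simulations the detected
sink falls exactly at the granular depth; with default noise it stays
within one electrode. Stimulus-CSD correlations keep the sign of r so
polarity flips across layers remain visible. The MUA chain is the
standard 300–3000 Hz bandpass, full-wave rectification, 200 Hz low-pass.

# ICA source attribution

The averaged FFRs of all four tones, concatenated in time, are reduced by
PCA to the smallest subspace holding the configured variance (96%/99% are
the documented retention levels) and unmixed by natural-gradient Infomax
with a logistic nonlinearity, seeded initial rotation, and learning-rate
annealing on oscillation. Components are reported in descending order of
total PVAF (percent variance accounted for,
`100·(1 − var(x − back-projection)/var(x))`) so numbering is reproducible
regardless of convergence order; spatial weights are the pseudoinverse of
(unmixing × sphering). Components explaining < 10% of total variance are
excluded from labeling. Labels follow two rules with documented
thresholds: latency versus the stimulus waveform ≤ 6 ms *and* a flat
spatial profile (SD/|mean| of intracranial weights ≤ 0.5) ⇒ putative
subcortical (a distant, volume-conducted generator projects almost
uniformly); latency > 6 ms *and* a steep gradient ⇒ putative cortical;
anything else unclassified. The 6 ms cut sits between the documented
subcortical (≤ 4.1 ms) and cortical (≥ 10.5 ms) component latencies.
Latency uses the stimulus waveform as reference (the documented choice),
measured on a falling-contour tone because a varying F0 breaks the
period ambiguity that a level tone leaves in waveform cross-correlation;
the envelope is available as an option. Labels are invariant to component
sign flips and reordering, which the suite asserts.

# Numerical and size choices

Problem sizes in the tests and acceptance script are desk-scale by
design: 200 trials/tone for the decoding benchmark (12 pseudo-trials per
tone at k = 16), 20-seed repetition for ICA labeling, 200 replicates ×
1000 bootstrap resamples for the p-uniformity check. The bundled
fixtures are all generated in code at run time; nothing is shipped as
data. Determinism: every stochastic call is governed by an explicit seed
(`forward_model_config(seed=)`, per-function `seed` arguments), and
rerunning any pipeline with the same config reproduces byte-identical
numeric outputs.

# Known limitations

- The forward model's two sources are deterministic responses plus
  noise; real generators add jitter, adaptation, and background rhythms,
  so ICA separation here is cleaner than on real data at matched SNR.
- Infomax assumes independent sources; strongly correlated generators
  (e.g. two pure harmonic stacks to the same stimulus) are not exactly
  separable by any independence criterion, and the decomposition then
  returns mixtures. The spatial-gradient/latency labels remain
  meaningful only when separation succeeds.
- The CSD is the unscaled second spatial difference (conductivity-based
  inverse methods such as iCSD/kCSD are out of scope), so units are
  relative.
- The HMM decoder operates on pitch tracks only; decoding from raw
  waveforms or spectrograms is out of scope.
- Electrode localization, acquisition tooling, and figure-level
  replication of in-vivo datasets are out of scope.
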