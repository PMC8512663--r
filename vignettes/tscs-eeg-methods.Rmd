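---
title: "Methods: simulating and suppressing spinal-stimulation artifacts in EEG"
author: "tscseeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and suppressing spinal-stimulation artifacts in EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcutaneous spinal cord stimulation (tSCS) delivers 30 Hz trains of ten
100 µs biphasic pulses through a cathode over the cervical spine. Volume
conduction carries a scaled copy of every pulse train into simultaneously
recorded EEG, producing narrow, high-amplitude peaks whose spectral power
is concentrated at the stimulation frequency — squarely inside the
sensorimotor band an experimenter usually cares about. `tscseeg` asks, on
fully synthetic data, the three questions such a recording setup raises:
how does the artifact distort time-domain summary statistics of EEG; can
standard suppression filters return contaminated EEG to statistical
similarity with stimulation-free EEG; and does the artifact (or its
removal) impair movement classification from sensorimotor rhythms?

Because no public recordings exist for this paradigm, the package's
generator is a first-class, tested component: every evaluation in the
package runs end-to-end on data whose ground truth is known.

## The synthetic recordings

A simulated session is `background + rhythms (+ artifact)` on the
19-channel 10-20 montage at 1200 Hz, in µV throughout.

**Background.** Per-channel independent 1/f noise (default RMS 5 µV,
spectral exponent 1) plus a shared-phase alpha oscillation whose amplitude
follows the eyes state (3 µV open, 10 µV closed — the Berger effect). The
alpha component is by default a stable spectral line (`alpha_bandwidth =
0`, random phase): the individual-alpha-frequency analysis compares argmax
positions at FFT-bin resolution, and only a line component keeps the peak
of a session pair stable at that scale. Real alpha is ~1 Hz wide;
`alpha_bandwidth` exposes that realism at the cost of a few bins of peak
jitter.

**Artifact.** The pulse train runs on the stimulator's own clock at
`burst_rate * (1 + clock_drift)`; each burst packs ten 100 µs biphasic
pulses back-to-back (a 1 ms burst with 10 kHz intra-burst rate). The train
is synthesised on a 100x-oversampled grid and point-decimated — no
anti-alias filter, because none exists between stimulator and scalp. At
1200 Hz and 30 Hz the artifact period is exactly 40 samples, so with a
locked clock every burst is sampled at identical phases; the default
relative clock offset of 1e-4 makes the sampling phase slide through the
burst in ~8 s, which is the aliasing mechanism behind the slowly modulating
artifact amplitude such recordings show. Note that the *raw* decimated
samples of an ideal rectangle always catch the full ±amplitude (the 1.2
sample-wide burst cannot fall between 0.83 ms-spaced samples); the
modulation becomes visible once the acquisition band-pass smears each
burst's sampled net charge, so envelope checks are performed on the
band-passed artifact (measured max/min peak ratio ≈ 15 over 90 s).

Per-channel amplitude is `intensity x channel_gain`, with the default gain
profile decaying exponentially with anterior–posterior distance from the
stimulation site (Oz closest, Fz farthest; Oz/Fz amplitude ratio 3). The
absolute scale (1.6 µV/mA at Oz) was calibrated once so that the cohort's
28–32 Hz power increase at Oz lands near +900 % at the default 40 mA — the
spatial-contamination surface this package treats as its primary anchor. A
single linear gain cannot simultaneously reproduce the ~4-fold Oz
peak-to-peak increase reported anecdotally at 10 mA; that would need ~3x
more gain, and the discrepancy is inherent to a linear impulse-train model
of what is, at the scalp, partly an amplifier/electrode nonlinearity. We
chose the spectral anchor and document the time-domain ratio as smaller
than in the human data.

**Movement sessions.** 30 trials per class of cued right-hand versus
bimanual finger flexion, 4 s movements, randomised 1.5–2.5 s inter-trial
intervals. Sensorimotor mu (10.5 Hz, 2 Hz bandwidth, 12 µV) and beta
(22 Hz, 4 Hz bandwidth, 5 µV) rhythms sit over the lateral hand areas;
during movement their band power drops by `erd_depth` (default 0.5) in the
left hemisphere for right-hand trials and bilaterally for bimanual trials.
The bandwidths matter more than the amplitudes: a 2 s classification
window sees roughly `2 x bandwidth x T` independent amplitude draws, so an
unrealistically narrow rhythm makes log-variance features fade-limited
regardless of SNR. These values were calibrated once so the artifact-free
cohort reproduces the ~76 % CSP-LDA accuracy reported for executed
movement. Two forearm EMG channels carry 20–500 Hz noise (2 µV RMS at
rest) with 60 µV bursts starting 0–300 ms after the cue on the moving
side(s).

**Session pairs.** `compose_paired_sessions()` emulates a two-day
crossover: the structured content (alpha draws, cue schedule, rhythm
waveforms, EMG) comes from identical generator draws, while each session
redraws its broadband noise and receives a small physiological jitter
(log-normal ±20 % on amplitudes, ±15 % on noise RMS, ±0.08 on the spectral
slope — the order of published test-retest variability of resting EEG
measures). Without that jitter the paired variance is so small that even a
filter's per-mille distortion of artifact-free EEG tests significant,
which no real two-session study could detect. `shared_noise = TRUE`
disables both, giving a pair that differs from its partner by the artifact
alone — the configuration used for exact-additivity checks and for
isolating the artifact's effect on the alpha peak.

## The four suppression filters

All four operate per channel and could run in a streaming setting; the
centred template of the first implies an explicit look-ahead of three
stimulation periods.

* **Superposition of moving averages (SMA).** The channel is split into
  consecutive 40-sample windows (one stimulation period); each window has
  subtracted from it the mean of the six windows centred on it (three
  before, itself, two after — the symmetric reading that preserves the
  printed divisor of 6). The template is recomputed per window and tracks
  slow changes in artifact shape. Its frequency response is a comb with
  ~5 Hz-wide nulls at every multiple of 30 Hz: periodic artifacts vanish,
  but so does genuine 28–32 Hz content, which is why the filtered 30 Hz
  topography overshoots below the stimulation-off level (as the human data
  also show for this family of filters). On artifact-free white noise the
  output variance is analytically 30/36 of the input.
* **Self-referenced adaptive filter.** Each 40-sample frame is predicted
  as a least-squares combination of the six previous frames and the
  prediction subtracted; the weights are re-solved per frame, minimising
  residual energy. Anything predictable one stimulation period ahead is
  removed — including genuine narrowband rhythms. On the synthetic
  recordings, whose 3–50 Hz content is very smooth at 1200 Hz, the filter
  removes nearly all EEG, an exaggeration of the tendency that also makes
  it the one filter that destroys classification performance. Singular
  normal equations fall back to a pseudo-inverse solution (logged, never
  an exception).
* **Median filter.** Centred running median over 7 samples (~6 ms),
  shrinking windows at the record edges; removes spikes up to 3 samples
  wide exactly, at the cost of underestimating high-frequency content.
* **Band-stop ("notch") filter.** 3rd-order Butterworth, 29–31 Hz,
  zero-phase. Attenuates only the fundamental; burst harmonics outside
  29–31 Hz pass.

Zero-phase filtering throughout is implemented by applying the squared
Butterworth magnitude response on the FFT grid — the transfer function
forward–backward filtering realises, up to boundary transients, at a
fraction of the cost for long multi-channel records. Printed cutoffs are
kept; effective order doubles.

## Evaluation layers

**Descriptive statistics.** Kurtosis (Pearson, m4/m2², Gaussian reference
3), RMS (no mean removal; input is 3 Hz high-passed), Higuchi fractal
dimension (k_max = 10, slope of log mean curve length versus log 1/k), and
zero crossings per 10 s (strict sign changes, zeros inheriting the
previous sign). Each channel is split into 10 s non-overlapping segments;
statistics are computed per segment, averaged within a recording, then
across subjects. Eyes-open recordings feed this analysis.

**Spectral analysis.** Multitaper PSD with Slepian tapers at 0.1 Hz half
bandwidth (NW = 9 for 90 s records, 17 tapers). Tapers come from the
standard symmetric tridiagonal eigenproblem; for records longer than 1024
samples they are computed at length 1024, spline-interpolated and
re-orthonormalised — the classical approximation, adequate because the
low-order tapers are smooth (measured in-band concentration ≥ 0.95 for all
17). "30 Hz power" is always the 28–32 Hz trapezoidal band integral.
Contamination is expressed as `100 x (on - off) / off` per channel, on the
seven midline electrodes, eyes closed. The individual alpha frequency is
the PSD argmax in 8–12 Hz; note that the multitaper estimate of a line
component has a ~0.2 Hz-wide plateau that is flat to ~0.05 %, so argmax
differences of a few FFT bins (~0.01 Hz each) between two estimates are
numerical conditioning, not physiology — the package therefore tests the
artifact's effect on the alpha peak with shared-noise pairs (exact
isolation) and treats the cohort-level question with one-way ANOVAs, as
the original analysis did.

**Hypothesis testing.** Two-sided throughout. A Shapiro–Wilk gate at
α = 0.05 on paired differences routes each comparison to a paired t-test
or a Wilcoxon signed-rank test (exact null for n ≤ 25 without ties);
families of p-values are Benjamini–Hochberg adjusted. Factorial
condition x electrode effects use the Scheirer–Ray–Hare rank test with the
`SS_effect / MS_total` statistic against chi-square, subjects entering as
replicates (the paired structure is ignored, as in the original analysis —
a documented limitation). Levene's test uses median centring.

**Movement classification.** Epochs −2 to 6 s around EMG-envelope onsets
(20–500 Hz band-pass, rectification, 10 Hz low-pass; onset = first span
0.1 s above rest mean + 2 SD within 1.5 s of the cue), cropped to
0.5–2.5 s. CSP on trace-normalised class-average covariances (diagonal
loading 1e-9 of the mean diagonal if rank-deficient, logged), six filter
pairs, log-variance features, plain LDA, stratified 10-fold
cross-validation with CSP and LDA refit per fold (leakage-free, possibly
stricter than the original). The chance level is the smallest k/n with an
upper binomial tail below α — 66.7 % (printed as 67 %) for 30 trials.

## Problem sizes and determinism

The canonical cohort is 21 simulated subjects, 90 s resting records, 30
movement trials per class — the study conditions. The analysis drivers and
the acceptance script run that full size; the test suite runs the resting
cohort at full size and the movement cohort at 12 subjects, the package's
test problem size. Every random draw derives from a single base seed
through a deterministic child-seed map, so identical configurations
reproduce byte-identical result files.

## Known limitations

* The artifact model is linear; amplifier saturation, slew limiting and
  electrode polarisation — which shape real tSCS artifacts between pulses —
  are not modelled. Time-domain artifact prominence is correspondingly
  smaller than in human recordings at matched intensity.
* The synthetic EEG is smoother and more predictable than real EEG; the
  self-referenced adaptive filter consequently over-suppresses it, and the
  within-pair variance of amplitude-invariant statistics (kurtosis,
  Higuchi dimension) is several times smaller than real day-to-day
  variability. Two SMA-restoration comparisons at Oz remain statistically
  distinguishable on the synthetic cohort for exactly this reason, where
  the human data found none.
* No lateralised artifact asymmetry, no volume-conduction model, no
  eye-blink or movement artifacts.
* Passing tests on this generator show the pipeline's statistics and
  filters behave correctly under a known ground truth; they do not certify
  performance on human recordings.
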