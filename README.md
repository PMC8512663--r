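# tscseeg

Tools for asking whether EEG remains usable while transcutaneous spinal
cord stimulation (tSCS) is being delivered. Cervical tSCS injects 30 Hz
trains of ten 100 µs biphasic pulses through the skin of the neck; volume
conduction puts a scaled copy of every train into simultaneously recorded
EEG as narrow, high-amplitude peaks whose power sits at the stimulation
frequency — inside the sensorimotor band. The package is written for
neural-engineering and BCI researchers who need to know (a) how badly such
an artifact distorts standard EEG measures, (b) whether real-time-capable
suppression filters can repair it, and (c) whether movement decoding from
sensorimotor rhythms survives it.

No public recordings exist for this paradigm, so the package ships a
tested synthetic-data generator that emulates the acquisition end-to-end —
19-channel 10-20 EEG at 1200 Hz (1/f background, eyes-state-dependent
alpha, lateralised event-related desynchronisation during cued movements),
forearm EMG with movement bursts, and the tSCS artifact itself with its
distance-dependent spatial gain and the slow amplitude modulation caused
by sampling an unlocked stimulator clock — and evaluates everything
against that known ground truth.

## What is implemented

**Artifact model.** Pulse trains at `burst_rate (1 + clock_drift)`,
synthesised on an oversampled grid and point-decimated with no anti-alias
filter; per-channel amplitude `intensity × gain(channel)` decays
exponentially with distance from the neck-posterior stimulation site
(Oz most contaminated, Fz least).

**Four suppression filters** (per channel, streaming-capable):

* *Superposition of moving averages* — each stimulation-period window `n`
  of the signal `x` has a running template subtracted:
  `X(n) = x(n) − (1/(M+1)) Σ_{k=n−⌈M/2⌉}^{n+⌊M/2⌋} x(k)`, with `M = 5`
  and 40-sample windows at 1200 Hz / 30 Hz.
* *Self-referenced adaptive filter* — per frame, the least-squares
  predictor `ŷ(n) = Σ_{j=1}^{M} b_j x(n − jN)` over the `M = 6` previous
  stimulation periods (`N = 40` samples) is subtracted, minimising
  residual frame energy; it uses no stimulator reference signal.
* *Sliding median*, 7 samples (~6 ms), shrinking at record edges.
* *Band-stop Butterworth*, 29–31 Hz, 3rd order, zero phase.

**Evaluation layers.** Time domain: kurtosis, RMS, Higuchi fractal
dimension and zero crossings on 10 s segments, compared across conditions
with a Shapiro–Wilk-gated paired-t/Wilcoxon layer, the Scheirer–Ray–Hare
rank test for condition × electrode effects, and Benjamini–Hochberg FDR.
Frequency domain: Slepian multitaper spectra (0.1 Hz half bandwidth),
28–32 Hz band power expressed as `100 (P_on − P_off)/P_off` along the
midline, and the individual alpha frequency (8–12 Hz argmax). Movement
decoding: CSP via the generalised eigenproblem extremising
`w X₁X₁ᵀ wᵀ / w X₂X₂ᵀ wᵀ` (six filter pairs), log-variance features, LDA,
stratified 10-fold cross-validation, and the exact binomial chance level.
EDF/EDF+ input and output (16-bit, annotation-based events) round out the
I/O.

## Worked example

A paired resting session (stimulation off/on, eyes closed) for one
simulated participant, with the midline contamination profile:

```r
library(tscseeg)

pair <- compose_paired_sessions(background_spec(), erd_spec(),
                                stim_profile(intensity = 40), seed = 7,
                                task = "rest_eyes_closed", duration = 90)
prof <- midline_30hz_profile(preprocess_recording(pair$on),
                             preprocess_recording(pair$off),
                             filters = c("sma", "notch"))
subset(prof, method == "raw")
#>   method channel rank change_pct
#> 1    raw      Fz    6   50.89919
#> 2    raw     FCz    5   85.19486
#> 3    raw      Cz    4  140.43563
#> 4    raw     CPz    3  264.94152
#> 5    raw      Pz    2  373.43366
#> 6    raw     POz    1  523.03049
#> 7    raw      Oz    0  787.65999
```

Stimulation raises 28–32 Hz power by ~50 % at the channel farthest from
the stimulation site and by ~790 % at the closest for this participant,
growing monotonically along the midline (the cohort average at Oz is
around +1000 %). The full 21-subject analyses are driven by the numbered
scripts:

```sh
Rscript analysis/01_artifact_characterisation.R
Rscript analysis/02_resting_state_analysis.R
Rscript analysis/03_movement_classification.R
```

`03_movement_classification.R` ends with the decoding table (cohort means
of 10-fold CSP-LDA accuracies):

```
        condition mean_acc sd_acc  p_vs_off p_adjusted chance_level_pct
         tscs_off    75.97  9.106        NA         NA            66.67
          tscs_on    76.41  7.578 6.670e-01  6.958e-01            66.67
      tscs_on_sma    78.48  6.275 9.787e-02  2.447e-01            66.67
 tscs_on_adaptive    56.70  7.703 7.913e-06  3.956e-05            66.67
   tscs_on_median    76.41  7.863 6.720e-01  6.958e-01            66.67
    tscs_on_notch    76.41  7.248 6.958e-01  6.958e-01            66.67
```

Read: the raw artifact does not impair decoding (76.4 % vs 76.0 %,
p ≈ 0.7), SMA/median/notch filtering preserves it, and the
self-referenced adaptive filter — which removes everything predictable
one stimulation period ahead, genuine sensorimotor rhythms included —
drives accuracy toward chance (56.7 %, p ≈ 4e-5). All tables land under
`results/`.

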