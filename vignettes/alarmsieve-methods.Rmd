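---
title: "alarmsieve: model, losses and the synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alarmsieve: model, losses and the synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmsieve)
```

## The problem

Bedside monitors in intensive care raise arrhythmia alarms with very high
sensitivity and correspondingly poor specificity: most asystole,
bradycardia, tachycardia, ventricular-tachycardia and ventricular-flutter
alarms are false, triggered by motion artifact, electrode noise or signal
dropout rather than by a real rhythm change. `alarmsieve` classifies a
triggered alarm as true or false using only the five minutes of
multi-channel waveform data available *before* the alarm onset (two ECG
leads plus at least one pulsatile channel, PPG or ABP, optionally RESP,
all at 250 Hz) — the real-time setting of the PhysioNet/CinC Challenge
2015, scored as

$$\mathrm{score} = \frac{TP + TN}{TP + TN + FP + 5\,FN},$$

so that a suppressed true alarm costs five times a surviving false one.

## Model

The **signal encoder** is a 1-D CNN with four parallel blocks of kernel
sizes 50, 100, 200 and 400 samples (0.2 s to 1.6 s at 250 Hz). Each block
applies dropout to its input (training only), then twice
convolution(stride 5, zero 'same' padding) → batch normalization → ReLU,
then a global max over time, yielding 64 values per block and an encoder
output $E_e$ of $S_e = 4 \times 64 = 256$ features. The input is the
**alarm segment**: the final 10 s before onset ($5 \times 2500$ after
zero-imputation of missing channels and per-channel min–max scaling to
$[0,1]$ over the pre-onset window).

Two fully connected side-channels join the encoder output: an
**alarm-type embedding** $E_a = A W_a$ (one-hot type $A$ selecting a row
of a trainable $5 \times 64$ matrix) and a **rule embedding**
$E_r = R\,W_r$, the scalar output $R \in [0,1]$ of a rule-based verifier
scaling a trainable 64-vector. The classifier is a single sigmoid unit on
the concatenation:

$$O = \sigma\!\big(\mathrm{concat}(E_e, E_a, E_r)\, W_c + b\big).$$

### Siamese discriminative constraint

Each record also yields a **baseline segment** — a 10-s window sampled
uniformly before $t - 10$ s — encoded by the *same* encoder (shared
parameters are structural: there is one parameter store). With features
$f_A, f_R$ and $d = f_A^\top f_R$:

* false alarm: $C_\mathrm{false} = -\log \sigma(d)$ (the "event" should
  look like the patient's own baseline),
* true alarm: $C_\mathrm{true} = -\log \sigma(-d)$ (it should not),
* batch: $C = \tfrac{1}{N_1}\sum C_\mathrm{false} +
  \tfrac{1}{N_2}\sum C_\mathrm{true}$, a class absent from a batch simply
  contributing nothing (mini-batches of one class occur under class
  imbalance; erroring would be wrong).

The total objective is $L = L_\mathrm{BCE} + w\,C$ with $w = 1.5$, where
$L_\mathrm{BCE}$ weights positive (true-alarm) terms by 1.5 to counter
the roughly 1.5:1 negative:positive imbalance. Baseline segments are
resampled every epoch from a seeded stream — pairing one fixed alarm
segment with many baseline windows acts as data augmentation; a frozen
mode (`baseline_mode = "frozen"`) exists for exact reproducibility
studies.

Optimization is Adam (lr 0.001, L2 $5\times10^{-4}$ applied to
convolution and linear weights only — not biases, not BN parameters),
mini-batch 256, up to 1000 epochs, dropout 0.8 — all configurable through
`train_config()`, whose defaults are exactly these published values.
Final-epoch parameters are kept (no early stopping is described for the
original procedure).

### Numerical choices

* Convolutions use zero 'same' padding with output length
  $\lceil T/\mathrm{stride} \rceil$; the source gives kernel and stride
  but no padding rule, and 'same' keeps the 400-sample kernel valid on
  2500-sample inputs.
* Classification uses only the alarm-segment feature; the baseline
  feature feeds the constraint alone. A bias term is included in the
  classifier (zero-initialized) although the architecture equation omits
  it.
* The constraint consumes the raw 256-d encoder outputs with no
  projection head; the notation admits either reading and the simpler one
  was chosen.
* $-\log\sigma(x)$ is evaluated in its numerically stable form; BCE
  probabilities are clamped at $\varepsilon = 10^{-12}$.
* Ties at the decision threshold 0.5 classify as *true* — the
  conservative direction given the 5× FN penalty.
* Initialization is uniform fan-in scaling for conv/linear weights,
  $U(-0.1, 0.1)$ for embeddings, seeded; the source is silent here.
* The compiled core computes in single precision; gradients are verified
  against central finite differences of the total loss (conv biases are
  provably gradient-free because BN follows every convolution and absorbs
  constant shifts — they are retained only for fidelity to the stated
  parameterization).
* Batch-norm running statistics (momentum 0.1) serve inference;
  training always uses batch statistics.

## The rule scorer

The original system fed the output of an established rule-based Challenge
entrant into the rule embedding. That exact algorithm is not reproduced;
instead `evaluate_rules()` is a *reference implementation* of the five
alarm definitions, and any callable `record -> [0,1]` can be plugged in
(`rule_scorer("plugin:file.R")`, `"constant:v"`, or a function).

`detect_beats()` band-passes (5–25 Hz for ECG, 0.5–8 Hz with half-wave
rectification for pulsatile channels — high-passed pulses are biphasic
and would double-count), squares, integrates over 150 ms and picks peaks
adaptively (threshold 0.2× the 98th percentile, 250 ms refractory).
Channel quality: *flat* when the amplitude range (whole window or final
10 s) is below 0.01 on the normalized scale; *noisy* when strong
candidate peaks exceed a 300 bpm-equivalent ceiling in any 2-s window or
when the integrated energy sits above threshold more than 80% of the
time (broadband noise has no duty cycle; rhythms do).

Per-type tests on the final 10 s: ASY — any 4-s beat-free window; EBR — a
run of ≥ 5 beats below 40 bpm; ETC — a run of > 17 beats above 140 bpm;
VTA — a run of > 5 widened beats above 100 bpm, "wide" meaning the
half-max width of the squared, locally de-trended *raw* waveform around
the beat exceeds 1.5× the channel median (band-passing erodes exactly the
width excess being measured, so width is not taken from the filtered
energy); VFB — at least half of the 0.5–25 Hz spectral power inside
3.5–6.5 Hz over the trailing 4.5 s (an energy beat detector cannot
distinguish fibrillation cycles from beats, so the spectral signature
replaces the "no discrete beats" phrasing). The score is 0.9 if any
usable channel satisfies the record's definition, 0.1 if none does, 0.5
if no channel is usable — discrete levels because the embedding layer
only scales a learned vector, so only the ordering matters; the levels
are configurable.

## Synthetic test-bed

`generate_record()` builds records that reproduce the *timing statistics*
of the five alarm definitions, not ECG morphology: Gaussian-bump QRS
(σ ≈ 17 ms, small P/T waves), quasi-periodic baseline rhythm with heart
rate uniform in 60–100 bpm and 3% interval jitter, pulsatile channels as
smooth pulses lagged 200 ms (a nominal pulse-transit delay), RESP a
0.25 Hz sinusoid; channels carry random gains/offsets (normalization must
undo them) and PPG/ABP/RESP are present with probability 0.7/0.6/0.3
(at least one pulsatile channel always).

True alarms end at onset with the type's signature: a 4.5–5.5 s pause
(ASY); 7 beats at 36–39 bpm (EBR); 20 beats at 150–180 bpm (ETC); 8
inverted beats of doubled width (σ = 35 ms ≈ a 140 ms QRS) at
120–160 bpm with attenuated pulses (VTA); a 4.2–5.8 Hz
amplitude-modulated oscillation replacing beats and pulses for 4.5–5.5 s
(VFB). Every count leaves at least one beat of margin over its
definition's threshold so a single detector miss does not flip the
ground truth. False alarms keep the normal rhythm and corrupt one channel
inside the final 10 s with one seeded artifact: a 2–4 s noise burst,
baseline wander (0.3 Hz, large), an 8 Hz spike train, or a flattened
lead — the flat span starts ~12 s before onset so the channel is
recognizably dead in the decision window, which is how false asystole
alarms actually arise; a mid-window flat gap would be indistinguishable
from a real pause in noise-free data.

What a green synthetic run does **not** establish: performance on real
monitor data (morphology variation, inter-patient differences,
non-stationary noise, mislabeled channels), calibration of the
probabilities, or the published headline scores — the hidden Challenge
test labels are not distributed. The synthetic world is deliberately
separable; it validates the machinery (windows, losses, sharing,
optimization, scoring), not clinical performance.

## Desk-scale acceptance run

The end-to-end recovery check trains the tiny encoder (8 filters per
block, the published kernels) on 400 clean balanced records (60 s,
250 Hz, noise SD 0.02, 50% true alarms) with fivefold cross-validation,
full configuration versus basic (encoder + alarm embedding) on matched
folds and seeds. The published optimizer settings assume ~2500 Adam steps
(1000 epochs over 600 records at batch 256); the desk run has a 100-epoch
ceiling and uses 12 epochs × 7 batches ≈ 60 steps, so the learning rate
is scaled to 0.01 and dropout to 0 (an 8-filter encoder on clean,
separable data neither needs nor tolerates 0.8). These scaled values
live only in the acceptance test; `train_config()` defaults remain the
published ones.

## Known limitations

* The reference rule scorer is tuned to the synthetic morphology; on real
  records its discrete 0.1/0.5/0.9 output is a crude stand-in for the
  original rule engine — the plug-in interface exists precisely so a real
  verifier can be substituted.
* WFDB support covers the header + format-16 subset (the Challenge's
  `.mat` containers need conversion).
* Only the real-time event is implemented (records truncated at onset);
  the retrospective +30 s variant is out of scope, as are resampling of
  non-250 Hz inputs and alarm types beyond the five.
* Single-precision training is deterministic on a fixed BLAS but not
  bit-portable across BLAS implementations.
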