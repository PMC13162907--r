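---
title: "Pig vocalization classification with a time-frequency decoupled Conformer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pig vocalization classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by SwineVox, the
choices that were genuinely open during its design, and what the synthetic
test substrate does and does not establish about real barn recordings.

## Problem setting

Continuous acoustic monitoring of group-housed pigs supports early detection
of respiratory disease (coughing), acute stress (screams) and reproductive
receptivity (estrus calls), and works in the dark and under occlusion where
cameras fail. The task here is clip-level classification of 1–2 s segments
into five classes: cough, scream, estrus, feeding, normal. Two properties of
barn audio drive the design:

1. **Non-stationary broadband noise** (ventilation, feeders, pen friction)
   overlaps the low-frequency classes; feeding versus normal background is
   the canonical confusion pair.
2. **Strong within-session correlation.** Clips recorded in the same pen,
   on the same date, in the same session share a background sound field.
   Random sample-level splits let a model exploit that shared background,
   inflating accuracy. Every protocol in this package therefore splits by
   compound group keys.

## Front end

Clips are resampled to 16 kHz, peak-normalized and converted to
80-band log-Mel spectrograms with 25 ms frames and a 10 ms hop over
0–8 kHz. Framing uses **no center padding**, so the frame count is exactly
`T = 1 + floor((N − 400)/160)`; this makes shape arithmetic analytically
checkable in tests. The log uses an additive floor of `1e-10` on mel power,
keeping all-zero inputs finite. Peak rather than RMS normalization was
chosen because event clips have heavy-tailed amplitude distributions; the
choice only fixes a scale and is config-exposed.

Leading/trailing frames more than 40 dB below the loudest frame are trimmed;
residual quiet interior frames are flagged in a binary frame mask that
follows the clip through the network (downsampled by the front end's 2x2
pooling so it aligns with encoder frames). A uniformly silent clip raises an
error — mirroring the annotation pipeline's exclusion of unusable clips —
rather than returning an empty spectrogram.

**Spectral gating.** The adaptive noise suppression stage estimates, per mel
bin, a noise floor as the 20th percentile of that bin's frame values, and
multiplies each cell's power by a soft gain

\[ g = g_{\min} + (1-g_{\min})\,\sigma\!\big((E - 3\,\mathrm{dB})\cdot 1/\mathrm{dB}\big), \]

where `E` is the cell's dB excess over its bin floor and `g_min = 0.1`.
Cells well above the floor pass unchanged; noise-dominated cells lose up to
10 dB. Gating is deterministic, identical at train and inference time, and
bypassed by the `useGating = FALSE` ablation. The published description of
this stage leaves its hyperparameters to an appendix that is not part of the
text we worked from; the percentile/offset/slope/floor quadruple above is
this package's own minimal instantiation, chosen before any end-to-end
tuning and exposed in `gatingConfig()`. A multiplicative power gain was
preferred over compressing values towards the floor because only the
multiplicative form attenuates every sub-floor cell and keeps "high-energy
cells are attenuated less" true cell-wise.

## Network

The encoder consumes the gated spectrogram as a single-channel image.

* **Conv front end:** 3x3 convolution (same padding) to `C'` channels,
  batch norm, ReLU, 2x2 average pooling. With a per-clip batch the batch
  statistics are computed over the clip's own time-frequency cells
  (instance-style), with running averages retained for inference.
* **Triplet attention** recalibrates the `C' x F' x T'` tensor along three
  rotated axis-pair views. Each branch compresses the third axis by
  concatenated max- and mean-pooling (Z-pool), produces a sigmoid gate map
  through a 7x7 convolution, multiplies it back, and the three branch
  outputs are averaged. The branch internals (Z-pool, 7x7, sigmoid) follow
  the reference design of the triplet-attention literature since only the
  branch equations are fixed by the source.
* **Frame sequence:** each time step's `C' x F'` plane is flattened and
  linearly projected to `D`; sinusoidal positional encoding is added (a
  config switch disables it, which the permutation-equivariance test uses).
* **TFD block:** the temporal branch runs masked multi-head self-attention
  over time; the frequency branch applies, within each frame independently,
  a pointwise linear map followed by a shared 1-D convolution of odd length
  `k` along the feature axis and a SiLU. The two branches are concatenated
  channel-wise and fused by a feed-forward network projected back to `D`,
  wrapped in a residual connection and layer norm. Two blocks are stacked.
  Where the frequency information lives after flattening is an
  interpretation: we treat the projected feature axis as carrying the
  frequency-local structure, so "frequency-local convolution" becomes a
  depthwise convolution along that axis. The `useTfd = FALSE` ablation
  replaces the frequency-axis convolution with a time-axis convolution,
  recovering a standard symmetric Conformer-style block with identical
  parameter count but an entangled inductive bias.
* **Masked attentive pooling:** attention logits `W_p h_t` are softmaxed
  *only over valid frames* (masked frames receive `-Inf`), and
  `z = Σ m_t α_t h_t / (Σ m_t α_t + ε)` with `ε = 1e-8`. Computing the
  softmax over valid frames makes the mask multiplication exact: the
  embedding is bit-for-bit invariant to the content of masked frames, which
  the test suite asserts as an identity, not a tolerance.
* **AAM-Softmax head:** embeddings and class weights are L2-normalized;
  training uses the additive angular margin `m = 0.2` with scale `s = 30`,
  `θ_y + m` clamped to `[0, π]` (the `1/sin θ` factor in its gradient is
  guarded at the poles). With `m = 0` the loss reduces exactly to
  cross-entropy on `s cos θ`, a reduction the tests check against an
  independent implementation.

Unstated architecture hyperparameters default to conventional values
(`C' = 32`, `D = 128`, 4 heads, `k = 15`, FFN expansion 4, dropout 0.1) and
are all config-exposed; desk-scale runs in the tests use `C' = 4`,
`D = 64`, dropout 0 for speed and determinism.

**Gradients.** No autodiff framework is used: every layer's backward pass is
hand-written. The correctness oracle is a central finite-difference check
over sampled coordinates of every parameter tensor, run for all four
architecture variants; agreement is required to a relative error of 1e-3
(observed: ~1e-5, limited by float cancellation on analytically-zero
gradients).

## Training

Adam (initial learning rate 0.001, batch size 16, up to 100 epochs,
seed 42) minimizes the AAM loss; gradients are averaged over the batch.
Model selection is by validation Macro-F1 with earliest-epoch tie-breaking.
The published training protocol mentions scheduling and early stopping
without details; this package uses plateau reduction (factor 0.5 after 5
stale epochs) and early stopping after 15 stale epochs, both config-exposed.
No class weighting or oversampling is used — the five classes are nearly
balanced by construction. Determinism is guaranteed for single-process CPU
execution: initialization, data order and dropout draw from a seeded stream,
and regenerating any report from `(config, seed, manifest)` is bit-identical.
The harness asserts the group- and pig-exclusivity invariants of its split
before the first epoch and refuses to train on a violating split.

## Synthetic barn soundscapes

The generator emulates the documented class acoustics — cough: 0.8–3.0 kHz
transient bursts, mean 1.82 s; scream: 3.0–8.0 kHz sustained with a vibrato
harmonic tone, 1.75 s; estrus: 1.0–3.5 kHz rhythmic pulses at 4 Hz, 1.94 s;
feeding: 0.2–2.5 kHz amplitude-modulated rough noise, 1.88 s; normal:
0–1.5 kHz ambient, 1.80 s — as band-passed white noise (4th-order
Butterworth, zero-phase) shaped by the class envelope family over a barn
background of low-frequency rumble and 50/100 Hz hum. Event SNRs
(18/20/15/12/6 dB over background) are package choices on the "clearly
audible event" end of realistic; the source material quantifies only the
ambient level (60–70 dB(A)), not per-event SNR.

Group structure mirrors the acquisition design: each class's clips are
spread over a restricted pool of active pen x date x session groups (so
groups contain several correlated clips), estrus clips live in breeding
stalls with session-level groups, and 74% of cough clips are targeted
close-range recordings of 5 symptomatic pigs. Each pig's close-range clips
share one date and session — a single recording visit — which also keeps
pig-wise groups nested inside sessions so the pig constraint and
session-level LOSO splits cannot conflict. Noon sessions receive a +4 dB
background gain (evening +1 dB), injecting a midday domain shift sized so
that the noon degradation statistic on synthetic runs is positive but small,
on the scale of one macro-F1 point.

**What the synthetic data does not show.** The generator has no
reverberation, no overlapping simultaneous events, no microphone or
gain-chain variation, and its classes are more separable than real barn
recordings (synthetic grouped-CV macro-F1 reaches the high 90s, whereas
real-data numbers in this problem family are meaningfully lower and depend
on the farm). Passing the end-to-end tests therefore validates the
*machinery* — feature pipeline, gradients, leakage-aware protocols, metric
arithmetic — not field performance.

## Evaluation protocols

* **Grouped holdout (8:1:1)** and **grouped 5-fold CV** allocate whole
  groups greedily, largest groups first, with per-class target counts and an
  overflow penalty; achieved ratios are approximate by construction.
  Out-of-fold predictions (each sample scored once by the model not trained
  on its group) are tallied into the confusion matrix; reported percentages
  are row-normalized and rounded to one decimal.
* **LOSO:** one session held out as test domain; train/validation
  subdivision happens only inside the remaining sessions. The summary
  reports per-session Macro-F1, mean, sample SD (n = 3) and
  `ΔNoon = (Morning + Evening)/2 − Noon`, rounded to two decimals for
  reporting.
* **Metrics:** accuracy, per-class precision `TP/(TP+FP)`, recall
  `TP/(TP+FN)`, F1 and one-vs-rest AUROC via the rank statistic (tie-aware,
  invariant to monotone score transforms), macro-averaged without weights.
  The printed source formula for precision repeats the recall denominator;
  following its own prose ("how well the model avoids false positives"),
  standard precision is implemented. A class absent from the truth vector is
  excluded from macro averages with a warning rather than treated as zero.
* **Noise robustness:** test clips are mixed with noise-pool segments at
  fixed SNRs — the default bins `{+10, +5, 0, −5}` dB bracket the range
  where degradation accelerates — under the constraint that the noise
  segment's group differs from the clip's, and features are recomputed with
  the shared pipeline without retraining.
* **Fold-paired significance:** a two-sided Wilcoxon signed-rank test on
  fold-wise Macro-F1, with the exact null distribution computed by dynamic
  programming over (doubled) ranks so it stays exact under ties; zero
  differences are dropped with a warning. Note the exact two-sided p-value
  for n = 5 concordant folds is 0.0625 — the smallest attainable value at
  that n, which bounds what fold-level significance claims can mean there.
* **Background probe:** a ridge-regularized linear classifier on
  time-averaged log-mel features under grouped CV, reporting balanced
  accuracy and AUROC; used to check whether two recording environments are
  separable from non-event background alone (a near-chance result supports
  pooling them).

## Numerical and degenerate-input decisions

* Log floor `1e-10` on mel power; pooling `ε = 1e-8`; layer/batch norm
  `ε = 1e-5`; AAM pole guard `1e-7` on `1/sin θ`.
* `T` odd after the front end: the trailing frame is dropped by 2x2 pooling
  (and its mask bit with it).
* A frame mask that is all zero raises a no-valid-frames error at pooling;
  an all-zero waveform survives the pipeline (constant log-floor
  spectrogram) until the trim stage rejects it.
* Validation-metric ties select the earliest epoch; split allocation and
  fold assignment are deterministic functions of the seed.
* The dominant-band estimator normalizes each mel bin's mean power by its
  filter bandwidth before thresholding at 25% of the peak; without the
  normalization the widening of mel filters with frequency biases the band
  upward.

## Problem sizes used in the checks

The test suite trains reduced-width models (`C' = 4`, `D = 64`, 2 blocks):
grouped 5-fold CV on the default 500-clip synthetic dataset (seed 42), a
five-variant ablation over three seeds on a 100-clip dataset, and a
three-bin noise sweep on a held-out split — sizes at which the full suite
completes on a single CPU while still exercising every protocol end to end.

## Known limitations

* Determinism is contractual only for single-process CPU execution.
* The gating stage and several architecture constants are declared
  stand-ins for material the source text relegates to an unavailable
  appendix; they are documented defaults, not reverse-engineered values.
* The exact placement of concatenation versus residual inside the fused
  encoder block, and the use of a single feed-forward module rather than
  Conformer's half-step pair, are declared design choices.
* Real-data performance claims are out of scope: no pretrained weights, no
  baseline architectures, no farm recordings.
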