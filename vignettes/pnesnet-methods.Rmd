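---
title: "Methods: sub-band CNN discrimination of interictal ES vs. PNES EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-band CNN discrimination of interictal ES vs. PNES EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Differentiating epileptic seizures (ES) from psychogenic non-epileptic
seizures (PNES) is hard when the interictal EEG looks normal to the eye in
both groups. The pipeline implemented here asks whether a convolutional
network can separate the two groups from resting, between-seizure EEG, and —
because a bare accuracy number convinces no clinician — whether the network's
internal representations become more class-separable with depth, measured by
permutation entropy (PE).

The pipeline: 19-channel resting EEG at 256 Hz is band-passed to 0.5–32 Hz,
cut into non-overlapping 2 s epochs (512 samples), and each channel of each
epoch is decomposed into five levels of Daubechies-4 detail signals plus the
level-5 approximation (`d1..d5, a5`), each reconstructed back to 512 samples.
An epoch is therefore a 19 × 512 × 6 tensor. A small CNN (two 1 × k
convolutions along time with ReLU and 1 × 2 max pooling, then
Dense 32 → Dropout 0.3 → Dense 16 → sigmoid; 625,329 parameters) classifies
epochs (ES = 1, PNES = 0). Subjects are evaluated by leave-one-out
cross-validation: all of one subject's epochs are held out, the model is
trained on everyone else, and the subject is assigned to the class that wins
the majority of its epoch votes. Accuracy, precision, recall, F-measure and
Cohen's kappa (2 × 2 closed form, positive class PNES) summarise the
confusion matrix over subjects; the AUC uses the mean epoch probability as
the subject score.

## Permutation entropy as an interpretability probe

PE is the Shannon entropy of the distribution of ordinal patterns of `n`
consecutive values (order `n = 3`, delay 1 here): a complexity measure that
is fast, scale-free and robust to outliers. We compute it along the temporal
axis of (i) the input tensor, (ii) the post-ReLU Conv1 maps, and (iii) the
post-ReLU Conv2 maps, average over filters (over sub-bands at the input) and
over a subject's epochs, and obtain one value per subject, layer and channel
row. Per channel, an exact/tie-corrected Wilcoxon rank-sum test compares the
18 ES against the 18 PNES values. The scientific claim probed is *depth
separability*: channels that do not separate the classes at the input become
separable in deeper layers, i.e. the network concentrates class information.

Choices the source material leaves open, decided here:

* **Order 3, delay 1.** The smallest order with a non-trivial alphabet
  (3! = 6 patterns), well estimated from 512-sample series.
* **Ties rank by order of appearance** (earlier sample ranks lower). ReLU
  maps contain runs of exact zeros; a stable tie rule makes PE deterministic.
* **Filters are averaged after PE**, not before, preserving per-filter
  dynamics.
* **No multiple-testing correction** in the per-channel reporting (a
  Bonferroni flag exists), matching the per-channel reporting convention.

## The synthetic cohort: what it emulates and what it does not

No public recordings exist for this problem, so every stage is validated on
a seeded synthetic cohort (`generate_cohort()`): 18 subjects per class by
default, 214 clean 2 s epochs each, 19 channels at 256 Hz, microvolt scale
(RMS ≈ 10 µV).

Per subject and channel the background is a band-limited (0.5–32 Hz)
1/f^α Gaussian process (α ~ U(0.85, 1.15) per subject) plus an
amplitude-modulated alpha rhythm (individual frequency U(8.5, 11.5) Hz,
posterior-dominant topography, slow random envelope). Two nuisance
components, present in **both** classes with subject-specific amplitudes,
model inter-individual variability in background complexity: a broadband
0.5–32 Hz component (amplitude U(0, 0.9) × RMS) and a slow 0.5–8 Hz
component (U(0, 1.5) × RMS).

The class effect: ES subjects additionally carry an intermittent broadband
component in six frontal/central/parietal channels (F3, F4, C3, C4, P3, P4)
— white noise gated by a burst process (250 ms segments active with
probability 0.25, 40 ms ramps), band-limited to 0.5–32 Hz *after*
modulation, with within-burst RMS equal to `effect_size` (δ) times the
channel's background RMS. δ = 0 reproduces the PNES generative law bit for
bit under the same seed. This emulates intermittent fast interictal activity
over the regions where complexity differences are reported clinically; it
does not emulate artifacts (blinks, EMG), volume conduction, or any fitted
property of real patient EEG. A green synthetic test therefore establishes
that the *pipeline machinery* behaves as specified under a known effect —
not that the clinical effect itself is reproduced.

### Calibration of the free generator knobs

Band limits, montage, epoch geometry, sample counts and the δ-scaling rule
are stated by the design; burst duty cycle and the two nuisance amplitude
ranges are not. They were fixed once, before the test suite was frozen, by a
Monte-Carlo calibration whose target was the stated qualitative world:
(a) a δ = 2 cohort must be learnable by the CNN in 3 training passes;
(b) raw designated-channel PE must separate the classes at 18 vs 18;
(c) channel-wise PE at the *input* layer must **not** separate the classes
reliably, while Conv1/Conv2 PE does — the depth-separability regime. Point
(c) is the delicate one: any spectral band unique to the class effect makes
one sub-band of the input a noise-free detector. Two findings from the
calibration are worth recording. First, the burst envelope must be
re-band-limited after modulation, otherwise burst-edge spectral splatter
leaks into the otherwise-empty d1/d2 sub-bands and the input layer detects
the class perfectly. Second, the nuisance must occupy the same band as the
class effect (plus a heavier slow component), so that the six-band *average*
PE at the input is dominated by nuisance variance while trained filters can
still isolate the intermittent component. A stronger nuisance than the
frozen one was tried and rejected: it destabilised 3-pass training.

## Numerical and engineering choices

* **Wavelets.** MATLAB-style `wavedec`/`wrcoef` semantics: symmetric
  half-point extension, coefficient counts `floor((n+7)/2)` per level
  (bookkeeping vector `22, 22, 38, 70, 133, 259, 512` for a 512-sample
  epoch), per-band reconstruction by zeroing all other blocks. The identity
  `x = a5 + d5 + d4 + d3 + d2 + d1` holds to ~1e-15 relative error and is
  asserted at 1e-8. Filters are the standard published DB4 taps; the
  implementation was validated during development against an independent
  wavelet library, and frozen reference coefficients live in the tests.
* **Butterworth band-pass.** Designed in-package via the analog prototype →
  band transform → bilinear route (coefficients match the reference design
  to machine precision) and applied forward–backward (zero phase, no group
  delay; the standard offline-EEG choice). The stated stop-band behaviour is
  asserted on steady-state tones.
* **CNN engine.** No deep-learning framework is assumed. A double-precision
  reference engine (conv/pool/dense/dropout/Adam) defines the semantics; a
  fused float32 stack executes Conv1→Pool1→Conv2→Pool2→Dense1 in persistent
  C++ buffers for speed (large fresh R allocations cost more in page faults
  than the arithmetic). The two routes agree at float precision and both are
  under test. Training is bit-reproducible given a seed (weights, shuffling
  and dropout all draw from R's RNG; single-threaded BLAS).
* **Input gain.** A fixed scalar 0.02 is applied to the input tensor inside
  the network (amplitudes expressed in units of 50 µV). With microvolt-scale
  signals and a 19456-wide flatten, unit gain saturates the sigmoid head at
  initialisation and roughly a third of short training runs collapse to the
  constant-0.5 saddle. This is numerical conditioning of fixed units — no
  data-dependent normalisation is applied anywhere.
* **Adam** uses learning rate 1e-2, β₁ = 0.9, β₂ = 0.999, ε = 1e-8,
  batch 107, 10 passes by default; "iterations" is read as passes over the
  training set.
* **Ties and degenerate cases.** Exact Wilcoxon null when tie-free and
  `m·n ≤ 10⁴`, tie-corrected continuity-corrected normal approximation
  otherwise. Zero-denominator metrics report 0 with a warning flag. A
  subject's exact 50/50 epoch-vote tie is broken by the mean probability
  against 0.5.

## The leave-one-out null, honestly

At δ = 0 one might expect LOOCV patient accuracy ≈ 50%. It is not: each
training fold contains 17 subjects of one class and 18 of the other, the
trained network drifts toward the training majority, and the held-out
subject — always of the minority class — is voted the other way. Patient
accuracy under majority voting is therefore *systematically below* chance at
the null (near 0 in small cohorts). This anti-bias of leave-one-out with
class-balanced designs is well documented in the evaluation literature. The
package consequently tests the null on the subject-level AUC (≈ 0.5 when
there is no signal, robust to the fold imbalance) and on the requirement
that the δ = 2 accuracy strictly exceed the δ = 0 accuracy.

## Known limitations

* The synthetic effect is a stated surrogate; none of its parameters are
  fitted to clinical data, and headline clinical numbers (94.4% accuracy,
  AUC 0.99) are not reproduction targets at desk scale.
* Conv layers share weights across channel rows and never mix channels, so
  per-channel PE separability cannot spread to channels that carry no
  signal; the depth-separability property is driven by within-channel SNR
  gains plus the rectification nonlinearity.
* The SMO-based RBF SVM materialises the full kernel matrix; it is intended
  for cohort-scale problems (thousands of epochs), not beyond.
* EDF input/output is out of scope; the interchange format is the
  tab-separated text dialect plus a CSV manifest.
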