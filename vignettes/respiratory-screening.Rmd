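---
title: "Methods: lung-sound screening with wavelet and entropy features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-sound screening with wavelet and entropy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `respscreen`, the
parameters that matter, the numerical choices, and what the package's tests
do and do not demonstrate.

## The screening problem

Auscultation classifies lung sounds by their adventitious components:
pneumonia produces short, explosive crackles as air reopens fluid-filled
small airways; obstructive disease (COPD, asthma) produces sustained
musical wheezes from narrowed airways; many other conditions alter breath
sounds more diffusely. Normal sound conduction through the chest wall is
confined to roughly 80–1000 Hz, so everything outside that band is treated
as interference. The package turns a mono chest recording into the
probability that the patient is healthy or has pneumonia, COPD, or another
respiratory condition ("other" deliberately pools coronavirus disease,
LRTI, URTI, asthma, bronchiolitis, and bronchiectasis into one class).

## Pipeline and assumptions

1. **Filter.** A bandpass realized as a cascade of an order-5 high-pass at
   80 Hz and an order-5 low-pass at 1000 Hz (Butterworth by default;
   Chebyshev type 1/2 and elliptic are available for comparison). The
   cascade keeps each section numerically well-conditioned at the narrow
   normalized low edge (80 Hz at fs = 4000 Hz) and preserves each section's
   textbook cutoff property. Application is zero-phase (forward, then
   time-reversed, with odd-reflection edge padding): offline processing has
   no latency constraint, and zero phase keeps crackle timing intact. The
   price is a squared magnitude response — the designed −3 dB cutoffs are
   −6 dB effective — which is immaterial here because the features compare
   like-filtered signals.
2. **Normalize.** Each recording is divided by its peak absolute amplitude,
   mapping it onto [−1, 1]. Normalization is per recording (not per
   segment), so relative level differences between a recording's segments
   survive. This is one of two orders the pipeline description leaves open;
   the package fixes filter → normalize → segment.
3. **Segment.** Consecutive non-overlapping 6-s windows (one full breathing
   cycle at typical adult rates); a trailing remainder is discarded rather
   than padded, so every feature vector summarizes a complete window.
4. **Features (13 per segment).** Shannon entropy and spectral entropy are
   computed on the segment *before* the wavelet transform; the remaining 11
   features are the RMS of the level-10 db7 approximation (cA) and of each
   detail set (cD1 … cD10). At fs = 4000 Hz the detail bands are
   dyadic: cD1 ≈ 1000–2000 Hz, cD2 ≈ 500–1000 Hz, cD3 ≈ 250–500 Hz, and so
   on — cD2–cD4 straddle the crackle and wheeze bands, which is why their
   RMS carries class information.
5. **Selection.** One Kruskal–Wallis H per feature with the classes as
   groups, ranked descending, accepted when H exceeds the upper-α
   chi-squared quantile at k − 1 degrees of freedom (α = 0.05). H is
   rank-based, hence invariant to any monotone rescaling of a feature and
   robust to the heavy-tailed amplitude statistics of adventitious sounds.
6. **Classifier.** One hidden ReLU layer (default 250 units), softmax over
   the four classes, categorical cross-entropy plus L2 penalty, dropout on
   the hidden layer, Adam, early stopping on a stratified validation split
   with restoration of the best weights. The training split is balanced by
   random oversampling *before* training; real corpora of this kind are
   extremely skewed, and undersampling would discard scarce disease
   examples.
7. **Evaluation and reporting.** One-vs-rest reductions of the 4×4
   confusion matrix give per-class sensitivity, specificity and precision;
   macro averages are unweighted class means; overall accuracy is
   trace/total. Screening reports render per-segment probabilities as
   percentages (two decimals) and aggregate them per recording with the
   arithmetic mean and the *population* standard deviation (divisor n) —
   the convention recovered by recomputing the reference screening tables,
   whose printed SDs match only the population form.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| working sample rate | 4000 | Hz | smallest round rate with Nyquist above the 1000 Hz band edge; a 6-s segment (24000 samples) still supports 10 db7 levels |
| filter order | 5 per section | — | reference device configuration |
| band | 80–1000 | Hz | lung-sound conduction band |
| segment length | 6 | s | covers a breathing cycle |
| entropy bins | 256 over [−1, 1] | — | 8-bit amplitude quantization; stable histograms at 24000 samples/segment; configurable |
| wavelet / depth | db7 / 10 | — | fixed by the method; other wavelets only via the internal interface |
| selection α | 0.05 | — | conventional significance level |
| split | 80:20 stratified | — | reference protocol |
| hidden nodes | 250 | — | chosen by the sweep criterion: highest test accuracy with the smallest train–test gap |
| epochs / patience | 1000 / 50 | epochs | early stopping governs the effective length |
| dropout / L2 / lr / batch | 0.3 / 1e−4 / 1e−3 / 32 | — | mechanisms are part of the method; these values are conventional defaults, all configurable |

## The synthetic corpus

The generator exists so that every stage is testable end to end without
any external recordings. It emulates, per class:

- **healthy** — Gaussian noise band-limited to 100–900 Hz, amplitude-
  modulated by a raised-cosine breath envelope (inspiration over the first
  35 % of a 4-s cycle, a weaker expiration over 40–85 %, a pause, and a
  small noise floor);
- **pneumonia** — the healthy model plus Poisson-placed crackle transients
  within inspiration: exponentially damped sinusoids, 200–600 Hz,
  5–15 ms, 12 events per cycle, amplitudes 8–14× the breath RMS. The
  amplitudes are deliberately dominant: crackles are brief, so only loud
  events survive peak normalization with enough contrast to move
  segment-level entropy and RMS statistics (milder settings left the class
  statistically inseparable from healthy at the segment level);
- **COPD** — sustained tonal wheezes (default 250 and 420 Hz, slight
  per-recording frequency jitter) gated by the expiratory envelope;
- **other** — a randomized mild mixture: shortened breath period
  (2.2–3.2 s), stronger expiration, a low wheeze (110–190 Hz), sparse mild
  crackles, and a wider noise band, so the class is a distribution, not a
  fifth acoustic type.

Sensor noise is added at a configurable SNR (default 15 dB) and the result
is scaled to peak 0.9 for 16-bit PCM storage. All randomness flows through
explicit seeds; per-recording seeds derive deterministically from the
corpus seed.

**What passing tests show — and do not.** The generator produces
class-conditional distributions that the 13 features separate; the
end-to-end recovery test (held-out accuracy ≥ 0.90 at 40 recordings/class)
demonstrates that the pipeline's plumbing, feature definitions, selection
and training are correct and leak-free. It does *not* validate clinical
performance: real auscultation has device coloration, inter-patient
variability, co-occurring conditions, and ambient noise that the generator
does not model.

## Numerical choices

- **DWT boundaries.** Feature extraction uses symmetric (mirror) extension,
  the common convention for non-dyadic signals. The periodized mode keeps
  the transform exactly orthonormal and is used in the energy-conservation
  tests; exactness requires an even length at every level, so those tests
  use dyadic-compatible lengths (1024, 24576), while perfect reconstruction
  is verified at the working length 24000 in both modes (max error ≤ 1e−8).
- **Tie handling in H.** Midranks, and no tie-correction divisor by
  default — the plain rank-sum formula is reproduced literally; the
  corrected variant (the one `stats::kruskal.test` reports) is available
  via `tie_correction = TRUE` and is cross-checked against it in tests.
- **Entropy conventions.** 0·log 0 := 0; entropies are unnormalized (no
  division by log of the bin count). Amplitudes outside [−1, 1] are clipped
  into the end bins; after normalization this never occurs.
- **Periodogram.** Rectangular window, one-sided, normalized so that the
  summed power equals the mean-square amplitude (discrete Parseval) — this
  makes the spectral-entropy probabilities well-defined and testable to
  1e−9.
- **PCM quantization.** 16-bit writes use a 32768 full scale with clamping,
  bounding round-trip error by 2⁻¹⁵.
- **Chebyshev ripple note.** The "1 dB ripple" equiripple property holds
  per section; the high-pass × low-pass cascade shows up to ~1.7 dB
  peak-to-trough because both sections ripple across the shared passband.
  `frequency_response(..., section =)` exposes the per-section curves.
- **Determinism.** Training is bit-deterministic for a fixed seed on a
  fixed platform/BLAS; across platforms, accuracy metrics reproduce, exact
  weights need not.
- **Degenerate inputs.** All-zero signals are rejected by normalization and
  spectral entropy (degenerate-input errors); undefined evaluation metrics
  (zero denominators) raise errors naming the class and metric instead of
  silently reporting 0.

## Open design points resolved here

- Amplitude discretization for Shannon entropy is undefined in the source
  method; 256 equal-width bins over [−1, 1] were chosen once (8-bit
  convention) and exposed as a parameter.
- Spectral entropy sums over periodogram bins (not banded energies); the
  alternative reading of "each frequency band" would only rescale the
  feature monotonically at fixed segment length, which rank-based selection
  ignores.
- Evaluation is at segment level; screening reports aggregate segments per
  recording. Whether headline accuracy of this class of system is segment-
  or recording-level is genuinely ambiguous; segment-level is the stricter
  choice (no majority-vote smoothing).
- The default pre-selected feature set (used when a caller skips selection)
  is the 10-feature subset that maximized test accuracy in the reference
  incremental evaluation: Entropy, RMScD9, Spec.Entropy, RMScD10, RMScD3,
  RMScD2, RMScD4, RMScD8, RMScA, RMScD5.

## Problem sizes

The test suite runs the full recovery experiment at 40 recordings per class
(320 six-second segments) and completes in about a minute on one CPU;
`scripts/acceptance.R` repeats it from scratch — corpus, features, ranking,
training, incremental curve, node sweep — in well under a minute. These
sizes were chosen as the smallest at which the selection statistics are
stable and the recovery invariant is met with margin.

## Known limitations

- The acoustic generator is a statistical emulation, not an airway model;
  transfer to real recordings is untested by design.
- The WAV codec covers integer PCM and IEEE float RIFF files; compressed or
  extensible-format WAVs beyond plain PCM are out of scope.
- The classifier is a deliberately small fully-connected network; no
  convolutional or sequence models, no GPU path.
- Single-channel processing only; multichannel files are averaged to mono
  on load.
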