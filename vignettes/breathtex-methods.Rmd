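---
title: "Spectrogram-texture classification of respiratory sounds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrogram-texture classification of respiratory sounds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breathtex)
```

# The problem

Intubated, mechanically ventilated patients accumulate sputum in the
trachea and endotracheal tube. Unless it is suctioned in time, the airway
occludes. Nursing staff monitor for this by auscultation, which is
subjective, skill-intensive and labour-intensive. `breathtex` implements an
automatic alternative: classify the sound of a single breath, recorded at
the tube, as *with sputum* or *without sputum*.

The acoustic signature exploited is simple: air flowing past secretions
produces short broadband transients. In a time-frequency power image of a
breath these transients are columns of elevated energy across many
frequency bins — *vertical texture* — whereas the airflow-on-tube-wall and
ventilator background behave like wideband noise with no oriented
structure, and most normal respiratory-tract energy lies below roughly
1 kHz. The pipeline therefore renders each breath as a spectrogram image,
amplifies vertical structure, and measures image texture.

# Pipeline and model

## Filtering and breath segmentation

Input audio (mono, 44.1 kHz modelled) is bandpass filtered with a
third-order Butterworth IIR filter, 20–6000 Hz, the band that carries both
the respiratory-tract energy and the sputum transients. Filtering is causal
(forward-only) by default, as a bedside real-time system would run;
`filter_spec(zero_phase = TRUE)` switches to forward–backward filtering.

Segmentation into inhale–exhale cycles works on the raw (unnormalised)
short-time autocorrelation of 2048-sample frames advanced by 1024 samples:

$$R(k) = \sum_{m=1}^{L-k} x(m)\,x(m+k), \qquad k_{\min} \le k < L .$$

A frame's score is $\max_k R(k)$. Two points here are deliberate design
choices rather than givens:

* **`k_min` = 20 samples.** Without a lower lag bound the maximum is always
  the near-zero-lag energy term and the statistic degenerates to frame
  energy; excluding lags under ~0.45 ms makes it sensitive to correlated
  (airflow) structure rather than raw power.
* **Noise floor from 40 leading frames (~0.95 s).** The working thresholds
  are $T_1 = a\,\max(R)$ and $T_2 = b\,\max(R)$ with $a = 1$, $b = 10$,
  where $\max(R)$ is the maximum score over leading voiceless frames
  (recordings are assumed to begin with a ventilator-only gap; the
  synthetic generator guarantees 1.5 s). The estimate must sit at the upper
  edge of the background-score distribution: taken over too few frames it
  lands in the bulk of that distribution, and the $T_1$ release then fails
  to close segments inside inter-cycle gaps. Forty frames uses most of the
  guaranteed gap while requiring only ~1 s of lead-in.

A segment opens when a score reaches $T_2$ (its start refined backward to
just after the last sub-$T_1$ frame), closes when scores stay below $T_1$
for `min_gap_s` = 0.3 s, and is kept if at least `min_breath_s` = 0.5 s
long. Both thresholds and all scores scale as the square of the waveform
amplitude, so segmentation is exactly gain-invariant. If the leading frames
are digital silence ($\max(R) = 0$) the opening threshold is floored at the
smallest positive double so that zero-score frames can never open a
segment. Breaths with no inter-cycle pause are out of scope: with no gap
the score never releases and adjacent cycles merge — a documented
limitation of the pause-based approach, not something the package attempts
to fix.

## Spectrogram image

Each breath is transformed with an STFT (window 1024, hop 512, 4-term
Blackman-Harris taper with coefficients 0.35875/0.48829/0.14128/0.01168,
symmetric form). The one-sided power spectrum $E(n,k) = |X(n,k)|^2$ is
floored at $\varepsilon = 10^{-12}$ of full-scale power — silent frames stay
finite without disturbing texture statistics — and converted to dB. The
matrix is treated as an image with row 1 = 0 Hz ascending and columns =
time, so "vertical" always means along the frequency axis.

## Vertical-texture enhancement

Three steps, in fixed order:

1. **Edge mask.** Convolution with the 6×6 mask whose six identical rows
   are $(-1, 2, -1, 2, -1, -1)$. Each row sums to zero, so anything
   constant along time (sustained tones, stationary background) cancels
   while single-column structures are amplified.
2. **LoG filtering.** Convolution with a sampled Laplacian-of-Gaussian
   kernel $-(x^2+y^2-2\sigma^2)/\sigma^4 \cdot e^{-(x^2+y^2)/2\sigma^2}$
   (default $\sigma = 1$ px, 7×7), mean-subtracted so it integrates to
   zero. The Gaussian part suppresses pixel noise; the Laplacian sharpens
   edges. The analytic normalising constant of the Gaussian is immaterial
   once the kernel is mean-subtracted and is omitted.
3. **Triple-threshold line strengthening.** Sputum energy is often
   intermittent, so a burst appears as a *dashed* vertical line. For every
   time column the package computes a sign-transition count (ZCR), a
   short-band energy (SBE: maximal sliding 32-row sum of squares) and the
   total energy (TE). A column whose transition count is below
   `zcr_th` = 0.25 of the row count *and* whose SBE and TE exceed their
   thresholds carries a genuine but fragmented line; the run between its
   first and last line pixels (those above `fill_threshold` = 0.25 of the
   column maximum — stricter than the ZCR zero-band, so noise pixels do not
   stretch the run) is filled *at the line's own intensity*, the mean of
   those pixels, extending the dashes into a continuous line. Filling at
   the line's intensity rather than some extreme grey level matters
   downstream: the texture features sit on a min–max grey quantization, and
   fills that introduce an outlier level would compress the rest of the
   histogram into fewer levels in both classes. (A `fill_full_column`
   switch extends over the whole image height instead.)

Interpretation choices worth recording: the sign function in the ZCR uses a
zero-band — magnitudes under 5% of the column maximum count as zero —
because without it any noise column alternates sign at almost every pixel
and the test cannot discriminate; the ZCR/SBE/TE statistics are computed
per *time column along frequency*, the only reading under which the rule
detects vertical lines; and the SBE/TE thresholds default to per-image
0.75-quantiles of the column statistics, which makes the stage invariant to
overall gain where absolute numbers would not be (absolute overrides exist
for cross-image comparisons).

The enhancement is evaluated as one method: the *no-strengthening*
comparison arm (`strengthen = FALSE`) computes texture features directly
from the plain dB spectrogram, skipping all three steps — mirroring a
workflow that classifies the raw time-frequency image. The figure
describing the first (edge-detection) step already belongs to the
strengthening method, so the comparison toggles the method as a whole, not
merely its last step. `featurize_corpus(..., strengthen = "both")` computes
both arms in one pass, sharing filtering, segmentation and the
spectrograms. In the shipped evaluation the comparison runs on a
noise-degraded corpus with the breath-to-ventilator SNR halved to 6 dB: at
that level segmentation is still fully operable, so the comparison isolates
the enhancement (at far lower SNRs the autocorrelation thresholds
themselves start missing breaths and recording losses confound the
comparison).

## GLCM texture features

The (enhanced) image is quantized to 16 grey levels by min–max binning —
invariant to positive affine rescaling, preserving histogram shape. For
each direction $\theta \in \{0°, 45°, 90°, 135°\}$ at pixel distance
$d = 1$ a symmetric grey-level co-occurrence matrix is accumulated and
normalised, and four statistics computed with levels indexed $1..g$:

* energy $\sum_{ij} P^2$,
* inertia $\sum_{ij} (i-j)^2 P^2$,
* correlation $\big(\sum_{ij} ij\,P - u_1 u_2\big)/(d_1 d_2)$,
* entropy $-\sum_{ij} P \log_{10} P$ (with $0 \log 0 = 0$).

This inertia form squares the probability inside the sum; the standard
Haralick contrast uses $P$ un-squared. The squared form is the package
default and the un-squared one is available as `classic_contrast = TRUE`.
With rows = frequency, the 90° features read along-frequency structure, so
vertical (sputum) texture loads on the 90° and diagonal features: a
continuous vertical line raises grey-level co-occurrence of identical
levels along frequency, driving 90° correlation up and 90° inertia down
relative to noise. Degenerate cases are defined totally: a constant image
gives the single-entry GLCM (energy 1, inertia 0, entropy 0) and its
correlation is defined as 0 since both marginal deviations vanish. The
canonical feature order is statistic-major (`energy_0 … entropy_135`).

## Feature selection

Because information-theoretic scores need discrete inputs, each continuous
feature is discretized by recursive entropy minimisation with the
Fayyad–Irani MDL stopping rule; when MDL accepts no split at all the
feature falls back to 10 equal-frequency bins (rather than being scored 0)
so that weakly informative features still receive a graded score. Three
filter criteria are reported per feature: information gain
$H(\text{class}) - \sum_v p(t{=}v) H(\text{class}\mid t{=}v)$ in bits, gain
ratio (IG over the bin-distribution entropy), and the absolute Pearson
correlation between the raw feature and the 0/1 class code — the plainest
reading of a "correlation" criterion. Ranking is a descending stable sort
with ties broken by canonical feature index; the top $k = 13$ of 16 are
retained by default, under the information-gain criterion.

## Classifier and evaluation

The classifier is binomial logistic regression with a small ridge penalty
($\lambda = 10^{-8}$, the conventional default of WEKA-style logistic
implementations) fitted by IRLS on internally standardised features; the
penalty keeps the normal equations well-posed under near-separation.
Evaluation is stratified 10-fold cross-validation with a seeded fold
assignment; the pooled out-of-fold confusion matrix yields sensitivity
(with-sputum recall), specificity, accuracy, and per-class accuracies
(correct/row-total). By default feature selection is *re-run inside each
training fold* to keep the selection out of the held-out data;
`select_once = TRUE` reproduces the simpler rank-once-then-validate
protocol (selection leakage, but comparable to workflows that rank on the
full table before CV). Features are likewise standardised per training
fold. The positive class is `with_sputum` and the decision threshold 0.5.

# The synthetic generator

Real bedside recordings are not redistributable, so the package ships a
generator whose defaults define the emulated study conditions:

* corpus: 110 recordings per class (220 total), one seeded substream per
  recording;
* per recording: 4 cycles of 3 s separated by 1.5 s ventilator-only gaps
  (leading and trailing gaps included — total 19.5 s at 44.1 kHz);
* breath: 100–1500 Hz Gaussian noise (most respiratory-tract energy lies
  below ~1 kHz) under a raised-cosine inhale (40% of the cycle), a short
  pause (7%), and a raised-cosine exhale; the envelope is floored at 0.15
  of peak so the pause retains some airflow — without that residual the
  intra-cycle pause reads as a gap and single breaths split;
* background: white ventilator noise at 12 dB below the breath peak
  envelope (SNR jittered ±3 dB per recording, cycle length ±15%, envelope
  shape and burst rate also jittered);
* sputum class: Poisson bursts at 4 /s during breathing epochs, each
  5–20 ms of 100–6000 Hz noise with a raised-cosine taper and
  exponentially jittered amplitude (capped at 3× its mean) — short
  broadband events that produce exactly the dashed vertical spectrogram
  texture the enhancement stage targets.

No acoustic statistics of real intubated-patient recordings were available
to calibrate against, so these are field-plausible conventions, chosen
once. The generator does *not* model ventilator modes, patient variability,
microphone transfer functions, friction artefacts, or non-sputum
adventitious sounds (wheeze, crackle); a high synthetic accuracy therefore
demonstrates that the pipeline recovers the texture signal it is designed
for, not that clinical performance would match.

# Numerical choices and degenerate inputs

* Frame scores are computed exactly (zero-padded FFT autocorrelation, two
  real frames packed per complex transform); the brute-force definition is
  kept as the reference in tests.
* Convolutions are zero-padded to "same" size; analytic zero-response
  claims (mask on row-constant images, LoG on constants) hold on the
  interior, away from the padding border.
* dB floor $10^{-12}$; GLCM of an all-zero (unnormalisable) matrix is an
  error, while constant images take well-defined degenerate feature
  values.
* All randomness flows through explicit integer seeds (`synth_spec(seed)`,
  corpus master seed, CV fold seed); repeated runs are bitwise
  reproducible, and the generator restores the caller's RNG state.
* Problem sizes used by the shipped checks: the end-to-end evaluation uses
  the full default 220-recording corpus; oracle-equivalence suites use 50
  random small instances per operation; segmentation recovery uses 100
  recordings.

# Known limitations

* Segmentation requires a silent(ish) lead-in of about a second to
  estimate the noise floor, and fails by design when breath cycles have no
  pause between them.
* Quantile-based SBE/TE thresholds adapt per image; images consisting
  almost entirely of lines would raise their own thresholds and can
  suppress detections (absolute thresholds are provided for such regimes).
* The enhancement method's margin over plain-spectrogram features grows
  with noise (fragmented texture) and shrinks on clean, well-separated
  corpora, where both arms classify near ceiling.
* The comparison classifiers sometimes used alongside logistic models
  (Bayes nets, MLPs, k-NN, trees) are out of scope; the classifier
  interface is a plain feature matrix + labels, so they are easy to bolt
  on externally.
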