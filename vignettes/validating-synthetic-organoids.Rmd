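---
title: "Validating synthetic bright-field organoid images: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating synthetic bright-field organoid images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidval)
library(dplyr)
```

This vignette is the package's own account of its science: the generative
model and its losses, the metric suite, the psychovisual statistics, the
concordance search, the segmentation harness — and, throughout, the design
decisions taken where more than one reading was defensible.

## The problem

Brain organoids are 3-D neural cultures derived from pluripotent stem
cells, typically imaged in bright-field: grayscale frames with a
light-to-dark illumination gradient, an ovoid organoid body, a bright
neuroepithelial rim, and dispersed cells around the body. Public datasets
are tiny (tens of images), which blocks deep-learning analysis tools.
Generative augmentation can expand such a dataset, but synthetic images
must be *validated*: by similarity metrics, by human experts, or — ideally
— by a metric combination that predicts the human judgment.

## Synthetic data: what it emulates and what it does not

`make_organoid()` renders a parametric scene: an anisotropic ellipse
(optionally perturbed at low angular frequency so bodies are ovoid rather
than perfectly elliptical), a bright speckled rim band just inside the
boundary, sparse dark halo cells outside it, a monotone vertical gradient
background, and optional blobs emulating acquisition artifacts, plus
Gaussian blur and noise. The mask returned is the exact pixel support of
the body, which gives the segmentation stage perfect ground truth by
construction.

These scenes capture the features experts actually use (ovoid shape,
neuroepithelial rim, cell dispersion, gradient background, artifacts) but
are *not* photorealistic: no internal tissue texture, no optics model, no
developmental trajectory. Consequently, passing tests demonstrate that the
pipeline measures what it claims on data with known structure — not that
any particular generator reaches publication-grade realism on real
acquisitions.

`simulate_experts()` draws one decision per (expert, image): a pass with
probability `pass_prob`, otherwise an error with the group-specific
false-positive probability (synthetic images) or the false-negative
probability (originals). Decision times are lognormal — a modeling choice,
not an empirical claim: times must be positive and right-skewed, and the
lognormal is the simplest such family. Error categories default to longer
median times than correct ones, emulating the observed longer hesitation
on wrong answers. The default panel of eight centres its per-group FP
probabilities on the ordering reported for the six losses (perceptual
Wasserstein ≈ 0.6, Wasserstein ≈ 0.4, BCE family ≈ 0.2–0.25, least
squares ≈ 0.1, originals' FN ≈ 0.07), with ±30% between-expert variation
so per-expert positive counts spread realistically.

## The adversarial autoencoder and its six losses

The generator is an encoder–decoder regularized adversarially in latent
space: a discriminator learns to separate encoded latents from draws of a
standard-normal prior while the encoder learns to fool it — the usual
min–max objective. Since no architecture was prescribed, the package uses
a deliberately small MLP topology (image → tanh hidden → latent;
mirrored decoder with sigmoid output; latent discriminator), trained
full-batch with Adam and hand-derived gradients. This keeps the whole
trainer in base R, bit-reproducible under a seed, and fast at desk scale.

The reconstruction objective is pluggable with six losses:

| name | definition | notes |
|---|---|---|
| BCE | mean −(y log y′ + (1−y) log(1−y′)) | predictions clipped to (10⁻⁷, 1−10⁻⁷); the clip is documented so tests are exact |
| BCE_L1 | BCE + α·mean(\|y−y′\|) | α = 10⁻⁴ |
| LS | mean (y−y′)² | |
| POISSON | mean (y′−y)·log(y′+ε) | ε = 0.25; can be negative |
| WASS | mean \|sort(y) − sort(y′)\| | exact 1-D order-1 transport |
| P_WASS | mean (sort(y) − sort(y′))² | same plan, squared ground distance |

Two readings deserved a decision. First, the Wasserstein primal coupling
is intractable per batch; the package implements the exact 1-D
sorted-sample transport on flattened intensities (exact for empirical
distributions on the line, and verified in tests against an exhaustive
assignment search for n ≤ 5). No gradient penalty is applied. Second, the
"L2 normalization" defining the perceptual variant could mean normalizing
the loss value or squaring the ground distance; only the
squared-ground-distance reading matches the printed formula (a ‖·‖² inside
the expectation), so that is implemented, and the order-1 loss obeys the
Jensen bound W₁² ≤ W₂-cost, asserted in tests.

The full-scale profile is 2,000 epochs at 250 × 250; the test and example
profile is 8 fixtures at 32–64 px and ≤ 200 epochs, chosen so the entire
suite runs in seconds while exercising the identical code path. The
trainer's contract is deliberately modest: reconstruction MSE after
training must be below its value at initialization (and trend downward
across checkpoints); no claim is made about generation quality at desk
scale. Class labels (physiological/pathological, acquisition day) are not
used: generation is unconditional.

## The metric suite: formula readings

Several printed formulas needed interpretation; each decision is
configurable or documented:

- **FID without Inception.** The group distance is defined on *pixel
  statistics*, not Inception embeddings: each image maps to a feature
  vector (mean, standard deviation, and a fixed 8 × 8 area-downsample on
  the [0, 1] scale), a Gaussian is fit per group, and the Fréchet distance
  ‖Δμ‖² + Tr(Σ₁+Σ₂−2(Σ₁Σ₂)^½) is returned. This reproduces the ~0.5–2
  magnitude regime of the reference results. The feature recipe is an
  argument (`feature_fun`), and the 1-D closed form is tested through it.
  Singular covariances receive diagonal loading, reported via a message.
- **PSNR.** The printed form 20·log₁₀ max − 20·log₁₀ MSE is inconsistent
  with the reported 12–14 dB values, which match the standard
  10·log₁₀(max²/MSE); the standard form is the default and the printed
  form is available behind `form = "printed"`. The maximum is taken from
  the reference image, making PSNR (documented) asymmetric. Identical
  images return a 100 dB cap.
- **Mutual information.** Raw histogram MI is unbounded; since the metric
  is specified to range 0–1, it is normalized by min(H(o), H(g)). The
  normalization also makes tests invariant to the logarithm base; nats are
  used internally. 64 intensity bins by default.
- **UQI.** The μ_og factor is read as the covariance σ_og (the standard
  universal quality index); no other reading yields 1 on identical
  non-constant images. Two constant images return the luminance-term
  limit with a warning.
- **Blur index.** The predictive residue is the horizontal first
  difference p(i,j) = x(i,j+1) − x(i,j) — the simplest estimator of the
  cited family — and the index is the mean squared deviation of residues
  from their per-image median. Its direction along a blur sweep
  (decreasing with σ) was recorded once on a fixed textured fixture and is
  asserted stable in tests.
- **SSIM** uses whole-image statistics with K₁ = 0.01, K₂ = 0.03 and
  dynamic range 255, since no constants were given numerically.

Aggregation follows the study protocol: pairwise metrics are averaged over
the full original × group cross-product (self-pairs excluded for the
original reference range); blur is per-image, min/max for originals and
mean per group; FID is group-wise, with the original reference range taken
across strata of the originals (a `stage` column when available, otherwise
an odd/even split — the package's substitute for developmental stages that
synthetic datasets lack).

## Psychovisual statistics

Decisions label as TP/FN (originals) and FP/TN (synthetic). Two details
are policy rather than arithmetic:

- **Passes.** A pass is recorded as an explicit third answer. The default
  policy excludes passes from the four counts and tallies them separately
  — the only reading under which each group's four counts sum to
  experts × group size, as the reference confusion table does — with an
  option to count passes as "generated" answers instead.
- **NER times.** The time weights t_FP, t_FN are the mean decision times
  of the corresponding error category *within the analyzed group*, not
  global means. With unit times NER reduces exactly to ER.

Percent reporting rounds half away from zero (`as_percent()`), so
134/320 = 0.41875 reports as 42%.

The test battery routes exactly as the classical decision tree: Shapiro
per group, then Bartlett (all normal) or Levene, then ANOVA + Tukey HSD or
Kruskal–Wallis + Holm-adjusted pairwise Wilcoxon, all at α = 0.05, with
every routing decision logged in the returned object. All tests are
delegated to their standard R implementations.

## Concordance search

"Dimensional reduction" of a metric subset is under-specified; the package
standardizes each selected metric and takes the score on the first
principal direction (a single metric reduces to its z-score; the sign is
fixed so the first metric loads positively, making results deterministic).
Feature histograms use 16 equal-width bins over the pooled range with
additive smoothing ε = 10⁻⁶ before the KL divergence (natural log, nats);
both constants are declared, and KL non-negativity plus a two-bin hand
example (0.5108 nats) are tested. The printed KL formula divides a metric
value by a decision-time value inside the logarithm, which is
dimensionally not a divergence; the histogram-distribution reading is
adopted. Correlations default to per-group aggregation (seven points in
the full design) with a per-image option; ranking is by |Pearson r| with
NER, ties broken by |Kendall τ|, and the top-10 is extracted. Of the seven
metrics, the six per-image ones (blur, SSIM, PSNR, MSE, MI, UQI) enter the
enumeration — FID is group-level and cannot take a per-image value, and
six is the count that yields the stated 63 combinations.

## Segmentation stage

Training sets hold 80 images: all 40 originals plus synthetic images
validated by at least k experts (capped at the 40 open slots,
highest-voted first), the remainder filled from a classical-augmentation
pool (flip, quarter-turn rotation, whitening, seeded crop; whitening is
implemented as per-image intensity standardization rescaled to [0, 255],
since it was named but not defined). The reference counts for the vote
thresholds (33, 41, 22, 16, 14 synthetic images for k = 0, 2, 4, 6, 8) are
non-monotone under a "votes ≥ k" reading and 41 exceeds the 40 available
slots, so the builder defaults to "votes ≥ k" with slot capping and
provides an exact-k mode; the discrepancy is surfaced in this paragraph
rather than silently resolved.

Scoring is plain per-pixel confusion arithmetic (Dice, accuracy,
sensitivity, specificity, precision, F1; Dice ≡ F1 is asserted on random
masks), with zero denominators returning NaN plus a warning, and no
morphological post-processing so scores reflect the raw predictor. The
FP/FN overlay paints false positives light pink and false negatives light
green, and the painted counts are cross-checked against the confusion
counts in tests.

Leave-one-out tests only on originals — one session per original, with an
explicit leakage guard that aborts if the held-out id appears in its
session's training set. The default segmenter is a small encoder–decoder
MLP with a per-pixel input-to-output skip connection (the role skip paths
play in U-Net-style segmenters), trained at 32 × 32; on high-contrast
ellipse fixtures, 16 training images reach mean held-out Dice above 0.8 in
a few seconds. It is a desk-scale default honouring the segmenter
contract, not a replication of any full-scale architecture; any
`(images, masks) → predict` function can be plugged in.

## Numerical choices and degenerate inputs

- BCE clip δ = 10⁻⁷ (so `bce_loss(y, y)` equals −log(1−δ), its documented
  floor, rather than 0).
- FID matrix square roots via symmetric eigendecomposition with negative
  eigenvalues clipped at 0; results floored at 0.
- Sample moments use n−1 denominators everywhere (R's `var`/`cov`).
- Rates and scores with empty denominators are NaN-with-warning, never
  silently dropped; empty summary cells are kept with n = 0.
- Every generator (images, experts, training, synthesis) is a pure
  function of its parameters and seed; per-item seeds derive from the
  master seed and stay below 2³¹.

## Problem sizes

The test suite and the acceptance script run the full pipelines at reduced
scale, chosen as the smallest sizes at which each property is
demonstrable: 16–64 px canvases, 3–60 AAE epochs (600 for the segmenter
experiment), 8 × 40 decision designs for the binomial-recovery checks, and
40-image datasets wherever the study's structural arithmetic (280 images,
63 combinations, 40 sessions) is recomputed. The 2,000-epoch, 250 × 250
profile remains the default configuration for real use.

## Known limitations

Synthetic scenes are stylized; metric magnitudes on them (for example the
blur index of noisy renders) need not match magnitudes on real
acquisitions. The desk-scale AAE demonstrates the optimization contract,
not image quality. Expert simulation assumes decisions independent across
images and experts — no learning over a session, no image-difficulty
heterogeneity beyond group membership. Group-level correlations rest on
few points (seven groups in the full design) and are reported as
descriptive rankings, not inferences.
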