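---
title: "Quantifying UV-induced cell damage in stained epidermis: models, scores and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying UV-induced cell damage in stained epidermis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ultraviolet radiation produces DNA lesions — predominantly cyclobutane
pyrimidine dimers (CPD) and 6-4 photoproducts (6-4PP) — in the keratinocytes
of the epidermis, the outermost skin layer. In histological practice these
lesions are revealed by immunohistochemical staining (a red chromogen over
the damaged nuclei) and a pathologist summarizes each slide by the fraction
of damaged nuclei,

$$S_\mathrm{nuclei} = \frac{N_\mathrm{dmg}}{N_\mathrm{all}},$$

where $N_\mathrm{dmg}$ and $N_\mathrm{all}$ count damaged and all nuclei
visible in the epidermis. Counting is costly, and on slides with spatially
heterogeneous damage different experts arrive at noticeably different
ratios. An alternative summary is the area ratio

$$S_\mathrm{area} = \frac{A_\mathrm{dmg}}{A_\mathrm{epi}},$$

the number of damaged-epidermis pixels over all epidermis pixels of a
3-class segmentation (background / healthy epidermis / damaged epidermis).
Damaged pixels count as epidermis, so $S_\mathrm{area} \le 1$ always; a
mask without any epidermis raises an error rather than scoring 0, because a
failed epidermis detection must stay visible downstream.

This package implements both scores, two model families that estimate them
from images, the evaluation machinery (stratified cross-validation, MAE,
macro IoU, pixel accuracy, paired bootstrap of interobserver agreement),
and a synthetic stained-epidermis generator that provides exact ground
truth so the entire pipeline can be exercised and tested without slide
scans.

## Models

**Segmentation.** A U-Net family parameterized by its base width $N$
(U-Net/$N$, $N \in \{16, 32, 64\}$): encoder widths $(N, 2N, 4N)$ with
three 2×2 max-pool steps and an $8N$ bottleneck, a mirrored decoder with
skip connections, two 3×3 convolutions with batch normalization per block,
and a per-pixel 3-way softmax. Full images are downsampled 2×, predicted by
a sliding window (windows snapped to the image border, overlapping softmax
maps averaged, ties broken toward the lower class index) and the label map
is upsampled back with nearest-neighbour. $S_\mathrm{area}$ is then read
off the predicted mask. The default recipe is Adamax (learning rate 0.001,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$) under categorical
cross-entropy, 50 epochs × 100 steps × batch 32 of 256 px patches with
flips, brightness in $[0.75, 1.25]$ and rotations within $\pm 15^\circ$.

**Regression.** A VGG16-style backbone (thirteen 3×3 convolutions, five
pools, widths 64…512) whose final 512-channel feature map is reduced by
concatenated global max and mean pooling (1024 = 512 + 512 features),
followed by dropout, a 128-unit ReLU layer, dropout, and one sigmoid output
neuron; inputs are whole images downsampled 4×. The *masked* variant first
zeroes all non-epidermis pixels using a separately trained binary
epidermis U-Net (four blocks of 32/64/128/256 filters, Adamax 0.001,
per-pixel binary cross-entropy, 150 epochs × 50 batches × 32 patches of
256 px from 2×-downsampled images), with the thresholded epidermis map
resized to the regression input resolution.

All networks, including backpropagation and the Adamax optimizer, are
implemented in the package's own RcppArmadillo engine (double precision,
im2col + BLAS convolutions). The backprop is validated against central
finite differences for every layer type in the test suite. Training is
deterministic for a fixed seed on a single-threaded BLAS: weight
initialization and dropout use a per-network generator, batch sampling and
augmentation draw from R's RNG.

Because no pretrained ImageNet weights ship with the package, the
`pretrained` flag only accepts user-supplied weights. The backbone
fine-tuning scope is configurable (`train_scope`): `"full"` fine-tunes
everything; `"head"` freezes the (randomly initialized) backbone and trains
the pooled head on extracted features, re-augmenting and re-extracting once
per epoch. Head-only training is the package's recommended CPU recipe — a
random convolutional backbone is a serviceable feature extractor for this
globally color-driven score, and the head then affords thousands of cheap
updates.

## The synthetic generator

`generate_sample()` emulates what the models must learn from stained
sections, with exact ground truth:

* an undulating epidermis band (sinusoidal surface, thickness drawn from
  40–80 µm, amplitude 15 µm, period 120 µm) over an eosin-pink dermis,
  at the acquisition resolution of 0.645 µm/px;
* nuclei as 4–8 µm ellipses placed uniformly inside the band at
  0.005 nuclei/µm²;
* damage assigned by thresholding a Gaussian-smoothed white-noise field at
  the quantile that makes the damaged band fraction equal the requested
  target; the smoothing length is the single **heterogeneity** knob
  (fine speckle at 0, large coherent patches at 1). Damaged regions are
  tinted with a red chromogen and their nuclei drawn chromogen-dense;
* a **contrast** knob that compresses all colors toward the background
  tone, emulating the low-contrast failure mode of real slides;
* `true_scores` that are exact by construction: `s_nuclei` is the damaged
  fraction of the placed nuclei and `s_area` equals `s_area_from_mask()`
  of the returned mask, bit for bit.

`generate_dataset()` writes the exact on-disk layout the I/O module reads
(PNG images, palette-coded PNG masks, CSV manifest), allocating tissue
(60.6 / 33.5 / 6.0 %), staining (51.6 / 39.4 / 4.5 / 4.5 %) and
mask availability (25.1 %) by largest remainder so stratum counts match to
within one sample. Per-sample damage fractions come from a three-component
mixture covering $[0,1]$ (mostly-low Beta(1.5, 6), uniform, mostly-high
Beta(6, 1.5)); heterogeneity is uniform. The manifest's `s_nuclei` column
carries the exact ground truth; annotator noise is a separate, explicit
layer (below), so experiments can choose clean or noisy labels.

What the generator does **not** emulate: stain physics (no Beer–Lambert
deconvolution), nuclei instance boundaries beyond center + damage flag,
scanner artefacts, tissue folds, or out-of-distribution variation between
laboratories. Passing the desk-scale benchmarks therefore demonstrates that
the pipeline — scores, training loops, stitching, metrics — is correct and
learns color/texture-separable histology, not that the models reach any
particular accuracy on real slides.

## Annotator-noise model

An annotator returns the true score plus zero-mean Gaussian noise with
standard deviation `base_noise_sd + heterogeneity_coupling × h`, truncated
to $[0,1]$ — heterogeneous damage is where experts disagree. The reported
interobserver disagreement that this model is calibrated against is an MAE
of roughly 0.2 between two pathologists on heterogeneous samples (published
figures for the same dual-annotated set vary between 0.17 and 0.23; the
model is calibratable to either). `calibrate_annotator()` runs the
prescribed Monte-Carlo sweep (2000 draws, uniform true scores, common
random numbers, root find on the coupling); at the default noise floor of
0.02 it yields a coupling of 0.19, which is frozen as the default in
`annotator_config()`.

A truncated Gaussian was chosen over a Beta model because the only
published quantities are the MAE and the spread of disagreement, to which a
single coupling parameter calibrates directly.

## Evaluation choices

* **MAE statistics** report the mean and the *population* standard
  deviation of absolute errors (reading "standard deviation of absolute
  errors" literally).
* **Macro IoU** averages the three per-class Jaccard indices with equal
  weight; a class absent from both masks scores 1.0, so the average stays
  over exactly three classes while a spurious prediction of an absent class
  (union > 0, intersection 0) is punished sharply — reproducing the known
  failure mode where an almost-perfect mask scores badly because a small
  blob of an absent class was predicted.
* **Stratified folds** group samples by (staining, tissue, mask
  availability), shuffle within stratum, and deal round-robin with the
  dealing position carried across strata, so per-stratum *and* overall fold
  sizes stay within one.
* **Bootstrap agreement** resamples index pairs jointly (size $n$, with
  replacement) and recomputes the MAE statistics per draw;
  `human_level_bootstrap()` shares the resampled index sets across its
  three scenarios so draw $b$ is directly comparable across scenarios, and
  reports the fraction of paired draws in which the model-vs-annotator MAE
  lies below the annotator-vs-annotator MAE. No multiple-testing correction
  is applied: distributions, not corrected p-values, are reported.
* **Cross-validation reports** aggregate per-fold means with two spreads:
  across folds (`sd_folds`) and across all fold × repeat runs (`sd_runs`),
  since either convention is defensible for repeated trainings.

## Desk-scale benchmark protocol

The reference recipes assume GPU-scale budgets. The package defines a
desk-scale protocol — the sizes used by the acceptance script, the test
suite and the analysis scripts — chosen once as a benchmark that one CPU
core completes in minutes:

* **Data:** 256 × 256 synthetic samples at default generator settings.
* **Segmentation:** U-Net/16, 60 training samples, 5 epochs × 20 steps,
  batch 8, 128 px patches (`desk_unet_config()`). Held out: 15 samples.
  Expected: macro IoU ≥ 0.70 and MAE[$S_\mathrm{area}$] ≤ 0.10; observed in
  development runs: IoU ≈ 0.85–0.9, MAE ≈ 0.03.
* **Regression:** head-only training, dropout 0.1, Adamax 0.003,
  20 epochs × 300 feature-minibatch steps, batch 16
  (`desk_regressor_config()`), 80 training samples, 15 held out. Expected:
  MAE[$S_\mathrm{nuclei}$] ≤ 0.15; observed: 0.07–0.12 across seeds. Full
  fine-tuning from random initialization is implemented and tested for
  loss decrease, but at this scale it is slower and weaker — consistent
  with pretrained backbones mainly buying convergence speed.
* **Masker:** 10 epochs × 5 batches of 4 patches of 64 px on 20 samples;
  held-out foreground IoU ≥ 0.6 (observed ≈ 0.86).
* **Interobserver bootstrap:** a synthetic dual-annotated validation cohort
  of 150 fully heterogeneous samples. This is deliberately larger than the
  18 dual-annotated real samples: with the calibrated noise level the
  MAE separation between scenarios is modest, and the cohort size was
  chosen so the paired comparison has stable power rather than hinging on
  bootstrap luck. The near-truth stand-in model uses score noise with
  sd 0.05, between the real models' cross-validated errors.

The width ablation (U-Net/16 vs /32 vs /64 × 3 seeds) lives in
`analysis/07_width_ablation.R` rather than the test suite: at equal recipe
it is the most expensive comparison, and its scientific content — width is
a secondary choice above /16 — does not gate any other component.

## Numerical and degenerate-input choices

* Images are 8-bit RGB arrays on the 0–255 scale; networks see
  $x/255 - 0.5$.
* Masks are integer matrices over $\{0, 1, 2\}$; on disk either palette
  PNGs (black/green/red by default, remappable via `mask_palette()`) or
  grayscale class-index PNGs.
* Image downsampling is bilinear; every label-map resize is
  nearest-neighbour so the class set is preserved exactly.
* Sliding windows snap the final row/column to the border (overlap grows)
  instead of zero-padding, avoiding fabricated background at edges; images
  smaller than one window are reflect-padded and cropped back.
* Probability ties at argmax go to the lower class index, so an
  all-uniform prediction degenerates to "background", which then raises
  the undefined-score error instead of returning $S_\mathrm{area} = 0$.
* `target_damage_fraction` 0 and 1 short-circuit the field threshold to
  $\pm\infty$, so the degenerate masks are exact.
* Quantile thresholding of the damage field makes the realized damaged
  fraction match the target to within one pixel's worth of mass; the
  50-seed fidelity check in the acceptance suite bounds the mean absolute
  deviation at 0.05.
* An explicit `exclude` argument on `load_manifest()` accommodates cohort
  definitions that drop individual samples (the deposited data is
  described with both 804 and 802 samples; the default exclusion list is
  empty).

## Known limitations

* No pretrained backbone weights; transfer-learning claims are out of
  reach of the synthetic benchmark.
* The engine is single-threaded CPU code; full-scale recipes (50 × 100 ×
  32 on 1040 × 1384 slides) are architecturally supported but impractical
  without hardware acceleration.
* The relevance-map explainability used to motivate masked regression in
  the original study is out of scope; the masked variant itself is
  implemented.
* Nuclei counts are never estimated from pixels — $S_\mathrm{nuclei}$
  prediction is direct regression, mirroring the study design.
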