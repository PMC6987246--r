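---
title: "dmriqc: models, simulator physics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dmriqc: models, simulator physics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dmriqc` performs slice-wise quality control of diffusion MRI: every 2D
slice of a 4D acquisition is classified as artifactual or artifact-free by
one of two view-specific detectors, and slice decisions are aggregated
into volume-level flags. This vignette explains the models and the
numerical and design choices behind them; the README shows the user-facing
workflow.

## Slicing and normalization

A diffusion acquisition is a 4D array (three spatial axes × gradient
volumes). Array axes are mapped to anatomical axes (L-R, A-P, I-S) by the
dominant direction of each column of the NIfTI affine, so obliquely stored
volumes still slice along the intended planes; strongly oblique
acquisitions (45° ambiguity) are rejected rather than guessed. All indices
reported by the package are 1-based over the stored array axes.

Peripheral slices contain mostly background and would dominate training
with uninformative examples, so they are excluded by rule:

* **Sagittal**: slices outside the head are excluded by construction
  (only indices inside the detected L-R extent are candidates), and a
  margin of 5 slices at each left/right edge is dropped, boundaries
  inclusive. With extent `[lo, hi]` the retained set is
  `(lo+5)..(hi-5)`, empty when `hi − lo < 10`.
* **Axial**: the retained set is `lo..(hi−5)` of the I-S extent — slices
  above the head and below the cerebellum are outside the extent already,
  and 5 further slices just below the superior surface are dropped.

Both margins are configurable; 5 is the default in all reports.

The head extent itself is an intensity bounding box: voxels whose
mean-over-gradients intensity exceeds 0.1 × the 99th-percentile intensity.
The percentile (rather than the maximum) makes the threshold robust to
isolated bright voxels; 0.1 separates tissue from air-background noise at
any realistic SNR. We approximate the "superior surface of the skull" by
the superior boundary of this mask — phantoms and most dMRI contrasts have
little skull signal, and only the 5-slice top margin depends on it.

Each slice is normalized to zero mean and unit variance using the
*population* standard deviation, so that a slice's normalization depends
only on its own pixels and `normalize(normalize(x)) = normalize(x)`
exactly. A constant slice maps to zeros instead of erroring: degenerate
all-background slices can survive extraction at extreme margins and should
flow through prediction, not crash it.

## Detectors

Two configurations share one interface:

* `vgg16_imagenet` — the transfer-learning configuration: a frozen
  pretrained VGG-16 convolutional stack whose pooled 512-vector feeds a
  retrained head (fully connected 256 units + two-way softmax;
  512·256 + 256 + 256·2 + 2 = 131,842 trainable parameters). Building this
  configuration requires pretrained weights on disk; without them the
  constructor raises an error that points to the compact backbone.
* `compact_scratch` — a three-block network (3×3 convolutions of 8, 16,
  32 channels, each ReLU + 2×2 max-pool, then global average pooling and
  the same 256-unit head) trained end to end. It has no pretrained
  dependency and trains on a CPU in minutes, which is what makes the
  package's end-to-end tests possible.

Training follows the fixed recipe: RMSprop (decay 0.9, epsilon 1e-7),
cross-entropy loss, 20 epochs by default. The default learning rate is
2×10⁻⁴ — appropriate for retraining a head on frozen features. For the
compact network trained *from scratch* the package's benchmarks use
1×10⁻³: a freshly initialised network needs larger steps than a
fine-tuned head, and 2×10⁻⁴ visibly underfits within the benchmark's
epoch budget. Batch size (unstated in the recipe) defaults to 32.

Class imbalance is the norm in QC — artifactual slices are a few percent
of the axial stream — and is handled by inverse-frequency class weights in
the loss (default), with label-aware subsampling as the alternative used
by the benchmark (below). The decision threshold is 0.5 with ties labeled
artifactual: in QC a false positive costs an analyst a glance, a false
negative costs a missed artifact.

Slices are padded to a square *before* resizing to the network input
(48×48 for the compact net), so artifact patterns are never anisotropically
distorted; the single MR channel is replicated across the channel
dimension. Input geometry of 48 px keeps slice-periodic banding of period
3-5 comfortably above the resampled Nyquist limit.

All training is bit-reproducible: shuffling, initialisation and dropout
derive from one integer seed, and the engine is deterministic base-R
linear algebra (convolutions are nine matrix products via
shift-and-multiply).

Cross-validation shuffles slices into k folds whose sizes differ by at
most one. Slice-level folds are the default protocol and are flagged in
the result as permitting subject leakage (slices of one volume can appear
in train and test); `by_volume = TRUE` partitions volumes instead. The
package takes no position on which protocol is "correct" — it exposes
both and labels the default honestly.

## Classical baselines

* **Gabor (32)** — 4 scales × 4 orientations; scale s has frequency
  0.25/√2^(s−1) cycles/px and a one-octave envelope (σ = 0.56/f);
  orientations span 180°. Per filter, the mean and population SD of the
  complex response magnitude, scale-major ordering: 16 × 2 = 32 features.
  This is the only natural reading of a 32-dimensional feature from a 4×4
  bank. Kernels are made zero-mean so constant images give zero response.
* **Zernike** — magnitudes of all valid moments to order 4 ((0,0), (1,1),
  (2,0), (2,2), (3,1), (3,3), (4,0), (4,2), (4,4); 9 values) on the
  inscribed disk. "Order 4, repetition 2" is ambiguous between this full
  set and the single (4,2) moment; the full set is the default and
  `zernike_spec(full_set = FALSE)` selects the single moment.
* **LBP** — rotation-invariant uniform patterns, P = 8 interpolated
  neighbours at radius 1, 10-bin normalized histogram; exactly invariant
  to gray-level shifts.
* Downstream classifiers: random forest (100 trees, default depth), RBF
  SVM (default regularization) — neither is specified further upstream, so
  library defaults are used. The Gabor-FC detector is one 256-unit hidden
  layer with ReLU, dropout 0.5 (rate unstated upstream; the standard
  default) and softmax, trained with the same RMSprop engine. The
  CNN-feature pipeline fits PCA on the training fold only, keeps the
  smallest component count reaching 98% cumulative variance, and fits an
  RBF SVM on the projection; test folds are projected with the training
  means and axes, never refitted.

All feature schemes are computed on normalized slices, consistent with the
detector path (whether the original comparisons normalized first is
unstated).

## Simulator

The simulator exists because no labeled corpus ships with the package: it
produces volumes whose artifact content is known exactly, at desk scale.

The phantom is a stack of ellipsoids: a grey-matter shell, white-matter
core and two CSF-like ventricles inside an outer head surface, with a
bright fat rim at the surface separated from the brain by a dark gap
standing in for skull (intensities CSF 1, GM 0.7, WM 0.5, rim 1.2,
background 0). Gradient volumes scale the tissue (not the rim — fat is
diffusion-insensitive) by per-gradient attenuation factors, then Rician
noise `|(x+n₁) + i·n₂|` is applied (σ = 0.02 by default, SNR ≈ 25 for
white matter).

Each artifact class is injected by its minimal physical mechanism:

| class | mechanism | severity range |
|---|---|---|
| ghosting | alternate phase-encode k-space lines × (1±α) ⇒ half-FOV ghost | α 0.1–0.5 |
| herringbone | conjugate spike pair added in k-space ⇒ plane-wave stripes | 2–10 × median |k| |
| chemical shift | fat-rim component translated along frequency-encode | 2–5 px |
| susceptibility | Gaussian-bump displacement along phase-encode, linear interp | 2–6 px peak |
| motion dropout | whole axial slices × (1−a) ⇒ dark sagittal bands | a 0.4–1.0 |
| multiband interleave | every p-th axial slice × (1−m) ⇒ venetian blinds | m 0.2–0.6, p 3–5 |

Severity ranges were chosen once so artifacts are visible but not
saturating, and are recorded in the manifest. Zero severity is the exact
identity for every injector, and only the listed (slice, gradient) pairs
are touched — properties the tests verify bit-wise. The ghosting
construction is provably identical to superimposing an α-weighted copy of
the slice shifted by half the field of view (linearity of the DFT), which
is the independent oracle used in the tests. Susceptibility warping uses
linear interpolation: the displacement fields are smooth, and higher-order
schemes would ring at the rim. Labels attach in the view where the class
manifests: axial for ghosting, herringbone, chemical shift and
susceptibility (the affected slices); sagittal for motion dropout and
multiband interleave (every retained sagittal slice of an affected
gradient crosses the banding, so all are labeled).

Injected slices can dip below zero where a plane wave's trough crosses
background; written datasets are floored at zero (magnitude images), while
the in-memory injectors stay linear so spectral tests remain exact.

What the phantom does **not** emulate: gyral/sulcal texture, skull and
scalp signal, partial-volume effects, spatially varying coil sensitivity,
physiological noise, or interactions between concurrent artifacts. Passing
benchmarks on this substrate therefore demonstrates that the pipeline can
learn and rank the injected artifact physics end to end — not that the
shipped detectors transfer to scanner data; on real data the detectors
must be retrained on labeled slices.

## Augmentation

One random affine per draw — translation (≤10% of the frame), rotation
(≤15°), zoom (0.9–1.1), shear (≤10°), horizontal flip (vertical off by
default) — with bilinear resampling and nearest-edge fill. The ranges are
deliberately mild so augmentation cannot turn a clean slice into an
artifact mimic, and edge fill avoids black borders that would resemble
dropout. Intensity, elastic and noise augmentation are deliberately
absent. Augmentation applies to training folds only, default multiplier 2
(the upstream multiplier is unstated).

## Reporting

Metrics are exact rational evaluations; zero-denominator cases return `NA`
as an explicit undefined marker, never a silent 0/1 and never an error.
A volume (one 3D gradient image) is flagged in a view when its
artifactual-slice count is **at least** the threshold T. Read literally,
"more than the threshold" would mean `> T`, but a threshold of 1 only
makes sense as "a single artifactual slice flags the volume", so `≥ T` is
implemented; the flagged set is nested as T grows, which makes recall
non-increasing in T — a property the tests check.

The workload estimator inverts precision/recall arithmetic: at volume
precision P and recall R on a corpus with `n_a` artifactual volumes among
`n`, the expected flagged count is `R·n_a/P` and the inspection reduction
is `100·(1 − R·n_a/(P·n))` percent. This is the unique reconstruction
that reproduces both reference reduction percentages (86.05% axial at
T=3, 96.75% sagittal at T=10) from the reference counts to two decimals,
verified in the tests.

## Benchmark conditions

The end-to-end benchmark (`synthetic_benchmark()`, also run by
`scripts/acceptance.R`) uses 60 volumes of 64×64×32 voxels with 2
gradients each, artifact fraction 0.5 with the full six-class menu, a
volume-level 70/30 split (no volume straddles train and test), a cap of
25 training slices per volume and view (roughly 1,000–1,600 training
slices per view once scarce positives are retained in full), and 10
epochs at learning rate 1e-3 with batch size 16. Training-fold
subsampling is
label-aware — all artifactual slices are kept and only the abundant clean
slices are subsampled — because axial artifacts touch only a handful of
slices per volume and label-blind subsampling leaves too few positives to
learn from; the held-out fold is subsampled label-blind so the evaluation
distribution is untouched. The training fold is then passed through
minority-class augmentation to parity (`augment_to_balance()`):
augmentation expands exactly the data that is scarce, which balances the
heavily skewed axial stream (where an unbalanced weighted loss can sit
near chance for 10 epochs and then favour an overflagging solution)
while leaving the naturally balanced sagittal stream effectively
untouched. Susceptibility is the
hardest class for the compact net — a localized warp leaves a weak
signature in globally pooled features — so its per-slice recall lags the
other axial classes. The severity sweep injects ghosting at
α ∈ {0.1, …, 0.5} into a fresh phantom and records the axial detector's
mean artifact probability per level; the Spearman correlation of that
curve is the monotonicity measure. The texture-baseline comparison uses
400 slices per class (herringbone/ghosting vs clean) and 5-fold
cross-validation, reporting pooled recall per feature family.

## Known limitations

* The VGG-16 path is an interface contract here: without pretrained
  weights on disk it refuses to build. All shipped results use the
  compact backbone.
* Detectors are binary; no artifact-type attribution, no localisation.
* The brain-extent box is an intensity heuristic, not a segmentation;
  very low SNR or severe dropout at volume boundaries can shift the
  retained slice range.
* b=0 and diffusion-weighted volumes are treated identically during
  slicing and training; gradient metadata is carried opaquely.
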