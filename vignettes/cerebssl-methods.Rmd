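---
title: "Self-supervised multi-domain cerebellum segmentation: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised multi-domain cerebellum segmentation: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tissue segmentation of the infant cerebellum — background, CSF, gray
matter (GM), white matter (WM) — is hard for three compounding reasons:
the cerebellar cortex is a thin, tightly folded sheet; the white-matter
core (the arbor vitae) is a branched tree whose limbs are one or two
voxels wide at 0.8 mm resolution, so partial-volume averaging erases
much of its contrast; and tissue contrast itself collapses towards
birth, so a model trained where contrast is good (around 24 months)
degrades progressively on younger cohorts and other scanners. Manual
labels are realistically available only in the high-contrast domain.

CerebSSL implements a two-step self-supervised learning (SSL) answer to
this setting:

1. **Supervised step (source domain).** A dense-block encoder–decoder
   segmentation network is trained on the labeled source domain with the
   voxel-wise cross-entropy
   $$L_{seg} = -\sum_{i=1}^{C} Y_i \ln X_i, \qquad C = 4,$$
   where $X_i$ is the predicted probability map and $Y_i$ the one-hot
   target. A second, simpler U-Net — the confidence network — is then
   trained to predict, per voxel, whether an automated segmentation
   agrees with the manual label. Its binary target $Y_c$ (the agreement
   map) comes from K-fold self-testing ($K = 2$): each fold's subjects
   are segmented by a model that never saw them, so the confidence
   network learns from genuine out-of-sample errors. Its loss is the
   class-balanced binary cross-entropy
   $$L_{cp} = -\bigl(Y_c \ln X_c + a\,(1 - Y_c)\ln(1 - X_c)\bigr),
   \qquad a = 0.1,$$
   where the constant $a$ counteracts the volume imbalance between the
   many correctly classified and the few misclassified voxels.

2. **Self-supervised step (target domains).** The current model
   segments the unlabeled target volumes; the confidence network scores
   those segmentations; the spatially varying weights
   $$w(x) = \begin{cases} M_{cp}(x), & M_{cp}(x) \ge 0.5 \\
                           0, & M_{cp}(x) < 0.5 \end{cases}$$
   gate the pseudo-labels, and a new domain-specific model is trained
   with the spatially-weighted cross-entropy
   $$L_{seg\_weights} = -w \sum_{i=1}^{C} Y_i \ln X_i,$$
   normalized over the positively weighted voxels. Because the gap
   between the source domain and the youngest domain is too large to
   jump at once, adaptation runs along a **gradual propagation chain**
   (24m → 18m → 12m → 9m → 6m → 0–3m): the model adapted to one domain
   becomes the teacher for the next. One confidence model — trained on
   the source domain only — is reused at every step, motivated by the
   observation that the probability signature of errors (misclassified
   voxels cluster near probability 0.5, correct ones near 0 or 1) is
   stable across domains.

Why a misclassification signature near 0.5 helps: for a voxel whose
probability of being correctly labeled is $q$, the minimizer of
$L_{cp}$ is $X_c^\ast = q / (q + a(1-q))$. With $a = 0.1$ the gate
$w > 0$ therefore excludes only voxels that are almost certainly wrong
($q < 1/11$), and otherwise passes confidence *values* through as
weights — the gating is deliberately conservative, and most of the
selection pressure comes from the weights themselves.

## The networks

No deep-learning framework is assumed: the package carries its own
small, deterministic 3D CNN engine (compiled im2col/GEMM convolution
kernels plus plain-R layer graph, with every backward pass verified
against finite differences in the test suite).

**Segmentation network.** The contract is a dense-block
encoder–decoder: seven dense blocks along a contracting and an
expanding path; each block is three normalize → ReLU → 3×3×3
convolution → dropout operations with dense within-block concatenation;
each convolution has `16 * sizeScale` kernels and dropout rate 0.1.
After each block a normalize → ReLU → 1×1×1 transition compresses to
twice the growth rate; 2× average pooling descends between encoder
levels, nearest-neighbor upsampling plus skip concatenation ascends
between decoder levels; the final stage is a 1×1×1 convolution and a
per-voxel softmax over the four classes. The architecture contract
fixes the block count, block content, kernel count and dropout; the
down/upsampling operators, transition widths and skip wiring are fixed
here (and recorded in `SegModelConfig`) so results are reproducible.

**Confidence network.** A depth-2 U-Net over 8 input channels — the
one-hot segmentation (4) concatenated with the probability maps (4);
one-hot encoding avoids imposing an ordinal structure on the tissue
codes. A logistic final stage squashes the output into (0, 1) so the
confidence loss is well defined.

**Normalization layers.** The "normalize" step in the block pattern is
a channel-wise learnable affine (scale and shift). Batch statistics are
deliberately not recomputed per patch: input volumes are standardized
once, channel-wise, over the foreground (an Otsu mask of the first
channel — the analog of intensity normalization over the extracted
cerebellum in MRI pipelines), and per-patch re-centering would erase
absolute intensity, which is the dominant tissue cue, while turning
uniform background patches into amplified noise. With volume-level
standardization upstream, an affine layer retains the normalize →
rectify → convolve ordering without those pathologies, and training and
inference behave identically.

**Optimization.** Kernels are Xavier-initialized; optimization is
stochastic gradient descent with learning rate 0.005 multiplied by 0.1
after each epoch. Classical momentum 0.9 is used (the standard SGD
variant in this literature; configurable), which is what makes training
with a few hundred updates meaningful. Because of the strong per-epoch
decay, epochs beyond the second contribute little; the effective
training budget is set by `patchesPerSubject` and `batchSize`.
Probabilities are clamped to $[10^{-7}, 1]$ (and confidence predictions
to $[10^{-7}, 1 - 10^{-7}]$) inside every logarithm.

**Patches and whole-volume inference.** Training samples cubic patches
whose corners are drawn uniformly over positions overlapping the
non-background mask — sampling pure air wastes the budget; the
full-scale default is 1000 patches of 32³ per subject. Whole volumes are
segmented by a regular sliding-window grid (default 50% overlap; the
last window is flush with the boundary), class probabilities averaged
over covering windows and renormalized; the label is the arg-max with
ties broken toward the lowest tissue code. Averaging is the standard
variance-reducing fusion rule for patch-trained models applied to
whole volumes.

## The phantom generator

Real infant MRI in this setting is controlled-access, so the package
ships a seeded phantom generator that reproduces the *statistical*
challenges rather than the anatomy:

- **Geometry.** WM is a recursively branching, dilated tree (depth,
  thickness and volume size configurable): children start where their
  parent ends, so WM is one 26-connected component by construction; a
  GM shell of configurable thickness (default 2 voxels) wraps the tree;
  where shells of nearby branches would merge into thick cortex, the
  interior is carved out as CSF — the analog of CSF-filled fissures
  between folia — so every GM voxel keeps a non-GM neighbor; a CSF
  shell and background complete the map. Default 64³ voxels at a
  nominal 0.8 mm spacing, branch depth 4.
- **Intensities.** Per tissue and channel, voxel values are drawn from
  a normal distribution (T1w-like ordering CSF < GM < WM; T2w-like
  inverted), blurred with a Gaussian of σ = 0.6 voxel to emulate
  partial volume — which, on one-voxel branches, removes most of the
  nominal WM/GM gap, exactly the arbor-vitae difficulty — and finally
  additive Gaussian noise. Gaussian (not Rician) noise suffices for
  mechanism testing.
- **Domains.** An age-descending series pulls the CSF/GM/WM means
  toward their common center by a fixed fraction per step and grows the
  noise, so the scalar contrast index |mean GM − mean WM| / pooled sd
  decreases strictly. Defaults: six domains named 24m … 0–3m, contrast
  decay 0.25 per step, noise growth 0.10 per step. Real-data intensity
  distributions for this problem are known only as qualitative
  illustrations, so the schedule is an emulation parameter; it was
  calibrated so that the *direct-transfer* profile of a source-trained
  model across the six phantom domains shows what full-scale studies of
  this framework measure for the non-adaptive baseline — a graceful
  decline (WM Dice falling from the low 90s to the mid 80s towards the
  youngest cohort), not a collapse. An earlier candidate (decay 0.30)
  made the last phantom domain catastrophically harder than anything
  measured on real data and was rejected on that ground.
- **Defects.** `injectTopologyDefects()` emulates the characteristic
  failure modes of automated segmentations of a folded tree: a *hole*
  relabels a small interior WM region as GM, a *handle* adds a spurious
  WM bridge across the adjacent GM/CSF gap. Defect sites are kept
  mutually distant so the returned mask has one connected component per
  defect; voxels outside the mask are untouched.

What the phantom does **not** model: anatomically realistic lobule
geometry, bias fields, motion artifacts, Rician noise (optional flag
omitted), multi-coil effects, or registration error between the two
channels (phantoms are born aligned). Passing tests on phantoms
therefore demonstrates that the *mechanisms* — confidence learning,
gating, weighted self-training, gradual propagation — behave as
designed under controlled domain shift; they do not certify performance
on clinical data.

## Desk-scale study conditions

All training in the tests and the acceptance script runs on one CPU, so
the study is scaled down from the full-scale protocol while keeping
its structure (full scale: 18 labeled source subjects, ten target
subjects per domain, 1000 patches of 32³ per subject, GPU training):

| quantity | package default (full scale) | desk scale used in tests |
|---|---|---|
| volume | — | 64³ voxels at 0.8 mm |
| source subjects | 18 | 2 |
| target volumes per domain | 10 | 1 |
| patch size | 32³ | 8³ |
| patches per subject | 1000 | 256 |
| kernels per convolution | 16 | 4 (sizeScale 0.25) |
| batch size | 8 | 1 |
| epochs (source / adaptation) | 4 | 2 / 2 |
| inference stride | patch/2 | 8 (= patch) |

One propagation design choice deserves justification. *Anchored
propagation* (`anchorPrevious = TRUE`, the default): each adaptation
step trains on the union of the target domain's gated pseudo-labels
and the previous domain's self-segmented volumes. This mirrors the
gradual-propagation protocol — once a domain has been adapted, that
domain, with its automated segmentations, is regarded as the source
domain for the next step — and it matters in practice: self-training on gated pseudo-labels
is prone to minority-class erosion (WM occupies ~0.5% of the volume,
so a student trained only on its teacher's under-segmented WM labels
under-segments further, and the loss compounds along the chain), and
the previous domain's labels act as a brake on that drift. The switch
exists so the unanchored variant can be ablated.

## Numerical conventions

- Tissue codes 0 background, 1 CSF, 2 GM, 3 WM, everywhere.
- Arg-max ties break toward the lowest code (documented, tested).
- Dice is `2|A∩B| / (|A|+|B|)`; classes absent from both volumes are
  reported `NA` (undefined), not scored.
- HD95 uses face-exposure (6-connectivity) surface voxels, nearest-
  surface Euclidean distances scaled by voxel spacing, the max of the
  two directed 95th percentiles, and linear-interpolation percentiles
  (R type 7). Conventions differ between toolkits; these are pinned by
  a brute-force all-pairs oracle in the tests.
- Resampling: trilinear for intensities, nearest-neighbor for labels;
  output extent per axis is `round(extent * spacing / target)`; a
  volume already at the target spacing is returned unchanged.
- All generators and training loops are pure functions of their
  arguments and a seed; stage seeds derive from one master seed.

## Known limitations

- The full layer table of the dense encoder–decoder backbone this
  model family descends from is not public; the wiring here is a
  documented reconstruction around the stated block structure, not a
  replica.
- The confidence network sees only label + probability channels, so it
  can detect errors through their probabilistic and geometric
  signatures but cannot consult the raw image.
- Whether "1000 patches per subject" is resampled per epoch is
  unstated; a fixed per-run sample is used.
- At desk scale the adaptation gains reproduce the widening-advantage
  age trend for CSF and GM, and for WM over the first half of the
  chain, but **not for WM in the youngest domains**. The reason is
  structural: WM is a thin minority class (~0.5% of voxels), so each
  self-training round loses a fraction of its teacher's WM recall, and
  five compounding rounds lose more WM than gradual adaptation gains —
  while the source model's direct WM generalization degrades only with
  the contrast index. At full scale (teachers with >90% WM recall per
  step, ten subjects per domain, full training) the erosion term is
  negligible and the adaptation benefit dominates everywhere;
  at desk scale it dominates only for the larger tissue classes. The
  acceptance suite asserts the full widening-advantage pattern anyway
  and therefore documents this WM clause as a genuine failure rather
  than weakening the check.
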