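---
title: "Predicting chemotherapy response from paired DCE-MRI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chemotherapy response from paired DCE-MRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neoadjuvant chemotherapy (NACT) for breast cancer is monitored with
dynamic contrast-enhanced MRI (DCE-MRI): six T1-weighted phases S0–S5 are
acquired around contrast injection, capturing the lesion's enhancement
kinetics. Clinical response is assessed under RECIST 1.1 by the diameter
change between the pre-treatment scan and follow-up: complete or partial
response (CR/PR, a decrease of at least 30 %) versus stable or progressive
disease (SD/PD). Predicting this binary endpoint early — from the
pre-treatment scan and the scan after the first cycle — is the package's
task: the classifier sees a *pair* of six-channel composite images per
patient and outputs the probability of response.

## The model

The network is a dual-branch spatio-temporal vision transformer with three
stages.

**Tokens-to-token embedding with multi-scale local–global attention.**
Each timepoint's six-channel image is tokenised by an overlapping *soft
split* (all k×k patches at stride s after zero padding; token dimension
k²·6) and linearly projected to the token width c. Each subsequent block —
one per tokenisation level, with *parameter-isolated* weights per arm so
the pre- and post-treatment branches never share embedding weights —
applies (i) a pre-norm transformer step (multi-head self-attention +
feed-forward), (ii) a reshape of the token sequence to its (h, w) map,
(iii) one same-padded convolution per kernel size in the scale bank, (iv)
per scale, windowed local attention (independent softmax(QKᵀ/√d)V inside
non-overlapping ω×ω windows) and global attention over all positions,
fused as α·local + β·global with (α, β) the softmax of two learned
scalars, so α + β = 1 by construction, (v) a softmax-weighted sum over
scales, the weights produced by a fully connected layer on the
concatenated global-average-pooled scale descriptors, and (vi) a soft
split that re-tokenises the fused map, halving the spatial grid; a linear
projection returns the k²·c patch vectors to width c.

**Spatio-temporal embedding.** A three-layer convolutional network
(3×3 → 3×3 → 1×1, each with batch normalisation and ReLU) generates a
*dynamic position embedding* from the token map itself — data-dependent,
unlike a shared static table — followed by a learned linear projection
(W·f(T)+b). A sinusoidal *temporal embedding*, TE_t[2j] = sin(t/10000^(2j/d)),
TE_t[2j+1] = cos(t/10000^(2j/d)), indexes the timepoint (t = 0 pre, t = 1
post) and is broadcast identically to every token. Their sum is added to
the arm's tokens. Ablation modes expose none / TE-only / DPE-only /
static-table (SPE) / SPE+TE / full.

**Adaptive feature fusion and classification.** A transformer encoder with
*shared* parameters processes both arms (followed by a final layer
normalisation). Global average pooling of each arm's features drives a
fully connected layer + softmax producing convex fusion weights (α, β);
the fused features α·F_before + β·F_after are concatenated along the
feature axis with the explicit difference ΔF = F_after − F_before, pooled,
and classified by a fully connected layer + softmax into two classes
(argmax with ties to class 0). The difference term makes the head
deliberately asymmetric in its inputs — the direction of change is the
signal.

## Design choices the description above leaves open

Several architecture details are not fixed by the model description and
were chosen once as package defaults:

- **Depths and widths.** Full profile: two tokens-to-token blocks, token
  width 64, 4 heads, scale bank {3, 5, 7}, window 7, soft split
  k = 3, s = 2, p = 1, initial tokenisation k = 7, s = 4, p = 2
  (T2T-ViT conventions), shared encoder depth 4, feed-forward ratio 2.
- **Constant token width.** The soft-split output (dimension k²c) is
  projected back to c after every block so the width stays fixed while
  the grid halves.
- **Window padding.** Maps whose extent is not a multiple of the window
  are zero-padded *after* the Q/K/V projections (padded rows are exact
  zero vectors) and cropped after attention; deterministic and directly
  checkable against a naive per-window loop.
- **Convolution before attention** within a stage, following the order in
  which the stages are composed (conv on the reshaped maps, then local
  and global attention per scale).
- **DPE placement.** The dynamic position embedding is computed once,
  after the final tokenisation block and before the shared encoder.
- **Normalisation.** The DPE convolution stack uses batch normalisation
  over the token axis with running statistics at inference (eval-mode
  determinism); transformer blocks use pre-norm layer normalisation; a
  final layer normalisation precedes the head. The final LN is an
  addition we found necessary for stable optimisation of the scaled-down
  profile — without it the randomly initialised head sees features whose
  scale grows with the residual depth and the cross-entropy saturates.
- **CLS ablation head.** A learnable token prepended to each arm, the
  classifier reading the concatenated encoded CLS outputs of the two
  arms.

## Training recipe

Cross-entropy loss; AdamW with β₁ = 0.85, β₂ = 0.998, weight decay 0.02;
cosine-annealed learning rate; early stopping with model selection at the
minimum validation loss; initial learning rate 1e-4 (the full-profile
recipe). Gradients are clipped to a global norm of 1 before each update:
with β₂ = 0.998 the second-moment estimate adapts slowly, and as the loss
first drops the growing gradients otherwise trigger large, destabilising
steps (loss spikes after three or four epochs were reproducible across
learning rates without clipping). Gradients are accumulated over
mini-batches of image pairs;
every stochastic choice (initialisation, data order) derives from the
seed, so a fixed configuration reproduces its fit bit for bit in
single-threaded mode.

The *test profile* used by the package's own experiments is scaled for a
single CPU: 64×64 inputs, token width 32, 2 heads, one tokens-to-token
block, scales {3, 5}, window 4, encoder depth 2, and a shorter, hotter
schedule (learning rate 2e-3, batch 8, up to 12 epochs). The smaller
model has far fewer, better-conditioned parameters than the full profile
and tolerates the larger step size; the full-profile default remains the
conservative recipe above.

## The synthetic phantom cohort

No patient data ships with the package; a phantom generator emulates the
statistical structure the pipeline assumes:

- **Cohort flow.** Manifests with exact response-category allocation,
  an MRI-incomplete flag (those records keep their row but get no
  images and no category — the drop-outs), and an optional no-NACT flag.
  The reference flow is 181 patients, 9 incomplete, CR 20 / PR 129 /
  SD 23, hence 172 eligible, 149 responders vs 23 non-responders
  (≈ 6.5:1).
- **Anatomy.** An axial slice: air background, a chest-wall band at the
  left edge, a circular breast with a 2-pixel bright skin rim, mild
  static fibroglandular texture, and a circular enhancing lesion. The
  chest wall is deliberately separated from the breast by an air gap so
  that the documented segmentation operator (Otsu threshold → largest
  connected component → 2-pixel rim erosion) has a well-defined target;
  real para-sternal anatomy is more connected than this.
- **Kinetics.** Lesion intensity at phase p is baseline + amplitude ·
  u(p) + noise with u(p) = (1 − e^(−washin·p)) · e^(−washout·max(0, p−3)):
  u(0) = 0, monotone wash-in, optional late washout. With zero noise the
  lesion mean reproduces u(p) to machine precision, which the tests
  assert. Noise is additive Gaussian; Rician noise, bias fields and coil
  artifacts are out of scope.
- **Follow-up.** The post-treatment lesion diameter scales by a
  category-dependent factor: CR → 0; PR → shrink fraction drawn in
  [0.30, 0.95]; SD → relative change within the RECIST stable band
  (−30 %, +20 %); PD → growth ≥ 20 %. The enhancement amplitude scales
  with the same factor. The RECIST thresholds are imported from the
  criterion itself, which the cohort description only names.
- **What passing tests show.** The phantoms are separable by design —
  lesion size change *is* the label — so recovery experiments
  demonstrate that the architecture, gradients and training loop work,
  not that the model reaches any particular performance on clinical
  images. Conversely the pre-treatment image carries no class signal at
  all (pre-treatment lesion parameters are drawn from one distribution
  for both classes), which the timepoint ablation exploits: a pre-only
  model can only reach chance AUC, while the dual-input model can use
  the change.

## Experiment sizes

The package's own experiments (test suite and the acceptance script) use
the scaled-down profile on a 120-patient cohort (60 responders / 60
non-responders, one central slice pair per patient, 64×64, noise SD
0.02): a 3:1:1 stratified split trains on 72 pairs and evaluates 24
held-out pairs; the signal-recovery check reports the median held-out AUC
over three training seeds and compares the dual-input model against the
pre-only ablation on the same cohort. Cross-validation mechanics are
exercised at k = 3 on 16×16 phantoms with an 8-dimensional token width.

## Numerical notes and conventions

- Tokens and feature maps are stored as [l × c] matrices with rows
  ordered row-major over the (h, w) grid; reshape between tokens and
  maps is an annotation, so flatten∘reshape is the identity bitwise.
- All indices are 1-based, the R convention, including slice selections.
- AUC uses midranks (ties count one half); the DeLong variance uses
  placement values with sample covariances; McNemar uses the
  continuity-corrected χ² computed from its closed form — the base-R
  implementation clamps the corrected statistic to zero when the
  discordant counts are equal, which contradicts the printed formula
  (|b−c|−1)²/(b+c) — with an exact binomial option; paired t-tests with
  zero difference variance report p = 1 when all differences are zero
  and p → 0 (with a warning) otherwise.
- Argmax ties break to the lower class index; checkpoint ties break to
  the earlier epoch; the alignment grid search visits candidates in
  order of increasing magnitude and accepts only strict improvements, so
  identical images yield the identity transform.
- Rigid alignment searches integer translations within ±8 px and
  rotations within ±10° (step 0.5°) scoring normalised cross-correlation;
  recovery tolerances (±0.5 px, ±1°) are asserted on noise-free phantoms.
- Augmentation: `uniform4` yields the pair plus h-flip, v-flip, one ±15°
  and one ±30° rotation (signs seeded), so 103 pairs become 515. The
  reported near-parity class balance after augmentation is arithmetically
  incompatible with a uniform 5× policy on an 89/14 training split, so a
  separate `class_balanced` policy chooses per-class variant counts
  (from the six-variant pool) that bring the ratio within 1.1:1; the
  discrepancy is surfaced rather than resolved. Validation and test sets
  are never augmented.
- The runner's desk-scale default does not augment (the phantom classes
  are balanced by construction); both policies remain available through
  the configuration.

## Known limitations

- 2-D single-slice phantoms; no 3-D volumes, no DICOM.
- The hard-split baseline is the minimal single-projection variant used
  by the ablation harness, not a full re-implementation of any published
  baseline; the WARFR-style fusion head from prior work is not
  re-implemented (no equations available), so the head ablation covers
  CLS vs the adaptive fusion head only.
- Training at the full 224×224 profile is supported but slow on a single
  CPU; the package's evidence for the architecture is at the scaled
  profile.
- The evaluation operates per image pair; optional per-patient mean
  aggregation is provided, but with one slice pair per phantom patient
  the two coincide.
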