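---
title: "Synthesizing en face OCT-A from fundus photographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing en face OCT-A from fundus photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Colour fundus photography is cheap, portable and ubiquitous, but extracting
retinal vasculature from it normally requires either laborious manual vessel
delineation or a segmentation network trained on such delineations. En face
OCT-angiography (OCT-A) measures blood perfusion directly — every pixel of
the en face projection is a flow signal — but OCT-A cameras are expensive and
have a small field of view. `octasyn` trains an image-to-image translator
that maps fundus patches to co-registered en face OCT-A patches, so that
perfusion-like vessel maps can be estimated from fundus photographs alone.
After translation, unsupervised post-processing (multiscale vesselness and
thresholding) turns the synthetic OCT-A into a binary vessel map, from which
the standard OCT-A biomarker — vessel density over the ETDRS grid — can be
computed and compared with ground truth.

## Model

The translator is a conditional adversarial pair. The generator
$G : x \mapsto G(x)$ is a U-Net: an encoder of $3\times 3$ convolution +
ReLU + $2\times2$ max-pool blocks, a bottleneck convolution, and a mirrored
decoder of nearest-neighbour upsampling + convolution blocks with skip
concatenations at matching resolutions, closed by a 1-channel $\tanh$ head so
outputs live in $[-1,1]$ like the normalized targets. The discriminator
$D(x, y)$ sees the 4-channel concatenation of the fundus patch and a
candidate OCT-A patch and reduces it through convolution + leaky-ReLU +
max-pool blocks and global average pooling to a single probability-real
score.

Training minimizes, over co-located patch pairs $(x, y)$,

$$
\mathcal{L} \;=\; \mathcal{L}_{ADV}(G, D) \;+\; \lambda\,
\mathbb{E}\big[\lVert y - G(x)\rVert_1\big], \qquad \lambda = 100,
$$

where $\mathcal{L}_{ADV}$ is the usual minimax game
$\mathbb{E}[\log D(x,y)] + \mathbb{E}[\log(1 - D(x, G(x)))]$. Both players
use Adam with learning rate $2\times10^{-4}$, alternating one discriminator
step and one generator step per patch pair. The generator's adversarial term
is implemented in the non-saturating form $-\log D(x, G(x))$, which has the
same fixed points as the saturating form but does not stall when the
discriminator dominates early. The reconstruction norm is L1 by default
(the `l2` switch exists in `reconstruction_loss()`): where a description of
the loss is ambiguous between "mean squared error" wording and an
$\lVert\cdot\rVert$-style formula named $L_{L1}$, we follow the symbol and
the pix2pix lineage this family of models descends from; with $\lambda = 100$
the choice of norm dominates training behaviour far more than the
adversarial term.

A second, non-adversarial mode (`mode = "direct_segmentation"`) reuses the
same U-Net backbone with a sigmoid head and per-pixel binary cross entropy
against binary vessel masks, optimized with Adam at $10^{-3}$ — the recipe
used by segmentation networks trained directly on OCT-A-derived vessel
masks. Because published multi-stage segmentation architectures are out of
scope here, this mode deliberately uses our own backbone and is named
accordingly in outputs.

### Scale-dependent decisions

Figure-level descriptions of the original architecture do not pin down layer
counts and filter widths, so the architecture is fully parameterized
(`generator_spec()`, `discriminator_spec()`). Full-scale defaults are
depth 4 with 64 base filters capped at 512 — a "deep generator" able to
localize large vessels while later decoder levels add fine vasculature. The
discriminator emits one scalar per patch (a "final class vector"), not a
PatchGAN score map. Scores are clamped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-7}$, before logarithms so a saturated discriminator
yields finite losses. No explicit noise input is used: the expectation
subscripts of the adversarial formulation sometimes carry a latent $z$, but
no noise vector appears anywhere else in the formulation, so the map is
deterministic given $x$ (stochasticity could be reintroduced via dropout,
which is not enabled).

## Training schedule

Patch-based training follows the published recipe: patches are sampled with
uniformly random corners inside the macular and optic-disc regions of
interest, the same crop applied to both modalities; reflections and
rotations (the dihedral group of the square, drawn uniformly over its 8
elements, applied jointly to $x$ and $y$) augment the data. At full scale
the recipe is 512-px patches, 20 raw draws per epoch expanded by
augmentation to 120 training pairs plus 9 validation pairs, 1000 epochs.
Splits are by subject — an assertion rejects any subject appearing in two
partitions, so patient-level leakage is impossible by construction. After
every epoch the configured metric is computed on a fixed set of validation
patches, and the parameters minimizing it are retained ("lowest GAN loss"
for synthesis, lowest validation BCE for direct segmentation). We compute
the checkpoint metric on validation patches in both modes; where the
original recipe states the validation rule explicitly only for the
segmentation mode, we mirror it for synthesis rather than selecting on
training loss, since selection on training loss cannot detect overfitting.
The 120-from-20 expansion is interpreted as augmentation multiplicity; both
knobs (`raw_draws_per_epoch`, `patches_per_epoch_train`) are independent
configuration values, and batch size is 1 (patch-wise alternation), which
the original description leaves unstated.

## Full-field synthesis

A full 45°-style field is synthesized by sliding the generator over the
fundus image left-to-right then top-to-bottom at a stride of 8 px,
averaging overlapping outputs. Windows that would overrun the border are
replaced by final windows flush with the right/bottom edges — never by
padding — so every pixel is covered without fabricating context.
Accumulation happens in normalized float space with a single final
denormalization, avoiding per-patch quantization bias; whether the original
pipeline averaged raw or normalized intensities is unstated, and the
normalized choice is ours. Pixels outside the fundus background mask are
set to $-1$, the normalized minimum, because OCT-A background is dark.

## Vessel binarization

The external segmentation model that the original evaluation used for
binarizing OCT-A is a supervised network trained on an independent dataset;
shipping or retraining it is out of scope, and unsupervised post-processing
is an admissible substitute. The default binarizer is therefore multiscale
Hessian vesselness (Frangi-style, bright ridges): at each scale $\sigma$ the
image is filtered with $\sigma^2$-normalized Gaussian-derivative kernels,
eigenvalues $|\lambda_1| \le |\lambda_2|$ of the Hessian are combined as
$\exp(-R_b^2/2\beta^2)\,(1 - \exp(-S^2/2c^2))$ with $R_b = \lambda_1 /
\lambda_2$, $S = \sqrt{\lambda_1^2 + \lambda_2^2}$, $\beta = 0.5$ and $c$
set to half the maximal $S$ per scale, zeroed where $\lambda_2 \ge 0$. The
maximum over scales is min–max rescaled to $[0,1]$, making the map invariant
to affine intensity rescaling of the input. Second-derivative kernels are
re-centred to exact zero sum on the sampling lattice so constant images have
exactly zero response. Binarization thresholds at 0.5 and removes
4-connected components smaller than `min_object_px`. Users holding
externally produced probability maps can inject them via
`method = "external_map"`, which preserves the original post-processing
path exactly.

## ETDRS vessel density

`etdrs_grid()` fixes the standard grid: a central disc of 1 mm diameter and
an annulus out to 3 mm diameter, split by the ±45° diagonals into superior,
inferior, temporal and nasal quadrants. Density is
$100 \times$ (vessel pixels in region) / (pixels in region), computed on
binary masks only — perfusion-intensity density is deliberately excluded to
mirror the evaluation design this package follows. Conventions the source
material leaves open are fixed and documented here: "superior" is toward
smaller row indices; for a right eye (OD) the nasal side is toward larger
column indices, mirrored for OS; pixels exactly on the outer circle are
included (`<=`); pixels exactly on a diagonal join the
counter-clockwise-earlier quadrant; the central-disc density uses the inner
1 mm circle. These choices make the region partition exact and testable
pixel for pixel.

## Evaluation

Synthesis quality is measured by per-image MAE (on the 8-bit scale) and
SSIM (7-px square windows, $k_1 = 0.01$, $k_2 = 0.03$, dynamic range 255,
unbiased window moments, averaged over complete windows only), reported as
cohort mean with SD. Density agreement uses Pearson and Spearman
correlations per region across images, with two-sided p-values from the
$t$ transform on $n-2$ degrees of freedom for both coefficients (the
original tables flag significance at $p < 0.05$ without naming the test; the
$t$ approximation is the standard choice and is calibrated in the test
suite). Pixel-level quality uses precision–recall curves thresholded at
every distinct score, with trapezoidal AUC over recall, pooling pixels
across images; the synthetic image's own normalized intensity serves as the
probability score, since the synthetic OCT-A is itself a perfusion estimate
(a vesselness-based score is available through the binarizer
configuration).

## The retinal phantom

Real paired fundus/OCT-A data cannot ship with the package, so every stage
is exercised on procedurally generated retinal phantoms
(`phantom_spec()`, `generate_phantom_dataset()`). A stochastic vessel tree
grows from trunks leaving the optic disc rim: fixed-length segments with
jittered headings, bifurcating with probability `branch_prob`, daughter
radii scaled by `radius_decay` per generation, growth stopping at the image
border, at the foveal avascular zone, or below `min_radius_px`. The tree is
rasterized with anti-aliased distance-to-segment coverage (drawn width
$2r$), thresholded at 0.5 for the binary mask — so masks are reproducible
integer images. The fundus rendering is a warm bright background with a
darker macula, a disc with dark rim and bright core, dark vessels, and
additive Gaussian noise; the OCT-A rendering is dark background, bright
vessels, an empty FAZ disc, and multiplicative log-normal speckle; the FAZ
is rendered only in the OCT-A/mask modality because capillary-scale detail
is not visible in fundus images. A configurable rigid misalignment warps
the OCT-A/mask pair out of the fundus frame, and the manifest stores the
inverse as the aligning transform, which the preprocessing module applies —
the manual alignment GUI of the original workflow is out of scope, so this
module only applies stored transforms.

What the phantom reproduces is the *structural* relationship the translator
must learn: co-registered dark-on-bright versus bright-on-dark renderings
of one vessel tree, with modality-appropriate noise. What it does not
reproduce: real capillary plexi (no microvasculature below the rasterized
tree), pathology, lens distortion, illumination gradients, or the
imperfect rigid registration of real multimodal pairs. Passing phantom
tests therefore demonstrates that the pipeline's machinery — sampling,
optimization, checkpointing, stitching, binarization, densitometry — is
correct and that the model family can learn a fundus-to-OCT-A mapping; it
does not certify clinical-scale image quality, which requires the deposited
cohort and full-scale training.

## Problem sizes used in tests

The test suite runs a scaled-down study chosen to exercise every stage in
full: 40 phantom subjects of 128×128 px at 24 px/mm (the 3 mm ETDRS outer
circle, radius 36 px, fits with margin), split 25 train / 5 validation / 10
held-out test to mirror the published 25/5 counts; training uses 64-px
patches drawn only from 80-px macula/disc regions (so generalization can be
judged outside them), 20 patches per epoch for 150 epochs, with a depth-2,
8-base-filter generator against a 2-block discriminator. Stochastic
end-to-end checks run under fixed seeds with a 3-seed majority rule. The
full-scale recipe (512-px patches, depth-4/64-filter generator, 1000
epochs, stride-8 stitching of 2592×1944 fields) is available through the
same configuration objects and the packaged `defaults.yaml`.

## Numerical and degenerate-input choices

* Coordinates are 0-based `(row, col)` with pixel centres at integers;
  rotations are counter-clockwise positive about the geometric image
  centre, applied as rotation, then scale, then translation. Resampling is
  inverse-mapping bilinear (nearest-neighbour for masks); out-of-field
  pixels are zeroed and flagged in a validity mask.
* Normalization is $v/127.5 - 1$; denormalization clips to $[-1,1]$ and
  rounds half away from zero (0 maps to 128).
* `crop_roi` uses pixel-area mapping (pixel $u$ spans $[u-\tfrac12,
  u+\tfrac12)$), making a full-image crop at native resolution an exact
  identity; crops record their box for later re-insertion and rescale
  `px_per_mm` to `output_px / side_mm`.
* Empty ETDRS regions yield `NA` density with a warning; zero-variance
  density vectors yield `NA` correlations reported as undefined; PR curves
  require both classes and refuse single-class inputs.
* All randomness flows through R's RNG under explicit seeds: per-subject
  phantom seeds are drawn without replacement (hence distinct), pipeline
  stages derive seeds from the global seed by a fixed multiplicative hash,
  and two fits with one seed agree loss for loss.

## Known limitations

The adversarial game is optimized patch-wise with batch size 1 and no
learning-rate schedule, which is faithful to the recipe but leaves the
discriminator weak on small phantom runs — the L1 term does most of the
work there, as the $\lambda = 100$ weighting intends. The stitcher averages
overlapping windows uniformly; no feathered blending is attempted. The
vesselness binarizer, while standard, is not a learned segmenter: on real
OCT-A its masks will differ from those of a supervised model, which is why
the external-map path exists. FAZ-area estimation and perfusion-intensity
density are intentionally not implemented.
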