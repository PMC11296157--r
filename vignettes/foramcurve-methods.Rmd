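---
title: "Methods: training-set sufficiency for 3D microfossil segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: training-set sufficiency for 3D microfossil segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Manual segmentation of micro-CT volumes is the bottleneck of volumetric
morphometrics: a single foraminifera specimen takes on the order of a
working day to label by hand. Once a convolutional network can replace
the annotator, the practical question becomes *how many manually
segmented specimens are enough*, and whether cheap label-preserving
data augmentation can substitute for additional annotation.
`foramcurve` implements that study design end to end at desk scale:
synthetic shells stand in for the scans, a small 3D U-Net stands in for
the production-scale network, and the statistics operate on the
resulting learning curves exactly as they would on real data.

## The segmentation problem and its labels

Every volume is a `(z, y, x)`-indexed voxel grid with isotropic voxel
size (default 1.75 µm, stored as metadata rather than hard-coded).
Segmentations use three classes: background (0), the external calcite
wall (1), and the internal chamber space (2). The internal class
includes sediment-filled cavity: a human annotator labels the cavity by
shape, not by brightness, so in the phantoms the sediment infill
changes only the greyscale channel, never the label. Accuracy is the
multi-label Dice score

$$\mathrm{Dice} = \frac{2\sum_i |X_i \cap X'_i|}{|X| + |X'|},$$

summed over the labels in scope. By default only the two foreground
labels enter the score: the background class dominates the volume
(90%+ of voxels), and counting it would compress every comparison
toward 1. A flag (`labels_in_scope`) restores the strict all-labels
reading, under which the denominator is twice the voxel count. Two
segmentations with no in-scope voxels at all score 1 by convention.

The two volumetric traits are total volume (external plus internal, in
µm³) and *percentage calcite*, defined here deliberately literally: external
volume divided by internal volume, times 100. That quantity is a ratio rather than a true
percentage; the conventional external/(external+internal) form is
available behind `calcite_convention = "fraction_of_total"`. When a
segmentation contains no internal voxels the ratio is flagged
undefined (`NA`), never infinity.

## The phantom generator: what it emulates and what it does not

`generate_phantom()` builds a shell as spheres of geometrically growing
radius (`spiral_growth_rate` per chamber) placed along a logarithmic
spiral with an axial rise (`trochospire_pitch`), the minimal generative
geometry for a lenticular, low-trochospiral, multi-chambered test with
a continuous outer wall. The wall is the set of voxels inside the
union of outer spheres but outside the union of cavity spheres (outer
radius minus `wall_thickness_vox`). Chamber layouts that would leave
the volume are shrunk uniformly to fit (recorded in the
`"fitted_scale"` attribute) or raise an error — never clipped
silently.

Greyscale is per-class mean intensity plus additive Gaussian noise
clamped to the 16-bit range. The one deliberately realistic
complication is *sediment infill*: a fraction `infill_fraction` of
cavity voxels (filled bottom-up, as settled sediment) takes an
intensity close to the wall's. The constructor enforces that the
infill–wall contrast is small relative to the wall–cavity contrast,
because low within-shell contrast is the stated mechanism that makes
internal structure hard to segment. `infill_fraction` is therefore the
package's difficulty dial: 0 gives an easy, intensity-separable world;
values near 1 collapse the within-shell contrast entirely.

`generate_population()` draws per-specimen parameters from uniform
ranges, emulating inter-specimen variation in size, shape and infill,
and splits specimens 20/10/20 into train/validation/test pools by
default (the full-scale design; tests use smaller pools). In the
high-infill experiments the infill fraction varies per specimen
(default range in those tests: 0.65–0.95 around the nominal 0.8),
because sediment load varies among real specimens "from abundant to
absent" and that variation — uncorrelated with shell size — is
precisely what destroys the internal-trait agreement.

Not emulated: CT physics (no beam hardening, rings, partial-volume
blur, reconstruction artefacts), anisotropic voxels, species-level
taxonomy. A green test on phantoms therefore establishes that the
*pipeline* behaves as designed, not that any particular Dice value
transfers to real scans.

## Augmentation: the six axis orders

The augmentation scheme is exactly the six orderings of the three
volume axes ("xyz" identity plus "yzx", "zyx", "xzy", "yxz", "zxy"),
applied identically to grey and labels. These are implemented as pure
axis permutations (array transposes). Three of the five non-identity
permutations are improper (mirror) transforms; such reorderings are
conventionally described as rotations and imply no flip convention, so
no flips are applied by default, and `proper = TRUE` adds a single axis reversal
after odd permutations for users who want only proper rotations.
Augmentation expands N specimens to exactly 6N stacks (1 → 6,
20 → 120); `augment_set()` refuses input that is already augmented so
sets cannot be double-expanded. Per-label voxel counts, volumetric
traits, and Dice between commonly-reoriented volumes are exactly
invariant — these are permutation-equivariance identities, not
approximations, and the tests assert them exactly.

## The network and training protocol

The segmentation model is a 3-level 3D U-Net (two 3×3×3 convolution +
ReLU blocks per level, 2³ max-pooling, nearest-neighbour upsampling
with skip concatenation, 1×1×1 output convolution, softmax), written
directly in C++ because no deep-learning framework ships with the
target R installation. The backward pass is verified against central
finite differences in the test suite (tolerance 1e-4 on randomly
sampled weights), which is the correctness anchor for everything
downstream.

Training follows the full-scale protocol: voxel-wise three-class
cross-entropy (the loss is not stated at full scale; unweighted
cross-entropy is the default, with optional per-class loss weights —
`class_weights` — because at test scale the internal cavity is only a
few percent of the voxels and a narrow network otherwise lingers in
the all-background basin; the learning-curve tests weight
background/external/internal as 1/3/6), mini-batch SGD with learning
rate 0.01, decay 1e-6 (Keras-style `lr/(1 + decay * t)`), momentum
0.9, Nesterov enabled; sliding-window patches (full-scale: 64³ patches
at stride 32, volumes rescaled to 256³, batch 24) with the final
window of each axis snapped to the volume boundary so every voxel is
covered. "Batch size of 24 samples per epoch" is read as mini-batch
size (patches per gradient step), with each epoch iterating over all
patches once. The "scaled to 256³" step is read as volume-level
rescaling before patch extraction (trilinear for grey,
nearest-neighbour for labels); both readings are expressible in
`train_config()`, and the desk default (`desk_config()`) rescales to
64³ with 16³ patches, stride 8, batch 8 and a narrow (8-channel) net.
The test suite drops further, to 16³ volumes, 8³ patches and a
2-channel net, and raises the learning rate to 0.1 — at this width the
default 0.01 needs hundreds of epochs to escape the
all-background basin, and the raised rate is a test-scale compensation,
not a protocol change.

After every epoch the whole-volume validation Dice (mean over
validation specimens) is appended to the history. Early stopping keeps
the running-best epoch's weights and terminates once the best epoch is
`patience_epochs` (default 25) behind, within a `max_epochs` cap
(default 200). Because the returned model is the running maximum, a
patience run and a full-length run with the same seed return *exactly*
the same best validation Dice whenever the full run's best epoch
precedes `max_epochs - patience_epochs` — the desk-scale analogue,
exact per seed, of the expectation that early stopping loses nothing
once training has plateaued. Replicate training (default 3 networks per training set, with
derived seeds) selects the median-accuracy network — the lower middle
after a stable sort, so even counts and exact ties are deterministic.

Prediction stitches patchwise softmax scores over every overlapping
window and takes the per-voxel argmax of the accumulated scores
(overlap handling is not specified at full scale; score accumulation
is the standard choice). Prediction is orientation-consistent only in
expectation, and the contract deliberately does not promise exact
equivariance.

All randomness (initialization, patch shuffling, population draws)
flows from explicit integer seeds through R's RNG; the C++ core is
deterministic, so identical seeds give bit-identical histories.

## Mesh shape analysis

Surfaces are extracted per class as the voxel-boundary (cuberille)
surface: two consistently outward-oriented triangles per exposed voxel
face. This replaces marching cubes (no isosurface library exists in
the target R stack, and embedding its case tables buys little at desk
scale): the enclosed signed volume of the extracted surface equals the
voxel volume exactly, component counts are exact (a hollow shell's
wall yields two boundary components), and the blockiness is removed by
the subsequent smoothing. Decimation is vertex clustering with a cell
size grown until the face budget (full-scale protocol: 50 000 faces)
is met, a no-op when already under budget; smoothing is Taubin
lambda/mu (0.5/−0.53) — a Laplacian-style smoother whose expansion
pass compensates shrinkage, keeping sphere volumes within 5% at the
reductions the tests exercise.

Population alignment is a landmark-free stand-in for generalized
Procrustes surface analysis: every mesh is centred, scaled to unit
centroid size, and rigidly aligned to a chosen reference (atlas) mesh
by iterated closest-point correspondence on area-weighted surface
samples with an orthogonal-Procrustes (SVD, proper rotation) update.
ICP is initialized from principal-axes alignment over the four proper
sign flips, which removes the large-rotation local minima of plain
ICP; all meshes share one sampling seed, so meshes with identical
topology receive corresponding samples and identical specimens produce
identical features. Convergence is declared when the mean
nearest-neighbour distance changes by less than `tol` (default 1e-5
of centroid size).

Shape scores come from kernel PCA on closest-point displacement
features (each mesh described by the displacement from every reference
sample point to its nearest point on that mesh), with a radial-basis
kernel whose bandwidth defaults to the median pairwise feature
distance — a scale-free heuristic, since the full-scale method's
deformation-model inputs are out of scope here. As the bandwidth
multiplier grows the centered kernel approaches the feature Gram
matrix, so wide-bandwidth kernel PCA converges to linear PCA; the test
suite uses that limit (bandwidth scale 10) to check the kPCA machinery
against a linear-PCA oracle on features generated on a 2-D affine
manifold, and separately asserts the defaults' qualitative behaviour.
At the default (median) bandwidth the embedding is genuinely
non-linear and its variance fractions are *not* expected to match
linear PCA. An all-identical population returns zero scores with the
variance fractions flagged `NA` (tolerance 1e-9 on the median feature
distance). Per-axis variance percentages are data-dependent and are
not comparable across datasets.

## The experiment and its statistics

`run_learning_curve()` crosses training-set sizes (full scale: 1, 2,
4, 8, 16, 20 from a 20-specimen pool; desk default 1, 2, 4, 8 from 8)
with the two arms (original, augmented), trains the replicates per
cell, and keeps each cell's median network. Training sets are nested
by default (set₁ ⊂ set₂ ⊂ …) along one seeded ordering — nesting is
not specified at full scale; it is chosen here to reduce
between-size sampling variance, and a flag samples independently.

* `fit_dice_glm()` — Dice against `log2(size)`, arm, and their
  interaction under a logit-link quasibinomial GLM. The size scale and
  predictor coding are not fixed by the full-scale protocol, so the
  coefficients are reported rather than compared against external
  values; the test instead verifies parameter recovery on records
  simulated from a known logit-linear model (within 2 SE). An
  all-equal response returns a flagged zero-slope fit.
* `compare_early_stopping()` — paired patience/full runs per size with
  identical seeds; reports the pairs, their squared correlation, and a
  one-way F-test between stopping modes (a likelihood-ratio test and a
  nested-model ANOVA F coincide in role here; the F-test is
  implemented).
* `agreement_regression()` — per-training-set OLS of network-derived
  on manually derived trait values (slope, intercept, R²) plus a
  pooled nested-model F-test for group-specific slopes. Constant
  manual values flag an undefined R².
* `trait_agreement()` — applies each cell's median network to the test
  pool; external-structure agreement is the R² of external volume,
  internal-structure agreement the R² of percentage calcite (the trait
  that hinges on the sediment-prone cavity). When a weak network
  predicts no internal voxels at all, its percentage calcite is
  undefined; the difficulty tests read that as zero internal
  agreement, the limiting case of "internal is harder".
* `minimum_specimens()` — smallest size whose median Dice reaches the
  accuracy threshold (default 0.95), per arm, `NA` when never reached.

No multiple-testing correction is applied anywhere, matching the
full-scale analysis.

## Numerical choices and degenerate inputs

* Patch dimensions must be divisible by 4 (two pooling levels); the
  patch grid always covers every voxel via boundary snapping.
* Softmax is computed with max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Argmax ties in prediction resolve to the lowest class code;
  nearest-neighbour ties in ICP and feature extraction resolve to the
  lowest index.
* Weight init is He-scaled Gaussian from the run's seed; biases start
  at zero.
* 8-bit greyscale input is rescaled to the 16-bit range on read
  (×257); label codes outside {0, 1, 2} are reported, never remapped.
* TIFF I/O is a minimal in-package reader/writer for baseline
  uncompressed single-channel multipage stacks (8/16/32-bit unsigned,
  either byte order on read; little-endian, one strip per page on
  write), because no TIFF package exists in the target installation.
  The test suite cross-checks written files against an independent
  reader.

## Known limitations

* Desk-scale Dice values, GLM coefficients and variance fractions are
  not comparable to full-scale results; only definitional
  identities (augmentation counts, Dice bounds, equivariances,
  early-stopping equality) and qualitative patterns (learning curves
  rise; augmentation helps most at small sizes; internal structure is
  harder under heavy infill) transfer.
* The cuberille + clustering + Taubin mesh stage is a deliberate
  simplification of marching cubes + quadric decimation; at extreme
  reductions of thin-walled shells (two nearby surfaces collapsing
  into one cluster cell) volume is not preserved.
* The network is narrow and trained on small volumes; its failure
  mode at very small training sets is total background collapse,
  which the learning-curve tests treat as a legitimate (bad) outcome
  rather than an error.
* Kernel-PCA scores depend on the sampling density and bandwidth;
  they are comparable within a population processed together, not
  across populations.
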