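---
title: "musclesegkit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{musclesegkit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

musclesegkit implements a complete pipeline for multi-label skeletal-muscle
segmentation of 3D MR volumes: synthetic phantom generation, per-muscle
statistical shape models (SSMs), deformable registration, shape-model-driven
data augmentation, four encoder–decoder segmentation networks trained
slice-wise, and 3D evaluation metrics with paired nonparametric statistics.
This vignette explains the model behind each stage, the default parameters
and why they are what they are, and the package's limitations.

```{r setup}
library(musclesegkit)
```

# Data model

Volumes are `msk_volume` (3D double array + mm spacing), label maps are
`msk_labelmap` (3D integer array, 0 = background, 1..C = muscles), and an
`msk_subject` couples the two on one grid with a provenance record. I/O is
NIfTI via RNifti; a cohort directory holds `<id>_img.nii.gz` /
`<id>_lab.nii.gz` pairs plus a JSON manifest.

The pipeline assumes isotropic 1 mm spacing by default — the resolution a
merged lower-limb acquisition is resampled to — but every stage honours
anisotropic spacing where it matters (surface extraction, metrics, EDTs).

# Synthetic phantoms

No public cohort with per-muscle labels exists at the scale needed for tests,
so `phantom_spec()` / `generate_cohort()` emulate knee-to-hip anatomy:
elongated quasi-cylindrical muscle compartments arranged as angular wedges
around a central bone, a surrounding fat sheath, additive Gaussian noise and
a smooth multiplicative bias field. Compartment radii and centre-lines are
perturbed per subject by seeded smooth morphological jitter, so a cohort has
genuine shape variation while remaining fully reproducible from its seed.
Grids are configurable down to ~32³ so that unit tests stay fast.

```{r}
spec <- phantom_spec(grid_shape = c(32, 32, 48), n_muscles = 4, seed = 101)
cohort <- generate_cohort(spec, 4)
cohort[[1]]
```

# Statistical shape models

## Particle correspondence

For each muscle, every subject's boundary surface (`extract_surface()`, voxel
centres of boundary voxels in mm) is sampled with `m` corresponding
particles. `optimize_correspondence()` minimises an ensemble-entropy
objective: the sum of a Gaussian-model entropy across shapes (which pulls
corresponding particles into statistical agreement) and per-shape Parzen
entropies (which spread particles uniformly over each surface). Particles
are initialised from a common seed point and split in stages
(`m0 = 16 → m`), with gradient steps projected into each surface's local
tangent plane and re-projected onto the surface. The regularisation
`alpha_rel = 0.1` sets the covariance ridge relative to the total ensemble
variance, and the Parzen kernel width follows the local particle density
(`sigma ~ sqrt(area / m)`). The trace of accepted objective values is
non-increasing within every stage by construction (steps that do not
decrease the objective are rejected and the step size shrinks).

## PCA shape space

`fit_pca()` aligns the corresponded particle sets by rigid generalised
Procrustes (translation always; rotation off by default, because surfaces
extracted from a common scanner frame are already co-oriented and a
rotation-free model maps straight back onto the image grid) and extracts the
mean and up to N−1 orthonormal modes with variances from the ensemble
covariance (via SVD). `synthesize_shape(model, mode, s)` returns
`mean + s·sqrt(λ_mode)·v_mode`, so `s` is in SD units.

# Deformable registration

`register()` estimates a dense displacement field parameterised on a coarse
nodal grid (spacing `NS` voxels, trilinear interpolation to voxels). The
objective is the mean squared similarity residual plus
`λ/500 ×` the mean squared forward difference of nodal displacements.
Label maps are compared through per-label *clamped signed distance*
channels — SSD on raw integer labels carries no useful gradient, whereas
distance channels give a smooth, boundary-aware similarity. Optimisation is
L-BFGS with the analytic gradient, over a two-level multiresolution pyramid
to extend the capture range.

Defaults (`registration_params()`): `NS = 5` voxels, `λ = 50`, clamp 20
voxels — suited to whole-volume alignment of full-size images.
`augmentation_params()` overrides them (`NS = 2`, `λ = 5`, clamp 3) because
phantom compartments span only 10–20 voxels on the 48×48×96 test grid: a
finer nodal grid and a boundary-focused clamp are needed for the
registration to move individual compartments, and the smooth SDF objective
converges in ~20 L-BFGS iterations per level.

# Augmentation

`augment_cohort()` runs the full pipeline:

1. one SSM per muscle label (`build_ssms()`);
2. whole-subject target label maps at planned shape-space coordinates — the
   default plan is the model mean and the ±1 SD shapes of mode 1
   (`augmentation_plan()`);
3. each target is paired with all but one original subject (the left-out
   subject rotates round-robin), and `produce_subject()` registers each
   reference's label map onto the target, then warps the reference image
   (trilinear) and labels (nearest-neighbour) through the same field.

A cohort of N therefore grows to N + 3(N−1) subjects — 10 → 37 with the
default plan. Because the displacement field is stored in the provenance,
an augmented label map can be reproduced *bit-identically* by re-warping its
reference: image and labels are perfectly matched by construction, which is
the property that makes the synthetic pairs usable as training data.

Two implementation details matter for robustness:

- **Donor densification.** Synthesised particle sets are sparse (`m = 256`
  by default); rasterising them directly is noisy. Instead the per-particle
  displacement from the donor shape is carried onto the donor's *dense*
  boundary cloud by inverse-distance-weighted k-nearest-neighbour
  interpolation, and the dense deformed cloud is rasterised.
- **Signed distance rasterisation.** A point cloud with outward normals is
  converted to a signed field by a winding-number-style sign test near the
  surface, with far-field magnitudes from an exact Euclidean distance
  transform of the voxelised inside mask. Target label maps composite the
  per-muscle fields by "most interior wins"; only *deep* conflicts (voxels
  more than one voxel inside two shapes) count as inconsistency, since
  adjacent compartments legitimately contest a one-voxel band along shared
  faces.

# Networks and training

Four 2D encoder–decoder architectures are provided: `unet`, `unetpp`
(dense nested skips), `ffu` (feature-fusion U-Net: multi-scale skip fusion
plus an ASPP bottleneck) and `affu` (FFU plus attention gates on the skips
and CBAM channel/spatial attention). No deep-learning framework is used:
the networks run on a small tape-based reverse-mode autograd with
RcppArmadillo convolution kernels. Setting `gate_passthrough = TRUE` and
`cbam_identity = TRUE` in `network_forward()` reduces AFFU exactly to FFU
under shared weights — the ablation identity the test suite checks.

Training (`train()`) is slice-wise along the third axis: volumes are
z-scored per volume, sliced, and fed as shuffled mini-batches of random
square crops (training only; validation uses full slices). The loss is
cross-entropy + soft Dice; the optimiser is SGD with momentum 0.9 and the
geometric schedule `lr = 0.01 · 0.9^(epoch−1)` (`learning_rate()`).
Defaults follow the architecture: batch 16 and crop 256 for unet/unetpp,
batch 10 and crop 125 for the heavier ffu/affu (crops clamp to the slice
size on small phantoms). The split is at subject level, the checkpoint with
best validation DSC is retained, and non-finite or diverging loss aborts
with a diagnostic. `predict_labels()` reassembles 3D label maps from
per-slice argmax.

`run_experiment()` provides the bookkeeping: `cross_validation`
(leave-one-out), `cross_cohort` (train once, evaluate a disjoint test
cohort) and `augmented` (leave-one-out where augmented subjects derived
from the held-out original are excluded from its training fold — the
guard against information leakage through the augmentation).

# Metrics and statistics

`dsc()`, `rve()` and `hausdorff()` are the three 3D metrics; Hausdorff uses
an exact anisotropic Euclidean distance transform between boundary voxel
sets, in mm. Conventions: DSC of two empty masks is 1 (a correctly predicted
absent label), RVE is relative to the reference volume and errors on an
empty reference, Hausdorff errors on any empty mask. `evaluate_subject()`
scores every reference label and flags labels missing from the prediction
(DSC 0, RVE 1, Hausdorff NA).

`compare_models()` performs the paired analysis: a Kolmogorov–Smirnov check
of the score differences against a fitted normal (to justify nonparametric
testing), then a Wilcoxon signed-rank test — exact for n ≤ 25 without ties,
normal approximation otherwise. `wilcoxon_exact_enum()` computes the exact
p-value by full 2^n sign-flip enumeration and serves as the independent
oracle for the exact path.

# Limitations

- Phantoms are geometric stand-ins, not anatomically faithful muscles, and
  no MR physics is simulated beyond noise and a smooth bias field.
- The registration is small-deformation (no diffeomorphic guarantee) and
  label-map registration requires both maps to share a label vocabulary.
- The networks are 2D slice-wise; no 3D context beyond slice reassembly.
- The pure-R/Armadillo training loop is CPU-bound: full-scale 256×256
  training is possible but slow; the defaults scale down proportionally for
  phantom-sized grids.
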