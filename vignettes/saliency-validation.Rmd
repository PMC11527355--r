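---
title: "Validating attribution saliency for brain-age CNNs with synthetic ventricular dilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating attribution saliency for brain-age CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(salvox)
```

## The problem

Deep 3D convolutional networks estimate a person's *brain age* (BA) from a
structural T1-weighted MRI with useful accuracy, but the estimate by itself
says nothing about *which* anatomy drove it. Attribution-based saliency
methods promise voxelwise answers, yet on real cohorts there is no ground
truth against which to judge them: nobody knows which voxels "really" carry
a person's brain age. salvox implements a validation strategy that
manufactures its own ground truth. A known, age-proportional anatomical
change — dilation of the lateral ventricles into adjacent white matter — is
injected into every training volume, a CNN is trained on the modified data,
and seven attribution methods are scored on how well their saliency maps
recover the voxels where the signal was injected.

The package is fully self-contained: a phantom generator stands in for the
multi-site clinical cohorts that the original validation design used, so
the entire pipeline (simulate, perturb, train, attribute, evaluate) runs on
a laptop from a single master seed with no data download.

## The synthetic phantoms and what they emulate

`generate_phantom()` builds a cubic volume (default 32^3 voxels at 2 mm)
containing four tissue classes: background (intensity exactly 0, the
skull-stripped convention), a non-white-matter cortical shell, a white
matter core, and a mirrored pair of lateral-ventricle ellipsoids. Voxel
intensities are Gaussian per tissue class (defaults are T1-like: WM 110 ± 8,
NWM 80 ± 10, ventricular CSF 30 ± 6, clipped at zero), giving distinct but
overlapping histograms for the histogram-based metrics to work with.

The ventricle radius carries the age signal:

* the *age-expected* radius grows linearly,
  `base + growth * (ca - age_min)` (defaults: 2 voxels at age 40,
  0.02 voxels/year);
* each subject adds a seeded Gaussian jitter (`ventricle_radius_sd`,
  default 1 voxel, truncated at two standard deviations).

The jitter is essential, and deliberately large relative to the age trend.
Real cohorts show wide ventricular variability at any fixed age, so the
natural ventricle-size signal available to a model trained on *unmodified*
volumes is noisy and weak. The injected dilation, by contrast, is a clean
deterministic function of age. This asymmetry reproduces the regime the
validation design needs: the model trained on perturbed volumes (M_D) has a
strong, focal, *known-location* signal to exploit, while the control model
trained on unperturbed volumes (M_ND) does not. With a deterministic radius
(jitter 0) the phantoms encode age almost noiselessly at exactly the
ground-truth voxels, both models attend the same shell, and the M_D/M_ND
contrast degenerates — the validation would have nothing to validate. Set
`ventricle_radius_sd = 0` if you want the deterministic encoding (the
monotone LV-volume contract is exact in that case).

What the phantoms do *not* emulate: cortical folding or any anatomical
realism, lesions, scanner/site effects, registration error. Passing tests
on phantoms therefore demonstrate that the pipeline recovers a known focal
signal under controlled conditions — not that any saliency method is
trustworthy on clinical data.

## The ventricular-dilation perturbation

For each subject, `dilation_coefficient()` maps chronological age to a
coefficient in [0, 1]: 0 at or below the cohort's 5th age percentile, 1 at
or above the 95th, linear in age between those anchors. `dilate_ventricles()`
then:

1. finds the ventricle edge voxels (6-connectivity; the face-adjacency
   convention is the conservative volumetric reading of "adjacent");
2. splits their non-ventricle face neighbors into adjacent white matter
   (AWM) and adjacent non-white-matter (ANWM);
3. selects `round(coeff * |AWM|)` AWM voxels uniformly without replacement
   (round half to even, so selection counts are unbiased across a cohort)
   and sets each selected voxel's intensity to that of its nearest ventricle
   edge voxel (Euclidean distance, ties broken by (x, y, z) lexicographic
   order — a deterministic reading of "corresponding ventricle voxel");
4. re-assigns the edge voxels of the *enlarged* ventricle region to the mean
   ANWM intensity, reflecting that structure boundaries carry their own
   intensity distribution. This step is skipped when nothing was replaced or
   the ANWM set is empty (in the default phantoms the ventricles are fully
   embedded in white matter, so it is exercised by crafted label fixtures).

The surrogate ground truth (`build_ground_truth()`) is the voxelwise mean of
`|perturbed - original|` across the cohort, normalized to total mass 1.
Absolute differences are used because replacement lowers intensity
(WM to CSF) and the saliency convention is magnitude-based. The fixation map
is the indicator of the ground truth's support — the simplest deterministic
construction; DC and NSS consume the fixation map, NMI/CC/SIM the
continuous ground truth.

## The brain-age CNN

`build_model()` constructs the regression architecture: convolutional
blocks of convolution (valid padding) -> batch normalization -> ReLU -> 2^3
max pooling, then a flatten and dense head with a linear scalar output. The
full-scale defaults are a 128^3 input, four blocks with 16/32/64/128 filters
of 6^3 kernels, dropout 0.2 on blocks 2–4, one 128-unit dense layer, MAE
loss with Adam at learning rate 1e-4, early-stopping patience 20. Reduced
desk-scale configurations (e.g. 32^3, two blocks of 4/8 filters with 3^3
kernels, learning rate 1e-3) run through the same code path.

Choices the architecture description left open, resolved as follows:

* ReLU is applied after batch normalization within a block (the
  conventional ordering);
* the dense stage is flatten -> dense -> dense(1); the scalar-output
  constraint fixes the geometry;
* no activation on the regression head (brain age is unbounded regression);
* on stopping, the weights of the best-validation epoch are restored (the
  standard early-stopping contract);
* targets are standardized internally during training and the affine
  mapping is folded into the model, so optimization is well-scaled without
  changing the represented function;
* `train_model()` stops after `patience` consecutive epochs without strict
  validation improvement — a monotone-worsening validation sequence with
  patience 20 stops at epoch 21.

Everything is implemented in base R: im2col convolution driven by BLAS
matrix multiplication (index matrices cached per geometry, chunked when
large), a transposed convolution for input gradients, exact max-pool argmax
routing, and batch statistics in training mode versus running statistics at
evaluation. The same backward machinery serves training, plain input
gradients, the guided-ReLU variant, and Grad-CAM feature capture, which
keeps the seven attribution methods definitionally consistent with the
model they explain.

## The seven attribution methods

All methods return a *signed raw* field; `normalize_saliency()` takes
absolute values and normalizes to total mass 1 ("saliency probability
density"), so a single normalization step serves every method.

* **G** — gradient of the output with respect to the input.
* **IXG** — input times gradient.
* **MG** — gradient with voxels outside a brain mask zeroed; the default
  mask is the nonzero-intensity support (skull-stripped inputs make that
  the natural brain mask).
* **GB** — guided backpropagation. Both guided gates are applied: gradients
  are zeroed where the forward ReLU activation was non-positive *and* where
  the incoming gradient is negative. The method's original formulation uses
  both gates; implementing only the gradient gate is the other defensible
  reading, and the difference is documented here rather than hidden.
* **GGC** — guided Grad-CAM: channel activations of the final convolutional
  block weighted by spatially averaged output gradients, rectified,
  upsampled trilinearly (the 3D analogue of the standard bilinear choice;
  nearest-neighbor available), multiplied voxelwise with GB.
* **IG** — integrated gradients along the straight path from an all-zero
  baseline, Gauss–Legendre quadrature with nodes mapped affinely from
  [-1, 1] to [0, 1]; 50 nodes by default. Note that the path gradient of a
  ReLU network is piecewise constant, so the 50-node convergence
  (completeness) delta is a few percent; the completeness property test
  uses a much finer quadrature. With a single node the rule degenerates to
  a midpoint input-times-gradient evaluation — the sense in which IXG is
  the simplest version of IG, and exactly IXG for a linear model.
* **GSHAP** — gradient SHAP: per sample, jitter the input with Gaussian
  noise (`gshap_sigma`, default 0 matching the common reference default),
  draw a baseline uniformly from a pool, evaluate the gradient at a
  uniformly random point of the interpolation segment, multiply by
  (jittered input − baseline); average over 5 samples by default. The
  uniform interpolation point is the natural choice where no distribution
  is stated.

For analytic validation the package ships `linear_volume_model()`, a model
with closed-form gradient: G and GB return the weight field exactly, and
IXG, IG (any node count), and noiseless GSHAP return input times weights
exactly. CNN gradients are additionally validated against central finite
differences.

## Scoring

`score_saliency_maps()` computes, per method:

* **DC** — Sørensen–Dice after binarizing the saliency map to its top-N
  voxels with N the fixation support size (threshold-free and
  scale-invariant; ties broken lexicographically). The standard
  `2|A∩B|/(|A|+|B|)` denominator is used.
* **NMI** — `(H(A)+H(B))/H(A,B)` over 64 equal-width bins by default;
  range [1, 2].
* **NSS** — mean of the population-z-scored saliency over fixation voxels.
* **CC** — Pearson correlation over all voxels.
* **SIM** — sum of voxelwise minima of the two unit-mass maps.

Population (not sample) standard deviations are used for NSS z-scoring: a
map's voxels are the full population, not a sample from one. Cohort maps
average per-subject normalized maps and renormalize, preserving the density
invariant. `percent_diff_vs_baseline()` reports
`100 * (score - score_MG) / |score_MG|` per metric against the
masked-gradient baseline; a zero baseline score flags the cell undefined.

## The validation experiment and its problem sizes

`run_experiment()` (or the `inst/cli/salvox.R` subcommands) chains the
stages under one master seed, which fans out deterministically to per-stage,
per-subject streams (`derive_seed()`), so results are independent of
evaluation order and bit-reproducible end to end.

The package's own validation experiment uses 200 phantoms at 32^3 voxels,
ages uniform over 40–90 years, an 80/10/10 train/validation/test split, and
the reduced two-block CNN (up to 30 epochs, patience 8). At these sizes the
dilated-trained model reaches a validation MAE of roughly 2–7 years against
a cohort age standard deviation of about 15 years, the full experiment runs
in minutes on one CPU core, and:

* cohort-mean IG maps of the dilated model score above a spatially shuffled
  permutation null (100 shuffles, one-sided p <= 0.05) on all five metrics;
* the dilated model's scores exceed the non-dilated model's on every metric
  (direction only) — the desk-scale analogue of the original design's
  dilated-versus-control contrast.

Saliency maps for both models are computed on the *unperturbed* test
volumes, mirroring the original design's evaluation on an independent
unmodified cohort.

## Numerical choices and degenerate inputs

* All-zero attribution fields (e.g. MG with an empty mask, or a model that
  collapsed to a constant predictor) raise an explicit degenerate-attribution
  error rather than producing a NaN map.
* Constant maps make NMI, NSS, and CC undefined; each raises an explicit
  error. Dice of two empty maps is likewise refused.
* Pool windows use floor division (a 27^3 feature map pools to 13^3);
  max-pool ties resolve to the first element, and top-N saliency ties
  resolve lexicographically, so every path is deterministic.
* Batch-norm uses eps 1e-5 and running-statistics momentum 0.1.
* Very small training runs (a dozen 16^3 phantoms for a handful of epochs)
  can collapse to a constant predictor through dead ReLUs; the attribution
  layer then correctly reports degenerate fields. The shipped experiment
  sizes avoid this regime.

## Limitations

The phantoms are geometric idealizations; no claim is made about saliency
fidelity on real MRI. The perturbation touches only the lateral ventricles;
other age-related changes (cortical thinning, white-matter integrity) are
out of scope. Wall-clock benchmarking of attribution methods and qualitative
anatomical grading are likewise out of scope. Clinical-scale cohorts
(thousands of 128^3 scans) and the real-data accuracy figures they support
are not reproducible at desk scale and are not attempted: the full-scale
architecture is exercised for its contracts (shape, geometry, parameter
counts), not trained.
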