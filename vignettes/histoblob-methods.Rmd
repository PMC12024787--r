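---
title: "Detecting nuclear lesions in H&E histology: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nuclear lesions in H&E histology: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoblob)
```

histoblob detects cancerous nuclear lesions ("blobs") in hematoxylin-and-
eosin stained breast histology images. This vignette explains the models
behind each stage, the parameters that matter, the numerical choices, and
what the synthetic test bed does and does not establish about real tissue.

## The optical model and stain unmixing

Transmitted light through stained tissue follows Beer–Lambert absorption:
with incident intensity $I_0$ and per-pixel stain concentrations
$c = (c_H, c_E)$, the recorded intensity is
$I = I_0\,10^{-M c}$, where the columns of $M \in \mathbb{R}^{3\times 2}$
are the unit optical-density (OD) absorbance vectors of hematoxylin and
eosin. Working in OD space, $\mathrm{OD} = -\log_{10}(I/I_0)$, stain
contributions add linearly, which is what makes unmixing a linear problem.

`estimate_stain_matrix()` implements Macenko-style estimation: discard
near-transparent pixels (all channels must exceed `beta`, default 0.15 OD —
the alternative reading, discarding *high*-OD pixels, would remove all
tissue), take the plane of the two leading right-singular vectors of the
retained OD cloud, and map the `alpha` / `100 - alpha` percentile angles
(default `alpha = 1`) of the projected pixels back to unit vectors. The
percentile makes the extremes robust to outlier pixels. Hematoxylin is the
extreme vector with the larger red-to-blue OD ratio: blue-purple
hematoxylin absorbs red light, pink eosin transmits it. (Angle order in
the SVD plane is not a reliable identifier because the sign and
orientation of singular vectors is arbitrary.)

Concentrations are recovered per pixel by non-negative least squares
(`compute_concentrations()`); for two stains the NNLS optimum has a closed
form — the unconstrained solution when it is feasible, otherwise the better
of the two clamped single-stain projections — so the concentration map is
structurally non-negative. Normalization to a reference
(`normalize_to_reference()`) rescales each concentration channel so its
99th percentile matches the reference's and re-renders through the
reference stain matrix; the 99th percentile is a robust stand-in for "the
densest stain in the image".

Everything downstream operates on the hematoxylin concentration surface:
nuclei are bright, stroma is dark, and eosin variation is gone.

## Enhancement and candidate grouping

`binary_threshold()` (Otsu on a 256-bin histogram) keeps the dense nucleus
cores; an opening with a disk of radius `se_radius` (default 1) removes
speckle. The Euclidean distance transform and
`partition_regions()` produce the classic sure-foreground /
sure-background / unknown split (`fg_frac = 0.4` of the maximum distance;
background beyond a dilation of radius 3). Connected-components labeling
(`label_components()`, default 8-connectivity so diagonally touching nuclei
group together) turns the mask into candidate regions;
`component_masks()` drops regions below `min_size` (default 20 px, applied
after contour refinement — the raw cores are intentionally small).

## Geodesic active contours

Each component is refined by a level-set geodesic active contour. The
field $u$ is negative inside, and evolves by

$$\frac{\partial u}{\partial t}
  = g\,\big(\kappa + v\big)\,|\nabla u| + \nabla g \cdot \nabla u,
  \qquad
  g = \frac{1}{1 + (\gamma\,|\nabla G_\sigma * I|)^p},$$

where $\kappa$ is the curvature of the level sets, $v$ a balloon constant,
and $g$ the edge-stopping map built from the Gaussian-smoothed input
(`smoothing_sigma = 2`, `p = 2`). The raw stopping formula's contrast
depends on the physical scale of the input, so the gain $\gamma$
auto-calibrates to map the 99th-percentile gradient to $g = 0.05$;
passing `gain = 1` recovers the plain formula.

Numerics: explicit scheme with `dt = 0.25` (the 2D stability bound for the
curvature term), central differences for curvature, Godunov upwinding for
the balloon term, gradient-sign upwinding for the advection term, and
re-initialization to a signed distance every `reinit_every = 25` steps.
Under this sign convention a *positive* `v` shrinks the contour and a
negative one inflates it; the pipeline default `v = -0.5` inflates because
Otsu cores start well inside the true nucleus rim and must grow out until
the stopping map halts them. Convergence is declared when the mean
absolute update falls below `tol = 1e-3`.

Two properties anchor the solver's correctness: under $g \equiv 1,\ v = 0$
a circle follows the mean-curvature law $r(t)^2 = r_0^2 - 2t$ (checked to
5% down to $r = 5$ px, with $r_0$ measured from the initial zero contour —
rasterizing a disk shifts the effective radius by about a tenth of a
pixel), and on synthetic disks with strong edges the final contour sits
within 2 px mean radial error of the true boundary.

## Blobness, splitting, and false-positive elimination

`hessian_blobness()` scores each pixel by the geometric mean
$\sqrt{\lambda_1\lambda_2}$ of the scale-normalized Hessian eigenvalues at
scale `sigma` (default 4), gated to zero unless both eigenvalues are
negative. The score is rotation invariant, maximal for bright isotropic
caps, and near zero on ridges and edges — exactly the contrast between
nuclei and elongated clutter. The per-candidate statistics are the mean
and maximum blobness over the candidate's pixels plus its size.

Overlapping nuclei that survive as one connected region are split at the
local maxima of a difference-of-Gaussians surface
(`dog_surface()`, inner scale `split_sigma = 1`, outer scale three times
that). The bandpass removes the smooth absorbance gradient a bright
neighbor casts over a dim nucleus *and* averages pixel noise over the
inner Gaussian; bare second-derivative operators at this scale are
statistically indistinguishable from rim noise, and raw intensity maxima
are swallowed by neighbor gradients. Peaks must clear both a per-mask
relative threshold (`split_rel_thresh = 0.15`) and an absolute floor
self-calibrated to the image (`split_abs_frac = 0.55` of the
95th-percentile response over the foreground); mask pixels then go to the
nearest peak, and a final non-maximum suppression keeps one candidate per
location (`split_min_sep = 3` px), since inflated neighboring components
can regrow over the same nucleus.

False positives are eliminated by the logistic selection function
$L_s(T) = \sigma\!\big(\beta_0 + \sum_i \beta_i x_i\big)$ over the three
candidate features (blobness mean, blobness max, size), fitted by
iteratively reweighted least squares on standardized features
(`fit_selection_model()`); convergence at $\max|\Delta\beta| < 10^{-8}$,
with a warning plus ridge-stabilized refit under perfect separation.
Candidates at probability $\ge 0.5$ — the sigmoid's natural decision
boundary, exposed as `cutoff` — survive as detections.
`train_selection_from_scenes()` labels training candidates by peak-to-truth
distance; candidates between one and one-and-a-half match radii from a
true center (typically fragments chipped off a real nucleus) are excluded
as ambiguous: labeling them negative drags the boundary into the
dim-nucleus region, labeling them positive teaches the model to keep
fragments.

## The detection network

`train_detector()` is a small feed-forward dense network — one input dense
layer (width 64), three hidden dense layers (64, 32, 16) each followed by
dropout, and a softmax output: eight layers in all — trained with Adam
(learning rate $10^{-4}$, batch 32, 30 epochs, categorical cross-entropy),
with dropout 0.2 and early stopping (patience 5, best-validation weights
restored) as the regularizers. Training is deterministic given a seed.
The regularization contrast is reproducible on simulated candidate
features (`simulate_candidate_features()`, 8,000 candidates, 10% label
noise): the epoch-30 train/validation loss gap is smaller with dropout and
early stopping than without, median over ten seeds.

## The synthetic scene generator

`make_scene()` emulates the relevant physics of an H&E field of view:

- elliptical nuclei (semi-major axis 5–8 px; lesions 8–12 px and more
  intensely stained) with a Gaussian-bump chromatin profile peaking at the
  stated concentration and falling to 0.35 of it at the rim — chromatin is
  densest near the center, and a profile with genuine central curvature is
  what makes overlapping nuclei optically separable at all;
- additive absorbance where structures overlap (Beer–Lambert: co-occurring
  absorbers add in OD), so overlaps are darker, as in real tissue;
- a smooth seeded eosin texture around the background mean (stroma density
  varies; a perfectly flat eosin field would leave no pixel above the
  Macenko OD filter and make eosin estimation ill-posed), suppressed under
  nuclei where chromatin displaces cytoplasm;
- optional thin, elongated, stained clutter structures that pass
  thresholding but have near-zero blobness — the false-positive load for
  the selection stage;
- Gaussian noise added in OD space so the unmixing residual model is
  exact; clipping to [0, 1] only afterwards.

Overlap placement puts a nucleus center within one semi-major axis (of the
larger of the pair) of an independently placed partner, never closer than
4 px: touching and intersecting, but still two nuclei rather than one
drawn twice. Ground-truth labels resolve overlaps by the higher
concentration, except that every nucleus keeps its own center pixel, so
each centroid lies in its own region.

The standard study condition (`standard_scene()`) is 20 nuclei on a
128×128 frame, 30% overlapping, 30% lesions, 4 clutter structures, OD
noise 0.02. At that condition, with the selection model trained on 20
disjoint scenes, the pipeline reaches precision and recall above 0.9 at a
5 px matching radius over 20 evaluation scenes — the package's stand-in
for a detection-accuracy claim on real data.

What passing these tests does **not** show: the generator has no tissue
texture inside nuclei, no out-of-focus blur, no staining artifacts or
folds, no mitotic figures, and its clutter is geometrically simple. Real
H&E images vary far more; the synthetic results validate the machinery
(unmixing, geometry, statistics), not clinical performance.

## Degenerate inputs and edge cases

- Blank or unstained images: stain estimation fails (no pixels above the
  OD filter) and the pipeline reports zero candidates rather than erroring.
- Constant surfaces: Otsu refuses (degenerate histogram) with an
  informative error; the stopping map is identically 1.
- All-foreground masks: the distance transform falls back to distance from
  the frame; level-set initialization requires both phases and says so.
- Rank-deficient OD clouds (single-stain images): estimation errors,
  naming the rank.

## Problem sizes

Test and acceptance workloads are sized for a single CPU: 128×128 scenes,
20 evaluation plus 20 training scenes end-to-end, 10 seeds for the
level-set and regularization studies, 8,000 simulated candidates for the
network experiments, and oracle sweeps of 50–100 random masks at 16–32 px.
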