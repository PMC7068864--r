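---
title: "Methods: lesion classification, features, and the sixteen-layer network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion classification, features, and the sixteen-layer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lesionclass` implements a complete desk-scale pipeline for classifying
dermoscopy skin-lesion images as benign or malignant: seeded synthetic image
generation, point-of-interest (POI) region-growing segmentation, a
twelve-dimensional colour/shape descriptor with classical classifiers, a
sixteen-layer VGG16-style convolutional network, a confusion-count /
ROC-sweep evaluation suite, and an embedding-based case-retrieval layer.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic experiments do and do not show.

## The synthetic data generator

Real dermoscopy archives cannot be redistributed with a package, so every
experiment here runs on generated images that emulate the two visual
signatures the classifier is supposed to exploit:

* **benign**: near-elliptical outline, homogeneous colour;
* **malignant**: irregular border, heterogeneous colour.

A lesion is a star-shaped region around a centre point. The boundary radius
at polar angle $\theta$ is an ellipse radius modulated by smooth periodic
noise,
$$ r(\theta) = r_{\mathrm{ellipse}}(\theta)\,\bigl(1 + \alpha\,\eta(\theta)\bigr), $$
where $\eta$ is a normalized sum of low-order harmonics (orders 2–6) with
$\max|\eta| = 1$ and $\alpha$ is the `border_irregularity` parameter. A
pixel belongs to the mask iff its distance to the centre is at most
$r(\theta)$, so every mask is connected and hole-free by construction, and
$\alpha = 0$ rasterizes an exact filled ellipse. Benign presets use
$\alpha = 0.03$ (at most 0.05), malignant presets $\alpha = 0.30$ (at least
0.25).

Colour heterogeneity is a seeded Voronoi partition of the lesion interior:
`n_color_patches` sites are sampled inside the mask and each lesion pixel
takes the palette colour of its nearest site (1 patch for benign, 4 for
malignant). The malignant palette was chosen *luminance-matched* — four hues
(brown, blue-gray, reddish, dark tan) whose gray values all sit near 0.30 —
so that colour heterogeneity is visible to the colour descriptors and the
network while gray-value region growing still recovers the lesion as one
region. The background is a constant skin tone (0.87, 0.72, 0.62), and
i.i.d. Gaussian noise (sd 0.02 per channel) is added before clipping to
$[0,1]$. Images are synthesized as floats and written as 8-bit PNG, which
round-trips losslessly at that precision.

POIs are the mask centroid plus, for malignant presets, two extra points
sampled uniformly inside the mask (multiple marked spots are the documented
input convention for heterogeneous lesions, and they make seed-value
region growing robust to patches). All randomness is drawn inside a
save/restore RNG scope, so a parameter set including its seed reproduces
bit-identical cases; dataset seeds are derived per case from the master
seed by fixed integer arithmetic kept below $2^{31}$.

What the generator deliberately does **not** emulate: hair and ruler
artifacts, specular highlights, vignetting, smooth lesion borders,
intra-patch texture, or more than two classes. Passing benchmarks on these
images therefore demonstrates that the pipeline's mechanics are correct and
that its features separate the two geometric/chromatic signatures — not
that the system reaches clinical accuracy on real dermoscopy data.

## Segmentation

The preprocessing order is fixed: gray conversion → 3×3 median filter →
contrast stretch → region growing → morphological refinement.

* **Gray conversion** uses the ITU-R BT.601 luminance weights
  (0.299, 0.587, 0.114), which sum to one.
* The **median filter** takes the median (5th smallest) of the nine values
  in each zero-padded 3×3 neighbourhood. Zero padding means border pixels
  of a bright image darken — that is the documented filter behaviour and is
  kept as such.
* **Contrast stretching** affinely maps the gray range onto $[0,1]$;
  constant images pass through unchanged, and pixel rank order is always
  preserved.
* **Region growing** compares each candidate pixel's gray value with the
  value of the *originating seed* (not a running region mean): a pixel
  joins the mask iff it is connected to a seed through pixels within the
  `similarity_threshold` (default 0.15) of that seed's value. This makes
  the result a pure function of the image, the seed set, and the threshold
  — independent of visit order and of seed-list order. The grown region is
  the union over seeds. Defaults: 8-connectivity, threshold 0.15.
* **Refinement** fills interior holes up to the opening scale (opening of
  the complement by a disc of radius `opening_radius`, i.e. a closing of
  the mask; default radius 2) and removes connected components below
  `min_object_size` (default 64 px). If refinement removes every
  seed-containing component the function errors rather than returning an
  empty mask.

The narrative the defaults follow names a "modified decision-based
unsymmetrical trimmed median filter" but then describes a plain sorted-9
median; the described behaviour is what is implemented. Similarly,
"brightness adjustment" and "histogram rearrangement" are treated as the
single contrast-stretch step above.

## The twelve-feature descriptor

The descriptor has a fixed order and length (see `feature_names()`):

| # | feature | definition |
|---|---------|------------|
| 1–3 | mean R, G, B | channel means over the ROI |
| 4–6 | mean H, S, V | HSV means over the ROI; hue averaged circularly |
| 7 | colour structure | normalized entropy of the 8×8-window structure histogram |
| 8–9 | colour layout | first two non-DC zigzag DCT coefficients of the 8×8 luminance grid |
| 10 | principal-component ratio | $\sqrt{\lambda_{\min}/\lambda_{\max}}$ of the coordinate covariance |
| 11 | filled fitted ellipse | $|ROI \cap E| / |E|$ |
| 12 | unfilled fitted ellipse | $|ROI \setminus E| / |ROI|$ |

Two reductions deserve comment. The MPEG-7 colour-structure and
colour-layout descriptors are vectors; this descriptor budget allots them
one and two scalars respectively. For **f7** we slide an 8×8 window
(stride 1) over the ROI bounding box, quantize ROI pixels into a fixed
32-bin HSV space (8 hue × 2 saturation × 2 value), count for each bin the
number of windows containing it, and report the histogram entropy
normalized by $\log 32$: a single-colour lesion scores 0, a maximally even
structure scores 1. For **f8–f9** the bounding box is block-averaged onto
an 8×8 colour grid (pixels outside the ROI are first replaced by the ROI
mean colour so the descriptor never sees background), the luminance grid is
transformed by an orthonormal 2-D DCT, and the first two non-DC zigzag
coefficients — horizontal AC(0,1), then vertical AC(1,0) — are squashed
into $[0,1]$ by the fixed affine map $(c + 4)/8$, whose zero point is 0.5.

The fitted ellipse is moment-matched: centred on the mask centroid, axes
along the covariance eigenvectors, semi-axes proportional to the eigenvalue
square roots and scaled so the ellipse area equals the mask area. This is
deterministic and needs no iterative boundary fit. "Coverage of the
ellipse" (f11 → 1 for compact lesions) and "escape from the ellipse"
(f12 → 0) resolve the direction ambiguity in favour of benign-compactness,
matching the observation that benign lesions are the more elliptical class.
Hue is an angle and is averaged as a unit-circle vector mean; a degenerate
resultant yields hue 0.

Features are min-max normalized to $[0,1]$ with parameters learned on the
training matrix only; test values are clamped and training-constant
features map to 0.5.

## Classical classifiers

`lesion_knn()` stores the normalized training matrix; prediction is a
majority vote among the $k = 5$ nearest neighbours under Euclidean
distance, ties broken toward the single nearest neighbour, and the
malignancy score is the malignant fraction among the $k$ — which gives
k-NN a continuous score so ROC analysis treats both classifiers uniformly.
`lesion_svm()` is a Gaussian-RBF support-vector machine (cost 1, kernel
width $1/(12 \cdot \overline{\mathrm{var}})$ on the normalized features);
the quadratic-programming solver is the standard libsvm implementation —
established optimizer plumbing, not re-derived here — behind a fixed
contract: class order (benign, malignant), scores oriented so larger means
more malignant, the normalizer embedded in the model. No hyperparameter
search is performed; all settings are exposed in the fitting functions.

## The sixteen-layer network

`build_depict_net()` declares the VGG16 recipe: five convolution blocks of
2, 2, 3, 3, 3 layers with 64, 128, 256, 512, 512 filters — every
convolution 3×3, stride 1, zero-padded to preserve spatial size, followed
by ReLU, every block closed by a 2×2/stride-2 max pool — then FC-4096 +
ReLU + dropout, FC-4096 + ReLU + dropout, FC-2, softmax: thirteen
convolutional plus three fully-connected trainable layers, five pools.
Fillers follow the published recipe: convolution biases constant 0.2,
FC6/FC7 gaussian weights (sd 0.005) with bias 1, FC8 gaussian (sd 0.01)
with bias 0. The convolution weight filler is cited to an initialization
reference whose exact variant is not recoverable from the text; the default
here is a fan-in-scaled uniform draw ($\pm\sqrt{6/\mathrm{fan_{in}}}$),
switchable per layer. Dropout probability is not stated; 0.5 on FC6 and
FC7 is used. 2×2/stride-2 pooling keeps exactly 25% of the elements of an
even plane; odd trailing rows/columns are dropped (floor semantics).

Two implementation routes exist on purpose. Pure-R *reference operators* —
`conv2d()` (convolution = cross-correlation with the kernel rotated 180°,
zero-padded, 'same'-sized, window anchored $\lfloor(k-1)/2\rfloor$ before
each output pixel), `maxpool()`, `relu()`, `softmax()`,
`multinomial_log_loss()` — define the semantics and are tested against
brute-force summation oracles. The trainer uses C++ kernels (im2col +
BLAS convolution, pooling with argmax bookkeeping) that the test suite
cross-checks against the reference operators layer by layer.

### Numerical choices in training

Two choices depart from a naive reading of the recipe, both forced by
making the *prescribed* architecture actually trainable at desk scale:

1. **Input scale.** The forward pass feeds raw 8-bit-scale intensities
   (`x * 255`). The FC fillers (sd 0.005 against bias 1) are calibrated
   for raw-intensity activations; on unit-scale inputs they produce
   fully-connected activations that are constant to within 0.2%, dropout
   noise then dominates the class signal by two orders of magnitude, and
   the network never leaves chance level regardless of learning rate.
2. **Optimizer.** The default is Adam (lr 0.001, $\beta_1 = 0.9$,
   $\beta_2 = 0.999$), not plain momentum SGD. With the prescribed fillers
   the output layer's gradient magnitude exceeds its weight scale by an
   order of magnitude while convolution gradients are hundreds of times
   smaller, so any single global SGD step size either oscillates FC8 or
   freezes everything else; per-parameter adaptive steps train all sixteen
   layers together. Momentum SGD remains available via
   `train_config(optimizer = "sgd")`.

Training is fully seeded (initialization, shuffling, dropout masks);
dropout uses inverted scaling and is inactive at inference, so embeddings
and predictions are deterministic. The loss is the multinomial logistic
loss, probabilities clamped at $10^{-12}$ inside the trainer only.

The desk-scale profile used by the benchmark and the acceptance script is
64×64 inputs with a width multiplier of 0.25 (16–128 filters, FC width
1024) trained for 8 epochs with batch size 16 — small enough that the full
benchmark (300 training and 100 test images, the first-round split of the
reference experiments) runs in a few minutes on one CPU. The 256×256
full-width recipe remains the package default in `build_depict_net()`.

### Case representation

"The features coming out of the last layer" is read as the last *hidden*
layer: the post-ReLU FC7 activation (4096-d at full width), not the 2-d
logits or softmax — retrieval needs a rich representation, and the 2-d
alternative would collapse the case base onto a line. The case base stores
that embedding (or, optionally, the 12-feature descriptor) per labelled
case; retrieval is exact Euclidean k-nearest-neighbour search with ties
broken deterministically by case id, and the predicted class is the
majority label among the retrieved cases. Persistence is a JSON manifest
plus a CSV vector matrix written at full double precision, so a save/load
round trip preserves rankings bit-exactly.

## Evaluation

`metrics()` computes precision, recall/sensitivity, specificity, F-measure
and accuracy from confusion counts, unrounded; any metric with a zero
denominator is returned as `NA` and named in `flags` — silent zeros would
corrupt comparisons. `printed_metrics()` additionally reproduces the
convention of published comparison tables, which compute the F-measure from
the already-rounded precision and recall: with unrounded inputs one of the
six bundled reference rows (the first-round CNN test, counts 35/33/17/15)
would print 0.69 where the published table prints 0.68, and the
rounded-input convention reproduces all six rows exactly. The six published
confusion rows ship in `isic_reference_counts()` as regression fixtures.

`roc_pr_curves()` sweeps every unique score (plus infinite endpoints),
classifies positive at `score >= threshold`, and integrates by trapezoid —
equal to the Mann–Whitney pair statistic with ties at half weight. The
full-scale archive results of the reference experiments (e.g. 0.75 CNN
accuracy on 1346/450 real images) are covered *only* through these printed
confusion counts: they derive from external data and full-scale training
and are not desk-scale reproducible, which is a deliberate scope boundary.

## Known limitations

* Synthetic lesions are far easier than real dermoscopy images; the
  benchmark floors (k-NN ≥ 0.9, CNN ≥ 0.8 test accuracy) are regression
  guards for the pipeline, not clinical performance claims. In practice
  both routes saturate near 1.0 on the default presets.
* Region growing assumes the lesion is darker or lighter than skin in gray
  value and connected through seed-similar pixels; luminance-matched
  multi-colour lesions need one POI per distinct patch family.
* The word-association / staging recommendation machinery of the original
  CBR system is out of scope; recommendation text is a stored string.
* The SVM decision values are not calibrated probabilities, and no
  hyperparameter search is performed anywhere.
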