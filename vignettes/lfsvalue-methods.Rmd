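---
title: "Feature-based construction of aesthetic value: models and methods"
author: "lfsvalue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based construction of aesthetic value: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfsvalue)
```

## The scientific problem

How does a brain (or a model) turn a complex visual stimulus — a painting —
into a single subjective value, a liking rating on a 0–3 scale? The working
hypothesis implemented by this package is *linear feature summation* (LFS):
every stimulus $i$ is first decomposed into a vector of interpretable feature
values $f_{i,j}$, and its value is a weighted sum

$$ v_i = \sum_{j=0}^{n_f} w_j\, f_{i,j}, \qquad f_{i,0} = 1, $$

where the weights $w_j$ are a property of the *rater* (their taste), not of
the stimulus. Features come in two tiers: **low-level** features computed
directly from pixels (segment colour statistics, spatial moments, entropy,
symmetry, blur), and **high-level** attributes (concreteness, dynamics,
temperature, valence, presence of a person) that are supplied by human
annotation and hypothesized to be constructed *from* the low-level tier. The
package implements the full analysis chain around this model: the feature
bank, the behavioural model fit, group-level feature selection, encoding
analyses on multi-region BOLD data, a psychophysiological-interaction (PPI)
test of feature–value integration, and a layerwise decoding probe of a
convolutional rating network. Because the human dataset the design mirrors is
not redistributable, every stage is exercised on data from the package's own
synthetic generators, which plant the structure the analyses are meant to
detect.

## The feature bank

`feature_catalog()` registers 83 candidate features: 12 whole-image
statistics, local statistics of the two largest segments under three
segmentation backends (graph-based merging, statistical region merging, and
k-means on the Lab chroma plane), five intensity-histogram bin fractions,
HSV modes, aspect ratio, global entropy, and the five annotated high-level
attributes. Local features for a third-largest segment are deliberately
excluded: they are nearly collinear with those of the first two segments.

Numerical conventions that required a decision:

* **Hue averaging** uses the plain arithmetic mean on hue $\in [0,1)$, not
  circular statistics, matching the lineage of the feature set; a circular
  mean is available behind `hue_circular = TRUE`.
* **HSV, not HSL**, is used throughout.
* **Intensity bins**: five equal bins tiling 0–255; all five are catalog
  entries (`feature_catalog(intensity_bins = 4)` builds the narrower
  convention).
* **Spatial moments** use 0-based pixel coordinates, x = column, y = row,
  normalized by the image dimensions by default so that moments are
  comparable across image sizes (features are z-scored downstream either
  way). The skew statistic is the raw third central moment sum over area —
  deliberately not standardized by variance$^{3/2}$.
* **Blur** (`compute_blur`) is the highest spatial frequency (Nyquist = 1)
  whose spectral power exceeds a threshold, computed on 0–255 luminance.
  Power is the squared modulus of the *pixel-count-normalized* DFT, so the
  default threshold 4 means "amplitude of at least two gray levels". The
  normalization is essential: the raw DFT of any finite image carries
  wrap-around leakage that exceeds any fixed threshold at every frequency,
  which would pin the statistic at 1 no matter how blurred the image is. We
  verified this numerically on heavily smoothed stimuli before fixing the
  convention.
* **Segmentation backends**: SRM doubles its granularity parameter (up to 32
  sweeps) until at least three segments appear; the graph backend sweeps the
  Felzenszwalb–Huttenlocher scale parameter to land as close as possible to
  a six-segment target; k-means is seeded and reduces `k` with a flag when an
  image has fewer distinct chroma values. Degenerate single-colour images
  return one segment with `target_not_met = TRUE` rather than failing, and
  statistics of an absent second segment are `NA` sentinels.
* **Modes** of hue/saturation/value use fixed 64-bin histograms (mode = bin
  centre); entropy uses a 256-bin intensity histogram, so it lies in
  $[0, 8]$ bits.

```{r catalog}
cat83 <- feature_catalog()
nrow(cat83)
table(cat83$level)
```

## Behavioural modelling

`fit_ridge_cv()` fits the LFS model to one participant's ratings with ridge
regression in 20 outer cross-validation folds; the penalty is chosen by
nested cross-validation inside each training set, features are z-scored with
training-fold statistics only, ratings are treated as continuous, and
predictive accuracy is the Pearson correlation between the pooled
out-of-fold predictions and the data. `permutation_test()` re-runs the
identical pipeline on label-permuted ratings (10,000 permutations by
default), scoring each permuted analysis against its own permuted labels;
`p = (1 + \#\{null \ge obs\})/(1 + n_{perm})` and chance is the null mean.
The permutation path reuses the fold-wise SVDs of the (fixed) design, so the
full null distribution is a set of matrix products rather than refits — this
is what makes calibration suites with hundreds of replicates feasible on one
CPU.

### Group-level shared feature selection

To find features shared across raters, low-level features are first
orthogonalized by sparse PCA (`orthogonalize_sparse_pca()`: soft-thresholded
power iteration with projection deflation; `sparsity` is the fraction of
loadings zeroed per component, and sparsity 0 reduces exactly to PCA). A
group lasso (`group_lasso_select()`) then solves a single joint objective
over all participants, one group per component collecting that component's
coefficients across participants, using FISTA with a group soft-threshold
proximal step, backtracking line search (step halving), a monotone safeguard,
and convergence at a relative objective change below $10^{-8}$. The penalty
is selected by stimulus-level cross-validation shared across participants on
a 30-point log grid spanning $[10^{-4}, 1] \times \lambda_{max}$; validation
uses an unpenalized refit on each candidate active set (relaxed CV) so that
the curve reflects *selection* rather than shrinkage bias, followed by the
one-standard-error rule. Components active in fewer than two participants
are discarded, survivors are mapped back to named features through the
sparse loadings, and any feature pair with $r^2 > 0.5$ on the selection data
keeps only the earlier catalog entry (`finalize_shared_set()`). High-level
features are appended afterwards, mirroring the two-stage procedure of
selecting a low-level set first.

Open choices resolved here: the group lasso uses one joint objective with
participant-specific coefficients (rather than per-participant fits combined
afterwards), and the sparse-PCA variant and sparsity level are configurable
because no canonical choice exists.

### Interaction features

`build_interaction_groups()` forms all pairwise products of z-scored
features in three groups (low×low, high×high, low×high; no self-products;
deterministic lexicographic column order), and `reduce_groups()` keeps the
first five principal components of each group — matching the dimensionality
of the high-level set — with z-scored scores. Products are taken after
z-scoring so they are centred and scale-free; the PCA is fit on the full
stimulus set before any cross-validated regression, a known leakage
trade-off inherited from the described feature-construction-then-regression
order.

## Synthetic data: what it emulates and what it does not

The generators plant exactly the structure the analyses test:

* `make_stimulus_images()`: procedural "paintings" (solid background,
  random rectangles, optional exact mirror symmetry, optional Gaussian blur
  with a 6σ-truncated kernel) with the constructor's ground truth returned.
* `make_annotations()`: high-level attributes as noisy linear mixtures of
  the low-level features (noise SD 0.5 by default), with presence-of-person
  binarized at the median — encoding the hypothesis that high-level features
  are constructible from low-level ones.
* `make_ratings()`: the LFS equation plus Gaussian noise, discretized to
  0–3 by population quartiles (balanced classes; the human rating
  distribution is unknown). The default noise SD equals the signal SD
  (SNR 1), a level at which planted weights are still recoverable at
  $r \ge 0.9$ but single-trial prediction is far from perfect — a realistic
  behavioural regime.
* `make_design()`: 20 runs × 50 trials (1000 unique stimuli), 3 s stimulus,
  up to 3 s decision with a uniform 0.4–2.5 s reaction time, 0.5 s feedback,
  2–9 s uniform ITI, TR 1.12 s.
* `make_bold()`: each feature-ROI voxel responds at stimulus onsets with an
  amplitude mixing low- and high-level stimulus information according to the
  ROI's position on a planted gradient $g = (0.1, 0.3, 0.5, 0.7, 0.9)$ over
  five ordered visual-stream analogues; integrator analogues (PPC/lPFC) mix
  both tiers equally; a value ROI (mPFC analogue) is modulated by the
  continuous rating. During stimulus epochs only, a shared latent noise
  series (strength `coupling`) is injected into the value and integrator
  ROIs — the stimulus-locked noise correlation a PPI analysis detects.
  Responses are convolved with a canonical double-gamma HRF (unit-peak
  kernel, no derivatives); noise is AR(1) with $\rho = 0.3$ plus white noise
  at SD 1 against a signal amplitude of 0.5, which yields graded (neither
  floor nor ceiling) significance proportions; six smooth motion-like
  nuisance regressors contribute weakly to every voxel. The full manifest
  regenerates the dataset bit-for-bit.

What the generator does **not** emulate: anatomy and spatial structure,
scanner artefacts, motion, physiological noise spectra, hemodynamic
variability across regions, and — most importantly — real images and real
tastes. Passing tests therefore demonstrate that the estimators recover the
structure they assume when it is present at realistic noise levels, not that
the scientific conclusions hold for any particular human dataset.

## Encoding and PPI analyses

`build_design_matrix()` constructs HRF-convolved task regressors (stimulus,
decision, action and feedback events, plus one parametric regressor per
feature), mean-centres modulators before convolution, never serially
orthogonalizes them, appends nuisance columns unconvolved, and fails loudly
on rank deficiency. Parametric modulators can enter as onset impulses or as
3 s boxcars; the boxcar variant is used in the PPI model because feature
integration may span the whole presentation. `estimate_trial_betas()` uses a
single GLM with one regressor per trial (the alternative per-trial-GLM
scheme was considered and not taken; with jittered ITIs of 2–9 s the joint
design is well conditioned). `group_f_test()` computes the partial F per
voxel for a named regressor group at $p < 0.001$ uncorrected — the
voxelwise replacement for cluster-level correction, which is out of scope —
and `roi_proportion_profile()` summarizes each ROI by its fraction of
significant voxels per group, with the **hierarchy index** defined as the
Spearman correlation between ROI order and (high − low) proportion.
`voxelwise_sparse_encoding()` is the cross-validated counterpart: lasso at
every voxel (12-fold penalty selection), a sum-of-squared-weights statistic
per feature group, and an empirical null pooled per ROI from fits with
stimulus labels shuffled anew at every regression (200 shuffles by default;
the published shuffle count is unstated).

`build_ppi_regressor()` works at the signal level (no hemodynamic
deconvolution): seed mean timecourse, a mean-centred psychological boxcar
(stimulus epochs, or ITIs for the control), and their elementwise product.
Centring the boxcar is what separates the interaction from the seed main
effect. `ppi_map()` adds the three columns to the boxcar-modulated design in
which all feature and value signals are regressed out, so a positive
interaction reflects stimulus-epoch-specific *noise* coupling;
`feature_ppi_overlap()` counts, per ROI, the fraction of feature-encoding
voxels that are also PPI-positive. The planted expectation — recovered in
the test suite — is high overlap in the integrator analogues during
stimulus epochs, near-zero overlap in visual analogues, and near-zero
everywhere in the ITI control.

## The rating network and layer probes

`rating_net_config()` describes a small convolutional network with the
recipe head: a 10-way softmax output whose probability-weighted average of
bin centres yields a scalar in $[0, 3]$, Huber loss, SGD with momentum 0.9,
learning rate $10^{-4}$ decayed ×0.1 every 30 epochs, weight decay
$5\times10^{-4}$, batch size 100, and zero-padding preprocessing (longest
edge scaled to the canvas). Convolutional weights are frozen by default and
only the fully connected head is trained — the fine-tuning regime — which
also lets training run on cached convolutional features.
`reference_rating_net_config()` builds the 13-convolution + 2-FC layout
(pooling after layers 2, 4, 7, 10, 13) at reduced width; it exposes the 15
ReLU activation points used by the decoding analyses and by the
layer-grouping interface (`layer_groups()`: 1–4, 5–9, 10–13, 14–15).

`decode_feature_from_layer()` probes one layer: per training fold, PCA to
the smallest component count explaining 80% of training variance (test
activations projected with the training transform — no leakage), then ridge
(continuous; Pearson r) or L2-logistic (categorical; accuracy, AUC, F1) over
a 13-point penalty grid, reporting the best grid point's pooled score.
`classify_feature_level()` fits a slope to score-vs-layer and classifies
high/low by a 10,000-permutation layer-label null at $p < 0.001$.

The probe oracle in the test suite plants two features in a desk-scale
experiment: global mean luminance (computable at layer 1; its decodability
decays under the five pooling stages) and the median-binarized readout of a
trained network (a deep composite by construction; its decodability rises
toward the head). For this oracle the head is deepened to five FC layers so
the rise spans several activation points — a step confined to the last two
layers of a 15-point profile cannot reach $p < 0.001$ under layer-label
permutation for purely combinatorial reasons. Categorical profiles are
scored by AUC (the least granular of the three metrics at n = 100; the
slope signs of the three metrics agree), profiles are averaged over two fold
assignments to reduce estimator noise, and a training run that collapses to
constant output is restarted with a fresh initialization. An untrained
network with fresh random weights serves as the control: it does not
reproduce the deep feature's positive slope.

## Problem sizes and runtime

The test suite runs on one CPU with pinned seeds: behavioural recovery at
500 stimuli × 18 features; permutation calibration with 200 replicates of a
500-permutation null (feasible because of the matrix-algebra permutation
path); hierarchy recovery over 20 seeds of a 5-ROI × 2000-voxel × 400-trial
session; PPI specificity on a 200-trial session plus a 6-seed
zero-coupling calibration; and the 20-seed layer-probe experiment at 100
stimuli per seed. These sizes are the package's chosen desk-scale study
conditions; the generators accept larger values.

## Known limitations

* The feature catalog's 12 whole-image statistics follow the *spirit* of the
  published global feature lineage (colour distribution, brightness,
  blur, edge statistics); the original 40-feature naming scheme is not
  reproduced item by item.
* The graph segmentation backend is a Felzenszwalb–Huttenlocher merger tuned
  to a segment-count target, standing in for kernel Graph-Cuts; downstream
  statistics only need the largest segments.
* Lasso encoding nulls pool over voxels within an ROI; with few voxels and
  shuffles the 99.9th percentile is an extrapolation.
* The rating network is desk-scale: nothing here reproduces ImageNet
  pretraining, and probe conclusions are about the method's ability to
  classify planted features, not about any particular published network.
* PPI is correlational and signal-level; a deconvolution-based variant and
  directed-connectivity questions are out of scope.
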