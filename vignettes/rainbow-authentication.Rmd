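---
title: "Methods: diffraction-rainbow segmentation and chemometric classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffraction-rainbow segmentation and chemometric classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rainbowclass)
```

## The measurement model

A diffraction-grating sheet placed in front of a flashlight disperses the
light reflected from a sample into a small wavelength-ordered "rainbow"
patch, which a phone camera photographs against a dark background. The
intensity profile along the patch's dispersion axis is a crude
pseudo-spectrum: it is not wavelength-calibrated, it is convolved with the
camera's RGB response, and it carries instrumental artifacts — but
differences in surface chemistry between samples still modulate it. The
package turns such photographs into length-100 feature vectors and
classifies them, with a synthetic-data module standing in for the
never-deposited physical data.

## Segmentation

The pipeline is: grayscale conversion → median filter → automatic
threshold → saturation gate → morphological clean-up → connected-component
selection → standardized crop.

**Grayscale and median filter.** Grayscale uses the standard luminance
weights (0.299, 0.587, 0.114); the feature-extraction weights
(0.2, 0.7, 0.1) are deliberately separate, since nothing forces the two
stages to share them. The median filter (3×3 by default, reflect padding)
removes isolated sensor noise while preserving the patch edge — exactly the
property the later thresholding needs.

**Thresholding.** For a gray-level histogram $p_i$ and candidate threshold
$T$, with background class at levels $\le T$ and object class above it,

$$\omega_1(T) = \sum_{i \le T} p_i,\quad
  \omega_2(T) = 1-\omega_1(T),\quad
  \mu_k(T) = \textstyle\sum_{i \in C_k} i\,p_i / \omega_k(T),$$

the selected threshold maximizes the between-class variance
$g(T) = \omega_1\omega_2(\mu_2-\mu_1)^2$, which is algebraically identical
to the weighted squared deviation of the class means from the global mean
$\mu = \omega_1\mu_1 + \omega_2\mu_2$ (both forms are implemented and
tested for pointwise agreement; minimizing the weighted within-class
variance is the same criterion). One source we follow describes $\mu$ in
prose as a "probability", but its own defining equation is the global mean
gray level; we implement the equation's meaning. Candidates where either
class is empty are skipped; a single-level histogram is a degenerate-input
error; ties break toward the smallest threshold. Thresholding operates on
the *median-filtered* image (the pipeline diagram ordering), and the object
is the class *strictly above* $T$.

**Saturation gate.** The rainbow is strongly coloured while dark background
and gray clutter are not, so the threshold mask is ANDed with an HSV
saturation gate (default $S \ge 0.15$ on the 0–1 scale, switchable off).

**Morphology and component choice.** The clean-up is binary opening then
closing with a disk of radius 1 (configurable; radius 0 is the identity):
opening removes specks the median filter missed, closing fills pinholes.
Because the grating produces *two* symmetric rainbows, exactly one
component is kept: the largest by area, ties broken by leftmost then
topmost bounding box — deterministic and orientation-free.

**Standardized crop.** The RGB bounding box is cropped, transposed if the
long axis (the dispersion axis) runs horizontally so that it always runs
along rows, and resampled to 100×100 by bilinear interpolation with final
rounding. The "row index ≈ wavelength position" orientation is what makes
variables comparable across images; it is why the synthetic species signal
sits at specific variable indices.

## Feature extraction

Each 100×100×3 patch is collapsed per pixel to
$F = W_1 R + W_2 G + W_3 B$ with defaults $(0.2, 0.7, 0.1)$, kept as reals
(no re-quantization, so no precision is lost before smoothing), then
averaged along each row, giving a length-100 pseudo-spectrum with values in
[0, 255]. Feature matrices round-trip losslessly through CSV
(`v1…v100`, `species`, `type`, `sample_id`).

## Pre-processing

The default is Savitzky–Golay smoothing with a degree-2 polynomial over a
33-point window — the combination found to work best for this kind of data;
SNV, min–max, total-area normalization and polynomial baseline correction
are available behind the same interface. Two numerical choices matter:

* **Edges.** A 33-point window on a 100-point vector leaves 16 points at
  each end without a full window. We fit the nearest full window's
  polynomial and evaluate it at the edge positions (the standard
  "polynomial extrapolation" edge treatment). A consequence worth knowing:
  polynomials up to the fitting degree are reproduced *exactly*,
  everywhere.
* **No leakage by construction.** All pre-processing is fitted and applied
  per row; no training-set statistics exist, so the test set cannot leak
  into the model. The only data-dependent centring (PLS mean centring)
  lives inside the classifiers and uses training rows only.

## Classifiers

All five share a deterministic fit/predict contract over labelled feature
matrices. Class labels are dummy-coded as 0/1 indicator columns in sorted
class order; predictions are the argmax across class columns, ties going to
the first class in that order. Argmax (rather than a 0.5 threshold) extends
unchanged to more than two classes.

**PLS-DA.** NIPALS: after mean-centring $X$ and $Y$ on the training data,
each latent variable takes the weight direction maximizing the covariance
between the $X$-score and the $Y$-score, then deflates both $X$ and $Y$ by
their rank-one score approximations. Deflating $Y$ as well as $X$ is
mathematically redundant for prediction — we do both and verified the
predictions agree — but keeps the scores/loadings interpretation
conventional. If the requested number of latent variables exceeds the data
rank it is reduced with a warning. With as many components as the rank, the
continuous predictions coincide with ordinary least squares on centred
data, which the tests use as an oracle.

**Kernel PLS-DA.** The Gaussian Gram matrix
$K_{ij} = \exp(-\lVert x_i - x_j\rVert^2 / 2\sigma^2)$ is double-centred
($K_c = CKC$, $C = I - \tfrac1n\mathbf{1}\mathbf{1}'$) and kernel NIPALS
runs in dual form; test rows are centred consistently using the training
column means. Neither centring step is optional — it is what makes the
linear-kernel special case reproduce PLS-DA exactly, which is the
equivalence the test suite asserts.

**LW-PLSC.** A just-in-time model: for each query, training samples are
weighted by $\omega_n = \exp(-d_n / (\varphi\, s_d))$ where $d_n$ is the
Euclidean distance to the query and $s_d$ the standard deviation of those
distances; a sample-weighted PLS-DA (weighted means and weighted covariance
in every NIPALS step) is fitted and the query predicted. The weight
function is stated here as an *interpretation*: the localization parameter
$\varphi$ is named in the literature this follows, but its kernel is not
spelled out, so we adopt the standard exponential just-in-time similarity;
any monotone-decreasing kernel could be plugged in behind the same
contract. Small $\varphi$ localizes (a query on a training point inherits
its class), large $\varphi$ makes the weights uniform and the prediction
converges to global PLS-DA — both limits are tested numerically. If all
weights underflow, the classifier falls back to global PLS-DA with a
warning.

**SVM.** A binary soft-margin SVM with the Pearson VII universal kernel
$k(x,y) = 1/\bigl(1 + (2\sqrt{2^{1/\omega}-1}\,\lVert x-y\rVert /
\sigma_p)^2\bigr)^{\omega}$, defaults $\omega = 1$, $\sigma_p = 1$, solved
by sequential minimal optimization with deterministic working-pair
selection (the partner maximizing $|E_i - E_j|$, falling through degenerate
pairs), verified against an exhaustive dual-QP oracle on a small problem.
A practical caveat the defaults expose: on unscaled 0–255 spectra,
$\sigma_p = 1$ makes the Gram nearly diagonal and the SVM memorizes the
training set; since the tuning grid only searches the penalty $C$, users
working on raw intensities should set `puk_sigma` near the typical
inter-sample distance (see the README example).

**k-NN.** Euclidean majority vote; $k = 1$ returns the nearest neighbour's
class. Vote ties go to the first class in sorted order, distance ties to
the lower sample index.

## Evaluation protocol

**DUPLEX split.** The pair of still-unassigned samples with the largest
Euclidean distance is assigned to the training set, the next such pair to
the test set, and so on alternately until the smaller set's quota is full;
the remainder goes to the larger set. The integer rule is
$n_{test} = \lfloor n \cdot r_2/(r_1+r_2)\rfloor$ (so 150 samples at 2:1
give exactly 100/50); a set with one free slot takes the lower-index point
of its pair. The procedure involves no randomness, keeps the extreme points
in training, and preserves the spread of the data in both sets — a property
the tests check directly. The split runs on *pre-processed* features,
globally (not per class); a stratified variant was considered and rejected
to keep the protocol identical to its description.

**Grid search.** Leave-one-out cross-validation over the full Cartesian
grid: $k \in \{1,3,\dots,49\}$, latent variables $\le 10$, $C \in 1\dots8$
(integer steps), $\sigma \in \{10^{-3},\dots,10^{3}\}$ (7 decade points),
$\varphi \in \{0.1, 0.5, 1, 2, 5, 10, 15, 20, 25\}$. The $\sigma$ and
$\varphi$ step choices are ours (the stated ranges have no stated step);
the $\varphi$ set includes 15, a value of particular interest in the work
this follows. Accuracy ties break toward parsimony — fewest latent
variables first, then the smallest remaining parameter — because a simpler
model at equal validation accuracy is the better selection. Grid values
infeasible for the data size (e.g. $k > n-1$ under LOOCV) are dropped with
a warning. For the PLS family, each LOOCV fold is fitted once at the
largest component count and read off at every smaller count, which keeps
the full protocol on 150 samples under half a minute. The full accuracy
surface is returned (and exported as CSV) for mesh plotting.

## The synthetic world

**Photographs.** A dark background (mean level 3) with one or two symmetric
elliptical patches (semi-axes 45×16 px in a 160×120 frame by default). The
colour varies smoothly along the dispersion axis through per-channel
Gaussian bands (red near one end, green centred, blue near the other), on
top of a broadband "glow" floor of 90 counts inside the ellipse — without
the floor the patch would fade to black at its ends and no
threshold-based extractor could recover the *full* ellipse, which is what
the ground-truth bounding box demands. Sensor noise is additive Gaussian
(sd 3) plus salt-and-pepper pixels (rate 0.002), applied last. The ground
truth carries the noiseless mask, the primary (leftmost) patch's bounding
box, and the true pseudo-spectrum defined as the feature vector the
pipeline would produce from the noiseless scene cropped at the true box.
The generator does *not* model grating physics, wavelength calibration,
illumination gradients, perspective, or apple-shaped occlusion — a green
segmentation test establishes correct recovery of bright compact patches
on dark backgrounds, nothing more.

**Feature populations.** 150 samples: three species of 50 (25 organic + 25
non-organic each). Each row is a smooth base spectrum plus a species bump
(Gaussian, width 3, height 25 counts, centres 44/50/56 — confined to
variables 40–60, making species linearly separable), plus a *type* signal:
two latent factors $z_1, z_2$ embedded along smooth curves at variables
~25 and ~75 (scale 20 counts), with organic samples drawn at latent radii
$\le 0.95$ and non-organic in an annulus $[1.2, 1.9]$. Labels depend only
on the radius, so the type classes are rotationally interleaved and no
linear direction separates them; additive Gaussian noise (sd 2 on the
0–255 scale) is applied and values clipped. At generation time a
**nonlinearity certificate** is asserted: linear PLS-DA LOOCV over 1–10
components on the type labels must stay below 75%, otherwise generation
errors — so every downstream linear-versus-nonlinear comparison is
meaningful by construction. With `noise_sd = 0` rows within a cell still
differ: the latent factors are part of the signal structure, not the
noise, and removing them would destroy the radial rule itself (the test
suite instead verifies that zero-noise features are an exact deterministic
function of the stored latent draws).

Defaults were chosen once to mirror the qualitative facts the protocol is
meant to reveal — clear species separation, near-chance linear type
classification, high nonlinear-classifier accuracy with few latent
variables — and are not tuned against test outcomes; the acceptance suite
computes the resulting ordering itself.

## Numerical choices and degenerate inputs

* NIPALS convergence: relative score change $\le 10^{-10}$, capped at 500
  iterations; component extraction stops early (with a warning) when the
  residual X variance reaches machine-level zero.
* Otsu and argmax tie-breaks: smallest threshold, first sorted class.
* Savitzky–Golay windows must be odd, degree < window ≤ vector length;
  SNV/min–max/area normalization raise degenerate-input errors for
  constant or zero-sum rows rather than emitting NaNs.
* Segmentation failures (no component, single gray level) raise a typed
  condition carrying the diagnostic mask; batch extraction logs and skips.
* Model JSON serialization writes full precision; reload reproduces
  predictions to 1e-12 (exact bit-identity is not achievable through a
  decimal format followed by a linear solve).

## Limitations

* No real photographs of this sensor are publicly available; all
  end-to-end claims are about the synthetic world described above.
* The LW-PLSC weight kernel and the PUK parameterization are documented
  interpretations of named-but-unspecified components.
* The SVM is binary-only by design; multiclass use, probability
  calibration and variable-importance measures are out of scope.
* Connected-component labelling uses iterative minimum-label propagation —
  ideal for compact blobs, slow for pathological filament shapes.
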