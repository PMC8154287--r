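---
title: "Multi-feature analysis of breast-ultrasound lesions: methods and design notes"
author: "buscad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-feature analysis of breast-ultrasound lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buscad)
```

## The problem

B-mode breast ultrasound is a first-line screening modality, but reading it
is subjective: the sonographic signs radiologists weigh — whether a lesion is
taller than wide, whether its margin is sharp or infiltrative, whether it
casts a posterior acoustic shadow, how irregular its contour is — are exactly
the kind of cues that vary between readers.  `buscad` turns those four signs
into numbers.  It segments the lesion from a 2D grayscale image with a
level-set active contour, computes four handcrafted *characteristic features*
(CF) from the segmented boundary, optionally concatenates externally computed
deep-feature vectors, and classifies the lesion as benign or malignant with
an RBF-kernel SVM.

Nothing in the package requires clinical data: a seeded speckle-phantom
generator produces images with fully known lesion geometry, so every stage is
testable against ground truth.

## Segmentation: distance-regularized level-set evolution

The lesion boundary is the zero level of a scalar field $\phi$ evolved to
minimize

$$E(\phi) = \mu \int_\Omega p(|\nabla\phi|)\,dx
  \;+\; \lambda \int_\Omega g\,\delta(\phi)\,|\nabla\phi|\,dx
  \;+\; \alpha \int_\Omega g\,H(-\phi)\,dx ,$$

where $g = 1/(1+|\nabla (G_\sigma * I)|^2)$ is the edge indicator, $\delta$
and $H$ are smoothed Dirac/Heaviside functions of half-width $\varepsilon$,
and $p$ is a distance-regularization potential.  The explicit update is the
standard gradient-descent flow of this energy with time step $\tau$;
the regularization term keeps $\phi$ close to a signed distance function
near the contour with no reinitialization.

Design choices a user should know about:

* **Double-well potential.** We use the double-well $p$ with minima at
  gradient magnitudes 0 and 1, so the field relaxes to a unit-gradient band
  near the contour while staying flat far away.  (The single-well form
  $p(s) = (s-1)^2/2$ produces an equivalent flow near the band but keeps
  pulling far-field gradients toward 1; the double-well behaviour is the
  established choice for step-initialized fields like ours.)
* **Edge-indicator gradient scale.** Images are normalized to $[0,1]$ on
  load.  On that scale the raw gradient magnitude of a realistic lesion edge
  is of order $10^{-1}$, so $1/(1+|\nabla I|^2)$ would hardly leave 1 and
  the edge terms would be inert.  `edge_indicator()` therefore measures
  gradients in grey levels per pixel (`grad_scale = 255` by default), which
  reproduces the classical behaviour of the functional on 8-bit images while
  keeping the loader's $[0,1]$ convention.  Because every image passes
  through the same two conventions, segmentation does not depend on whether
  the source file was 8- or 16-bit.
* **Defaults.** $\mu = 0.2$, $\tau = 1$ (the diffusion stability bound
  $\mu\tau < 0.25$ is enforced), $\lambda = 5$, $\alpha = -3$ (expansion
  from an interior seed rectangle), $\varepsilon = 1.5$ px,
  $c_0 = 2$, $\sigma_g = 1.5$ px, at most 1000 iterations.  All of these
  live in `drlse_params()` / the YAML config, not in code.
* **Stopping.** Every 10 iterations the zero-crossing pixel set
  $\{\phi < 0\}$ is compared with the previous check; evolution stops after
  10 consecutive unchanged checks, or at the iteration budget.  The final
  mask is the largest connected component of $\{\phi<0\}$, and the contour
  is its sub-pixel zero level set, stored counter-clockwise in the y-down
  image convention.
* **Full-grid updates.** At the image sizes this package targets
  (~100–500 px per side) the whole-grid explicit update is cheap, so no
  narrowband bookkeeping is implemented.

## The four characteristic features

**Orientation** is the height/width ratio $|y_u - y_d| / (x_r - x_l)$ of the
four contour extreme points (top, bottom, leftmost, rightmost).  When an
extreme is attained along a flat run of vertices, the run's midpoint is used,
which still lies on the polyline.  Taller-than-wide lesions (ratio near or
above 1) are a malignancy sign.

**Edge indistinctness (EI)** cuts an $m \times n$ patch (defaults
$m = 21$ rows $\times$ $n = 15$ columns, centered on the vertex so the long
side spans the margin vertically) at the top and bottom extremes, computes
the mean per-column and mean per-row population standard deviation, takes
the larger of the two per patch, and averages the two patches.  A sharp
margin produces large within-patch dispersion; an infiltrative blurred
margin a small one.

**Posterior-shadow (PS) score** crops the rectangle spanning the lesion's
horizontal extent from its bottom vertex down by one lesion height (clipped
at the image border), computes second-order normalized central moments of
the intensity function with 1-based pixel coordinates,
$\eta_{pq} = \mu_{pq}/\mu_{00}^{(p+q)/2+1}$, and reports
$-\mathrm{sign}(\eta_{20}+\eta_{02})\log_{10}|\eta_{20}+\eta_{02}|$.
Because $\eta_{pq}$ scales as $1/c$ when intensities are scaled by $c$, the
pipeline converts the $[0,1]$ crop to 8-bit grey levels before scoring
(`grey_levels = 255` in `characteristic_features()`); published clinical PS
values (roughly 2.0–2.8) are on that scale, and our phantoms land in the
same range.  `hu_ps_score()` itself applies no hidden factor — it scores the
region exactly as given.  The EI score, by contrast, is left on the loaded
$[0,1]$ scale; min-max normalization removes the absolute scale before
classification either way (published clinical EI values around 17–35
correspond to the 8-bit scale).

**Shape complexity (SC)** walks a divider of radius $R$ along the contour
from the top vertex: each step moves to the first forward intersection of
the circle of radius $R$ centered at the current point with the contour,
and $N(R)$ counts the steps needed to pass the start again, the final
partial step counting as one (the cartographers' convention).  The contour
is resampled to uniform arc length (an eighth of the smallest radius)
before walking, and intersections are refined by exact segment–circle root
finding.  The SC score is the slope $b$ of the least-squares line
$\log_{10} N(R) = a + b\,\log_{10} R$ over $R \in \{4,\dots,11\}$ px; for a
smooth rectifiable curve $b \to -1$, and more negative slopes mean a more
complex (fractal-like) boundary.

## Normalization, fusion, classification

Features are min-max normalized with parameters learned on the training set
only: standard direction $(x-\min)/(\max-\min)$ for orientation, EI, PS and
any deep features, and inverted direction $(\max-x)/(\max-\min)$ for the SC
slope, whose suspicious end is the negative one.  This choice of method and
direction exactly reproduces the published normalized values of the
six-lesion reference table bundled as `bus_cf_examples()` (two printed cells
of that table are internally inconsistent with its own original values —
presumably typographical — and are excluded from checks).  Values outside
the training range extrapolate linearly beyond $[0,1]$ with a warning; the
map stays affine and nothing is clipped.

Deep-feature vectors (any even length; computed outside this package, e.g.
by a pretrained CNN, and supplied as CSV keyed by image name) are fused by
serial concatenation after the four CF values.

The classifier is a soft-margin RBF-SVM,
$K(u,v) = \exp(-g\|u-v\|^2)$, with $(c, g)$ chosen by stratified 3-fold
cross-validation over a powers-of-two grid $2^{-5}\dots2^5$ (the fold
assignment is seeded and bit-reproducible; ties break toward the smallest
$c$, then the smallest $g$).  Evaluation reports the confusion matrix with
malignant as the positive class, sensitivity, specificity, accuracy,
precision, F1, and the trapezoidal/rank AUC; ratios with empty denominators
are reported as missing rather than zero.

## The phantom generator

`phantom_spec()` describes a single hypoechoic lesion by a polar boundary
$r(\theta) = r_0\,s(\theta)\,(1 + \frac{A}{K}\sum_{k=1}^{K}
\sin((k{+}1)\theta + \varphi_k))$, where $s(\theta)$ is an ellipse factor
implementing the height/width aspect and $A$ is the irregularity amplitude.
Notable generator decisions:

* The harmonic sum is divided by $K$ so the maximal relative perturbation
  equals $A$ and the radius stays positive over the whole admissible range
  $A \le 0.5$; harmonics start at angular order 2 because order 1 merely
  translates the boundary.
* The default harmonic count is $K = 14$.  The divider radii probe spatial
  scales of 4–11 px; with a lesion radius of 16–30 px, harmonics up to
  order 15 put boundary structure at wavelengths down to ~13 px, so
  irregular phantoms are genuinely more complex *at the scales the SC
  feature measures*, as spiculated malignant margins are.  With only 2–3
  low-order harmonics a "complex" phantom is merely lobulated and the SC
  slope cannot see it.
* Speckle is the standard fully-developed approximation: a multiplicative
  mean-1 Gamma factor with shape equal to the number of looks (variance
  $1/\text{looks}$; 4 looks is the default test condition, `Inf` disables
  it).  Intensities are clipped to $[0,1]$ after speckle.
* The posterior shadow is a rectangular band spanning the lesion's
  horizontal extent from its bottom to the image bottom, attenuated by
  $1 - \text{strength}\cdot t(x)$ with a linear horizontal taper $t$ —
  a deliberately simple geometry.
* Edges are blurred by convolving the binary lesion with a Gaussian of the
  requested width, emulating the blurred mixed zone of infiltrative margins.

The benign-like and malignant-like presets of `phantom_cohort()` encode the
two regimes the features target: wide/smooth/unshadowed
(aspect 0.45–0.65, $A \le 0.05$) versus tall/irregular/shadowed
(aspect 0.85–1.05, $A = 0.2$–$0.3$, shadow strength 0.2–0.4), both speckled
at 4 looks on 96×96 px images with lesion radii 16–21 px.  These sizes keep
a full 40-phantom end-to-end study (segmentation included) around half a
minute on one core.

What the phantoms do **not** emulate: anisotropic point-spread functions,
depth-dependent attenuation and focusing, refraction and reverberation
artifacts, heterogeneous tissue backgrounds, multiple or non-convex lesions
beyond the polar family.  Passing phantom tests therefore demonstrates that
the measurement chain is faithful to known geometry under speckle — not
that clinical accuracy on real ultrasound matches any published figure.
In particular, phantom cohorts are close to linearly separable by the
orientation feature alone, so held-out accuracies near 1.0 say nothing
about performance on real lesions, where published accuracies for this
kind of pipeline are around 0.87–0.93.

## Numerical notes and degenerate inputs

* Explicit evolution enforces $\mu\tau < 0.25$ at construction; NaNs in an
  update abort with the iteration number.
* A vanished zero level (over-shrunk contour) aborts with a hint to reduce
  $|\alpha|$; a seed rectangle covering the whole image (no exterior) and
  out-of-bounds seeds are rejected at initialization.
* `hu_ps_score()` rejects zero-mass regions ($m_{00}=0$) and the
  (measure-zero) case $\eta_{20}+\eta_{02}=0$ where the log transform is
  undefined.
* `divider_counts()` rejects radii that are not smaller than the contour
  extent; counts are integers, so fitted slopes on small lesions carry
  quantization noise of a count or so — monotonicity studies should average
  a few phantoms per condition.
* Extreme-point ties (flat runs) resolve to the run midpoint; tie tolerance
  is $10^{-7}$ of the coordinate range.
* Constant features abort normalization by name; features absent at predict
  time abort rather than silently reordering.

## Problem sizes used by the tests

The bundled tests and the acceptance script use 96×96 phantoms with lesion
radii 16–22 px, 400-iteration evolution budgets, 10-phantom Dice cohorts,
and five 40-phantom classification studies — sizes chosen so the whole
suite exercises every stage end-to-end in a few minutes while leaving the
statistical conclusions (Dice ≥ 0.85 under 4-look speckle, CF-only
held-out accuracy ≥ 0.85 across seeds) comfortably stable.

## Known limitations

* Seed rectangles are user-supplied; there is no automatic lesion detection.
* One lesion per image; multi-region level sets are out of scope.
* The deep-feature path ingests precomputed vectors only — no network
  inference happens in this package.
* The PS region is a rectangle; clinically the shadow cone can be oblique,
  and a non-rectangular construction might track it better.
* The divider walk assumes a simple closed contour; self-intersecting
  contours are not supported.
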