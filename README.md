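# buscad

Computer-aided analysis of 2D breast-ultrasound (BUS) images in R:
level-set lesion segmentation, four handcrafted *characteristic features*
that quantify the sonographic signs radiologists use, optional fusion with
precomputed deep-feature vectors, and RBF-SVM classification of lesions as
benign or malignant.  A seeded speckle-phantom generator makes the whole
chain testable without clinical data.

## What it computes

Given a grayscale image and a seed rectangle inside the lesion:

1. **Segmentation** — distance-regularized level-set evolution (DRLSE).
   The boundary is the zero level of a field φ evolved under

   ∂φ/∂t = μ·distReg(φ) + λ·δ<sub>ε</sub>(φ)·div(g·∇φ/|∇φ|) + α·g·δ<sub>ε</sub>(φ),

   with edge indicator g = 1/(1 + |∇(G<sub>σ</sub>∗I)|²).  Evolution stops
   when the zero-crossing pixel set is stable.

2. **Characteristic features (CF)** from the segmented contour:
   * *orientation* — height/width ratio |y<sub>u</sub> − y<sub>d</sub>| / (x<sub>r</sub> − x<sub>l</sub>)
     of the contour extreme points (taller-than-wide suggests malignancy);
   * *EI score* — edge indistinctness: max of mean column/row standard
     deviations in 21×15 patches at the top and bottom vertices, averaged
     over the two patches (blurred infiltrative margins score low);
   * *PS score* — posterior-shadow score: −sign(η₂₀+η₀₂)·log₁₀|η₂₀+η₀₂| of
     the normalized central moments of the region below the lesion;
   * *SC score* — shape complexity: the slope b of the least-squares fit
     log₁₀N(R) = a + b·log₁₀R from the cartographers' divider method
     walked along the contour with radii R = 4…11 px (more negative =
     more complex boundary).

3. **Classification** — min-max normalization fitted on training data
   (inverted direction for SC), optional serial fusion CF∥DLF with
   externally computed deep features, and a soft-margin RBF-SVM
   K(u,v) = exp(−g‖u−v‖²) tuned by stratified 3-fold grid-search
   cross-validation; metrics include sensitivity, specificity, accuracy,
   precision, F1 and AUC with malignant as the positive class.

## Worked example

```r
library(buscad)

# a malignant-like speckled phantom: tall, irregular, shadowed
spec <- phantom_spec(rows = 96, cols = 96, base_radius = 20, aspect = 0.9,
                     irregularity_amp = 0.25, speckle_looks = 4,
                     shadow_enabled = TRUE, shadow_strength = 0.3, seed = 42)
ph <- generate_phantom(spec)

seg <- segment_lesion(ph$image, c(38, 40, 58, 56), drlse_params(max_iters = 400))
seg$contour
#> bus_contour: 160 vertices, bbox x [27.5, 68.4], y [30.3, 66.6]

round(characteristic_features(ph$image, seg$contour), 3)
#> orientation    ei_score    ps_score    sc_score
#>       0.891       0.196       2.802      -1.004
```

The lesion is read as nearly as tall as wide (orientation 0.891 — the
generating aspect was 0.9), with a posterior-shadow score of 2.802 on the
8-bit grey-level scale used by the clinical literature, and an SC slope of
−1.004 (the smooth-curve limit is −1; clinically complex contours run to
about −1.1).

A full end-to-end study — 40 speckled phantoms from benign-like and
malignant-like regimes, segmentation, feature scoring, train/test split,
grid-searched SVM:

```r
study <- phantom_classification_study(n_benign = 20, n_malignant = 20, seed = 1)
study$metrics
#> confusion: TP 10  FP 0  FN 0  TN 10
#> accuracy 1.000  sensitivity 1.000  specificity 1.000  precision 1.000  F1 1.000
```

Phantom regimes are nearly separable by orientation alone, so perfect
held-out accuracy here validates the measurement chain, not clinical
performance (see the vignette for what the phantoms do and do not emulate).

## Command line

`inst/cli/buscad` exposes subcommands over the same functions:

```sh
buscad phantom  --out img.png --mask mask.png --contour truth.csv --seed 3 --aspect 0.7
buscad segment  --image img.png --seed 37,40,57,54 --config seg.yaml \
                --out-mask mask.png --out-contour contour.csv
buscad features --image img.png --contour contour.csv --out features.csv --trace trace.csv
buscad train    --features train.csv --labels labels.csv --dlf dlf.csv --out model.rds
buscad predict  --model model.rds --features test.csv --out pred.csv
buscad evaluate --pred pred.csv --truth labels.csv --out metrics.json
buscad run      --config run.yaml --out-dir out/
```

Contours are CSV (`x,y`, 0-based pixels), masks 0/255 PNG, metrics JSON.

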