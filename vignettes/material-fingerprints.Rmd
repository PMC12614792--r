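---
title: "Visual fingerprints of material appearance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual fingerprints of material appearance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matfp)
```

## The representation

A *visual fingerprint* summarises the appearance of one material as a vector
of sixteen perceptual attribute values — colour vibrancy, surface roughness,
pattern complexity, striped and chequered pattern, brightness, shininess,
sparkle, hardness, movement effect, pattern scale, naturalness, thickness,
multicolouredness, value and warmth (`attribute_schema()` carries the anchor
terms and the instructive question behind each scale). The attributes fall
into five loose clusters: gloss, texture and pattern, light and colour,
physical, and abstract properties. Fingerprints are obtained by aggregating
slider ratings from many observers, and can alternatively be predicted
directly from a pair of photographs of the material. This package implements
both paths and everything needed to test them end to end.

Two frames describe each material: a *non-specular* view (the middle of a
rotating-sample sequence, where reflected light points away from the camera)
and a *near-specular* view, offset about 6 degrees from the mirror
configuration because the exact specular frame saturates for shiny materials
(`select_frames()` computes both indices for a given sequence length).

## From raw ratings to fingerprints

`aggregate_ratings()` runs the aggregation pipeline:

1. **Participant-level z-scoring** (`zscore_participant()`): within each
   participant-by-attribute stratum, responses are shifted and scaled to mean
   0 and sample (n-1) SD 1. This removes idiosyncratic offset and gain in
   slider use. Zero-variance strata carry no ranking information; they are
   set to 0 and flagged.
2. **Discordant-rater exclusion** (`exclude_discordant()`): for each
   attribute, any participant whose ratings correlate negatively (or
   undefinedly) with the all-participant mean ratings is dropped for that
   attribute. The consensus includes the participant under test — a single
   pass, not leave-one-out and not iterated — so a lone rater on an attribute
   can never be excluded.
3. **Averaging** across the surviving participants per material and
   attribute.

The result is on the *z-score scale*. For similarity computations the set is
min–max rescaled per attribute onto \[-1, 1\] over a reference corpus
(`rescale_to_unit()`); the stored ranges map novel fingerprints (e.g. model
predictions) onto the same scale. The rescaling is what makes the L1 term of
the similarity metric (below) a proper \[0, 1\] quantity; the raw z-range is
unbounded, so some convention of this kind is unavoidable and this one is
recorded as the package's choice.

Two study-level statistics accompany the pipeline. `attribute_importance()`
scores free-naming responses by `ap * (max(ao) - ao)`, combining the
probability `ap` that an attribute is mentioned with its mean rank `ao`
(early mentions matter more). `fleiss_kappa()` and `unanimity_counts()`
quantify inter-rater agreement when several raters sort responses into the
sixteen categories; both are implemented from the published formulas since no
installed package provides them.

## The similarity metric

Similarity between unit-scale fingerprints $V_1, V_2$ is

$$d(V_1,V_2) = \alpha\, R(V_1,V_2) + (1-\alpha)\Big[1 -
\frac{1}{2n}\sum_{i=1}^{n} |V_1(i)-V_2(i)|\Big], \qquad n = 16,$$

a weighted combination of the Pearson correlation (relative, shape
similarity) and an L1 amplitude term. The default $\alpha = 0.5$ weights them
equally; $\alpha = 1$ is pure correlation, $\alpha = 0$ pure amplitude
agreement. Higher is more similar; identical non-constant fingerprints score
exactly 1 and the range is $[-\alpha, 1]$. A constant fingerprint has
undefined correlation; its correlation term is taken as 0 with a warning —
a neutral contribution rather than a hard error, since the L1 term remains
meaningful. Retrieval (`retrieve_top_k()`) sorts candidates by this
similarity with ties broken by ascending material id so results are
reproducible; typicality (`typicality()`) is the mean similarity to the top
`ceiling(0.10 * (N-1))` most similar other materials.

## Image-computable features

Three representations map an image pair to a feature vector.

**S — compact statistics (28).** Fourteen deterministic statistics per
frame, non-specular first: luminance mean, SD and skewness (Rec. 709
weights); relative energy in four log-spaced radial frequency bands with
edges at $2^{-7}\dots2^{0}$ of Nyquist, chosen to cover pattern periods from
4 px up to about half the frame; directionality strength (resultant length of
the magnitude-weighted, angle-doubled gradient orientation distribution) and
the entropy of a 16-bin orientation histogram; the number of dominant colours
(clusters occupying at least 5% of pixels after 8-cluster quantisation of
8×8-block-averaged pixels — block averaging suppresses fine pattern
modulation so that spatially coherent colours dominate, and the pixels are
sorted before clustering so the statistic is invariant to rotations and
translations); stripe and checker scores from the orientation profile of the
power spectrum (one dominant orientation pair scores as stripes, two
orthogonal pairs as checks); mean chroma; and the circular SD of hue.
Degenerate constant frames yield zeros for all contrast-type features. The
set is rotation-invariant by construction, which is why rotation augmentation
is refused for it.

**T — texture-synthesis statistics (1341).** The joint texture statistics of
a complex steerable pyramid with 3 scales, 3 orientations and a 7×7
correlation neighbourhood, computed per colour channel on both frames and
averaged. The per-channel layout stores 798 slots of which exactly 447 are
generically non-zero:

| block | slots | non-zero |
|---|---|---|
| pixel moments (mean, var, skew, kurt, min, max) | 6 | 6 |
| highpass residual variance | 1 | 1 |
| skew/kurtosis of partial reconstructions (4 scales) | 8 | 8 |
| central autocorrelation of partial reconstructions | 49×4 | 25×4 |
| central autocorrelation of band magnitudes | 49×9 | 25×9 |
| magnitude means (highpass, 9 bands, lowpass) | 11 | 11 |
| cross-orientation magnitude covariance (strict triangle) | 9×3 | 3×3 |
| cross-orientation real covariance (incl. diagonal) | 9×3 | 6×3 |
| cross-scale magnitude covariance | 9×3 | 9×2 |
| cross-scale real covariance vs phase-doubled parents | 18×3 | 18×2 + 15 |

Redundant slots are stored as exact zeros: the point-symmetric half of every
autocorrelation, the magnitude cross-orientation diagonal (an exact duplicate
of the magnitude autocorrelation centre), symmetric lower triangles, the
cross-scale magnitude slice at the coarsest scale (no parent exists), and the
unused columns of the coarsest real-parent block, where the upsampled lowpass
residual and its four one-pixel shifts act as the five parents. Removing
zero-valued features over any corpus of non-degenerate images
(`texture_zero_mask()`) therefore retains 447 per channel — 1341 over three
channels. The pyramid itself is built in the frequency domain with
raised-cosine radial masks (highpass residual above $\pi/2$, octave-wide
oriented bands, subsampled lowpass) and single-sided angular masks giving
complex analytic bands; low-frequency content reconstructs through the
chain to machine precision, which the tests assert.

**C — embedding features (1024).** Each frame is resampled so the depicted
sample side (canonically 26 mm) spans `round(26 / 25.4 * 250) = 256` px at
250 DPI, centre-cropped to 224 px, and embedded by a pluggable backend that
maps a 224×224 image to a 512-vector; the two frame embeddings are
concatenated. The shipped `projection_backend()` block-averages the frame to
32×32×3 and applies a fixed seeded Gaussian projection — deterministic and
self-contained, it exercises the full pipeline offline. A pretrained
vision–language backbone (e.g. a ViT-B/32 image encoder) plugs in through the
same `embedding_backend` interface when available.

## Predictors

`fit_knn()`/`knn_predict()` interpolate the fingerprints of the k nearest
training materials (L2 distance on per-feature standardized vectors) with
inverse-distance weights $w_i = (1/d_i)/\sum_j (1/d_j)$; a query at zero
distance returns its neighbour's fingerprint exactly. k = 2 is the default.
Inverse-distance weighting is one reasonable reading of "linear
interpolation" between two exemplars in a high-dimensional feature space; it
is continuous away from ties and exact at the exemplars.

`train_mlp()`/`mlp_predict()` fit a fully connected network with rectifier
hidden units and an identity 16-unit output: 1341-256-64-32-16 for T,
28-16-16-16 for S, 1024-512-512-16 for C. Training minimises mean squared
error with Adam (learning rate 1e-3, minibatches of 32, at most 4000 epochs)
on per-feature standardized inputs, early-stopped on a 10% validation slice
with patience 300, under a single seed that fixes initialisation, the
validation split and shuffling — two runs with the same seed produce
identical weights. A strong decoupled weight decay (1.0, biases excluded) is
the default: at the corpus sizes this package targets (tens to a few hundred
materials) an unregularised network of this capacity memorises the training
set and generalises worse than a linear fit, and the decay setting was
selected by validation loss on synthetic corpora. Image-space augmentation
(random crop, rotation — never for S —, up to 5% rescaling, and an azimuthal
jitter of up to 2.5 degrees that only applies when a full frame sequence is
available) enters through a feature-generator hook, since augmentation must
happen before feature extraction.

`split_dataset()` holds out `round(0.2 n)` materials per category (at least
one whenever a category has two or more members) so every category is
represented in the test set; singleton categories stay in training.

## Evaluation statistics

`evaluate_predictions()` bundles: **RSM²**, the squared Pearson correlation
between the strict upper triangles of the predicted and human similarity
matrices; **RD²**, the per-attribute squared correlation between predicted
and human values across materials (mean over attributes reported alongside);
**MAE**, the mean absolute error over materials × attributes; **top-k
overlap**, the intersection size of the k highest-ranked materials per
attribute (k = 5); and **RCI**, the Spearman correlation between human and
predicted values within the top-n materials *by human rating* (n = 100,
clamped to the corpus), re-ranked inside the subset — the only reading that
keeps the statistic in \[-1, 1\]. RD² is computed as a squared correlation
rather than 1 − SS_res/SS_tot; the two agree when predictions are calibrated
and the correlation form is the natural companion of RSM². `aic_compare()`
uses the Gaussian-likelihood form `2k + n log(RSS/n)` with k the trainable
weight count for networks and the stored exemplar coordinate count for the
neighbour model; absolute AIC values depend on this parameter-counting
convention, so only differences within one convention are meaningful.

## The synthetic testbed

Real corpora require captured video and human raters, so the package ships a
procedural generator whose ground truth is known by construction.
`generate_pair()` layers an oriented sine grating, an axis-aligned
checkerboard, a palette colour field (blobby regions from a quantised
smooth noise field) and a 1/f^β noise field on a base colour, and adds a
smooth highlight plus bright speckle to the near-specular frame only.
`truth_fingerprint()` maps the parameters to unit-scale attribute values:
ten attributes are direct monotone maps of single parameters (stripes,
checks, brightness, gloss/shininess, sparkle, palette size, palette chroma,
log period, noise roughness, gloss+sparkle/movement); the six cognitive
attributes (complexity, hardness, naturalness, thickness, value, warmth) use
explicit surrogates — e.g. hardness inverse to roughness, warmth from the
base colour's red–blue balance — documented so that recovery tests are
meaningful, with no claim of perceptual validity. Warmth deliberately avoids
palette-mean colour statistics: for palettes whose hues are spread around
the circle the mean cancels, which would collapse the axis into ties and
make rank recovery undefined rather than hard.

`simulate_ratings()` models each honest rater as a gain (0.7–1.3), a bias
(±0.2) and Gaussian response noise (SD 0.2 on the truth scale) applied
before mapping onto the 0–100 slider; adversarial raters answer with the
negated truth, guaranteeing a negative consensus correlation so the
exclusion rule has a ground-truth target. `make_corpus()` stratifies draws
over four pseudo-categories (striped-fabric-like, wood-grain-like,
glossy-coating-like, noisy-matte-like) whose ranges jointly make every
generator-controlled attribute span most of \[-1, 1\].

What passing tests on this testbed do and do not show: they demonstrate that
the aggregation pipeline recovers a planted signal under realistic rater
noise, that the exclusion rule isolates planted adversaries, and that the
feature–predictor path carries enough information to recover the generator's
appearance axes on held-out materials. They do not show that the surrogate
cognitive attributes behave like human judgements, nor how the predictors
fare on photographic texture, specular microstructure or anisotropic
materials the generator cannot produce.

## Numerical choices and problem sizes

Canonical working resolution is 512×512 px for a 26 mm sample; texture
statistics assume even sizes divisible by $2^{4}$. Sample SD (n−1) is used
for z-scores; skewness and kurtosis of zero-variance images are defined as 0;
correlation of constant vectors contributes 0 with a warning everywhere it
can arise. All randomness flows through explicit seeds (generator, rater
panel, split, training, backend), and seeded functions restore the caller's
RNG state. The test suite exercises recovery at the sizes a laptop handles
comfortably: a 50-material corpus with 10 raters for rating recovery, and a
200-material corpus (150/50 per split over three seeds) for predictor
recovery at 512 px; texture-statistic unit tests run at 128 px, where the
layout is identical and each extraction is a few hundred milliseconds.

## Known limitations

The embedding backend shipped here is a fixed random projection, not a
pretrained perceptual representation; with it, C features are a test vehicle
rather than a competitive predictor. The texture-statistic layout is one
defensible reconstruction of the classic joint-statistics set at this
configuration; other implementations prune redundancy differently and land
on different raw counts, though the non-redundant content is the same. The
generator produces stationary, flat, isotropically lit samples only —
no BRDF/BTF simulation, no anisotropy, no goniochromatism — and its
cognitive-attribute surrogates are conventions. Aggregation assumes every
(material, attribute) cell retains at least one rater after exclusion and
aborts otherwise, naming the empty cell.
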