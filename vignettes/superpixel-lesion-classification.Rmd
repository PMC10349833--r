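---
title: "Superpixel-level classification of skin lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superpixel-level classification of skin lesions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dermsp classifies dermoscopy images of pigmented skin lesions — melanoma
versus nevus — not at the image level but at the *superpixel* level: each
image is over-segmented into roughly uniform superpixels, the superpixels
lying on the lesion are kept, and each one becomes a training record
described by six geometric descriptors. A small number of images therefore
yields a large, information-dense training table. This vignette explains
each stage, the modelling assumptions, the tunable parameters, and the
choices made where the design was genuinely open.

## Pipeline overview

```
image -> hair removal (Dull Razor) -> lesion ROI (seeded graph cut)
      -> black-masked image -> SLIC superpixels -> background-SP elimination
      -> per-SP geometric features -> stratified split -> z-score (train-fitted)
      -> nine classifiers -> confusion-matrix metrics (accuracy ... MCC)
```

```{r}
library(dermsp)
cfg <- pipeline_config(n_images = 20, models = c("RF", "CNN1D"), seed = 1)
res <- run_pipeline(cfg)
res$metrics
```

## Hair removal (Dull Razor)

Hairs are thin, dark, curvilinear. A grayscale morphological **closing** with
a linear structuring element brightens any dark structure narrower than the
element; the closing residue (closed − original), maximized over element
orientations {0°, 45°, 90°, 135°}, is therefore large exactly on hair pixels.
Defaults: element length 11 px, residue threshold 10 (0–255 scale), detected
mask dilated by 1 px. Detected pixels are refilled by onion-peel
nearest-neighbour averaging — each pass fills mask pixels adjacent to known
pixels with the mean of their known 8-neighbours. This is rotation-agnostic
and exact for constant surroundings; we chose it over the classical
two-point bilinear scheme because it has no direction-selection step while
honouring the same contract (replacement from neighbouring intensities).
Pixels outside the dilated mask are untouched, and a second detect+remove
pass changes less than 0.1 % of pixels.

The luminance convention throughout is Rec. 601
(0.299 R + 0.587 G + 0.114 B).

## Lesion ROI by seeded minimum cut

The lesion mask minimizes the standard seeded binary energy
$$E(x) = \sum_i D_i(x_i) \;+\; \lambda \sum_{(i,j)}
\exp\!\big(-(I_i - I_j)^2 / 2\sigma^2\big)\, [x_i \ne x_j]\,/\,d(i,j)$$
over a 4-connected pixel grid (8-connected optional). Data terms are
negative Gaussian log-likelihoods of luminance under models estimated from
the seed pixels (standard deviations floored at 1 intensity unit so constant
seed regions stay well-posed). Defaults: λ = 50, σ = 10.

Seeding is automatic, because a batch tool cannot ask for scribbles: the
border frame (width 8 px) seeds the background — dermoscopy lesions sit
centrally — and the largest connected component of pixels *strictly darker*
than the 10 % luminance quantile, restricted to the central half of the
frame, seeds the lesion. A constant image has no pixel strictly below its
quantile and is rejected: there is no darkness contrast to work from.

Exactness at practical speed: solving the full 256×256 grid with a
general-purpose max-flow routine is prohibitively slow, so the solver first
applies an exact reduction — any pixel whose unary margin
$|D_i(\mathrm{fg}) - D_i(\mathrm{bg})|$ exceeds the summed weight of its
incident neighbour edges takes the cheaper label in **every** optimal
labeling (flipping it changes the pairwise part by at most that sum, so the
flip is always an improvement). Only the uncertain band near the lesion
boundary (typically a few thousand pixels) reaches the flow solver
(igraph's push-relabel); edges between a free pixel and a fixed one become
terminal capacities. The reduction provably preserves the argmin, and the
test suite checks energy optimality against exhaustive enumeration on
seeded miniatures through this same code path.

Post-processing keeps the component(s) containing foreground seeds and fills
interior holes (holes containing background seeds stay open, so seed
compliance is unconditional). It can be disabled (`postprocess = FALSE`) to
inspect the raw energy optimum; hole filling intentionally departs from that
optimum because a lesion is a filled region.

## Superpixels and background elimination

SLIC is localized k-means in joint CIELAB + image-plane coordinates with
distance $D = \sqrt{d_{lab}^2 + (d_{xy}/S)^2 m^2}$, grid step
$S=\sqrt{HW/n}$, centers initialized on a regular grid (grid shape follows
the image aspect so even n = 2 yields two centers), nudged to the lowest
3×3 gradient position, 10 assignment/update sweeps over 2S-radius windows.
Defaults n = 100 (the count at which classification works best in this
pipeline) and compactness m = 10. Everything is deterministic.

Connectivity enforcement splits every 4-connected fragment into its own
label, merges fragments smaller than (HW/n)/4 into their largest adjacent
label, and compacts labels to 1..L in scan order. Superpixel generation runs
on the **black-masked full image** (background zeroed), not a cropped ROI:
the strong lesion/black contrast makes superpixel boundaries snap to the
lesion outline.

Background elimination is a majority rule: a superpixel is kept when at
least `overlap_threshold` (default 0.5) of its pixels lie inside the lesion
mask. "Belongs to the mask" is not otherwise defined for straddling
superpixels, and majority is the least surprising reading; the kept set
shrinks weakly as the threshold rises, and full/empty masks keep all/none.

## Geometric descriptors

Six per superpixel: area (pixel count), perimeter, orientation,
eccentricity, major axis length, convex area. The ellipse descriptors come
from the second-order central moments with the +1/12 pixel-extent correction
on the diagonal (each pixel treated as a unit square, the regionprops
convention), so single pixels and 1-px-wide bars have well-defined ellipses:
a single pixel has major axis $4/\sqrt{12} \approx 1.155$. Orientation is
$\tfrac12\,\mathrm{atan2}(2\mu'_{11}, \mu'_{20}-\mu'_{02})$ in degrees,
measured counter-clockwise from the +x (column) axis with the image y-axis
flipped to point up, range (−90°, 90°]. Eccentricity is
$\sqrt{1-\lambda_{\min}/\lambda_{\max}}$; major axis length
$4\sqrt{\lambda_{\max}}$.

Perimeter is the length of the closed outer-boundary walk (Moore tracing,
8-connected, diagonal steps weighted √2). This is simpler than the corner-
corrected toolbox estimator; toolbox bit-compatibility is a non-goal and the
convention is oracle-tested (a 10×10 square has perimeter 36, a single pixel
0). Convex area counts pixel centers inside (or on) the filled convex hull
of the region's pixel centers; it equals area exactly when the digitized
region is convex. Labels that decompose into several components (possible
after mask intersection) use their largest component.

## Dataset handling

Records are split at the superpixel level (the study design: superpixel
datasets are split 0.7:0.3 by default; 0.8:0.2 and 0.85:0.15 are available),
stratified by class. Superpixels from one image are correlated, so an
image-grouped split (`by_image = TRUE`) is available as the leakage-safe
alternative. Normalization is z-score with mean and **population** standard
deviation (ddof = 0; the convention is documented because either choice is
defensible) estimated on the training part only and applied verbatim to the
test part — fitting on the full table would leak test statistics. Fivefold
cross-validation indices are balanced (fold sizes differ by at most one).

## Classifiers

Six classical learners with their published hyperparameters, plus three
fixed small networks on the 6-feature input:

| name | backend | notes |
|------|---------|-------|
| RF | randomForest, 100 trees | R forests split on Gini; the entropy criterion has no installed equivalent — recorded on the spec, documented here |
| SVM | e1071, linear kernel | one-vs-one is trivial for 2 classes |
| AD | in-package SAMME over rpart stumps | 100 estimators, seed 40; no AdaBoost package is available in the stack |
| KNN | class::knn, k = 1 | brute-force search; kd-tree/leaf-size fields recorded, predictions identical |
| DT | rpart, split = "information" (= entropy) | rpart caps depth at 30 (< the recorded 100); a depth-30 unpruned tree already memorizes 6-feature data |
| GNB | in-package Gaussian NB | implemented here so var_smoothing = 1e-9 (fraction of the largest feature variance added to every class variance) is honoured |
| PRNN | nnet, 10 hidden units, cross-entropy | the scaled-conjugate-gradient trainer is approximated by nnet's quasi-Newton optimizer, same architecture and loss |
| FNN | in-package engine | dense 10–8–6 (tanh) → 1 (sigmoid), Adam, BCE, 100 epochs, batch 32, lr 0.001 |
| CNN1D | in-package engine | conv(64,k2,relu) → dropout 0.2 → conv(32,k1,relu) → maxpool(1) → flatten → dense 32 → dense 1 (sigmoid); 7457 parameters, verified against layer-shape arithmetic |

The learning rate is 0.001 (the architecture table's value; a conflicting
0.01 appears once in prose — the more specific source wins). Batch size is
unstated upstream; 32 is the conventional default. The in-package network
engine is a deliberately small forward/backward implementation (dense and
1-d convolutional layers, inverted dropout, Adam) — fixed feedforward
chains, not a framework — and every stochastic learner is seeded, so
training is bit-reproducible.

`train_model()` records the mean fivefold CV accuracy on the training split
and then fits on the full split. Networks threshold their sigmoid output at
0.5.

## Metrics

Accuracy, precision, recall, F1 and the Matthews correlation coefficient are
computed from the confusion matrix with melanoma fixed as the positive class
(a false negative is a missed melanoma, the clinically expensive error). A
metric with a zero denominator is reported as 0 and *flagged* rather than
raised, so batch sweeps over degenerate splits never abort; the flag travels
into the metrics JSON.

## The synthetic generator: what it emulates and what it does not

Each image is a flat skin tone plus i.i.d. Gaussian noise (sd 2.5), one
darker lesion, and optional dark Bezier hair arcs with a known raster. The
lesion boundary is $r(\theta)=r_0(1+p(\theta))$ with $p$ a random Fourier
series over the `border_harmonics` band, rescaled to RMS amplitude
`border_irregularity` and clamped to ±0.5, then scaled by `axis_ratio`
along the minor axis and randomly rotated. Class defaults: melanoma
irregularity 0.25, axis ratio 0.55 and harmonics 2–16 (fine border
serrations down to the superpixel scale); nevus 0.05, 0.9 and harmonics 2–6
(lobed but locally smooth). Melanomas additionally receive smooth random
pigment blotches (`variegation_sd` = 18 intensity units; nevi 0) — the
colour variegation of real melanomas, and the feature that makes *interior*
superpixels class-informative. The serrated band and the variegation field
deliberately extend a first flat-interior, low-harmonic design: under that
design the kept-superpixel feature distributions of the two classes nearly
coincide (interior superpixels are identical regular tiles; harmonic 2–6
wiggles have wavelengths ~4 superpixel diameters), and no classifier can
recover the classes well — the generator would not express the very effect
the pipeline measures. Smooth-versus-serrated border fine structure and
colour variegation are both canonical dermoscopic class differences, so the
extension stays inside what the generator claims to emulate.

One knock-on interaction is worth knowing: melanoma border serrations are
genuinely hair-scale dark structures, so Dull Razor responds to them (a few
percent of pixels on a hair-free melanoma), and an inpainted hair stripe
crossing the sharp lesion boundary leaves a hair-scale ramp that a second
detection pass partly re-flags. The detector's noise-robustness contracts
(hair-free detections below 0.5 %, exact idempotence of detect+remove) hold
on smooth-bordered images and plain skin, and the pipeline applies hair
removal only when hairs are actually present.

Parameter choices in one place: 256×256 frames; lesion radius 78 px
(a centered lesion filling ~60 % of the frame, typical dermoscopy framing,
and large enough that 60 images yield >1000 kept superpixels at n = 100);
noise sd 2.5 (≈1 % of full scale — realistic for dermoscopy optics, and
compatible with the fixed Dull Razor threshold: hair-free images yield
<0.5 % detections); hair width 3 px.

What the generator does **not** emulate: real skin texture (no pigment
network, no vessels), gel bubbles or ruler marks, multi-lesion images,
camera vignetting, or realistic colour distributions. Passing the end-to-end
tests therefore shows the pipeline's machinery is correct and that it
recovers *geometrically encoded* class differences; it does not certify
clinical performance on real dermoscopy collections, which depend on
contrast regimes and artifacts the generator omits.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step derives its seed from one global seed; the
  same config + seed reproduces every output byte for byte.
* Graph-cut capacities are shifted per pixel so both terminal capacities are
  non-negative (the argmin is invariant); seed terminals get a capacity
  larger than any achievable energy.
* Moment eigenvalues are clipped at 0 before square roots; orientation ties
  (μ′₂₀ = μ′₀₂, μ′₁₁ = 0, e.g. squares) resolve to 0° via atan2.
* Convex-hull membership uses a 10⁻⁷ half-plane tolerance so boundary pixel
  centers count as inside; collinear regions fall back to counting lattice
  centers on the segment.
* Empty masks, single-class tables, zero-variance features, overlapping
  seeds and constant images are rejected with specific messages.
* Problem sizes in the shipped tests: 60-image studies for end-to-end
  recovery (three seeds averaged), 20 images for partition invariants,
  50 seeded miniatures (≤6×6, ≤14 free pixels) for exhaustive energy
  enumeration, 200 random blobs for the feature oracle. These sizes give
  stable Monte-Carlo estimates while keeping a full suite run comfortable
  on one CPU.

## Known limitations

* The graph-cut stage assumes the lesion is darker than the surrounding
  skin; amelanotic lesions would need different seeding.
* Superpixel-level splits share images between train and test by design
  (matching the study protocol); use `by_image = TRUE` for the conservative
  protocol.
* The perimeter convention differs from corner-corrected estimators by a few
  percent on smooth shapes; comparisons across packages should use one
  convention.
* Dataset adapters (MED-NODE, 7-Point, PAD-UFES-20, generic folders) only
  enumerate images and map diagnoses; reproducing published accuracies on
  those collections is out of scope here.
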