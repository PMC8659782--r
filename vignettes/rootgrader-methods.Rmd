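---
title: "Methods: image features, selection and tuning in rootgrader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image features, selection and tuning in rootgrader}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rootgrader)
```

`rootgrader` grades *Panax notoginseng* taproots from top-view images. This
vignette is the package's account of the science: the models, the choices
behind every tunable parameter, what the synthetic data does and does not
emulate, and the limitations a user should know before trusting a number.

## The grading problem

Commercial grade is defined by per-root weight bands (grade I ≥ 25 g,
II ≥ 17 g, III ≥ 12.5 g, IV ≥ 8.5 g; lighter roots are below standard and
`assign_grade()` refuses them). Grades differ visibly in silhouette size,
shape irregularity, surface color and surface texture, so a camera can
stand in for a scale. The pipeline turns one image of one root on a bright
uniform background into a 40-dimensional feature vector and classifies it
into a grade.

## Preprocessing

`preprocess()` chains: bilinear resize (default 512 × 512 — large enough to
keep texture, small enough to bound GLCM cost), per-channel Gaussian
filtering, ITU-R 601 grayscale (0.299, 0.587, 0.114 — chosen because the
source toolchain for this kind of work, OpenCV, uses it), Otsu
thresholding, morphological opening-then-closing with a square element plus
hole filling, and largest-connected-component retention (one specimen per
image by design).

Numerical choices:

* **Gaussian filter**: kernel 5 × 5; σ defaults to `0.3((k-1)/2 - 1) + 0.8`,
  the common machine-vision convention tying σ to kernel size. Borders are
  reflected, so constants are preserved exactly.
* **Otsu**: computed on the 8-bit histogram of rounded intensities; among
  tied maximizers of the between-class variance the smallest threshold is
  returned, making the operation fully deterministic. A constant image is a
  degenerate histogram and errors.
* **Foreground polarity**: the specimen is the side of the threshold with
  the smaller total intensity (mean × area). A bright background dominates
  the other side regardless of exposure, so the rule is robust to polarity
  without a hard-coded "dark object" assumption.
* **Morphology**: opening removes specks smaller than the element, closing
  seals gaps, hole filling removes enclosed background. Open∘close is
  idempotent on its own output, which the tests check empirically.

## Feature extraction

**Shape (9).** The rasterised specimen is treated as a union of unit pixel
squares: the axis-aligned and minimum-area rectangles and the minimum
enclosing circle are computed on the convex hull of the boundary pixels'
corners (so a filled 100 × 100 square measures exactly 100 × 100), the area
is the pixel count, and the perimeter is the length of the ordered outer
contour polygon. The minimum-area rectangle comes from rotating calipers
over the hull; the enclosing circle from Welzl's algorithm. Elongation is
normalized to longer/shorter so it is orientation-invariant and ≥ 1, and
the duty cycle (area over min-rect area) is ≤ 1 by construction.

**Color (24).** Four moments per channel over R, G, B, H, S, V, computed on
foreground pixels only — the uniform background would otherwise swamp every
statistic. H, S, V are rescaled to 0–255 so all 24 features share one unit
scale. The moments are, deliberately, the *root-scaled* forms: mean; square
root of the mean squared deviation; signed cube root of the mean cubed
deviation; fourth root of the mean fourth-power deviation minus 3. The
root-scaling keeps all four statistics on the intensity scale. The cube
root of a negative sum is taken as the signed real root.

**Texture (7).** The co-occurrence matrix uses distance 2, 64 levels, and
symmetric accumulation over the four directions 0°, 45°, 90°, 135°, whose
feature values are averaged — the direction set is closed under 90°
rotation, so averaged features are rotation-stable. Quantization is uniform
over the full 0–255 range, not the image's own min–max, so features are
comparable across images. Only pairs with both endpoints inside the mask
count. Entropy uses the base-10 logarithm. Correlation is the Haralick form
with marginal means and standard deviations; when a marginal variance
vanishes (constant region) it is defined as 1, the convention of
scikit-image. A windowed mode (features averaged over square tiles) is
available behind the `window` argument for users who want locality; the
default is one global matrix, which is better-conditioned on small
specimens.

## RMSECV and the internal regression

All three selectors score a candidate feature subset by
`RMSECV = sqrt(sum (Y - Y_v)^2 / n)`, the 5-fold cross-validated error of
predicting the grade codes 1–4. The internal model is the package's own
PLS1 (NIPALS) regression, written in C++ because the selectors evaluate
tens of thousands of sub-models: predictors are autoscaled per training
fold and the number of latent components is chosen by the cross-validation
itself (minimum CV error over 1–10 components). PLS is the standard
internal model for these selector families; grades enter as numbers only
here — everywhere else they are categorical.

## Feature selection

**IRIV.** Each round draws 500 random binary sub-models over the retained
variables. For every variable, each sub-model is re-evaluated with that one
variable flipped, giving paired RMSECV distributions "with" and "without".
The mean paired difference and a paired Wilcoxon test (α = 0.05) classify
the variable as strongly informative, weakly informative, uninformative or
interfering; the latter two are dropped and the process repeats (at most 20
rounds) until only informative variables remain, then greedy backward
elimination removes variables while the RMSECV does not increase. Folds are
redrawn every round so a variable survives only if it helps across
independent splits; within a round all sub-models share folds so
comparisons are paired; the elimination phase keeps one fold set so its
trace is monotone non-increasing.

**VISSA.** Inclusion weights start at 0.5 per variable. Each iteration
draws 500 weighted binary sub-models, keeps the best 5 % by RMSECV, and
sets each weight to its frequency among the kept models, so weights shrink
toward 0 or 1. The monitored score is the RMSECV of the current weight-1
set on a fixed evaluation fold assignment; iteration stops when weights
have all converged or the score has stopped improving (patience 3, at most
50 iterations). The final subset is chosen by ranking variables by mean
weight and minimizing RMSECV over nested top-k sets — the familiar
"error versus number of selected variables" curve that falls to a minimum
and rises again.

**Stepwise regression.** Classical forward/backward selection on the grade
codes: enter the variable with the most significant partial F while
p < 0.05, remove any entered variable whose partial F exceeds p > 0.10,
until no change. Zero-variance and collinear duplicate columns have no
defined partial F and are never entered. Deterministic.

**No-signal guard.** On a pure-noise table, IRIV and VISSA raise an
all-noise warning and return an empty set when no subset beats the
intercept-only cross-validated baseline by more than 5 %.

**What recovery tests show.** On planted tables (five informative columns
carrying a thresholded linear signal, 35 independent noise columns,
n = 200) both IRIV and VISSA recover essentially all informative columns.
They differ in parsimony: at n = 200 a handful of noise columns carry
genuine in-sample partial correlation with the labels, and VISSA — a pure
RMSECV minimizer — keeps them (about 4–6 on average), while IRIV's strict
backward elimination stops earlier (about 1–2). That mirrors the methods'
characters on real data, where VISSA-style selection is typically the
least parsimonious. Neither behavior is a defect of the other; users who
need tight false-positive control should prefer IRIV or the stepwise
selector.

## Classifiers

All models see features z-scored with training-set statistics (RBF kernels
are scale-pathological on raw units).

* **SVM**: one-vs-one soft-margin with kernel `exp(-g ||u - v||^2)`
  (libsvm via e1071); the package's reference classifier.
* **ELM**: 100 sigmoid hidden units with seeded uniform random input
  weights; output weights by ridge-regularized least squares (ridge 1e-6
  for conditioning) on one-hot targets; prediction by argmax.
* **BP network**: one hidden sigmoid layer (20 units), full-batch gradient
  descent on softmax cross-entropy, learning rate 0.01, 1000 epochs, seeded
  initialization; divergence (non-finite loss or exploding weights) errors
  with guidance to lower the learning rate.

`evaluate()` reports overall accuracy (confusion-matrix trace over total),
per-class accuracies and their macro average. Splits are stratified per
class at the 7:3 ratio, so 1800 balanced records give 1260/540 with 315/135
per class.

## Hyperparameter tuning

`tune_svm()` maximizes stratified 5-fold CV accuracy over `(c, g)` with a
population of 20 for 100 iterations (the standard budget for this task):

* **GWO** searches both parameters on [0.01, 100]: wolves move toward the
  three current leaders with the exploration coefficient decaying linearly
  2 → 0.
* **GA** searches c on [0.01, 100] and g on [0.01, 1000]: tournament
  selection (size 2), arithmetic crossover at 0.6, Gaussian mutation at
  0.03 (σ = 10 % of range), elitism of one. The conventional lower bound of
  0 is nudged to 0.01 because the SVM requires strictly positive
  parameters.
* **PSO** searches c on [0.1, 100] and g on [0.01, 1000]: inertia 0.729,
  cognitive and social coefficients 1.494 (the constriction values),
  velocities clamped to 20 % of each range.

The three ranges deliberately differ — each follows its algorithm's
conventional setup rather than being harmonized. All candidates are clipped
to bounds, non-finite fitness discards the candidate with a warning,
best-so-far traces are monotone by construction, and fitness values are
cached on `(c, g)` rounded to six significant digits so revisited
candidates are free.

## Synthetic data

**Images.** Each specimen is a star-convex blob: a superellipse core
(exponent 2.5, aspect 0.55–0.8) modulated by sinusoidal radial lobes, on a
uniform light-gray background (level 230 — high contrast keeps Otsu well
posed). Grade conditions the joint distribution: major-axis mean falls
0.66 → 0.37 of the canvas from grade I to IV (±2 % spread), lobe count
rises 2–3 → 5–8 (smaller roots are gnarlier), base color darkens from tan
(196, 168, 120) to brown (150, 116, 76), per-channel noise rises 6 → 12,
and sinusoidal shading amplitude/frequency rise 6 → 18 and 0.04 → 0.12
cycles/px. A radial brightness falloff rounds the blob. The root weight is
drawn uniformly within the requested grade's band (grade I: floor to 1.5 ×
floor), so the image label and the weight label agree. Everything is a
pure function of (spec, grade, seed).

What this does **not** emulate: real root lobes are not sinusoidal,
real surface texture is not a single spatial frequency, there are no
shadows, specular highlights, soil, or camera noise correlations.
Passing tests on this generator show the pipeline's machinery is correct
and that grade-separated inputs are separated in feature space — they do
not certify accuracy on photographs.

**Planted tables.** Each sample gets a balanced grade code y ∈ {1..4};
informative column j equals `w_j y` plus Gaussian noise (default σ = 0.5,
small against the unit class gap but large enough that no single column is
decisive), with distinct weights w spread over 0.6–1.4; noise columns are
standard normal. The label is therefore a thresholded linear function of
the informative block — exactly linear when σ = 0 — and ground truth is
recorded in an attribute.

## Pipeline and reproducibility

`run_pipeline()` orders the stages data → fusion subset → stratified split
→ selection → tuning → training → evaluation. Selection and tuning run on
the training side only, so reported test accuracies are leakage-free. Every
stochastic stage consumes a sub-seed derived by hashing (master seed, stage
name), so adding a stage never perturbs earlier stages' randomness.
Reports serialize to JSON with timings excluded, making identical-seed runs
byte-identical. `compare_fusions()` shares one split across fusion subsets
so subset comparisons are paired. Problem sizes used by the shipped
checks — 100 images per grade end to end, planted tables of 200 × 40, ten
seeds for recovery rates, 20 cases per oracle — were chosen to make each
property statistically meaningful at desk scale.

The package's functions are the interface; there is no shell entry point.
An R user drives runs with `pipeline_config()` + `run_pipeline()`, which
subsume the synthesize/extract/select/tune/train/evaluate stages a
command-line wrapper would expose.

## Known limitations

* Segmentation assumes one specimen on a bright uniform background; scenes
  with shadows, glare or multiple roots are out of scope.
* Head count (roots per 500 g) is not modeled; weight alone drives
  synthetic labels.
* The co-occurrence "correlation" statistic follows the Haralick marginal
  form; other GLCM conventions (e.g. min–max quantization) will give
  different absolute values.
* ELM and BP are reference baselines, not tuned competitors; only the SVM
  gets metaheuristic tuning.
* Synthetic accuracy numbers are upper bounds of a sort: the default
  grade conditions are well separated by construction.
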