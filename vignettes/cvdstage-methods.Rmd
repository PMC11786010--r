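---
title: "Methods: quantitative cervical-vertebral maturation staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative cervical-vertebral maturation staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdstage)
```

## The measurement model

The skeletal-maturation signal is carried by the shape of the third and
fourth cervical vertebral bodies: as a patient matures, the vertebral
bodies grow taller relative to their anteroposterior length. `cvdstage`
works entirely in coordinate space — eight landmark points (the four body
corners of C3 and C4) plus the source image width; no raster images are
read.

Each record is first rescaled so the image is 2000 pixels wide
(`scale_to_width()`), with the same factor on both axes. This puts every
cephalogram on a common pixel scale, which matters because the subsequent
error-reduction step perturbs landmarks by a fixed number of *pixels*.

Per vertebra the ratio is

$$C = \frac{AH}{AP},$$

with $AH$ the anterior border length (anterior-superior ↔
anterior-inferior corner) and $AP$ the inferior border length
(anterior-inferior ↔ posterior-inferior corner). Corners are identified by
their anatomical *role* in the input record, never by coordinate ordering,
so horizontally flipped radiographs need no special handling. The corner
pairing itself is a documented convention of this package: "anterior
height over anteroposterior dimension" admits more than one corner
assignment, and we fix the one that matches the names — the anterior
border for the height, the inferior border for the length.

Because the ratio is dimensionless it is exactly invariant under uniform
scaling, which removes magnification differences between devices.

### Error-reduced measurement

Operator placement of a corner landmark is reliable only to a few pixels.
`aer_ratios()` treats each clicked point as the centre of a small
neighbourhood: per iteration, every one of the eight landmarks is
displaced independently on each axis by an integer magnitude drawn
uniformly from $\{1, \dots, d_{max}\}$ with an independent random sign
($d_{max} = 4$ by default), both ratios are recomputed, and the arithmetic
mean over $n$ iterations (default 1000) is returned.

Two phrasings of the displacement law are defensible — per-axis magnitudes
of 1–4 pixels, or a radial bound of 4 pixels. We implement the per-axis
law because it honours both the 1-pixel minimum and the 4-pixel maximum on
each axis; a radial variant would need a different magnitude distribution.
Whether a zero displacement should be allowed per axis is the same
ambiguity; excluding it (as we do) follows the "1 to 4" reading.

Numerical notes:

* `max_disp = 0` short-circuits to the deterministic ratio, bit-exactly.
* An iteration whose perturbed $AP$ collapses to zero is redrawn; after
  100 consecutive failed redraws an error is raised. For realistic
  vertebra sizes (tens of pixels) the event has probability zero in
  practice; the policy merely keeps the mean well-defined.
* The estimator's standard error shrinks as $1/\sqrt{n}$; the test suite
  verifies the variance ratio between $n = 100$ and $n = 10{,}000$
  replicates.
* Every stochastic function takes an explicit integer seed, and one master
  seed fans out deterministically to per-record, per-learner and per-stage
  seeds (`fan_out_seeds()`), so identical inputs and seed give identical
  output everywhere in the package.

The mean perturbed ratio is not mathematically identical to the
unperturbed ratio (the ratio is a nonlinear function of the coordinates),
but for realistic vertebra sizes the bias is far below the placement error
the averaging removes.

## Features and labels

`SumC3C4 = C3 + C4` and `C3C4 = C3 × C4` are exact arithmetic on the
measured ratios and are *recomputed* — never stored independently — by
every code path that generates rows, so the identities hold to the last
bit on every row, real or synthetic.

The six visual CVM stages collapse onto three clinically actionable
classes (`map_cvm_stage()`): CVS1–2 → pre-peak, CVS3–4 → peak, CVS5–6 →
post-peak. The peak class marks the mandibular growth spurt, the window
for growth modification.

Model inputs are exactly `C3`, `C4`, `SumC3C4`, `C3C4`. Age and gender
are carried in the data tables (and reproduced by the generators) but are
excluded from the classifier to avoid demographic bias; the test suite
asserts that removing them never changes a prediction. Because all four
inputs share the same dimension-ratio nature, no normalisation or feature
scaling is applied anywhere.

## Train/test split

`split_dataset()` holds out 20% by default. The split is stratified by
maturation class: with near-balanced classes a plain random split behaves
almost identically, but stratification guarantees all three classes appear
in the test partition, which the per-class metrics assume. A
`stratify = FALSE` switch restores the plain random split.

## Class-conditional augmentation

`cvd_generate()` expands the *training* partition only — augmenting test
data would leak the generative support into evaluation. Per class, 1000
new rows (default) are drawn with `C3` and `C4` confined to the class's
observed `[min, max]` range in the training rows, the engineered features
recomputed, age drawn from a truncated normal with the class mean/SD, and
gender from a Bernoulli with the class male proportion.

"Within the range, considering the distribution" leaves the sampling law
open. The default is uniform on the range (`mode = "uniform"`), which
takes the range emphasis literally; `mode = "matched"` substitutes a
truncated normal with the class mean and SD for users who read
"distribution" as the stronger claim. `C3` and `C4` are sampled
independently, as the generation rule is stated per column; this discards
their strong empirical correlation, and is one reason augmentation flattens
rather than sharpens the class boundaries on overlapping data.

## The stacking classifier

`stack_config()` / `train_stack()` implement a two-stage ensemble. The
default roster of six base learners, each with frozen tuned
hyperparameters (overridable via config):

| learner | settings |
|---|---|
| `extra_trees` | 63 trees, depth 12, no bootstrap |
| `mlp` | 1 hidden layer of 20 logistic units, decay 1e-4, 300 iterations |
| `gbt_shallow` | 100 rounds, depth 3, η 0.2, subsample 0.9, colsample 0.85 |
| `gbt_depth5` | 100 rounds, depth 5, η 0.1 |
| `gbt_deep` | 1000 rounds, depth 10, η 0.1 |
| `voting` | hard vote over tuned `svm` (RBF, C = 800), `knn` (k = 4), `random_forest` (211 trees, depth 13) |

All three gradient-boosted variants are fitted with xgboost, carrying the
three hyperparameter profiles above; the forests use ranger, the SVM
e1071, the perceptron nnet. The voting committee's composition is a design
choice: the three extra tuned models are named alongside the stack's bases
in the tuning results but absent from the base-model list, and a hard vote
over them reconciles the two lists. All nine learners can also be placed
in the stack directly by config.

Each base learner is trained on 5 stratified folds and predicts its
held-out fold, giving out-of-fold class probabilities for every training
row; the meta-model — multinomial logistic regression with default
settings (`nnet::multinom`) — is fitted on those 18 probability columns,
and the bases are refitted on the full training data for prediction time.
The hard-voting member contributes vote *fractions* as its probability
columns. Predicted probabilities are renormalised to sum to one per row.

## Metrics

`compute_metrics()` reports accuracy, per-class and aggregated precision,
recall, F1 and Jaccard (intersection-over-union), log loss, and the 3×3
confusion matrix (rows = true). Aggregation is support-weighted by
default, with macro averaging by flag. Degenerate 0/0 precision or recall
scores 0. Log loss clips probabilities to $[10^{-15}, 1 - 10^{-15}]$
before taking logarithms so a confident wrong prediction is heavily but
finitely penalised. The whole suite is cross-checked in the tests against
an independently coded brute-force tally on hundreds of random prediction
vectors at $10^{-12}$ tolerance.

## Cutoff points

For a feature $x$ and adjacent classes $k, k+1$,

$$\mathrm{cut}_k = \frac{\max(x \mid y = k) + \min(x \mid y = k+1)}{2},$$

and the combined boundary couples both engineered features:
$100 \times \mathrm{cut}(C3C4) / \mathrm{cut}(SumC3C4)$. When adjacent
class ranges overlap, the midpoint formula is still applied verbatim and
an overlap warning is attached — on overlapping data a range-boundary
midpoint is a descriptive statistic, not an optimal threshold. Cutoffs are
computed on the full non-augmented dataset by default (the feature ranges
being described are those of the observed cohort); a flag restricts them
to training data. Which slice a published cutoff table used is generally
unstated, so the full-data default is a documented convention.

## The synthetic cohort

`simulate_cohort()` emulates the statistical skeleton of a real
980-cephalogram cohort: class sizes 326/326/328; per-class Gaussian
`C3`/`C4` with means 0.52/0.74/1.01 and 0.49/0.68/0.94 (SDs 0.08–0.14),
coupled by a Gaussian copula with latent correlation ρ = 0.9 (the two
ratios co-grow; ρ is a package parameter, not an empirical estimate, since
per-class correlations are not published); Gaussian age (8.6/11.5/16.1
years); Bernoulli gender with the observed male proportions. Ratios are
truncated below at 0.05 to stay physical. `simulate_landmarks()` closes
the loop at the geometry level: it constructs rectangular vertebrae whose
true ratios are prescribed, so measurement round-trips exactly at zero
jitter.

What the generator does **not** emulate — and hence what passing tests do
not show about real data:

* Real expert-labelled cohorts are close to separable in these features
  (published stacking accuracy on such data reaches ~99%); overlapping
  Gaussian profiles are a deliberately harder regime. With adjacent class
  means ~2.8 pooled SDs apart, the Bayes-optimal error is nonzero:
  roughly $\Phi(-1.4) \approx 8\%$ per adjacent boundary on a single
  feature, so *no* classifier can approach 99% accuracy on this fixture.
  The end-to-end tests therefore check that the pipeline runs, is
  deterministic, and classifies far above chance with errors confined to
  adjacent stages — not that it reproduces accuracy figures obtainable
  only on near-separable data.
* Gaussianity itself: real ratio distributions are likely skewed and the
  age–stage relation nonlinear.
* Landmark-level noise structure: corner placement errors in real tracing
  correlate across corners; the simulator jitters corners independently.

A related caveat: `SumC3C4` and `C3C4` are almost collinear by
construction, so *permutation* feature importance splits the shared signal
between them in a fit-dependent way; ranks among the two engineered
features are stable only in aggregate, and single-seed importance
orderings should not be over-interpreted.

## Problem sizes and runtime choices

The shipped tests exercise the full pipeline at the cohort's natural size
(980 rows, 1000 augmented rows per class, the full six-learner stack) once,
and use smaller, well-separated toy tables (30–60 rows, reduced rosters)
for the many property checks, keeping the whole suite at a few minutes on
one CPU. Monte-Carlo checks run at $n = 10^5$ iterations where a
standard-error argument needs them. These sizes are the package's own
testing choices and can be scaled up freely by users.
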