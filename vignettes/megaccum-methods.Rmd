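---
title: "Tracking information accumulation in MEG decoding: methods and design"
author: "megaccum authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking information accumulation in MEG decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaccum)
```

## The scientific question

When a person recognises a pictured object, does the brain *maintain* a
representation that is formed early, or does it keep *accumulating*
information that enriches the representation over several hundred
milliseconds? `megaccum` implements a decoding-based analysis chain that
separates these possibilities in event-related MEG (or EEG) data:

1. **Zero-shot decoding.** A multivariate ridge regression maps a
   concept's averaged sensor response in an analysis window to that
   concept's feature vector (a word-embedding vector, or the reduced
   output of a visual-network layer). Models are evaluated
   leave-one-concept-out: the held-out concept is absent from training,
   so successful prediction demonstrates generalization of the feature
   space rather than memorisation. Performance is the Euclidean
   prediction–target distance (lower = better), which matches the
   squared-error loss the regression minimises.
2. **Window schemes.** *Sliding* fixed-width windows see one time slice
   each; *cumulative* windows are anchored at stimulus onset and grow
   step by step, so each model sees everything up to time *t*;
   *cross-temporal* decoding trains at one bin and tests at another,
   mapping the generalization of encoded information across time.
3. **Plateau logic.** If the cumulative distance curve keeps falling
   well after cross-temporal generalization begins, new information is
   still entering the signal during the generalization window —
   accumulation. If the curve plateaus as soon as generalization starts,
   the representation is merely maintained. The plateau is defined by a
   5% rule: the earliest window whose distance is within 5% of the
   curve's total reduction.

## The decoding model

For a window with predictor matrix $X$ (concepts × channel–bin pairs)
and feature matrix $Y$ (concepts × dimensions), each leave-one-out fold
standardizes every predictor to zero mean and unit variance **using the
training concepts only**, then solves the multi-response ridge problem
with penalty $\lambda$ on the standardized predictors. The package uses
the dual (kernel) form: with training rows $Z$ and standardized test row
$z$,

$$\hat y = \bar y + (Z z)^\top (Z Z^\top + \lambda I)^{-1} (Y - \bar y),$$

so the held-out prediction is a fixed linear combination of the training
feature vectors, with weights that depend only on the responses. Two
consequences are exploited throughout:

* *Zero-shot hygiene is structural.* The standardizer, Gram matrix and
  ridge solve never touch the held-out concept's response.
* *Label permutations are cheap.* A permutation test reassigns feature
  vectors to concepts; the fold weights are unchanged, so each
  permutation costs one small matrix product per fold instead of a
  refit. This is what makes 200–1000 permutations practical at 204
  channels × 50 bins.

Choices the underlying method leaves open, and what this package does:

* **Ridge penalty** defaults to 1.0 on standardized predictors,
  configurable. No inner tuning loop is run by default so that repeated
  runs are exactly reproducible.
* **Standardization scope**: training-fold-only (the defensible
  zero-shot choice). An intercept per feature dimension (the
  training-fold mean) is always included.
* **Constant predictors** in a training fold are mapped to 0 after
  standardization rather than dropped, keeping predictor indexing
  stable across folds.
* **Cross-temporal scaling**: the standardizer fitted at the training
  bin travels with the model and is applied to the testing bin's data —
  a trained model's input convention belongs to the model.
* **Window labels**: windows are half-open in bins; a window ending at
  bin $b$ is labelled $t_0 + b \cdot \Delta t$ ms.

## Statistics

* **Chance-level tests** shuffle the concept→feature assignment once per
  permutation and reuse the shuffle across all windows, preserving the
  temporal dependence of the null. The statistic is the negated
  concept-mean distance; p-values use the add-one convention
  $(1+b)/(1+n)$ and are therefore never 0. FDR correction
  (Benjamini–Hochberg, via `stats::p.adjust`) is applied across windows,
  or jointly across tested cross-temporal cells.
* **Sliding vs cumulative** is a paired t statistic across concepts per
  window, two-sided, FDR-corrected. The default null re-evaluates both
  window schemes under the same label shuffles as the chance-level test
  and recomputes the paired t. This matters: even on pure noise, wider
  ridge windows shrink predictions toward the training mean more
  strongly than single-bin windows, so raw sliding distances exceed
  cumulative ones systematically. The label-shuffle null carries this
  signal-independent offset under H0 and is therefore calibrated for
  the question of interest (does the cumulative scheme decode *signal*
  better); a sign-flip null on the per-concept differences, which tests
  the stricter symmetric-distribution hypothesis and needs only the two
  distance series, is available as `null = "sign-flip"`.
* **Generalization onset** is the earliest bin $t$ whose (t, t+1) *and*
  (t+1, t) cross-temporal cells are significant. The underlying
  phenomenon is directionless in its usual description; requiring both
  directions is the stricter reading, and a one-directional variant is
  available (`requireBoth = FALSE`). Because only consecutive cells
  enter this definition, `crossTemporalPvalues(cells = "consecutive")`
  tests exactly those cells (FDR across the tested cells) at a fraction
  of the cost of the full matrix; `cells = "all"` is available when the
  whole significance map is wanted.
* **Plateau rule**: with first value $d_0$, minimum $d_{\min}$ and
  reduction $R = d_0 - d_{\min}$, the plateau (or trough, for sliding
  curves) is the earliest window with value $\le d_{\min} + 0.05R$. The
  reduction is measured to the *global minimum* by default; a variant
  measuring to the final value (`reference = "final"`) is provided, as
  the two readings differ for curves that dip and rise again. The rule
  is invariant to positive affine rescaling of the curve.
* **Searchlight RSA**: model dissimilarity is pairwise cosine distance
  between feature vectors; brain dissimilarity is one minus the Pearson
  correlation between concept patterns in a patch; their agreement is a
  Spearman rank correlation over upper triangles. Cluster-level
  inference across participants uses a one-sample t map, a
  cluster-forming threshold at the $t$ quantile of $p = 0.01$
  (one-sided positive — RSA hypotheses are positive correlations;
  two-sided available), connected clusters via the *declared adjacency*
  (not the searchlight radius), sum-of-t cluster statistics, and a
  max-statistic sign-flip null (5000 permutations by default). Units
  with degenerate patches yield NA and are excluded from clustering.
* **Group model**: plateau times are modelled with
  `plateauMs ~ model (+ participant) + (1 | concept)` via lmerTest.
  Degrees of freedom and CIs use the **Satterthwaite** method, which is
  recorded in the run manifest; estimated marginal means and
  Tukey-adjusted pairwise contrasts come from emmeans.

## The synthetic-data generator

Real recordings of this kind are typically not redistributable, so the
package ships a generator whose outputs have *known* dynamics, making
every stage testable against ground truth. It works at the averaged,
binned tensor level (no raw-trace simulation, no sensor physics, no
artifacts): the response of concept $c$ at channel $s$ and bin $t$ is

$$ r_{cst} = \sum_k g_k(t)\, a_{ks}^\top f_c^{(k)} + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma^2), $$

where component $k$ projects a subset of feature dimensions through a
dense Gaussian loading $a_k$ with a temporal gain $g_k$ that ramps
linearly from its onset bin to full gain and stays on until its offset
bin. Sustained components running to the end of the epoch model
maintained information; staggered sustained onsets model accumulation;
early offsets model transient codes. The ground-truth plateau is the
last bin at which a sustained component reaches full gain, and the
named scenarios are:

| scenario | schedule | ground truth |
|---|---|---|
| `accumulation` | staggered onsets at ~10–40% of the epoch; the earliest component fades at 80% of the epoch, the others are sustained | plateau at last sustained onset + ramp |
| `maintenance` | four sustained components, one shared onset, no ramp | plateau at the shared onset |
| `transient` | staggered components switching off | flagged transient |
| `null` | zero gain | plateau undefined (NA) |

The accumulation schedule deliberately mixes durations — overlapping
processes of differing length, some maintained, some not. This is what
produces the characteristic pair of curves: the sliding curve falls to
a trough and rises again once the faded early information is no longer
in its window, while the cumulative curve, which retains the early bins,
plateaus and stays low. With every component sustained, single-bin
windows late in the epoch would see all the information the cumulative
window has, and the sliding-vs-cumulative contrast would reduce to the
shrinkage artifact described above.

Defaults mirror a whole-head gradiometer study of visual concept
identification: 60 concepts in 7 categories, 204 channels, 50 bins of
20 ms, 19 participants, 300 feature dimensions. Per-participant
variability is an integer onset jitter plus independent loading and
noise draws — enough to produce participant-level spread in plateau
times without modelling anatomy.

Two generator parameters deserve explanation:

* **`categorySpread = 2`** (within-category dispersion twice the
  between-category dispersion). Feature vectors are category means plus
  within-category noise. If the category means dominate, the encoding
  components become mutually redundant: decoding any one component
  reveals each concept's category and with it the category-mean part of
  *every* feature dimension, so later components contribute almost
  nothing to the distance curve and an "accumulation" schedule does not
  actually accumulate. Setting the within-category share to ~80% of the
  variance keeps each component informative in its own right, and is
  also the realistic regime for corpus-derived word embeddings, where
  taxonomic category explains a minority of embedding variance.
  Category structure remains clearly visible in the model DSMs.
* **`noiseSd = 0.5`** against unit component gains gives a per-channel,
  per-bin signal-to-noise ratio of about 2 at full gain — high SNR for
  averaged evoked responses, which is the regime in which plateau
  recovery to within ±2 bins is a meaningful demand. Recovery behaviour
  is not sensitive to this choice (it is essentially unchanged between
  noiseSd 0.5 and 1.0).

What the generator deliberately does **not** emulate: spatially
correlated sensor noise (noise is i.i.d. Gaussian; real averaged MEG
noise has strong spatial covariance), anatomically structured channel
loadings, oscillatory or baseline activity, and between-concept
differences in timing. Passing tests on this generator therefore show
that the *analysis chain* is correct and calibrated, not that any
particular real dataset will behave this way.

Layered feature sets (`makeFeatureSets(nLayers = 4)`) emulate a visual
processing hierarchy: the chain is anchored at the semantic matrix and
each layer mixes the previous layer with a fresh independent draw
(scale-stabilized), so consecutive layers correlate more strongly than
distant ones and all layers share signal with the semantic space.

## Exemplar-level features and cross-validated PCA

Visual-network layer outputs arrive as one vector per (concept,
exemplar). `crossvalPcaReduce()` reduces them to one vector per concept
under zero-shot discipline: components are fitted on the training
concepts' exemplar rows only (centering on the training mean; per-
dimension standardization is off by default and configurable, since
either convention is defensible), all rows are projected, and
projections are averaged within concept. The effective component count
is capped at `min(nComponents, nTrainRows - 1, nDims)` — the
largest-possible rule generalised to arbitrary design sizes. A
no-holdout mode (`testConcept = NULL`) serves representational
similarity analysis, where no concept is held out.

## Numerical and degenerate-input conventions

* Distances are exact Euclidean norms; all reported distances are ≥ 0.
* A feature row with zero norm (cosine undefined), a concept pattern
  with zero variance (Pearson undefined), and a constant DSM triangle
  (Spearman undefined) raise informative errors at the single-DSM
  level; inside the searchlight they produce NA scores instead, because
  one degenerate patch should not abort a whole map.
* A plateau on a non-decreasing curve is the first window (the
  reduction is zero); ties in the 5% rule resolve to the earliest
  window.
* p-values are never 0 (add-one convention); permutation seeds are
  explicit arguments everywhere.

## Problem sizes used by the shipped checks

The package's own test-suite and the acceptance script run the recovery
and discrimination checks at the full study dimensions (60 × 204 × 50,
five seeds) with 200 permutations, and the exact oracle equivalences,
calibration simulations (50 repeats of the 20-participant cluster null)
and mixed-model coverage (50 simulated tables) at reduced sizes chosen
so each check completes in seconds to a few minutes. These sizes are
stated here as the package's reference configuration for its own
validation; all of them are plain function arguments.

## Known limitations

* The ridge penalty is fixed, not tuned; relative comparisons between
  window schemes are robust to this, absolute distances are not.
* The i.i.d. noise model understates spatial correlation in real sensor
  arrays; cluster-test calibration on real data depends on its own
  sign-flip null, not on the generator.
* The searchlight maps units to tensor channels by index; source-space
  analyses should supply their own `SpatialUnits` layout and tensors in
  the same unit order.
* Serialization uses plain CSV + JSON sidecars; response tensors in
  long CSV form are bulky for very large datasets.
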