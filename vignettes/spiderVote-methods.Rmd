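---
title: "Methods: imbalance-aware voting ensembles for expression classification"
author: "spiderVote authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware voting ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiderVote)
```

## The problem

Expression-based disease classifiers face two coupled difficulties: the
feature space is wide (thousands of genes, few of them informative) and the
cohorts are imbalanced — patients typically outnumber controls or vice
versa, with imbalance ratios anywhere from about 2 to about 9 in public
cohorts.  A classifier trained on such data drifts toward the majority
class, and the minority class — usually the one of clinical interest — is
the one misclassified.  spiderVote packages one coherent answer: balance
the training data by *selective over-sampling*, shrink the feature space
with one of four ranking strategies, and classify with a two-arm
probability-voting ensemble whose arms are boosted committees trained on
class-balanced subsets.  Throughout the package label 1 is the positive
class and is always the minority: metrics such as recall, F-score and MCC
then mean the same thing on every dataset.

## Preprocessing

Missing values are imputed by the *within-class feature mean*
(`imputeClassMean`), with two fallbacks: a feature with no observed value
in one class takes the overall feature mean, and a feature with no
observed value at all is zero-filled with a warning.  Features are then
min–max normalized to [0, 1] (`normalizeMinmax`); constant features map to
all-zeros rather than dividing by zero, which also leaves them with a
chi-squared score of 0, the sensible value for an uninformative constant.
Imputation precedes normalization.  In the orchestrated pipelines the
normalization ranges are learned on the training split only and applied to
the test split with clipping, so no test-set statistics leak into training
(`minmaxParams`/`applyMinmax`).

## Selective over-sampling

`spiderResample` follows the SPIDER family of selective pre-processors.
All neighbor computations use the Euclidean distance
$D(x,y)=\sqrt{\sum_i (x_i-y_i)^2}$; since kNN ordering is invariant to the
square root, flags would be identical under the squared form.

1. **Noise flagging** (`knnFlag`): a sample is *safe* when the majority
   vote of its $k$ nearest other samples agrees with its own label, else
   *noisy*.  Vote ties (possible for even $k$) count as safe.  Noisy
   samples of either class are removed from the neighbor pool used for
   synthesis — but noisy majority originals are *not* deleted from the
   returned data, because discarding majority information is exactly the
   failure mode of under-sampling this design rejects (a
   `drop_noisy_majority` flag enables literal removal for ablation).
2. **Weak/strong partition** (`partitionMinority`): among safe minority
   samples, those whose $k$ nearest pool neighbors are majority-dominated
   are *weak*; the rest are *strong*.  Noisy minority samples are
   *excluded* and seed no synthesis.
3. **Synthesis**: each weak sample $s$ generates $c$ interpolated copies,
   where $c$ is the number of majority samples among its $k$ nearest pool
   neighbors; each strong sample generates one.  A copy is
   $s + u\,(\nu - s)$ with $u \sim \mathrm{Uniform}(0,1)$ and $\nu$ drawn
   uniformly from the $k$ nearest pool neighbors of $s$ (interpolation
   rather than duplication, so synthetic points fill the local
   neighborhood instead of stacking).  Generation repeats over the weak
   set until the minority count reaches the balance target (default:
   parity with the majority), with a hard cap of 10 passes so tiny seed
   sets cannot loop forever; synthesis stops mid-pass the moment the
   target is met.

Ties in neighbor distance are broken by lower sample index, and all
randomness flows through the `seed` argument, so the resampler is fully
deterministic.  The amplification counts (weak → $c$, strong → 1) follow
the SPIDER lineage; they are not derivable from first principles and are
therefore exposed as behavior to test rather than constants to tune.

**Degenerate inputs.** Single-class data and data where every minority
sample is flagged noisy are rejected with specific errors; a dataset
already at the balance target is returned unchanged.

## Feature selection

Four strategies produce a `FeatureRanking` (scores descending, ties broken
by ascending feature index; all deterministic given their seed):

* `chi2Rank` — the standard nonnegative-feature chi-squared statistic:
  observed class-conditional feature sums against expected sums
  proportional to class frequencies.  It operates on the min–max
  normalized continuous values (whether the original analysis discretized
  first is unknowable; the continuous form is the common default).
* `rfeSvcRank` — recursive feature elimination with a linear SVM (C = 1,
  no class weighting), dropping the `step` smallest-squared-weight
  features per round; a feature's score is its elimination position.
* `boostfsRank` — gain importance from a gradient-boosted tree classifier
  (100 rounds, depth 3, learning rate 0.1 — conventional defaults,
  configurable); unused features score 0.
* `selectDegs` — per-gene Welch two-sample t-tests in three contrasts
  (control-vs-patient plus two follow-up stage contrasts), BH adjustment
  within each contrast, significance at adjusted p < 0.005, direction from
  the sign of the condition-minus-reference mean difference, and the
  up/down intersections across all three contrasts.  This is a deliberate,
  documented substitution: the moderated linear model used on raw
  microarray data (and probe-level preprocessing) is out of scope here, so
  published DEG counts from that pipeline are not reproduction targets for
  this package.

`applyCutoff` restricts a dataset to the top-n features and
`sweepCutoffs` scores a grid of cut-offs (default 5, 10, …, 1000, clipped
to the feature count) by training the default ensemble per cut-off.

## The classifier

`fitEnsemble` builds a `VotingEnsemble` with two heterogeneous arms — a
random-forest family and an SVM family — each an AdaBoost-style
`BoostedCommittee`:

* sample weights start at $1/n$;
* each round draws a class-balanced subset (size `per_class_size` per
  class, probability proportional to weight, without replacement when the
  class is large enough) and fits one base learner;
* the weighted training error $\varepsilon$ of that member is computed on
  the whole population; members with $\varepsilon \ge 0.5$ are discarded
  and redrawn (3 retries, then early stop);
* the member weight is $\alpha = \tfrac12\ln((1-\varepsilon)/\varepsilon)$
  with $\varepsilon$ clipped to $[10^{-6}, 1-10^{-6}]$ so $\alpha$ stays
  finite; misclassified samples are up-weighted by $e^{\alpha}$ and the
  weights renormalized;
* a round with zero raw training error ends the committee — later members
  would have nothing to correct.

Base-learner configuration: the forest uses 100 trees with
$\min(10, p)$ randomly selected attributes per tree; the SVM uses an RBF
kernel with $C=1$ and $\gamma = 1/(p\,\mathrm{var}(X))$.  SVM class
probabilities come from a Platt-style sigmoid fitted by logistic
regression on a stratified 20% holdout of the boosting subset; when the
holdout is degenerate (a single class, or a non-finite/negative-slope
fit), a unit-scale sigmoid of the decision value is used instead.
Committee probabilities are the $\alpha$-weighted average of member
probabilities ($\alpha$ normalized to sum to 1; uniform if all
$\alpha = 0$), and the ensemble averages its arms' probability pairs
unweighted.  An exact (0.5, 0.5) tie goes to the minority class by
default.  An optional third arm of gradient-boosted trees
(`with_gbt_arm`) is available for configurations whose boosting engine is
itself a gradient-boosted model; the two-arm form is the default.

Hyperparameter search is a small deterministic grid (`tune = TRUE`
selects `svm_C` from {0.1, 1, 10} by internal 3-fold CV accuracy) —
deterministic and desk-scale, in place of Bayesian optimization.

`per_class_size` defaults to the minority count of the (resampled)
boosting population and `rounds` to 10.  Note a consequence: when the
population has been balanced to parity, the default subset per class is
the whole class, the weighted draw degenerates to the identity, and the
committee behaves like seed-diversified bagging rather than weighted
boosting.  Smaller `per_class_size` values restore weight-driven
subsetting.

## Evaluation

`evaluateModel` reports the full suite: accuracy $(TP+TN)/n$; MCC
$(TP\cdot TN - FP\cdot FN)/\sqrt{(TP{+}FN)(TN{+}FP)(TP{+}FP)(TN{+}FN)}$
with the conventional value 0 when a denominator factor vanishes; RMSE
$\sqrt{\tfrac1n\sum (x_i-y_i)^2}$, computed on hard 0/1 predictions by
default (so it equals $\sqrt{1-\mathrm{accuracy}}$; `rmse_on = "proba"`
switches to probability residuals); F1, with value 0 when TP = 0; and a
ROC curve thresholded at every distinct score (ties share a threshold)
whose trapezoidal area equals the Mann–Whitney pair-counting statistic.
The ROC score is always the positive-class (minority) probability.

## The synthetic generator

`makeImbalanced` draws Gaussian features (SD `noise_sd`) and shifts the
first `n_informative` features by `effect` SD units in the minority class;
missingness is completely at random, matching the unconditional imputation
model.  `makeStageData` builds three two-group contrasts with planted
all-three-contrast up/down genes and optional single-contrast extras, the
truth sets disjoint by construction.  `makeKeelFixture` writes KEEL-format
files that read back losslessly.

The generator emulates the statistical skeleton the method's claims rest
on — a small mean-shifted informative subset, Gaussian within-class noise,
controlled imbalance — and deliberately nothing else: no probe-level
artifacts, batch effects, correlated gene modules or heavy tails.
Passing tests therefore demonstrate correct algorithmic behavior and
parameter recovery under the stated model, not performance on real
microarray cohorts.

## Validation problem sizes

The test suite exercises, among others: the metric boundary values
(error-free MCC 1, inverted MCC −1, random-scorer mean AUC 0.5 over 200
repetitions of a 500-sample balanced set); equivalence of the ROC area
with exhaustive pair counting on instances up to 200 samples and of the
kNN flags with a brute-force vote on 1,000 random 20-point layouts; an
exactly hand-traced 8-point resampling fixture; resampling invariants on
500 random generator datasets; recovery of 10 planted features among
1,000 (effect 3.0, 20 seeds) by the chi-squared and boosted rankers and of
30 planted all-three-contrast genes (effect 4.0, 30/group); and ordering
experiments at IR 9 (540/60, effect 1.5, 40 features of which 10
informative, 20 seeds) and IR 5 (415/83, effect 1.0).  These sizes are the
package's chosen validation conditions; they keep every experiment
analyzable and quick while leaving the claims nontrivial.

## Known limitations

* Probability voting averages its arms, so when one base family is alone
  near the Bayes optimum (as the RBF-SVM is on strongly separated
  synthetic classes) the ensemble tracks, and can slightly trail, its best
  arm; its advantage appears when the arms err differently, which is the
  regime the method was designed for.  The ordering experiment in the
  test suite documents both sides of this.
* The DEG selector is a two-sample Welch/BH procedure on expression
  values; it does not model probe effects, repeated measures or
  moderated variances.
* Binary classification only; multi-class imbalance is out of scope.
* The resampler assumes a meaningful Euclidean geometry; features should
  be normalized first.
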