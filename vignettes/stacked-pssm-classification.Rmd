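---
title: "Stacked ensemble classification of proteins from PSSM evolutionary features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble classification of proteins from PSSM evolutionary features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmstack)
```

## The problem

Functional protein classes such as vesicle transport proteins cannot be
recognized reliably from raw sequence composition alone; the evolutionary
substitution profile of a protein is far more informative. PSI-BLAST
summarizes that profile as a position-specific scoring matrix (PSSM): for a
protein of length $L$, an $L \times 20$ matrix of integer log-odds scores
$p_{i,j}$ describing how acceptable a substitution to amino acid $j$ is at
position $i$. `pssmstack` turns a directory of ASCII PSSM files into fixed
530-dimensional feature vectors, selects informative features, balances the
training classes, and classifies with a two-layer stacked ensemble.

## Feature model

All features are computed from the sigmoid-mapped matrix
$p \mapsto 1/(1 + e^{-p})$, which squashes the unbounded log-odds into
$(0, 1)$ so that variance- and product-based summaries are commensurate
across proteins.

**RPSSM (110 values).** The 20 columns are first merged to 10 by a reduced
amino-acid alphabet — by default
$\{FYW\}, \{ML\}, \{IV\}, \{ATS\}, \{NH\}, \{QED\}, \{RK\}, \{C\}, \{G\},
\{P\}$, member columns averaged row-wise. The grouping follows the standard
physicochemical 10-letter reduction used with reduced-profile features;
because other groupings exist in the literature the scheme is a first-class
argument (`reduction_scheme()`), not a constant. From the reduced matrix we
take

$$D_s = \frac{1}{L}\sum_{i=1}^{L} (p_{i,s} - \bar p_s)^2 , \qquad
  D_{s,t} = \frac{1}{L-1}\sum_{i=1}^{L-1} \frac{(p_{i,s}-p_{i+1,t})^2}{2},$$

i.e. 10 per-group variances (composition) and 100 adjacent-row dipeptide
terms (local order). $\bar p_s$ is the column *mean*: a plain column sum in
its place would make $D_s$ grow quadratically with $L$ and swamp every other
feature, so the mean-centred form is fixed rather than exposed as an option.
$D_{s,t}$ is computed as direct squared differences; the algebraically
equivalent cross-product expansion cancels catastrophically when adjacent
reduced values nearly coincide and cannot meet the package's own $10^{-12}$
relative-accuracy tests.

**AADP-PSSM (420 values).** The amino-acid composition part is the full
column mean $x_j = \frac{1}{L}\sum_i p_{i,j}$ (20 values); the dipeptide
part is the adjacent-row cross product
$y_{i,j} = \frac{1}{L-1}\sum_k p_{k,i}\, p_{k+1,j}$ over all ordered column
pairs (400 values). The cross-column form is the only one that yields
$20 \times 20$ distinct dipeptide terms; a same-column product would
collapse them to 20.

The combined vector is RPSSM first, then AAC, then DPC — 530 named features.
The order is fixed purely for stable serialization; ranking and classifiers
are order-agnostic.

## MRMD feature selection

`mrmd_rank()` scores each feature as

$$\text{score}_f = \underbrace{|r(x_f, y)|}_{\text{relevance}}
 + w \cdot \underbrace{\overline{d}(z_f, z_{g \ne f})}_{\text{distance}},$$

the absolute Pearson correlation with the class label plus the mean pairwise
distance between z-scored feature columns (high distance = low redundancy).
With z-scored columns all three supported metrics reduce to functions of the
feature-feature correlation $r$: Euclidean $\sqrt{2(1-r)}$ (normalized by
$\sqrt{n-1}$ so it lives on $[0,2]$ regardless of sample count), cosine
$1-r$, and tanimoto $1 - r/(2-r)$. The normalization is deliberate: a raw
Euclidean distance grows with $\sqrt{n}$ and would dominate the $[0,1]$
relevance term, making the default weight $w = 1$ meaningless. Constant
columns get relevance and distance 0 — never `NaN`.

Because no principled subset size is universal, `select_top_k()` takes an
explicit $k$ and `select_auto()` chooses the smallest $k$ on a grid whose
cross-validated accuracy is within one standard error of the best
(the usual parsimony rule).

## Class balancing

Real data of this kind is heavily imbalanced (the motivating benchmark has
2533 positives against 9086 negatives). `random_undersample()` keeps every
minority sample and draws `round(ratio * n_minority)` majority samples
without replacement (default ratio 1, i.e. balanced — the standard choice
when the minority class is the class of interest). Undersampling is meant
for the training portion only; `stratified_split()` produces a test set that
keeps its natural imbalance so reported specificity is not flattered.

## The stacked classifier

`fit_stack()` is the core estimator. Layer one fits three complementary base
learners — gradient boosting (xgboost; learning rate 0.05, 400 rounds,
maximum depth 7, row subsample 0.8), an RBF SVM (e1071; $\gamma = 0.018$,
$C = 19$, probability outputs) and extremely randomized trees (ranger,
`splitrule = "extratrees"`; 100 trees, minimum leaf size 1). The training
table is split into $k = 10$ stratified folds; each base model is trained on
9 folds and predicts the held-out fold, giving an $n \times 3$ matrix of
*out-of-fold* (OOF) positive-class probabilities. Entry $(i, m)$ never
depends on sample $i$'s own label — the property that makes the second layer
honest, and the one the test suite checks exhaustively by label
perturbation. Layer two fits a logistic regression on the OOF matrix
(maximum 100 IRLS iterations; the optimizer choice is immaterial for a
3-predictor GLM, which has a unique maximum-likelihood solution). For
inference each base family is refit on the full training table — the
standard stacking choice, preferable to averaging fold models because it
uses all data — and base probabilities are passed through the meta-model.

Choices worth knowing:

* OOF features are probabilities, not hard labels: they carry calibration
  information the meta-model can exploit, and soft voting needs them anyway.
* Folds are stratified by default so undersampled tables cannot produce a
  single-class fold; `stratify = FALSE` gives plain folds.
* The decision threshold is 0.5 and is a parameter, not a constant baked
  into metrics.
* SVM probabilities come from libsvm's internal sigmoid calibration, whose
  RNG is pinned to the fit seed; all learners run single-threaded with
  explicit seeds, so refitting with identical inputs is bit-reproducible.
* `voting_predict()` provides the hard/soft majority-vote baselines over the
  same three bases, for the comparison stacking must win to be worth its
  cost.

## Evaluation

`classification_metrics()` implements SN, SP, ACC (in percent) and MCC
directly from the confusion counts; a zero factor in the MCC denominator
yields 0 by convention. Two AUC variants are reported side by side because
they are distinct quantities that are easy to conflate: `auc_eq10()` is the
single-threshold balanced accuracy $(SN + SP)/2$, while `roc_auc()` is the
trapezoidal area under the threshold-swept ROC curve (equal to the
Mann–Whitney rank statistic; tied scores are grouped). `cross_validate()`
reports per-fold metrics with means and sample ($n-1$) standard deviations.
`mcnemar()` compares two classifiers on the same samples via the discordant
counts, using the exact binomial test when $b + c < 25$ and the
continuity-corrected $\chi^2$ otherwise.

## The synthetic generator, and what it does not show

The package's tests and acceptance checks run entirely on synthetic data
from `gen_dataset()`: integer log-odds drawn as rounded
$\mathcal N(0, \sigma^2)$ noise ($\sigma = 2$ by default, matching the
typical spread of real log-odds scores), with the positive class shifted by
`effect_size` in a designated column subset *before* sigmoid scaling, so the
class signal propagates through both feature families the same way real
evolutionary signal would. At `effect_size = 0` the classes are identically
distributed and any classifier must sit at chance — the negative control.

This emulates the *pipeline's* statistical situation, not protein biology:
real PSSM columns are correlated, position-dependent and length-biased in
ways independent Gaussians are not. Passing tests therefore demonstrate that
the machinery is correct (formulas, leakage-freedom, determinism, metric
algebra) and that the pipeline recovers a known planted signal; they say
nothing about accuracy on real proteins, which depends on data that must
come from PSI-BLAST runs.

Problem sizes used by the checks are chosen to keep Monte-Carlo noise well
inside the asserted bands: the end-to-end recovery check uses 300 training /
200 test profiles at effect size 2, and the chance control uses 400 test
profiles, where a chance AUC has standard error $\approx 0.029$ and the
asserted band $[0.45, 0.55]$ is roughly $\pm 2$ standard errors.

## Degenerate inputs and numerical corners

* Profiles must have $L \ge 2$ (dipeptide terms are undefined otherwise);
  rows with ambiguity codes (`X`, `B`, `Z`) are kept, since PSI-BLAST still
  defines their score rows and dropping them would silently change $L$.
* Both the 20-column and 40-column ASCII dialects are parsed; the first 20
  numeric columns are always the log-odds block. Malformed rows are reported
  with their line number.
* Identical feature columns give exactly zero distance; negated standardized
  columns give the metric's maximum — both are regression-tested.
* Ranking ties break by original column index, so results are stable across
  runs and platforms.

## Limitations

* No PSI-BLAST wrapper: the package consumes its ASCII output. Profile
  generation against a sequence database is out of scope.
* The three base families are fixed by design; `grid_search()` tunes within
  a family but swapping in other learners means writing a new config.
* Binary classification only; the meta-layer sees the three OOF columns
  only (no pass-through of original features).
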