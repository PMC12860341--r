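---
title: "Multistage stacked classification for referral triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage stacked classification for referral triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstriage)
```

## The problem

Pain-medicine departments receive referrals from many specialties and must
decide, ideally at referral time, which advanced procedure — peripheral
nerve stimulation (PNS), spinal cord stimulation (SCS), intrathecal pump
(ITP), basivertebral radiofrequency ablation (BVRF) or minimally invasive
lumbar decompression (MILD) — a patient is likely to need. Two features of
this problem shape everything in this package:

* **Heavy class imbalance.** In a cohort of a few thousand referrals, each
  procedure has between a handful and ~130 positive cases (prevalences
  0.3%–3.5%). Plain classifiers collapse to the majority class; every
  learner here is imbalance-aware by design.
* **The cost asymmetry favours recall.** A missed candidate (false
  negative) costs a patient a delayed or inappropriate care path; a false
  positive costs a clinician review. The method therefore optimises and
  tracks the true positive rate (TPR) first, with AUC and TNR as guard
  rails.

## The model

For each procedure separately, a binary base learner is cross-validated on
the feature matrix $x_j$, $j = 1..n$ (structured history features plus
binary NLP concept flags). Writing $y_i$ for the vector of out-of-fold
predicted probabilities at stage $i$:

* **Stage 1** fits the base learner on $x_1..x_n$ alone.
* **Stage $i > 1$** appends the earlier stages' out-of-fold probability
  vectors as extra columns (`stage_prob_1`, ..., `stage_prob_{i-1}`) and
  refits the same learner on the augmented matrix.

With $p_i$ the pooled out-of-fold TPR at stage $i$, the slope change

$$s_i = \lvert (p_i - p_{i-1}) - (p_{i+1} - p_i) \rvert, \qquad
  i = 2, \dots, M-1$$

measures how sharply the improvement trajectory bends at stage $i$. All
`M_max` stages are trained first; the selected stage $i^\*$ is the argmax
of $s$ (ties to the smallest stage). This is the familiar elbow rule used
for choosing cluster counts or retained principal components, applied to a
performance trajectory: the stage after which further stages change little
(or degrade into overfitting) is where the chain is cut.

Deployment-side, the per-procedure final probabilities feed an
argmax-with-margin triage rule: the top procedure is auto-scheduled only
when its lead over the runner-up strictly exceeds a review margin
(default 0.10); otherwise — including exact ties — the case goes to manual
review.

## Design choices in the open

Several aspects of the procedure admit more than one reasonable reading;
the package commits to the following and treats them as part of its
contract.

**One fold assignment, shared across stages and models.** The fold split
is drawn once (stratified, positives balanced to within one per fold) and
reused by every stage of a chain and every model of a baseline grid.
Re-randomising folds between stages would let stage $i{+}1$'s augmented
column carry information about its own training rows' labels through fold
overlap; sharing the split keeps every patient's meta-feature strictly
out-of-fold at every depth. It also makes the TPR trajectory comparable
stage to stage, which the elbow statistic implicitly assumes.

**What the leakage guarantee does and does not say.** Under a shared fold
split, the enforceable guarantee is *first-order*: no fold model ever
trains on its held-out fold's rows, and no patient's meta-feature was
produced by a model that saw that patient's label. A *second-order* path
is inherent to stacked generalisation itself: patient $p$'s label
influences other folds' stage-1 out-of-fold probabilities, which are
training features for the stage-2 model that scores $p$. Eliminating it
would require nested leave-two-folds-out meta-features (a $k(k{-}1)$-fold
blow-up in fits) and is not what stacking practice does; the test suite
verifies the first-order guarantee with sentinel-feature constructions
that a leaky implementation could not pass.

**Pooled rather than fold-averaged confusion metrics.** With 10–126
positives, single folds hold 1–13 positive patients; per-fold TPR is
quantised in steps of 1/13 or coarser. All thresholded metrics are
therefore computed once, on the pooled out-of-fold predictions. Per-fold
values are kept only for the AUC, whose fold-wise mean ± SD and Student-t
interval ($\mathrm{mean} \pm t_{0.975,\,k-1}\,\mathrm{SD}/\sqrt{k}$) are
the reported uncertainty convention.

**Threshold tie rule.** A probability exactly equal to the cut-off is
called negative. The choice is arbitrary but must be fixed: ensemble vote
shares land on a small grid of rational values, and 0.5 exactly is common.

**Retrospective stage selection.** All `M_max` (default 4) stages are
trained before $s$ is evaluated, rather than stopping at the first local
peak: $s_i$ needs $p_{i+1}$, so an online rule would always train one
stage beyond its decision anyway, and the full trajectory makes the
selection reproducible from the exported trace alone. With $s$ defined on
interior stages, $i^\*$ lies in $2..M_{\max}-1$; under the default
$M_{\max} = 4$ the selectable stages are 2 and 3.

**Inference chains refit on the full data.** Training-time augmentation
uses out-of-fold vectors (anything else leaks); at prediction time there
is no fold structure, so each stage's model is refit once on all training
rows and chained: stage 1 scores the new patient, its output is appended,
stage 2 rescores, and so on to $i^\*$.

**Cumulative augmentation by default.** Stage $i$ receives all of
$y_1..y_{i-1}$ (schema: $n + i - 1$ columns), not only $y_{i-1}$; the
alternative is available as `mode = "last_only"`.

## The base-learner registry

Ten imbalance-aware classifiers sit behind one fit/predict-probability
contract: four undersampling ensembles (Easy Ensemble, Balanced Bagging,
RUSBoost, Balanced Random Forest), four balanced-weight models (weighted
random forest, logistic regression, and its L1/L2-regularised variants),
a class-weighted RBF SVC, and a one-class SVM fit on the positive class
only (its decision scores min–max rescaled to [0, 1] per prediction
batch, so they can be thresholded like probabilities).

The boosting-based ensembles (Easy Ensemble, RUSBoost) are built on
discrete AdaBoost over shallow weighted decision trees written for this
package, with a fully vectorised split search. Weak learners default to
depth 2 rather than classical stumps: depth-1 boosting is purely additive
in the features and cannot represent pairwise interactions — neither the
interaction structure expected in referral data nor the
meta-feature-times-raw-feature corrections that later stages exist to
learn. Ensemble sizes follow common library conventions (10 balanced
subsets; 50 boosting rounds). Hyperparameters the underlying papers do
not pin down are exposed in `learner_spec()` and logged in every run
manifest.

AdaBoost member probabilities are normalised margins,
$p = (1 + \sum_t \alpha_t (2h_t - 1) / \sum_t \alpha_t)/2$, averaged
across ensemble members: monotone in the committee vote, 0.5 at a tie,
and adequate for thresholding and ranking. They are not calibrated
probabilities — which is exactly why the calibration table
(`calibration_bins()`) is part of the standard evaluation output.

## The synthetic cohort

No patient-level data ships with the package; `simulate_cohort()`
generates cohorts with the study's shape so that the full pipeline is
exercisable and testable:

* 3,552 patients; 192 structured features (half binary comorbidity-style
  flags at 5–50% prevalence, half Poisson counts at rates 0.2–3,
  mimicking visit and medication histories) plus 39 strictly binary NLP
  concept flags at 2–30% prevalence.
* Independent outcomes per procedure with **exact** positive counts
  (46/126/36/16/10), assigned by ranking a latent score and labelling the
  top-$k$ — exact counts make downstream bookkeeping deterministic, which
  Bernoulli draws would not.
* Latent score per outcome: a sparse linear term (5% of features,
  standardised, scaled to SD 1.5), five pairwise interaction products of
  signal features (jointly scaled to SD 1.0), and Gaussian noise. The
  default noise SD is 2.5, picked from candidates {2, 2.5, 3} as the one
  whose stage-1 Easy Ensemble operating point on the default cohort sits
  closest to where such cohorts realistically operate (SCS-scale
  outcomes: TPR near 0.7, AUC near 0.8, TPR weighted double as the focal
  metric) rather than in a regime so learnable that one stage saturates
  and later stages have nothing to add.

What the generator deliberately does **not** emulate: correlated feature
blocks, missingness and its informativeness, temporal drift in referral
behaviour, and the text side of the NLP pipeline (only its binary
outputs). Passing tests on synthetic cohorts therefore demonstrate the
machinery — exact accounting, leak-free stacking, elbow selection — not
clinical-grade performance on real referrals.

## Numerical and degenerate-input conventions

* Training splits with zero positives are skipped with a warning and
  recorded in the provenance log; their patients carry `NA` out-of-fold
  probabilities and are excluded from pooled metrics.
* A cohort with no positives at all flags metrics as degenerate rather
  than silently reporting zeros; F1 is defined as 0 when precision and
  recall are both 0.
* Stump split search breaks ties deterministically (first feature, then
  smallest cut in sorted order); all stochastic components derive their
  seeds from the user seed, so a fixed seed reproduces every table to the
  last bit.
* Calibration bins are fixed-width half-open intervals (last bin closed),
  10 by default: under 1–3% prevalence, quantile bins would place nearly
  all cut points below 0.2 and hide exactly the sparsely-occupied upper
  bins the calibration story is about. Empty bins are flagged, not
  dropped.

## Problem sizes used in the shipped checks

The test suite exercises cohorts of 60–400 patients with 8–20 features
(fold counts 3–5, trimmed ensemble sizes), where every oracle —
brute-force confusion counts, pairwise AUC, per-patient accounting
enumeration — is computable in milliseconds. The acceptance script runs
the full-size default cohort (3,552 × 231, 10 folds, 4 stages) for one
procedure (SCS, the best-populated outcome) and reconstructs the
remaining procedures' stage accounting from their printed narratives;
fitting all five full-size chains adds no information the SCS chain does
not already provide about the machinery.

## Known limitations

* **Under leak-free stacking, later stages do not reliably improve TPR on
  synthetic cohorts.** With one shared fold split and strictly
  out-of-fold augmentation, the stage-1 probability is a deterministic
  function of features the stage-2 learner already sees; for a base
  learner that is itself an aggregating ensemble it adds no information,
  and measured stage-2 TPR on the default cohort is flat to slightly
  lower (±0.05) rather than monotonically rising. Sustained stage-on-stage
  growth of the kind that motivates the method appears to require either
  re-randomised folds at each stage — which this package deliberately
  refuses, because it leaks label information into the augmented columns —
  or data structure the generator does not emulate. The elbow rule is
  well-defined either way; on a flat trajectory it selects an early stage,
  which is exactly the parsimony it exists to enforce (an all-equal
  trajectory selects stage 2 by the tie rule).
* AdaBoost margin probabilities cluster away from 0 and 1; calibration
  plots should be read before any probability is quoted to a clinician.
* The one-class SVM's rescaled scores depend on the prediction batch's
  score range; it is retained for registry completeness and comparison,
  not recommended for deployment.
* Multi-positive patients are resolved only at triage time (argmax with
  margin); the per-procedure models know nothing of each other.
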