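---
title: "Predicting post-translational modification sites with physicochemical encodings and neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-translational modification sites with physicochemical encodings and neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Post-translational modifications (PTMs) — phosphorylation, acetylation,
hydroxylation and dozens of others — are written onto specific residues
of a protein after translation, and the writing enzymes recognize short
sequence contexts around the modified residue. `ptmscan` predicts
candidate PTM sites from sequence alone: a query protein is dissected
into all overlapping 9-residue windows, each window is encoded as a
numeric feature vector, and a per-PTM-type classifier scores whether
the central residue is a plausible modification site.

The encoding describes every residue by ten physicochemical property
scales from the AAindex database (side-chain interaction parameters,
side-chain volume, accessibility information values, hydration number,
transfer free energy, hydrophobicity, fraction of site occupied by
water). A 9-mer therefore becomes a point in a 90-dimensional space.
The classifier is a multilayer perceptron (MLP) of sigmoid units with
90 input neurons (pass-through), one hidden layer, and two output
neurons, one per class. Training minimizes the sum of squared output
errors by per-sample back-propagation with a momentum term:

$$\Delta w(t) = -\eta\,\frac{\partial E}{\partial w} + \delta\,\Delta w(t-1),
\qquad E = \tfrac12\sum_j (R_j - t_j)^2,$$

with learning rate $\eta = 0.8$ and momentum (acceleration factor)
$\delta = 0.8$ by default. A prediction is reported both as a binary
decision (the class with the larger output response; ties go to
negative, the conservative call for a screening tool) and as a
confidence $C_j = R_j / \sum_k R_k$, the normalized response of the
winning output neuron.

## The training protocol

PTM datasets are extremely unbalanced — a proteome offers vastly more
unmodified serines than phosphoserines — so the harness controls class
ratios explicitly. `split_dataset()` partitions the positives 4:1 into
train and test (test count floored, remainder to training) and samples
negatives without replacement at 5 per positive in each partition.
Three independent random splits are drawn by default and test metrics
are averaged across them; random sub-sampling keeps the train/test
proportion independent of the number of repetitions, which k-fold
cross-validation does not.

For each split the hidden-layer width is swept over 2, 4, ..., 20.
Within every training run the held-out test split is evaluated after
each epoch and the weights achieving the best value of the selection
criterion so far are retained (checkpoint selection — the overfitting
control: the saved network is the one that generalized best, not the
one that fit the training set longest). Per-epoch granularity was
chosen over per-update checkpointing as the latter multiplies cost
without changing which basin is found. Ties across hidden sizes go to
the smaller network.

Three criteria are used in parallel — AUC, recall and precision —
yielding three networks per PTM type. A recall-optimized network serves
screening applications that must not miss sites; a precision-optimized
network serves validation applications that must not cry wolf; the
AUC-optimized network balances both. Because the training trajectory
does not depend on the criterion (it only decides which checkpoint is
kept), the recall-optimized network's test recall is by construction an
upper bound on the other two networks' recall, and likewise for
precision. `consensus_predict()` combines the triplet either by
reporting all three verdicts (the default — the user picks the
optimization that matches their question), by majority vote, or by
averaging positive-class confidences with a 0.5 threshold; no single
consensus rule is canonical, so all three are exposed.

Leave-one-out cross-validation (`loocv()`) is provided for small
datasets; folds whose training part degenerates to one class are
skipped and counted.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `learning_rate` ($\eta$) | 0.8 | gradient step size |
| `momentum` ($\delta$) | 0.8 | fraction of the previous update re-applied |
| `epochs` | 500 | passes over the training set per run |
| `init_range` | 0.5 | weights start uniform in $[-0.5, 0.5]$ |
| `train_pos_fraction` | 4/5 | positive train:test ratio (4:1) |
| `neg_per_pos` | 5 | negatives per positive (1:5) in each partition |
| `n_splits` | 3 | independent random splits |
| `h_values` | 2..20 by 2 | hidden-layer widths swept |

## Numerical and design choices

Several details are genuinely open in this family of predictors; the
package fixes them as follows and records them in model metadata so a
saved model is self-describing.

* **Feature normalization.** Raw AAindex scales differ in units by
  orders of magnitude (molecular weight vs. free energies), and sigmoid
  networks train poorly on wildly different input ranges. Each scale is
  min-max normalized over its 20 residue values onto $[0,1]$ by
  default; z-scoring and raw pass-through are selectable. The
  normalization mode and scale list are persisted with every model.
* **Vector layout.** Position-major: positions 1..9 each contribute one
  block of 10 scale values, in a fixed documented scale order.
* **Update mode.** Per-sample (stochastic) updates with momentum,
  order reshuffled every epoch under the training seed — the classical
  back-propagation regime matching the momentum vocabulary; batch
  gradient descent is not offered.
* **Targets and initialization.** One-hot targets (1,0)/(0,1) over the
  two output neurons; weights initialized uniformly in
  $[-0.5, 0.5]$ from a seed, so every run is reproducible.
* **Undefined rates.** Precision (and other ratios) with a zero
  denominator are reported as `NA`, never coerced to 0 or 1; an
  epoch at which a network predicts no positives simply cannot win a
  precision checkpoint. Silent zeros would corrupt model selection.
* **ROC convention.** Thresholds sweep the distinct score values
  (score $\ge$ threshold calls positive) plus the two sentinel corners;
  AUC is computed as the Mann–Whitney rank probability with ties
  counted $\tfrac12$, which equals the trapezoidal area under that
  curve exactly — the test suite verifies the identity on random
  instances.
* **Non-standard residues.** X/B/Z/U are rejected by default; the
  `impute_mean` policy substitutes each scale's mean normalized value,
  intended for proteome scans and for windows padded with `X` at
  protein termini (`edge_policy = "pad_X"`). The default edge policy
  skips near-terminal sites, since training segments are full 9-mers.
* **Candidate table quirk.** The published candidate table lists the
  scale BLAS910101 twice, once accepted and once rejected; the bundled
  manifest mirrors all 15 rows as printed, but the scale ships once and
  loaders return unique accessions.

## What the synthetic data emulates — and what it does not

`motif_spec()` and `generate_dataset()` emulate a kinase-like
recognition motif: a position weight matrix (by default the indicator
of a consensus 9-mer such as the PKA-like `KRRASFAAA`) mixed with a
background distribution at a `consensus_strength` between 0 and 1.
Positives are drawn from the mixture; negatives from the background.
Both classes share the central-residue constraint (e.g. serine at
position 5), so a classifier cannot succeed by reading the center
letter — it must learn flanking context, as a real kinase-specificity
model must. Negatives exactly duplicating a positive segment are
resampled, mirroring the curation rule that background windows must not
contain known modified sites. At strength 1 the positives are exactly
the consensus; at strength 0 the two classes are identically
distributed — a signal-free null.

This generator supports controlled recovery experiments, not realism:
real phosphosite data have position-dependent amino-acid biases,
correlated positions, homologous near-duplicate segments, and
annotation noise, none of which are simulated. Passing recovery tests
demonstrates that the estimator and harness work; it does not certify
performance on curated proteome data.

## Selection bias in checkpointed test metrics

One subtlety is worth stating explicitly because the package's own
validation had to respect it. The checkpoint criterion is *maximized
over* epochs and hidden sizes *on the test split*, so the selected
model's criterion value on that same split is an optimistically biased
statistic — even on pure noise, the maximum of a few thousand
chance-level AUC evaluations sits visibly above 0.5. The package's
null-data check therefore trains and checkpoints as usual but measures
AUC on an independent holdout drawn from the same null distribution,
where a sound implementation must sit at chance. Users comparing
models should likewise treat checkpoint-split metrics as selection
criteria, not as unbiased performance estimates; the three-split
averaging mitigates but does not remove this bias.

## Problem sizes used in validation

The shipped tests and the acceptance script exercise the full protocol
at sizes chosen to make the statistical claims sharp while keeping a
laptop-scale run: recovery experiments use 200 positives with 1:5
negatives (960 training / 240 test windows), the default ten-point
hidden sweep, and 150 epochs per run; the null experiment repeats this
over 10 seeds; oracle-equivalence properties use 1000 random instances;
gradient checks use random networks up to 10-8-2. PWM convergence is
checked at 5000 draws against 3-sigma binomial bounds.

## Known limitations

* One hidden layer by default (configurable); no alternative
  activations, regularization, or early stopping beyond checkpoint
  selection — matching the original design rather than modern practice.
* Only the 14 unique published candidate scales ship; the package does
  not parse the full AAindex distribution.
* `select_feature_subset()` re-runs subset selection on user data with
  greedy-forward or bounded-exhaustive search; it makes no attempt to
  retrace the original heuristic trial-and-error path, and on small
  datasets its held-out AUC estimates are noisy.
* The distributed archive of networks trained on Swiss-Prot /
  Phospho.ELM extractions is not reproduced here; users train their own
  models from labeled segment files.
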