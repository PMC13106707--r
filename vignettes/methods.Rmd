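---
title: "Methods: sequence-model BMI classification and adaptive prescription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-model BMI classification and adaptive prescription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitrx)
```

## What the package models

`fitrx` classifies WHO BMI categories (underweight / normal / overweight /
obese, half-open intervals with inclusive lower bounds at 18.5, 25 and
30 kg/m²) from four standard fitness tests, and converts the classifier's
explanations into weekly exercise prescriptions that adapt to progress and
fatigue. The input is deliberately low-dimensional but temporal: the
3,000 m run is observed as fifteen 200 m splits, and pacing decay over the
final laps — the fatigue signature — carries class information beyond the
total time. The other three tests (pull-ups, 60 s sit-ups, 30×2 shuttle)
are scalars, replicated across the 15 time steps so a single convolutional
stack sees one N×15×4 tensor per batch. Replication is applied after all
row-wise preprocessing, so the constant-channel invariant is exact by
construction and tested bitwise.

## Architecture and training

The extractor is three strided 1D convolutions (64/128/256 filters, kernel
5, stride 2, ReLU) with "same"-with-stride zero padding chosen to realize
the ceiling chain 15 → 8 → 4 → 2 — the padding scheme is forced by that
chain. Eight attention heads of width d/h = 32 then run scaled dot-product
attention over the remaining two positions, with dropout 0.3 applied to the
attention probabilities (the returned attention maps are the pre-dropout,
row-stochastic ones). Head outputs are concatenated, projected, added back
residually and layer-normalized; global average pooling yields the
256-dimensional embedding.

Two training-time choices deserve comment because the protocol leaves them
open:

* **Per-metric losses.** The total loss weights four component losses
  0.4/0.2/0.2/0.2 (3,000 m first) plus an attention regularizer at
  λ = 0.1. We define component *m* as the cross-entropy of an auxiliary
  4-class head evaluated on a forward pass in which every input channel
  except metric *m*'s is zero-masked. This keeps a single shared head,
  costs four cheap passes at T = 15, and makes each weight interpretable as
  the share of gradient signal granted to one metric. A single unmasked
  cross-entropy is available via `loss_mode = "standard"`; an alternative
  reading (per-metric reconstruction error) was considered and rejected
  because the downstream task is classification. The auxiliary head is
  discarded after training; only the embedding feeds the boosted
  classifier.
* **Attention sparsity.** The regularizer is the mean Shannon entropy of
  the attention rows (in nats): it is zero exactly on one-hot rows and
  ln T′ on uniform rows, so minimizing it concentrates attention. An L1
  norm cannot play this role — attention rows are already normalized to
  sum to 1, making their L1 norm constant.

The L2 penalty (λ = 1e-4) is implemented as a loss term over **all**
trainable parameters, including layer-norm gains and biases, matching the
stated protocol rather than the decoupled-decay convention. Hidden Gaussian
noise (σ = 0.05) is injected into the post-attention features immediately
before pooling during training; the protocol's phrasing ("concatenated
outputs … prior to pooling") is ambiguous because the CNN and attention
paths are joined by residual addition, not concatenation — the
pre-pooling site is the nearest faithful reading. Early stopping monitors
the validation data-plus-entropy loss (the L2 term is excluded so the
monitored quantity is comparable across epochs); training returns the
best-epoch weights. Gradients are computed by a hand-written
backpropagation through the full graph, verified in the test suite against
central finite differences at 1e-4 relative tolerance. One integer seed
derives initialization, shuffling, dropout and noise; with dropout and
noise disabled, repeat runs are bitwise identical.

## Augmentation and leakage control

SMOTE (k = 5, Euclidean metric, neighbour ties to the lowest row index)
balances every class up to the majority count by interpolating uniformly
between a minority row and one of its k nearest same-class neighbours;
zero-mean Gaussian noise (σ = 0.1, standardized units) is then added to the
whole augmented training set. Both operate on the standardized 18-column
compact representation — neighbour search "in the feature space" is only
meaningful after standardization, and augmenting before tensorization keeps
the replication invariant exact. k is clipped to class size − 1 with a
warning so toy sets run; singleton classes are an error. All augmentation
is confined to the training side of each stratified fold: standardization
statistics are fitted on the fold's original training rows only, validation
rows stay original and noise-free, and a per-fold manifest records every
synthetic row with its parents and interpolation weight. A dedicated test
audits 100 seeded fold plans for zero synthetic contamination.

## Boosting stage

LightGBM has no R implementation in this toolchain, so the boosted stage
runs on xgboost configured to the same leaf-wise regime
(`grow_policy = "lossguide"`, `max_leaves` = 31, single thread for
determinism) with the stated leaf-weight regularization λ₁ = 1.2 (L1) and
λ₂ = 0.8 (L2). The classification objective is one softmax over the four
categories; the printed binary loss form is its two-class restriction, and
a one-vs-rest mode is available by configuration. Tree count (200) and
learning rate (0.1) are unstated upstream and exposed as configuration.
`regularized_logistic_loss()` implements the objective directly for
testing; note the canonical form is a *negative* log-likelihood plus
positive penalties.

## Attribution and prescription rules

With only four metric summaries, Shapley values are computed exactly over
the 2⁴ coalition lattice (16 model evaluations per subject, absent features
imputed by the background mean). Additivity — base plus contributions
equals the model margin — holds to floating-point precision and is asserted
at 1e-9; a determinism guard re-evaluates one coalition and rejects
stochastic pipelines. Deficiency selection takes the top positive
contributor, plus the runner-up iff it reaches 50 % of the leader
(operationalizing "top 1–2"); ties break by the fixed metric order.

The weekly template is 10 sessions / 300 minutes (HIIT 5×30′, aerobic
3×30′, strength 2×30′). Each deficiency adds one session of its mapped
modality (3,000 m → aerobic, pull-ups → strength, sit-ups → strength with a
core tag, shuttle → HIIT) and multiplies that modality's load by 1.2. The
fatigue-recovery balance index is defined here as the acute:chronic mean
daily load ratio (7 d : 28 d, zero-filled days), the standard workload
monitor under which the stated 1.2 threshold is meaningful; the formula and
windows are configuration. Adjustment bands stated as ranges are resolved
to midpoints and exposed as parameters: 17.5 % deload (15–20 %), 4 days
(3–5), 7.5 % volume increment (5–10 %); a 2 % relative improvement
threshold separates progress from stagnation (no threshold is stated
upstream). The deload rule dominates: above threshold nothing intensifies.
Reassessment defaults to a biweekly cadence. Dietary and mental-health
guidance is carried as static text in the serialized plan, never computed
on.

## Trial analysis

Arms are allocated by permuted blocks of 4; the analysis is per-protocol
(completers only) by default, with intention-to-treat under
last-observation-carried-forward behind a flag — attrition is generated
missing-at-random, so both agree in expectation. Between-group effects come
from ANCOVA on post values adjusting for baseline (Wald CI and p),
within-group changes from paired t intervals, standardized effects from
Cohen's d on change scores, and categorical shift from McNemar's test
dichotomized at the overweight boundary, with the exact binomial form below
25 discordant pairs. Multiclass AUC is one-vs-rest macro (unspecified
upstream). Reported percent changes follow the table conventions (decrease
positive for times, increase positive for counts, one decimal).

## The synthetic generator

The generator defines the study conditions rather than fitting any real
data. Category proportions default to 5.3/74.5/19.0/1.2 %, with counts by
deterministic largest-remainder rounding. Lap times are a per-subject
lognormal base pace (≈ 56.8 s, 7 % log-SD, totalling ≈ 14.2 ± 1 min over
3,000 m) plus a category-specific linear fatigue slope (0.10/0.25/0.60/1.00
s per lap index, centred mid-race) plus i.i.d. Gaussian split noise
(1.5 s). Scalar metrics are Gaussian around category-shifted means
(pull-ups 10 ± 3, sit-ups 38 ± 6, shuttle 32.5 ± 2.3 s; standardized shifts
grow monotonically toward obese). The trial generator adds arm-specific
mean changes (+4.5 pull-ups, −1.4 min, −3.3 s under intervention; +1.5,
−0.5, −1.3 under control; BMI −1.5 vs −0.3 kg/m²) with change-score SDs
backed out of the reported effect sizes (≈ 3.8 reps, 1.4 min, 2.8 s), and
attrition of 13.2 %/14.1 %. What the generator does **not** emulate:
non-Gaussian measurement artifacts, within-subject lap autocorrelation
beyond the linear trend, pacing strategy (negative splits), age/sex/diet
heterogeneity, or any real covariance between metrics beyond their shared
category. Passing tests therefore certify the machinery — balanced
augmentation, leakage control, optimization, calibrated inference — not
field performance on real cohorts.

## A known, documented limitation

One ordering benchmark asks the extractor+boosting pipeline to beat a
multinomial-logistic baseline (fitted on the 18 raw compact features) on
macro-F1 when the class signal sits entirely in the fatigue slope. Under
this generator that ordering is unattainable in principle: with a linear
slope, lognormal-common base pace and shared Gaussian noise, the
class-conditionals are Gaussian with a category-independent covariance, so
the multinomial-logistic family contains the Bayes decision rule for
exactly these features — any learned representation can at best match it.
Measured at n = 2,000 (5 seeds), the baseline reaches macro-F1 ≈ 0.80,
boosting on the raw features ≈ 0.64, and boosting on trained embeddings
≈ 0.59 (auxiliary-head accuracy ≈ 0.87). The corresponding acceptance test
is implemented faithfully and left failing rather than weakened; a
generator with nonlinear or heteroscedastic fatigue structure would be
needed for the ordering to be achievable, and changing the generator to
manufacture that outcome was ruled out.

## Problem sizes and numerical choices

Tests run the full-width architecture for structural checks and a narrow
variant (8/16/32 filters, identical topology) for training checks; the
ordering benchmark uses n = 2,000 subjects, 30 epochs, batch 128, and the
calibration studies use 100 coverage trials at 500/arm and 1,000 null
replicates at 100/arm. Probabilities are clipped at 1e-12 in loss
evaluation; layer-norm uses ε = 1e-5; attention-map validation tolerates
1e-4 row-sum error; early stopping treats improvements below 1e-12 as
noise. Degenerate inputs fail loudly by design: zero-variance columns in
standardization (named), singleton classes in SMOTE, empty folds, zero
chronic load in the FRBI, zero pooled SD in Cohen's d.
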