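---
title: "Modeling individualized MCI progression trajectories with mciTrajectory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling individualized MCI progression trajectories with mciTrajectory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mciTrajectory)
```

## The problem

Amnestic mild cognitive impairment (aMCI) progresses to dementia at very
different rates across individuals, and amyloid-β status is a key stratifier
of that risk. Given a patient's longitudinal record — six MRI markers
(regional mean cortical thickness in the cingulate, frontal, parietal,
temporal and occipital cortices, and hippocampal volume normalized by
intracranial volume), nine neuropsychological scores (DSF, K-BNT, RCFT copy
and delayed recall, SVLT delayed recall, COWAT, Stroop color reading,
K-MMSE, CDR-SB), APOE ε4 carrier status, global amyloid burden on the
Centiloid scale, and demographics — the package forecasts all fifteen MRI
and cognitive outcomes at the *next* annual visit, per subject. Clinical
follow-up data of this kind are short (at most a handful of visits),
irregular, and full of holes: visits are skipped, individual tests are
omitted, and subjects drop out. The architecture is built around those three
facts.

## The model

Three modules are trained end to end.

**Feature fusion by self-attention.** At visit $t$ the $B = 17$
non-demographic features are concatenated into
$\tilde{x}_t = [m_t \mathbin{\circ} c_t \mathbin{\circ} p_t]$ and projected
to query, key and value vectors, $Q = W_q\tilde{x}_t$, $K = W_k\tilde{x}_t$,
$V = W_v\tilde{x}_t$ (all $W \in \mathbb{R}^{B\times B}$). Each scalar
feature acts as one attention token, so the row-wise softmax of
$QK^{\top}/\sqrt{B}$ is a $B \times B$ matrix of feature-to-feature weights —
directly interpretable as which markers inform which. The attended values
$AV$ pass through a small feed-forward refinement (affine + ReLU, depth
configurable, default 1), are added back to $\tilde{x}_t$ (residual), and
concatenated with the demographics, which bypass attention.

**Temporal representation with decay and mask.** The fused vector drives a
GRU whose previous hidden state is first attenuated elementwise,
$\tilde{h}_{t-1} = h_{t-1} \odot \omega_t$, by a temporal decay factor
$\omega_t = \exp(-\max(0, W_\omega \delta_t + b_\omega)) \in (0,1]^H$
computed from the per-feature staleness vector $\delta_t$ (years since each
feature was last directly observed). The gate input is the concatenation of
the fused features with the binary observation-mask vector $n_t$, so the
recurrence always knows which inputs were measured and which were imputed:

$$r_t = \sigma(W_r^i[\tilde{x}_t \mathbin{\circ} n_t] + b_r^i + W_r^h\tilde{h}_{t-1} + b_r^h)$$

with the update gate $z_t$ analogous, candidate
$h'_t = \tanh(W_h^i[\tilde{x}_t \mathbin{\circ} n_t] + b_h^i + W_h^h(r_t \odot \tilde{h}_{t-1}) + b_h^h)$,
and $h_t = (1-z_t)\odot\tilde{h}_{t-1} + z_t \odot h'_t$. With
$\omega \equiv 1$ and $n \equiv 1$ this is exactly a standard GRU — a
property the test suite checks against an independent reference
implementation. $W_\omega$ is initialized at one tenth of the Glorot scale
so that $\omega \approx 1$ at the start of training: the recurrence begins
as a plain GRU and learns how strongly to discount stale history, rather
than starting from a randomly crippled hidden state.

**Multi-task heads.** Two affine heads read $h_t$:
$\hat{m}_{t+1} = W_m h_t + b_m$ (6 MRI markers) and
$\hat{c}_{t+1} = W_c h_t + b_c$ (9 cognitive scores), in min–max-normalized
feature space. No output activation is applied.

**Loss.** $L_\text{total} = \alpha L_m + \gamma L_c$ with $\alpha = 0.75$,
$\gamma = 1.0$; each term is a *masked* MSE over visits $2..T$, restricted
to targets that were directly observed, and averaged over the count of such
cells so the weights keep their meaning regardless of cohort size or
missingness level. Predictions at imputed targets carry no loss — training
on them would let the model chase its own imputations. An MAE variant is
available behind `loss = "mae"`.

### A note on dimension bookkeeping

With 6 MRI + 9 cognitive + APOE + Centiloid the attended block is 17 wide;
adding age, education and gender gives a 20-dimensional fused vector and a
gate input of width 40 after mask concatenation. Published descriptions of
this architecture sometimes quote 21 GRU input nodes; 17 + 3 demographics is
20, and the package keeps all dimensions schema-derived rather than
hard-coding either number. All shapes are validated at model load.

## Missing-data handling

Three aligned tensors represent a cohort (`LongitudinalCohort`, a
`SummarizedExperiment` with features × subjects × visits assays): `values`
(NA where unobserved), binary `mask`, and `delta`, the recurrence
$\delta_{t} = \text{gap}(t-1,t) + (1 - n_{t-1})\,\delta_{t-1}$ measuring
years since last observation.

A missing input cell is filled with the decay-weighted convex combination

$$x \leftarrow \gamma_\delta \cdot x_\text{last} + (1-\gamma_\delta)\cdot\bar{x}_\text{train},
\qquad \gamma_\delta = e^{-w\,\delta},$$

falling back to the training mean when no prior observation exists. The
per-feature rate $w$ is calibrated on the training split by minimizing the
reconstruction error of *observed* cells from their own history over a
deterministic grid (`impute_decay = "fitted"`, the default — this is the
data-driven reading of the mechanism; `"fixed"` pins $w = 1$). On smooth
markers such as cortical thickness the fitted rates approach pure
carry-forward, which is exactly what a clinician would expect. The mask is
never altered by imputation: downstream modules always know what was
measured. Imputed values are convex between the last observation and the
training mean, and imputation is idempotent — both are enforced by tests.

No separate reconstruction loss is back-propagated through imputation: the
forecasting loss already scores every directly observed cell from visit 2
on, and the decay calibration above optimizes reconstruction of observed
cells explicitly, so an additional in-network reconstruction term would
duplicate both signals. The `"fixed"` decay mode keeps the imputation
parameter-free for ablation.

## Training protocol

Min–max normalization to $[0,1]$, imputation means, decay-rate calibration
and all hyperparameter selection use the training split only; mutating
validation or test subjects provably leaves the fitted model unchanged (a
no-leakage test asserts bitwise identity). Optimization is minibatch Adam by
default (`optimizer = "sgd"` for plain stochastic gradient descent), with
decoupled $\ell_2$ weight decay on the weight matrices, early stopping on
validation masked MSE (default patience 20), and the parameters of the best
validation epoch returned. The scalar the optimizer steps on is asserted
every batch to equal $\alpha L_m + \gamma L_c$; weight decay is applied as a
separate shrinkage so that identity is exact. All gradients are analytic
(hand-derived backpropagation through the attention softmax, the FFN, the
decay gate and the recurrence) and are verified against central finite
differences to $10^{-4}$ relative error.

Grid search is exhaustive over learning rate
$\{5\times10^{-5},10^{-4},10^{-3},10^{-2}\}$, FFN depth $\{1,2,3\}$, hidden
units $\{16,32,48,64,80,96\}$ and $\ell_2$
$\{10^{-6},10^{-5},10^{-4},10^{-3}\}$ (288 trials); ties prefer the smaller
model. Cross-validation runs 5 folds × 5 repetitions: per repetition each
class is shuffled into 10% chunks, fold $k$ taking chunk $k$ as test and a
disjoint chunk as validation — test sets are disjoint within a repetition
and realized fractions are within one subject per class. Grid search is a
separate entry point rather than being nested inside every fold; nesting
would multiply 288 trials by 25 fits, and the package treats the
configuration supplied to `crossValidate()` as fixed.

## The synthetic cohort generator

The real clinical cohort behind this class of models is not public, so the
generator is a first-class, tested module that emulates its structure: two
amyloid groups with baseline feature distributions matched to published
group tables (e.g. K-MMSE $26.8 \pm 2.4$ vs $25.1 \pm 3.3$; APOE ε4 carrier
rates 17% vs 64.6%; Centiloid $7.5 \pm 18.8$ vs $90.9 \pm 31.1$), linear
group-specific annual decline with the amyloid-positive group strictly
steeper on every progressing feature, CDR-SB increasing while every other
score and all MRI markers decrease, a subject-level latent severity factor
(loading 0.3 of each feature's baseline sd) inducing realistic cross-feature
correlation, and observation noise of 0.25 baseline sd. Annual decline
magnitudes are the package's own clinically plausible choices (e.g. K-MMSE
−0.3/yr vs −0.9/yr; cortical thickness −0.01 to −0.045 mm/yr). Missingness
is intermittent MCAR cell-level masking plus monotone dropout with a
per-visit hazard; the baseline visit is never masked, and demographics are
always observed (they are duplicated from baseline, age advancing with the
visit offset).

One consequence of matching the published baseline table: COWAT starts
*higher* in the amyloid-positive group (22.7 vs 22.2, a non-significant
difference, as in the table), so although its decline is steeper, the group
mean curves cross during follow-up instead of separating monotonically.
Group-ordering tests therefore cover every cognitive score except COWAT.

What the generator deliberately does *not* emulate: informative (MNAR)
missingness, nonlinear trajectories, practice effects on repeated testing,
measurement batch effects, and realistic imaging covariance beyond the
single severity factor. Tests passing on this cohort therefore demonstrate
correctness of the machinery and recoverability of linear group structure —
not clinical performance.

## Downstream analyses

**Amyloid-positivity classification** uses an RBF SVM on three feature sets:
baseline visit only; all visits with mean-filled gaps; and decay-imputed
observations augmented with the model's next-visit predictions. Cost is
selected per outer fold by inner 3-fold accuracy over $\{0.1, 1, 10\}$;
sensitivity is the recall of the amyloid-positive class and AUC is the
Mann–Whitney rank statistic on decision values (invariant to monotone
transforms).

**Relative change maps** quantify atrophy as
$s_t = (y_t - y_0)/y_0$ per marker and subject, jointly normalized to
$[-1,1]$ by a sign-preserving piecewise scaling (positives divided by the
tensor maximum, negatives by the magnitude of the minimum) — plain min–max
would destroy the increase/decrease sign that the visualization encodes.
Cells with $|s| \ge 0.25$ are flagged; the boundary value is flagged
(≥ convention).

**Attention interpretation** averages per-subject attention maps within each
group at each time step, normalizes each time slice to $[0,1]$, and flags
cells whose normalized series departs from its first observation: a drop
greater than 0.05 in a series that decreases over time (last ≤ first with at
least one strict drop) is an "orange" flag; a rise greater than 0.2 in a
series that increases (last ≥ first with at least one strict rise) is "red".
"Decrease over time" is operationalized as stated because the qualitative
description leaves it open.

**Centiloid cutoff.** The two-group split of global Centiloid values is the
exact one-dimensional 2-means solution, found by a sweep over sorted split
points minimizing total within-cluster sum of squares (deterministic, no
Lloyd iterations to seed), with the positivity cutoff taken as mean + 2
sample sd of the lower cluster. On synthetic Centiloid distributions this
number reflects the simulated groups, not any published clinical threshold.

## Numerical and design choices

* Sentinel for unobserved cells is NA in files and in the values assay;
  all computation consults the mask, never the sentinel.
* Decay is $\exp(-\max(0, \cdot))$ throughout, guaranteeing $(0,1]$ and
  decay 1 at zero staleness.
* Softmax rows are max-shifted before exponentiation for stability;
  attention row sums are tested to $10^{-6}$.
* $h_0 = 0$; hidden states are provably inside $(-1,1)$ from step 1.
* Weight initialization is Glorot-style scaled uniform, seeded; the decay
  projection is additionally scaled by 0.1 (see above).
* Rollout feeds predictions back with mask 0 and growing $\delta$, so the
  recurrence treats its own outputs as imputed; demographics are carried
  forward with age incremented; APOE and Centiloid are carried forward
  unchanged.
* Every stochastic stage derives its seed as a deterministic hash of the
  global seed and the stage name, so pipeline stages are independently
  reproducible and reruns are bit-identical.
* MAPE excludes targets with $|y| \le 10^{-8}$ (count reported): several
  cognitive scores normalize to values near zero, where MAPE is unstable —
  this is also why percentage errors on such scores should be compared with
  care.

## Problem sizes used by the test suite

The standard synthetic benchmark used by the acceptance tests and the
acceptance script is 200 subjects per group, 4 annual visits, 20%
intermittent missingness, seeds 1–5, trained for up to 300 epochs (patience
25, batch 64, hidden size 48). Unit tests use cohorts of 6–30 subjects per
group and models of 8–16 hidden units so the full suite runs in minutes.
The demo pipeline (`runPipeline()`) defaults to 80 subjects per group and a
120-epoch budget.

## Known limitations

* Teacher-forced one-step forecasts dominate the evaluation; multi-year
  free-running rollouts accumulate error and are exposed
  (`rolloutTrajectory`) but not optimized for.
* The SVM scenarios include the Centiloid feature, which on the synthetic
  cohort is strongly group-separated (as it is in the real clinic, where the
  label is *defined* from it); absolute AUCs on synthetic data are therefore
  near ceiling and only scenario *orderings* are meaningful.
* Single-head attention over scalar tokens; no positional encoding (the
  recurrence carries time).
* The generative model is linear-mixed; parameter recovery results do not
  transfer to nonlinear decline regimes.

## A worked example

```{r example, eval = FALSE}
sim <- simulateObservedCohort(defaultSimulationConfig(n_subjects = 80),
                              seed = 1)
sp <- stratifiedSplit(abetaGroup(sim$observed), seed = 1)
ids <- colnames(sim$observed)
model <- trainModel(sim$observed, ids[sp$train], ids[sp$val],
                    defaultTrainConfig(max_epochs = 120, hidden_units = 32))
regressionMetrics(model, sim$observed, ids[sp$test])
downstreamClassification(model, sim$observed, "longitudinal_imputed")$report
```
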