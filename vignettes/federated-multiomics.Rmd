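---
title: "Simulating cross-silo federated learning on multi-omics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cross-silo federated learning on multi-omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedomics)
```

## The problem

Multi-omics case-control cohorts — combined genetic, transcriptomic and
clinico-demographic features per patient — are typically access-controlled
and cannot be pooled across institutions. Cross-silo federated learning
(FL) offers a workaround: a handful of institutional clients each fit a
local model on their own samples, a coordination server averages the model
parameters, and only parameters ever cross institutional boundaries.
`fedomics` simulates this setting end to end for binary phenotype
classification (case vs control, with Parkinson's disease as the motivating
phenotype), so that the practical questions — how much performance does
federation cost relative to central training? how does dispersing a fixed
sample pool over more silos hurt? does client heterogeneity matter? — can
be studied reproducibly without access-controlled data.

One communication round of the simulation is:

1. the server broadcasts the global parameters $w^t$ to all $N$ clients;
2. client $k$ fits its local learner for $E$ epochs on its shard,
   minimizing $F_k(w)$ (mean regularized log-loss), or under FedProx
   $F_k(w) + \frac{\mu}{2}\lVert w - w^t \rVert^2$;
3. the server aggregates: $w^{t+1} = \frac{1}{N}\sum_k w_k$ — the
   *unweighted* mean, regardless of shard sizes (a size-weighted mean is
   available behind a flag, off by default).

After $R$ rounds the global model with the best validation AUC-PR
(earliest round on ties) is kept for testing. Rounds are synchronous and
failure-free; there is no transport layer, privacy mechanism, or
adversarial model — those are out of scope by design.

## The synthetic cohort generator

Real cohorts of this type reach the model only after heavy preprocessing:
covariate adjustment by linear regression and a Z-transform to mean 0,
sd 1. The generator therefore simulates at the *post-preprocessing feature
level*: no genotypes, read counts or LD structure, only standardized
feature columns.

`generate_cohort()` draws a class-conditional Gaussian cohort:

* **Feature blocks.** Defaults mirror a harmonized multi-omics cohort:
  72 genetic-like features (variant dosages and polygenic-score
  analogues), 596 transcriptomic-like features, 5 clinico-demographic
  columns — 673 in all. Within each omics block, features share an
  equicorrelation `block_correlation` (default 0.1), implemented with a
  per-block latent factor.
* **Signal.** A fraction `informative_fraction` (default 0.1) of the omics
  features carries a standardized class-mean difference of magnitude
  `effect_scale` with random sign. The default `effect_scale = 0.4` was
  calibrated once so that a centrally trained logistic regression reaches
  an internal-test AUC-PR of at least 0.85 at the default cohort size
  (171 cases / 427 controls), putting the simulation in the same
  high-signal regime as the motivating application.
* **Clinical block.** Age-like continuous column (effect
  `0.3 * effect_scale`), binary family-history, ancestry-flag and sex
  columns whose class-dependent Bernoulli rates shift on the log-odds
  scale proportionally to `effect_scale`, and a smell-test-like (UPSIT
  analogue) continuous column with the dominant single-feature effect,
  `-2.5 * effect_scale` (markedly lower scores in cases). Setting
  `effect_scale = 0` removes every class difference, including the binary
  rates.
* **External cohort.** `generate_external_cohort()` reuses the same
  informative-feature set (the structural stream depends only on the
  spec's seed) and applies a `shift_spec`: all effects multiplied by
  `effect_attenuation` (a drug-treatment analogue — treated external
  patients separate less) and informative continuous features offset by
  `mean_shift` (covariate shift). The identity shift reproduces the
  source cohort bit for bit.

One master seed drives a documented hierarchy of derived sub-streams
(`derive_seed(seed, tag, ...)`) for structure, samples, shards, learner
initialization and epoch shuffles, so every component is independently
reproducible and every experiment replays bit for bit.

What the generator deliberately does **not** emulate: raw-data artefacts
(batch effects, missingness, count noise), realistic LD or co-expression
topology beyond equicorrelation, site-of-origin structure, or label noise.
Passing tests on these cohorts therefore demonstrate the correctness and
qualitative behavior of the *federation machinery*, not clinical-grade
performance on real data.

```{r cohort}
spec <- cohort_spec(171, 427, seed = 1)
cohort <- generate_cohort(spec)
cohort
```

## Preprocessing

`fit_standardizer()` / `apply_standardizer()` implement the Z-transform
with the **population** sd convention (divide by $n$; documented because
the two conventions differ detectably on small columns). Constant columns
get their sd floored at `1e-12`, so the standardized column is ~0 rather
than a division blow-up. Binary clinical columns pass through untouched.
Parameters are fitted on the training split only and reused verbatim on
validation, holdout and external data — fitting functions simply never see
test rows.

`residualize()` replaces each feature by its OLS residual on
caller-supplied covariates plus intercept (the covariate-adjustment step
used on real data with genotype-derived principal components);
rank-deficient covariate matrices are an error, not a silent
pseudo-inverse. `select_features()` ranks features with an
extremely-randomized-trees classifier (`ranger`, `splitrule =
"extratrees"`, impurity importance), drops those below an importance
quantile (default 0.5), then greedily prunes, from any pair with squared
correlation above `correlation_cap` (default 0.36), the lower-importance
member. Both thresholds are plain config values, not claims of fidelity to
any particular study's cutoffs.

## Client sharding

Three strategies of increasing heterogeneity partition a cohort's indices
into $N$ disjoint shards (`split_cohort()`):

* `uniform_stratified` — split by phenotype, assign
  $\lfloor n_\text{class}/N \rfloor$ of each class per client: label and
  size homogeneity.
* `uniform_random` — assign $\lfloor C/N \rfloor$ samples uniformly at
  random: label heterogeneity, size homogeneity. Draws that leave a shard
  single-class are resampled with a fresh derived seed (up to 100
  attempts).
* `linear_random` — client $i$ receives $i \cdot c$ samples with
  $c = \lfloor 2C / (N(N+1)) \rfloor$: label and size heterogeneity with
  strictly increasing shard sizes.

Surplus samples always go to the **last** client. (The deterministic
last-client rule was chosen over random assignment for exact
reproducibility.) Every shard must contain at least one case and one
control — `validate_shards()` checks this feasibility condition together
with the partition invariants, and `shard_heterogeneity()` summarizes a
shard set by its label skew (max pairwise difference in case fractions)
and size skew (max/min size ratio).

## Local learners

All learners share one contract: `init_learner()`, `local_fit()` (E
epochs, optional proximal anchor), `get_parameters()`/`set_parameters()`,
`predict_scores()`.

* **`logistic_regression`** — full-batch gradient descent on mean
  L2-regularized log-loss; one step per epoch; rate 0.1, L2 `1e-4`.
* **`sgd_linear`** — per-sample averaged SGD: Robbins-Monro step size
  $\eta_t = \eta_0/\sqrt{t}$ with a cumulative update counter, and
  per-epoch Polyak iterate averaging (each epoch ends on the mean of its
  iterates, the `average = TRUE` convention of standard SGD classifiers),
  so exported parameters approximate the local optimum rather than a
  noisy final iterate. Its base rate defaults to $\eta_0 = 0.01$:
  per-sample steps at the batch learners' 0.1 are wildly unstable in 673
  dimensions (individual updates move the weight vector by
  $\eta \lVert x_i \rVert \approx 2.6$).
* **`mlp`** — one hidden layer of 32 tanh units, logistic output,
  mini-batch (32) gradient descent, seeded uniform init scaled by
  $1/\sqrt{\text{fan-in}}$.
* **`forest`** — boosted shallow regression trees (depth 3, 5 trees per
  round, Newton leaf values $-G/(H+\lambda)$ scaled by a 0.3 learning
  rate, exact greedy splits with deterministic first-best tie-breaking).
  Trees are plain nested lists (split feature, threshold, children, leaf
  value) so they serialize, concatenate across clients, and support
  server-side leaf rescaling.

**Proximal handling.** The FedProx term is applied *implicitly*: after
each loss-gradient step, every tensor is pulled toward the anchor by the
exact proximal map $w \leftarrow (w + \eta\mu\,a)/(1 + \eta\mu)$. An
explicit gradient term $\mu(w - a)$ diverges whenever $\eta\mu > 2$; the
implicit map is stable for every $\mu \ge 0$, collapses onto the anchor as
$\mu \to \infty$, and is bitwise identical to the plain update at
$\mu = 0$ (so FedProx with $\mu = 0$ *is* FedAvg, exactly).

**Epoch chaining.** Epoch shuffles derive from the learner seed and a
cumulative epoch counter, so fitting $E$ epochs equals $E$ chained
one-epoch fits, and a federation of one client with $R$ rounds of $E$
epochs reproduces central training with $R \cdot E$ epochs to the last
bit.

**Forest federation.** How boosted-forest models are averaged under
"FedAvg" is genuinely underdetermined in the cross-silo literature; the
scheme here is a bagging-style reconstruction: clients grow trees from the
shared incoming ensemble (a prefix check enforces this), and the server
appends every client's new trees with leaf values scaled by $1/N$, so the
aggregated margin increment is the mean of the clients' increments and
$N = 1$ reduces to central boosting.

## Evaluation protocol and metrics

`kfold_protocol()` runs stratified K-fold cross-validation (default
$K = 6$; on a 598-sample cohort the per-class surpluses are spread from
opposite ends of the fold range so fold sizes come out 99/100). Within
each fold, the remainder is split 80:20 (stratified) into fit and
validation subsets; preprocessing and all model fitting see only the fit
subset; the validation subset drives federated best-round selection;
models are scored on the holdout fold (internal test) and on the full
external cohort, which is never touched during fitting or selection. The
returned audit trail records each fold's index sets so leakage can be
checked mechanically.

`compute_metrics()` reports ten metrics. Conventions that matter at the
third decimal:

* ROC-AUC uses the rank (pairwise-comparison) definition with ties
  counted 1/2.
* AUC-PR uses step-wise average-precision summation
  $\sum_i (R_i - R_{i-1}) P_i$ over descending distinct thresholds, not
  trapezoidal interpolation.
* Thresholded metrics (balanced accuracy, precision, recall,
  $F_{0.5}/F_1/F_2$, MCC) use prediction $= 1$ iff score $\ge 0.5$; the
  threshold is config-exposed. Zero-denominator ratios are reported as 0.
* Log loss clips probabilities at $10^{-15}$ to keep extreme scores
  finite.

## Experiment arms and problem sizes

Three arms reproduce the study design on synthetic cohorts
(`experiment_plan()` + `run_experiment()`): central-vs-federated at
$n = 2$ stratified with paired AUC-PR deltas; a dispersion sweep over
$n \in \{2, 4, \dots, 18\}$ stratified shards of the same fit split; and
the heterogeneity cross of the three split strategies at $n \in \{2, 4\}$
with the shard heterogeneity indices attached to every delta. Each arm
emits a manifest from which `replay_experiment()` reproduces the outputs
bit for bit.

The federation schedule defaults to $R = 5$ rounds. The learner-level
default of $E = 1$ local epoch is the minimal faithful round; the
experiment arms default to $E = 8$ because the cross-silo setting being
emulated fits local learners to near-convergence each round — with a
single full-batch epoch, FedAvg over identical-rate clients collapses to
exact distributed gradient descent and the client-drift phenomena under
study vanish by construction. Central baselines train for $R \cdot E$
epochs so comparisons are epoch-matched.

The shipped tests and the acceptance script run at desk scale on one CPU:
the study-size cohort (598 x 673) for the trend checks with 10 seeds per
trend, $K = 6$ folds for the protocol runs, and smaller cohorts (tens of
samples, ~25 features) for the exact algebraic checks. These sizes are the
package's chosen operating point for routine verification; all of them
are plain arguments.

```{r gap, eval = FALSE}
# FL-vs-central gap at n = 2, ten seeds (the headline "FL tracks central")
gap <- fl_central_gap(cohort_spec(171, 427), n_seeds = 10, seed = 1)
mean(abs(gap$delta))
```

## Known limitations

* The generator's Gaussian equicorrelation blocks understate the
  heavy-tailed, networked dependence of real expression data; absolute
  metric values on synthetic cohorts should not be read as forecasts for
  real cohorts — the supported claims are comparative (federated vs
  central, trend in $n$, strategy deltas).
* The forest aggregation scheme is a reconstruction, not a standard; its
  absolute performance is sensitive to tree depth and count.
* Runtime measurements (`measure_runtime()`) are hardware-dependent and
  excluded from any correctness claim.
* No privacy accounting of the exchanged parameters: parameter averaging
  is sample-private only in the narrow sense that raw rows never leave a
  silo.
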