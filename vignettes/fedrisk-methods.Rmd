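---
title: "Methods: federated, differentially private risk prediction on simulated multi-site cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated, differentially private risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedrisk)
```

## The problem

Several hospitals each hold a sparse table of clinical covariates (mostly
binary indicators — diagnoses, drug exposures, procedures — extracted from
observational records) and a rare binary outcome: whether a patient first
diagnosed with depression is re-diagnosed with bipolar disorder within one
year. Pooling patient-level records across institutions is usually not
permitted, so a shared risk model has to be trained *federatedly*: only
model weights travel, never rows. `fedrisk` implements that workflow end to
end — synthetic multi-site cohort generation, federated feature selection,
a Deep & Cross Network (DCN) trained with differentially private SGD under
federated averaging, cross-site evaluation, and baseline-characteristics
tables — as ordinary R functions with a classed fitted-model object at the
centre.

Because no multi-hospital dataset can ship with a package, the generator is
a first-class, tested module: it defines the study conditions every other
stage is validated against.

## The synthetic cohort generator

For covariate $j$ a global marginal frequency $p_j$ is drawn log-uniformly
on $(10^{-4}, 0.5)$, reproducing the long tail of rare codes in
observational feature extraction (tens of thousands of features, most of
them rare). Site $s$ perturbs each frequency on the logit scale,

$$\operatorname{logit} p_{sj} = \operatorname{logit} p_j + \tau_s z_{sj},
\qquad z_{sj} \sim N(0,1),$$

with $\tau_s = \tau$ everywhere except one designated *shifted* site where
$\tau_s = 3\tau$ — the non-IID client whose covariate distribution visibly
departs from the rest, as one development hospital's did in the motivating
study. Covariates are independent Bernoulli draws given the site (code
correlation structure is deliberately not modelled; no pipeline stage
exploits it). The outcome follows a shared sparse logistic model

$$y_i \sim \mathrm{Bernoulli}\bigl(\sigma(\alpha_s + x_i^\top \beta)\bigr),$$

where $\beta$ is nonzero on $m$ *informative* covariates and the per-site
intercept $\alpha_s$ is calibrated by Monte-Carlo root finding
(`calibrate_intercept`, 100,000 probe draws, root bracketed in $[-20, 5]$)
so each site attains its target outcome prevalence.

Defaults are the study conditions: five sites of 3917, 5799, 4873, 3042 and
4541 persons (the last external), per-site outcome prevalences matching the
reported outcome counts (overall about 1.6%), $K = 2{,}000$ covariates at
desk scale (up to 20,000 supported), $m = 30$ informative covariates with
alternating-sign log-odds between 0.5 and 1.5, and $\tau = 0.5$ with the
fourth site shifted.

Two generator choices deserve explanation:

* **Informative covariates are drawn among covariates with marginal
  frequency $\ge$ 1%** (`informative_min_prevalence`). Established clinical
  predictors of the bipolar transition are non-rare codes (severe
  depression ~9%, anxiety disorder ~21%, hypertension ~16%); an effect
  planted on a one-in-ten-thousand covariate would be unidentifiable at any
  realistic cohort size and would make recovery experiments meaningless.
* **Splits are uniform per patient, not outcome-stratified**, with
  deterministic 7:1:2 counts ($\lfloor 0.7n \rfloor$, $\lfloor 0.1n
  \rfloor$, remainder). Unstratified splitting mirrors the patient-basis
  protocol and reproduces the outcome-count volatility small sites show.

What the generator does **not** emulate: realistic ICD/ATC vocabularies,
visit timelines and censoring, inter-code correlation, continuous
measurements (a Gaussian-value option exists but is off by default). Tests
passing on this generator therefore establish the pipeline's statistical
machinery, not clinical performance on real records.

## Federated feature selection

Each client fits a gradient-boosted tree ensemble (binary logistic
objective, 100 trees, learning rate 0.1, single-threaded) on its training
split; a covariate's *gain importance* is the total training-loss reduction
over all splits on it. Rankings are combined by the unweighted mean of
per-client gains — a covariate missing from one client's model contributes
zero, and covariates absent (all-zero) from any client's data are excluded
outright, since a model shipped to every site must resolve every input.
Ties break lexicographically on covariate id so the ranking is
deterministic.

The number of retained features $N$ is chosen by `search_top_n`: walk the
doubling grid $\{25, 50, 100, 200, 400, 800, 1600\}$, at each $N$ train the
federated model and record the tuning-set AUC averaged over clients with
tuning-set-size weights; stop early after three consecutive grid steps each
improving the running best by at most 2% (relative); finally choose the
smallest evaluated $N$ whose AUC reaches 98% of the best observed. The grid
doubles because training cost grows linearly in $N$; the 2% baseline is
relative to the best seen so far, and the AUC weights are tuning-set sizes
— both points the protocol leaves open, fixed here once.

## The risk model

The DCN takes the $d$ selected covariates as a dense numeric vector (they
are binary indicators post-selection, so no categorical embedding is used;
an optional standardisation by pooled train-split moments applies to any
non-binary column). Two towers run in parallel from $x_0 = x$:

* **Cross tower**, $L_c = 2$ layers of
  $x_{l+1} = x_0 (x_l^\top w_l) + b_l + x_l$ — explicit multiplicative
  feature interactions with $2d$ parameters per layer;
* **Deep tower**, ReLU affine layers of widths 64 and 32.

The concatenated towers feed a single affine + sigmoid head; the loss is
binary cross-entropy (probabilities at exactly 0/1 are clamped to $10^{-7}$
with a warning). Architecture hyperparameters are package defaults chosen
small for CPU training — the source protocol reports none — and all are
configurable via `dcn_config()`. Parameters flatten to a named vector
(`dcn_flatten`/`dcn_unflatten` are exact inverses), which is the unit of
aggregation and of the privacy mechanism.

## Differential privacy

`dp_sgd_step` computes *per-example* gradients analytically (matrix
backprop that never materialises an $n \times$ parameters tensor), clips
each to L2 norm $C$, sums, adds isotropic Gaussian noise of SD $\sigma C$,
and normalises by the batch size — the convention under which $\sigma$ is
the noise multiplier. With $\sigma = 0, C = \infty$ the step *is* plain
minibatch SGD, by the same code path.

Privacy accounting uses Rényi differential privacy. One step of the
subsampled Gaussian mechanism at integer order $\alpha$ and sampling rate
$q$ is bounded by

$$\mathrm{RDP}(\alpha) = \frac{1}{\alpha - 1} \log \sum_{k=0}^{\alpha}
\binom{\alpha}{k} (1-q)^{\alpha-k} q^k
e^{k(k-1)/(2\sigma^2)},$$

evaluated in log-space; at $q = 1$ the Gaussian value
$\alpha/(2\sigma^2)$ is returned exactly. Composition multiplies by the
step count $T$ and conversion takes
$\varepsilon = \min_\alpha \, T\,\mathrm{RDP}(\alpha) + \log(1/\delta)/(\alpha-1)$
over integer orders 2–64. Accounting is per client (each client's dataset
is the protected unit) with $q = \text{batch}/n$ (Poisson-subsampling
model; the trainer itself uses shuffled fixed-size batches, the standard
practical deviation) and $\delta = 10^{-5}$ by default — the protocol
never states its $\delta$, so reported $\varepsilon$ values are comparable
only under this documented choice. `select_dp_hyperparameters` searches the
$\{0.5, 1, 2.5, 5\}^2$ grid of $(\sigma, C)$ and returns the feasible cell
(AUC $\ge$ 95% of best) with the smallest $\varepsilon$.

## Federation

`train_federated` runs $R = 5$ rounds of broadcast, $E = 5$ local DP-SGD
epochs per client, and coordinate-wise sample-size-weighted averaging
($\sum_k (n_k/\sum n)\, w_k$, weights = train-split sizes). After each
aggregation the global model's tuning loss is computed on every client's
tuning split and combined with tune-split-size weights; the returned model
is the round snapshot with the lowest aggregated tuning loss, earliest on
ties. The local comparator (`train_local`) trains one client for 25 epochs
and keeps the epoch snapshot with the lowest tuning loss. Federation is
simulated in-process by a sequential client loop — transport is
infrastructure, not method; all weight-flow semantics are preserved. A
failing client aborts the round rather than partially aggregating.

Tunable parameters, with defaults: rounds 5, local epochs 5 (25 for the
local comparator), batch size 256, learning rate $10^{-3}$ in
`federation_config()`. The desk-scale experiments below pass `lr = 0.05`
explicitly: with binary inputs and the quadratic cross tower, 0.1
occasionally diverges (non-finite forward pass) while 0.05 is stable across
all tested seeds; $10^{-3}$ learns too slowly in 25 epochs at these sizes.

## Evaluation

Every model is scored on every site's held-out test split (the external
site contributes all its persons): AUC by the Mann–Whitney rank formulation
with half credit for ties, and the Brier score $\mathrm{mean}((p-y)^2)$.
The headline statistic is each model's unweighted mean AUC across sites
(size weighting available by flag). Sites whose evaluation labels are
single-class yield undefined AUC cells, excluded from means with a warning
— small synthetic sites can hit this. `balanced_bootstrap_auc` keeps all
cases and draws controls without replacement at a fixed control:case ratio
(1, 3, 4 or 9), 1000 replicates, summarised by the mean and percentile
2.5/97.5 interval (percentile, not normal-approximation, since only a "95%
CI" is specified). Attributions use a model-agnostic Monte-Carlo
permutation Shapley estimator — per permutation a background row is
sampled and features are revealed in random order, crediting each marginal
output change to the revealed feature — which satisfies efficiency in
expectation and recovers $\beta_j (x_j - E[x_j])$ exactly for linear
models.

## Baseline tables

`yates_chi_square` applies the continuity correction floored at $|O - E|$
(so proportional tables give exactly 0); multi-level rows use the
uncorrected Pearson statistic. `statistic_printed` reproduces the rounding
convention of published baseline tables — successive half-up rounding to
two decimals and then one (5.2467 → 5.25 → 5.3) — which is what the
reference table's printed statistics follow; plain single rounding
disagrees with one of its ten rows. Significance is flagged at $p < .05$
with no multiplicity adjustment, matching convention.

## Desk-scale study sizes

The test suite and `scripts/acceptance.R` run two simulation studies sized
for a single CPU: a federated-vs-local comparison (10 seeds; 4 clients of
4000/3000/2500/2000 persons, $K = 2{,}000$, $m = 20$ with alternating-sign
log-odds in $[1, 2]$, outcome prevalence 3%, $\tau = 1$) in which the
federated model's mean cross-site test AUC is compared with the average of
the four local models' means; and a planted-feature recovery experiment at
4 × 4000 persons. On the recovery side, a caveat the package states
plainly: protective (negative) effects and effects on covariates below a
few percent prevalence are close to the information floor for a 3% outcome
at these sizes, so top-20 recovery of all 20 planted features is not
expected — rare-and-protective planted effects are structurally hard, not
an estimator defect.

## Known limitations

* In-process federation only; no transport, stragglers, or partial
  participation.
* The accountant assumes Poisson subsampling while the trainer shuffles
  fixed-size batches; this is the standard practical mismatch and is
  documented rather than hidden.
* The generator omits code correlations and temporal structure, so
  feature-selection behaviour on strongly collinear real vocabularies is
  untested.
* DCN training with the protocol's DP setting ($\sigma = 2.5$, $C = 0.5$)
  at desk-scale cohort sizes is dominated by noise; meaningful utility
  under that budget requires the full multi-thousand-patient cohorts.
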