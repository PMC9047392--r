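---
title: "C-search: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{C-search: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the estimand and the update rule, what each tunable does and
why its default is what it is, what the simulator does and does not
emulate, and where the design was genuinely open and a choice had to be
made.

## 1. Estimand: win probability as a rank-form treatment effect

For treated patient $i$ the individual treatment effect compares two
potential outcomes, only one of which is observed. C-search replaces the
unobservable untreated outcome with *pseudo-counterfactuals*: untreated
patients $j$, weighted by similarity. Because outcomes are right-censored
survival times, differences are measured in rank form. Each pair
$(i, j)$ is a Bernoulli trial — does $i$ outlive $j$? — and the effect
measure is the **win probability**

$$Pw_i = P(\text{"win"} \mid X_i),$$

the chance that treated patient $i$ outlives a similarity-matched
untreated counterpart. $Pw_i > 1/2$ means treatment benefit in the
bipartite-ranking (Wilcoxon–Mann–Whitney) sense. This estimand is
identified under the usual observational assumptions — no unmeasured
confounding given the covariates used for matching/weighting, positivity,
and consistency — none of which the algorithm can verify; the simulator
deliberately violates the first one (hidden confounders) to measure the
consequences.

### Censored pair scoring

A pair is *comparable* when the ordering of the two survival times is
determined despite censoring:

| case | score |
|---|---|
| both events | $1$, $0$, or $0.5$ on exact ties |
| $i$ censored at $t_i \ge t_j$, $j$ event | $1$ ($i$ is known to outlive $j$) |
| $i$ event, $j$ censored at $t_j \ge t_i$ | $0$ |
| smaller observed time censored, or both censored | incomparable |

Incomparable pairs carry no evidence. Under the default policy their
weight is redistributed over the comparable pairs
(`incomparable = "drop"`); the alternative of scoring them $0.5$
(`"half"`) is implemented but biases every posterior toward $1/2$ under
heavy censoring, which is why it is not the default. Exact ties in event
times score $0.5$; both policies are deliberate choices on points where
a scoring rule must say *something*.

## 2. Similarity weights and the basal functions

Similarity is measured after projecting covariates to a scalar *basal
risk score*. Two blocks are projected separately: clinical covariates
$V$ and the binary gene matrix $G$. The projection is a linear
proportional-hazards risk score maximizing a ridge-penalized Cox partial
likelihood — a survival-native reading of "a regression function that
approximates the survival state". Projection differences feed a
Boltzmann kernel

$$W(i,j) \propto e^{-|P_i - P_j|/k\tau}, \qquad \sum_j W(i,j) = 1,$$

and the clinical and genetic weight vectors are multiplied elementwise
and renormalized.

Design points, with rationale:

* **Fitting pool** (`basal_fit_pool`, default `"all"`): the basal model
  is fit on the whole cohort with treatment as an *unpenalized
  adjustment* covariate whose coefficient is excluded from the
  projection, so the score ranks baseline risk, not treatment received.
  Fitting on untreated patients only is available but noticeably noisier
  below a few hundred patients.
* **Ridge penalty** (`basal_ridge`, default 0.1, dimensionless): the
  genetic block has hundreds of correlated binary columns; a small ridge
  keeps the partial-likelihood fit defined when $p \approx n$. The same
  default serves the genetic propensity model.
* **Bandwidth** (`k_tau`): the kernel constant and the temperature enter
  only as a product, so a single hyperparameter is exposed. Default
  `"auto"` sets it to the empirical standard deviation of the counterpart
  pool's projections, per block — scale-free, and interpolating sanely
  between the two degenerate limits (uniform weights as
  $k\tau \to \infty$; nearest-neighbor matching as $k\tau \to 0$). The
  temperature is fixed, not annealed: no schedule is defined anywhere,
  and a fixed bandwidth keeps the estimator deterministic.
* **Renormalized combination** (`renormalize_combined`, default `TRUE`):
  the elementwise product of two normalized weight vectors does not sum
  to one. Renormalizing makes every treated patient contribute exactly
  one pseudo-observation to its posterior, preserving the Bernoulli-trial
  reading of the update; without it, posterior concentration depends
  artificially on pool size. The verbatim product is kept as an option.

## 3. Bayesian accumulation and the decision rule

With a $\mathrm{Beta}(\alpha_0, \beta_0)$ prior (default uniform,
$\alpha_0 = \beta_0 = 1$; no other prior is canonical for this update),
each treated patient's posterior is

$$Pw_i \sim \mathrm{Beta}\!\left[\alpha_0 + \textstyle\sum_j s_j w_j,\;
\beta_0 + \textstyle\sum_j (1 - s_j) w_j\right],$$

and the point estimate is the posterior mean. One consequence is worth
stating plainly: because $\sum_j w_j = 1$, the posterior mean is
$(\alpha_0 + \bar{s})/(\alpha_0 + \beta_0 + 1)$ — with the uniform prior
every $Pw_i$ lives in $(1/3, 2/3)$, shrunk toward $1/2$ by design. The
per-gene posteriors inherit this compression.

Per gene $g_k$, carrier and non-carrier posteriors accumulate the
$Pw_i$ of treated carriers and non-carriers as fractional Bernoulli
outcomes (mean-propagation; the posterior spread of each $Pw_i$ is not
forwarded — only its mean is defined by the update equations). A gene is
**decided causal** when the equal-tailed 95% credible intervals separate,
and genes are ranked by the separation margin
$\mathrm{lower}_{g_k=1} - \mathrm{upper}_{g_k=0}$, which is monotone in
the decision rule; ties break by carrier count, then name. The "95%
confidence interval" of a Beta posterior is read as the credible
interval — the posterior is the only distribution in play.

Because of the shrinkage above, full interval separation demands
overwhelming evidence: on the simulation benchmark no gene is *decided*
even at $n = 4000$, yet the separation *ranking* recovers essentially
all planted modulators from $n \approx 1500$. The decision flag is a
high-specificity certificate (it fires on effectively zero genes under
permuted-treatment nulls); the ranking is the discovery instrument.

### Inverse propensity weighting

The marginal per-gene update can reweight each carrier by
$1/(\hat{e}(V_i)\hat{e}(G_i))$ on the win side and by the complementary
product on the loss side. Verbatim, these pseudo-counts sum to multiples
of the carrier count, so both intervals become overconfident; a
stabilized mode rescales the increments to total the number of
contributing carriers (means unchanged). Both are implemented and
tested. The default pipeline (`use_ipw = FALSE`) uses the unweighted
accumulation: in the benchmark the confounders are hidden from $V$ and
$G$, so observed-covariate IPW removes no bias while the verbatim
variant destroys the conservativeness of the decision rule under the
null. Propensities are clipped to $[0.05, 0.95]$ before weighting
(`propensity_clip`), the standard guard against positivity violations.

## 4. The simulator and what passing tests mean

`simulation_scenario()` defines the benchmark conditions: $n$ patients;
300 i.i.d. Bernoulli(0.1) binary genes of which 10 (drawn without
replacement) are causal; 10 hidden standard-normal confounders; age
$\sim N(60, 10^2)$ years and sex $\sim$ Bernoulli(0.5); treatment
assigned by a logistic model with log-odds $0.3$ per confounder unit;
exponential event times with log-hazard

$$\log h_i = \log(0.02) + 0.03\,(age_i - 60) + 0.2\,sex_i +
0.3\,\textstyle\sum_m C_{im} + T_i\,\gamma \sum_{k \in truth} g_{ik},$$

$\gamma = -1$ per carried causal gene (treated carriers roughly halve
their hazard, and only treated carriers), administrative censoring at 60
time units ($\approx$ two-thirds observed events). The generator is a
deterministic function of its seed. Defaults were chosen once, on
power-analysis grounds, so that the comparator's discovery curve rises
over the $n = 100\ldots4000$ grid rather than saturating immediately —
i.e., a strong-but-confounded signal regime.

What the simulator does *not* emulate: correlated genes
(linkage/co-mutation), non-proportional hazards, informative censoring,
covariate-dependent censoring, gene–gene interactions, and measured
confounding (the confounders are withheld from both algorithms).
Passing benchmarks therefore demonstrate internal correctness and the
claimed sample-efficiency ordering under this generative family; they do
not certify performance on real cohorts, where all of the above occur.

**Five-fold evaluation.** Cross-validation has no canonical meaning for
an unsupervised discovery run. Here the cohort is split into five
disjoint folds by stratified (treatment × event) assignment and the
discovery runs once per fold on the *complement* (4/5 of the data), the
standard training-split reading; precision@10 against the planted truth
is averaged over folds. Running on the 1/5 folds themselves is available
(`scheme = "fold"`) but conflates the per-run sample size with $n/5$,
which makes the grid's $x$-axis lie about what the algorithm saw.

## 5. The log-rank comparator

For each gene, treated carriers vs treated non-carriers by the standard
two-group log-rank statistic, after one 1:1 propensity matching pass
(clinical covariates, greedy nearest-neighbor on the logit with a
0.2-SD caliper, ascending-id tie-break for determinism), with BH step-up
control at FDR 0.05 (benchmark) or 0.01 (the conventional real-data
setting). The suggested list keeps rejections whose carriers fare
*better*, ranked by p-value.

Two small-sample facts shaped the implementation. The 1-df chi-squared
tail of the log-rank statistic is anti-conservative for rare genes
(measured at roughly twice the nominal far-tail mass at carrier:
non-carrier imbalance of 1:10), so genes with fewer than `min_carriers`
(default 10) carriers or non-carriers among the treated are reported as
untestable rather than tested on bad asymptotics. And false-discovery
control holds for the screen's actual output — the direction-filtered
suggestion list (empirical FDR 0.03 at nominal 0.05 under the global
null at $n = 300$) — while the undirected rejection mask alone inherits
the tail inflation; this is a property of the chi-squared approximation,
not of the BH procedure.

## 6. Numerical choices and degenerate inputs

* Boltzmann weights subtract the per-row minimum distance before
  exponentiating, so tiny bandwidths concentrate mass on the
  nearest counterpart(s) (ties split equally) instead of underflowing to
  0/0.
* Ridge fits approach the small target penalty through a descending
  ten-step lambda path with warm starts; a lone tiny lambda makes the
  wide Cox solver fail outright on some cohorts. If the solver truncates
  the path, the smallest lambda it reached is used, with a message.
* If the partial-likelihood fit fails entirely, the basal model falls
  back to a logistic regression of event-by-median-follow-up, loudly.
* Constant covariate columns are dropped with a warning (coefficient 0);
  an all-constant block yields an intercept-only propensity at the
  empirical treatment rate.
* Degenerate pools fail loudly rather than silently: single-arm cohorts,
  fitting pools with fewer than two events, zero matches within the
  caliper, and scenarios generating no events or one arm are all errors
  naming the cause. A treated patient with no comparable counterpart
  keeps its prior and is flagged (`no_evidence`), excluded from per-gene
  accumulation.
* A gene with zero carriers among evidence-bearing treated patients gets
  the bare prior on the carrier side and is flagged; it can never rank
  above a gene with evidence.
* Missing *clinical* values survive loading and are removed only by the
  explicit complete-case filter (which reports input = omitted +
  retained); missing *genetic* values are a hard error — the update has
  no missing-$G$ pathway, and a silent zero would fabricate a
  non-carrier.

## 7. Problem sizes used by the shipped checks

The test suite exercises the full pipeline at $n$ up to 4000 with 300
genes (the benchmark conditions), property checks on pools of at most
10×10 pairs against brute-force oracles, 200-replicate null studies at
$n = 300$ with 30 genes, and 20-permutation nulls at $n = 200$ with 50
genes. The acceptance script reruns the five-fold benchmark at
$n = 4000$ and $n = 1500$ for both methods plus the permutation null;
all random draws derive from the single `--seed` argument. These sizes
were chosen to keep a full run in the low minutes on one CPU while
leaving the Monte Carlo error of every asserted comparison well below
the asserted margin.

## 8. Known limitations

* Validity of the causal reading rests on no-unmeasured-confounding
  given the matched covariates; the benchmark quantifies robustness to
  *these* hidden confounders, not to arbitrary ones.
* The win probability is shrunk toward $1/2$ by construction (one
  pseudo-observation per patient); the decision rule is correspondingly
  conservative, and discovery in practice relies on the ranking.
* Only positive modulators are searched; the harm direction is symmetric
  but unvalidated, and multi-gene interactions are out of scope.
* Eq.-style IPW on observed covariates cannot correct hidden
  confounding and is off by default; doubly-robust estimators are not
  provided.
* The generator's exponential, proportional-hazards world is the
  benchmark's, not the world's.
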