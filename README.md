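# csearch

Discovery of genes that **positively modulate treatment effect** from
right-censored survival cohorts.

Most gene alterations catalogued in cancer genomics are prognostic at
best; the clinically decisive question is *causal*: does carrying
alteration `g_k` make the treatment work better? Classical per-gene tests
(log-rank + multiple-testing correction) only measure association and
need large cohorts to gain power over hundreds of genes. `csearch`
implements C-search, a causal-discovery algorithm built on the potential
outcome framework and Bayesian updating, for exactly this setting: many
binary gene covariates, few patients, censored survival outcomes,
observational treatment assignment.

## The method in brief

For a treated patient `i` the untreated potential outcome is not
observable; it is borrowed from similar untreated patients
("pseudo-counterfactuals"). Each treated/untreated pair `(i, j)` is
scored as a censoring-aware Bernoulli trial

```
s_j = 1  if Y_i(T=1) > Y_j(T=0),   s_j = 0 if the reverse,
```

with Wilcoxon–Mann–Whitney comparability rules deciding which censored
pairs are scorable. Similarity between patients is measured through
*basal functions* — ridge-penalized Cox risk scores `P(Y|V)` (clinical
block) and `P(Y|G)` (genetic block) — and converted into Boltzmann
weights over the untreated pool,

```
W(i,j) ∝ exp( −|P_i − P_j| / kτ ),        Σ_j W(i,j) = 1.
```

The combined clinical × genetic weights accumulate each patient's win/loss
evidence into a conjugate Beta posterior for the individual **win
probability** `Pw_i` — the chance that treated patient `i` outlives a
matched untreated counterpart:

```
Pw_i ~ Beta[ α0 + Σ_j s_j · W^V(i,j) · W^G(i,j),
             β0 + Σ_j (1 − s_j) · W^V(i,j) · W^G(i,j) ].
```

Per gene, the win probabilities of treated carriers (`g_k = 1`) and
non-carriers (`g_k = 0`) are pooled into two Beta posteriors
(optionally inverse-propensity weighted by `ê(V)·ê(G)`), and a gene is
**decided causal** when the 95% credible intervals separate: the lower
bound of `P("win"|g_k=1)` exceeds the upper bound of `P("win"|g_k=0)`.
Genes are ranked by this separation margin.

The package also ships the conventional comparator (per-gene log-rank
among treated carriers vs non-carriers after propensity matching, with
Benjamini–Hochberg FDR control), a survival-cohort simulator with
planted treatment modulators and hidden confounders, and the evaluation
surfaces (precision against planted truth, five-fold evaluation,
discovery-vs-sample-size curves, Kaplan–Meier policy comparisons).

## Worked example

Simulate a 2000-patient cohort with 300 binary genes, 10 of which are
planted positive treatment modulators, plus 10 hidden confounders that
push both treatment assignment and hazard; then run both discovery
methods against the planted truth:

```r
library(csearch)

sim <- simulate_cohort(simulation_scenario(n = 2000, seed = 42))
res <- run_csearch(sim$cohort)
res
#> C-search result: 300 genes over 2000 individuals (977 treated used)
#>   decided causal: 0; suggested top-10:
#>   g211, g201, g197, g254, g271, g289, g239, g246, g280, g092
precision_at_k(res$suggested, sim$truth, 10)
#> [1] 10

head(res$per_gene[order(-res$per_gene$separation),
     c("gene", "mean_carrier", "mean_noncarrier", "separation", "n_carriers")], 3)
#>      gene mean_carrier mean_noncarrier separation n_carriers
#> g211 g211        0.603           0.535    -0.0640         94
#> g201 g201        0.597           0.536    -0.0713         93
#> g197 g197        0.583           0.536    -0.0752        116

lr <- discover_logrank(sim$cohort, fdr = 0.05)
precision_at_k(attr(lr, "suggested"), sim$truth, 10)
#> [1] 5
```

All ten suggestions of C-search are planted modulators
(`mean_carrier ≈ 0.60` vs `mean_noncarrier ≈ 0.54`: treated carriers
win their counterfactual comparisons more often), while the log-rank
screen at the same sample size recovers five. No gene reaches full
credible-interval separation at this evidence level (`decided causal: 0`,
separations still negative) — the ranking, not the hard decision, drives
discovery at moderate `n`; see the methods vignette.

Real data enter through delimited text: `read_clinical_table()` (with
declared value codings such as `"1:DECEASED"`), `read_mutation_matrix()`
or `maf_to_matrix()`, `filter_complete_cases()`, and `make_cohort()`.
A command-line front end covering simulate / discover / baseline /
evaluate is installed at `system.file("cli/csearch.R", package = "csearch")`.

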