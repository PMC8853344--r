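---
title: "Linking an environmental exposure to urban features and wellbeing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking an environmental exposure to urban features and wellbeing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

lumenet implements a two-step procedure for population studies that ask
whether a scalar environmental exposure — here nighttime light emission
(NLE) measured on the satellite digital-number (DN) scale 0–63 — varies
together with a block of urban-feature measures and a block of
individual wellbeing items, and whether the conditional-dependence
network linking environment and symptoms differs between high- and
low-exposure strata.

## Step 1: multi-view sparse canonical correlation

Three views are analysed jointly: the exposure (NL, one column),
category scores of urban features (UF), and wellbeing items (IW). All
views are residualized on covariates, z-normalized, and the urban block
is reduced to one score per category (below). Writing $X_k$ for the
standardized view matrices and $w_k$ for per-view weight vectors, the
solver maximizes the summed pairwise cross-covariance

$$\max_{w_1,\dots,w_K} \sum_{k<l} \frac{w_k^\top X_k^\top X_l\, w_l}{n-1}
\quad\text{s.t.}\quad \lVert w_k\rVert_2 \le 1,\;\; \lVert w_k\rVert_1 \le c_k,$$

the sum-correlation criterion of penalized multi-set CCA on
standardized data. Block coordinate ascent updates one view at a time;
the update for view $k$ is the exact maximizer
$w_k = S(v_k,\delta)/\lVert S(v_k,\delta)\rVert_2$ with
$v_k = \sum_{l\neq k} X_k^\top X_l w_l/(n-1)$, soft-threshold $S$, and
$\delta \ge 0$ found by bisection as the smallest value meeting the L1
budget. Because each block update is exact, the objective is monotone
non-decreasing; the trajectory is recorded and asserted in the tests.
Budgets live in $[1, \sqrt{p_k}]$ — below 1 no unit-norm vector is
feasible, above $\sqrt{p_k}$ the constraint is vacuous. Initialization
is deterministic (leading singular vector of the concatenated
cross-covariance blocks, first nonzero entry positive), so the solver
needs no seed. Reported statistics are the three pairwise Pearson
correlations of the view scores and their mean. When the exposure view
has one column its weight is fixed to $+1$ by flipping all views
together, which leaves every pairwise term unchanged.

### Stability selection with random sparsity

Variable selection repeats the fit on `n_trials = 1000` half-samples
(50% subsampling without replacement, re-standardized per subsample),
drawing the budget $c_k \sim \mathrm{Uniform}[1, \sqrt{p_k}]$
independently per view and trial. A variable is *stable* when its
weight is nonzero (|w| > 1e-12) in strictly more than 75% of trials.
The budget distribution is a design choice exposed as a pluggable
`budget_sampler`; uniform over the whole feasible range is the default.
Note one consequence we document deliberately: when the drawn budget
exceeds the attainable L1/L2 ratio of the gradient, the soft threshold
is zero and *every* variable is momentarily nonzero, so null-variable
frequencies are far above zero (typically 0.5–0.65 in our simulated
designs) — the 0.75 rule is what separates them from signal variables.

### Validation

The final model is an unpenalized refit (`refit_unpenalized()`,
budgets at $\sqrt{p_k}$) on the stable variables of the training split;
its weights are applied unchanged to the hold-out split
(`project_holdout()`), which is preprocessed with *training*
residualization coefficients, z-scoring moments and category
components — any other choice leaks the hold-out. Significance uses
permutations that break cross-view links by independently permuting the
row order of every view except the first. On the training set the refit
is rerun per permutation (`mode = "refit"`), because the observed
statistic is itself the result of an optimization; on the test set the
weights are fixed (`mode = "fixed_weights"`). P-values use the add-one
convention $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$ and are
never zero. Rerunning stability selection inside each training
permutation would multiply the cost a thousand-fold and is not done.

## Feature reduction

Categories group raw urban measures (a named-list map). Per category,
the first principal component of the members' correlation matrix is
computed; its sign is chosen so the majority of loadings are positive
(ties: first member nonnegative). Members with a loading below 0.3 are
dropped and the component is refit on the survivors; we iterate this to
a fixed point so that every *retained* member's final loading really is
$\ge 0.3$ (a single drop-and-refit can leave a survivor just below the
cutoff). The category score is the projection onto the final unit
eigenvector, so its variance equals the first eigenvalue. "Loading"
defaults to the component loading $e_j\sqrt{\lambda_1}$ (the
member–component correlation, the conventional scale for a 0.3 cutoff);
`loading_type = "eigenvector"` applies the rule to raw eigenvector
entries instead. `refit = FALSE` gives the projection-on-original-PC
variant. Categories that lose every member are excluded with a warning;
single-member categories pass through with loading 1. Z-scores use the
sample (n−1) convention, recorded in the output metadata. Missing data
are not imputed: `drop_incomplete()` filters complete cases and logs
the count.

## Step 2: exposure-stratified networks

The test split is stratified into the top and bottom exposure quartiles
with $k = \lfloor 0.25\,n + 0.5\rfloor$ rows each (rank-based; this
reproduces 10,020 from 40,078; a strict-quantile alternative is behind
`method = "threshold"`; boundary ties follow stable row order).

Each stratum's Gaussian graphical model is selected the way the
familiar stepwise EBIC tool in network psychometrics does it:

1. a graphical-lasso path over `lambda_grid_size = 100` log-spaced
   penalties from $\lambda_{\max}$ (empty graph) down to
   $0.01\,\lambda_{\max}$, computed on the correlation matrix;
2. every distinct edge set on the path is refit as an *unregularized*
   Gaussian model (constrained MLE via the modified-regression
   algorithm) and scored by
   $\mathrm{EBIC}_\gamma = -2\ell + E\log n + 4\gamma E \log p$ with
   $\gamma = 0$;
3. greedy stepwise search: all single-edge additions and removals are
   scored by unregularized refit, the move that most decreases EBIC is
   accepted, until a local minimum. Ties within 1e-9 prefer removal,
   then the lowest edge index — determinism matters for reproducible
   reports.

Edge weights are partial correlations
$w_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$ of the final
unregularized fit, zeroed off the selected edge set. The C++ core keeps
a loose tolerance (2e-5) while *scoring* candidate models and refits
the selected model tightly (1e-10) — selection is driven by EBIC
differences orders of magnitude above the loose tolerance. Ordinal
symptom variables enter as numeric (Pearson); a correlation matrix
computed elsewhere (e.g. polychoric) can be supplied via `input_cor`.

The 1-step bridge expected influence of node $i$ is
$\sum_{j:\,\mathrm{comm}(j)\neq\mathrm{comm}(i)} w_{ij}$, keeping
signs. Bridge nodes are the top $\lceil 0.2\,p\rceil$ by value, with
boundary ties all included; an all-tied (e.g. empty) network is flagged
degenerate and the set is taken in roster order. Stability uses the
case-dropping bootstrap: for each drop proportion, networks are
re-estimated on subsamples and the node statistic is correlated with
its full-sample value; the CS coefficient is the largest proportion
whose 2.5% quantile of correlations stays at or above 0.7 (scanning
upward, stopping at the first failure). Correlations with a constant
statistic are reported as undefined rather than propagated as NaN.

The network comparison test pools rows, reassigns them to groups of the
original sizes, and re-estimates both networks per permutation with the
*same* estimator and hyperparameters as the observed fit. Statistics:
structure $M = \max_{i<j} |w^a_{ij} - w^b_{ij}|$ and global strength
$S = \left|\sum_{i<j}|w^a_{ij}| - \sum_{i<j}|w^b_{ij}|\right|$, with
add-one p-values. Inside the permutation loop the default estimator is
the glasso-path + EBIC-refit model (`stepwise = FALSE`): the stepwise
search multiplies cost by roughly the edge count and is
disproportionate inside 1000 permutations, and regularized estimation
inside the comparison test is the norm in this literature. The observed
fit inside `network_comparison_test()` uses the identical settings, so
the permutation distribution is exchangeable with the observed
statistic; stepwise can be switched on for both at once.

## The synthetic-data generator

`generate_multiview()` emulates the *structure* of large
population-cohort data: one exposure on the DN scale, 44 urban-feature categories
of 6 measures each (≈275 raw measures), 23 ordinal wellbeing items, and
covariates (age-like, gender-like, a five-level population-density
category, an assessment-centre factor). One standard-normal latent
factor $z$ is shared: the exposure is $a z + \varepsilon$ plus a
covariate mix, affinely rescaled to $[0, 63]$; signal measures are
$b z + \sqrt{\rho}\,g + \sqrt{1-\rho}\,\varepsilon$ with a
category-shared factor $g$; signal wellbeing latents are
$w z + \text{covariates} + \varepsilon$, discretized at equiprobable
thresholds into `ordinal_levels = 4` levels (ordinal items are treated
as numeric downstream — UK-style Likert coding, no measurement model is
claimed). Covariates confound exposure and wellbeing, so
residualization is doing real work in the tests.

Default effect sizes (`a = 0.45`, `b = 0.10` per measure, `w = 0.22`)
were fixed once by a small analytic calibration: they put the planted
variables inside the stability-selection regime (selection frequency
clearly above 0.75) and null variables clearly below it at the test
scale (n = 5000, 200 trials), and they produce canonical correlations
of roughly 0.15–0.25 — the magnitude typical of population-scale
exposure studies. Category scores and items relate to each other *only*
through $z$, so conditional dependencies among stable variables are
deliberately weak; the end-to-end pipeline on multiview data therefore
yields sparse, near-null step-2 networks at desk scale. The planted
network structure lives in `generate_stratified()`: two
multivariate-normal strata share a base precision matrix (unit
diagonal, within-community chains at partial correlation 0.25, three
cross-community edges at 0.10), and the high stratum adds
`stratum_edge_shift = 0.15` to the cross-community partial
correlations, so its true global strength exceeds the low stratum's by
0.45. With the 7+5 roster the planted cross edges are (PV, Dpr),
(DS, Dis), (DE, Trd). Precision matrices are validated for positive
definiteness and rejected with a diagnostic otherwise; inverting the
constructed covariance reproduces the planted partial correlations to
1e-10 by construction.

What the generator does *not* emulate: spatial structure of nightlight
rasters, geographic coordinates, realistic marginal distributions of
the urban measures, item-level measurement models, or missingness.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability of planted structure — not that the package would
reproduce any particular cohort's coefficient values.

## Problem sizes and seeds used by the test suite

All randomness flows through explicit seeds; the pipeline derives named
substream seeds from one master seed and the report is bit-reproducible
from config plus seed. The test suite runs the stability-selection
recovery at n = 5000 with 200 trials; permutation calibration with 200
replicates of 200 permutations; NCT size with 500 replicate pairs
(n = 1000 per group, 200 permutations, a 4+3-node network — size under
exchangeability does not depend on the roster) and NCT power with 100
replicates (n = 2000 per group, the 12-node roster, planted shift
0.15). The acceptance script runs the full pipeline at n = 12,000 with
300 trials and 300 permutations, and a stratified-network analysis at
n = 2000 per stratum. These sizes are the package's chosen
desk-scale operating points; the procedures themselves scale to cohort
sizes unchanged.

## Known limitations

* The msCCA objective is the sum-covariance criterion; the source
  literature names the method without writing its objective, and other
  normalizations (e.g. deflation for further components) are out of
  scope — only the first canonical component is provided.
* EBIC model selection with $\gamma = 0$ is BIC; consistency arguments
  assume $n \gg p$, which holds in the intended regime (dozens of
  nodes, thousands of rows).
* The NCT's structure statistic is the maximum edge difference; with
  very sparse networks it can coincide with the strength difference
  (one differing edge), which is expected behaviour, not an error.
* Polychoric correlations are accepted but not computed.

```{r}
library(lumenet)
report <- run_pipeline(
  synth = synth_config(n_participants = 4000, seed = 1),
  control = pipeline_control(n_trials = 300, n_perm = 300,
                             n_boots = 100, seed = 1))
report
```
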