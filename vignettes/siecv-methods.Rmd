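---
title: "Heterogeneity-aware prediction modelling with stepwise internal-external cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware prediction modelling with stepwise internal-external cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siecv)
```

## The problem

Clinical prediction models are increasingly developed on clustered
individual-participant data: pooled studies, multi-center registries, or
electronic health records grouped by hospital or region. A model that fits
such a data set well on average can still predict poorly in any particular
setting, because intercepts, predictor effects, covariate distributions and
hence model performance genuinely differ between clusters. Conventional
development ignores this and defers the problem to post-hoc local
recalibration.

This package builds the assessment of between-cluster transportability into
model development itself. The splitting unit is the cluster, not the row:
each cluster is held out once, the model is built on the remaining clusters,
and its performance in the hold-out cluster is recorded with a standard
error. The K hold-out estimates are then combined by random-effects
meta-analysis, which separates the average performance from its
between-cluster spread, and a stepwise selection engine uses a configurable
combination of the two to decide which candidate predictors earn their place.

## The two-stage model

Within cluster $k$, outcomes follow a cluster-specific logistic model

$$\Pr(y_{k,j} = 1) = \mathrm{expit}\Big(\alpha_k + \sum_{p} \beta_{p,k}\, x_{p,k,j}\Big).$$

Stage 1 fits this model in each cluster separately. Because some clusters
are small (and some predictor patterns separate), the fits use Firth's
Jeffreys-prior penalization, which keeps estimates and standard errors
finite under separation and removes the first-order small-sample bias. The
penalty also shrinks the intercept, which distorts the average predicted
risk, so the intercept is afterwards re-estimated without penalty, holding
the slopes fixed as an offset; after that correction the mean fitted
probability equals the observed event rate in the fitting cluster.

Stage 2 pools each coefficient across clusters with a univariate
random-effects meta-analysis: cluster-specific true coefficients are assumed
normal around a common mean with between-cluster variance $\tau^2$, weights
are $w_k = 1/(\widehat{se}_k^2 + \hat\tau^2)$, and confidence intervals use
the Hartung–Knapp variance with a $t_{Q-1}$ reference distribution, where
$Q$ is the number of estimates actually pooled ($K-1$ inside the
cross-validation loop, $K$ for the global model). The spread of a
coefficient in a *new* cluster is summarized by the approximate prediction
interval $\hat\mu \pm t_{Q-2}\sqrt{\hat\tau^2 + \mathrm{var}(\hat\mu)}$,
which uses the conventional variance $1/\sum w_k$.

The two-stage layout is also what makes the search affordable: every
cluster is fit once per candidate model, and the per-hold-out development
coefficients are just re-pooled combinations of those cached fits.

### Choice of $\tau^2$ estimator

`REML` is the default, with an automatic fall-back to DerSimonian–Laird if
the restricted likelihood cannot be maximized; the estimator actually used
is always recorded in the output. Paule–Mandel and a fixed-effect option are
available. With fewer than about ten clusters no estimator is reliable; the
intervals are then honest about uncertainty but $\hat\tau$ itself is noisy.

## Hold-out performance

Four metrics are computed in each hold-out cluster, each with a standard
error so it can be meta-analyzed like a coefficient:

* **MSE / Brier score** — mean squared difference between outcome and
  predicted probability. This is the metric the selection engine optimizes.
* **Calibration slope** — slope of a Firth logistic regression of the
  outcome on the linear predictor; 1 is ideal, below 1 means predictions
  are too extreme.
* **Calibration-in-the-large** — intercept of an unpenalized logistic model
  with the linear predictor as fixed offset (the standard recalibration
  framework); 0 is ideal, positive means observed risk exceeds predicted.
  The sign convention and the offset-model definition are recorded in the
  output because other definitions (difference of mean logits) circulate.
* **c-statistic** — exact concordance over all case–control pairs with ties
  counted half, computed via midranks; the Hanley–McNeil closed form gives
  the SE. Pooling can be done on the raw scale (default) or on the logit
  scale with delta-method SEs.

Clusters with fewer than two events or two non-events cannot support the
regression-based metrics; these are returned flagged rather than fitted,
and flagged values are excluded from pooling. An intercept-only model has a
constant linear predictor, for which the calibration slope is
unidentifiable; that case is flagged the same way.

## Aggregated losses and the stepwise engine

Let $\hat Z_{h}$ be the hold-out MSE in cluster $h$. The engine minimizes
one of:

| family | definition | emphasis |
|---|---|---|
| mean | $\tfrac1K \sum_h \hat Z_h$ | average only, clustering ignored |
| re | $\lambda \hat Z^{RE} + (1-\lambda)\hat\tau$ | weighted trade-off |
| sd | sample SD of the $\hat Z_h$ (K−1 denominator) | spread, clusters equal |
| gini | mean absolute difference over all pairs | spread, nonparametric |

In the `re` family, $\hat Z^{RE}$ is the random-effects pooled MSE and
$\hat\tau$ its between-cluster SD (the SD, not the variance, so both terms
share the units of the metric). $\lambda = 1$ optimizes performance in an
average cluster, $\lambda = 0$ purely minimizes heterogeneity, and the
default $\lambda = 1/2$ weighs them equally. Tuning $\lambda$ by nested
resampling is out of scope; it is a prespecified scientific weight, not a
fitted parameter.

Forward selection starts from the intercept plus any forced terms (cycle
0), scores every remaining candidate by a full cross-validation pass, keeps
the argmin, and repeats until the best extension no longer improves the
loss (the previous model is returned) or candidates run out. Ties are
broken by candidate order, which makes the whole procedure deterministic:
identical data and configuration reproduce the trace byte for byte. The
backward variant starts from the full model and removes terms instead.
Candidate scoring uses the MSE only; the other metrics are computed for
each cycle's selected model, from the already-cached predictions.

The stopping comparison is implemented exactly as "greater or equal", with
an optional minimum-improvement margin (default 0). An `interaction_guard`
option enforces the convention that an interaction may only enter once its
constituent terms are included, and locks those constituents against
backward removal; it is off by default because published models do include
bare interactions when prespecified.

## The global model and shrinkage

After selection, the final model is refit on all clusters (no hold-out) by
the same two-stage pooling. Because the greedy search itself risks
overfitting, the slopes are multiplied by the summary calibration slope of
the final cross-validation cycle, and the summary calibration-in-the-large
is added to the intercept; both the shrunken and unshrunken coefficient
sets are reported. Wrapping the entire selection in an outer bootstrap
would account for the search more fully but is deliberately not performed
here. Note that even a well-chosen model usually still needs a local
intercept update in genuinely new settings; the prediction interval of the
calibration-in-the-large says how much.

## Design matrix conventions

Terms are named transformations of base columns: identity, scaling by a
constant (e.g. age/25, which only rescales the coefficient), natural log
(strictly positive inputs enforced), squaring after within-cluster
centering, and elementwise-product interactions which may reference other
terms. Within-cluster centering statistics are always computed from the
data the design is built on, so a hold-out cluster is centered with *its
own* means: a deployed model cannot know development-cluster means for a
new cluster, and centering is a per-cluster operation by construction.
Consequently, removing whole clusters commutes with design building, while
removing rows within a cluster changes that cluster's centered terms; both
behaviors are asserted in the tests.

## The synthetic-data generator

The generator draws from exactly the model class the method assumes:
cluster intercepts $\alpha_k \sim N(\mu_\alpha, \sigma_\alpha^2)$,
cluster-specific effects $\beta_{p,k} \sim N(\mu_{\beta,p}, \tau_p^2)$,
binary covariates with logit-normal cluster-level prevalences, continuous
covariates with normally shifted cluster means, Bernoulli outcomes. Every
drawn parameter is returned alongside the data, and generation is a pure
function of the configuration (including its seed).

The `dvt_like_preset()` emulates the scale of a multi-study diagnostic
IPD set: 11 clusters with Poisson sizes around 910 (about 10 000
participants), three binary predictors with prevalences 0.083 / 0.301 /
0.111, common effects (0.98, 1.27, 0.55), effect heterogeneity (0.35,
0.15, 0.12), $\sigma_\alpha = 0.5$, and $\mu_\alpha = -2.18$, solved
once by numerical integration so the marginal event rate is close to
0.19. What the generator deliberately does **not** emulate: missing data
and imputation, categorical predictors with more than two levels,
informative cluster sizes, and covariate correlation structure. Tests that
pass on generated data therefore demonstrate correctness of the machinery
under the assumed model class, not robustness to those real-data features.

```{r preset-example}
sim <- generate_clustered(dvt_like_preset(seed = 1))
sim$data
```

## Numerical choices

* Firth fits: Newton–Raphson on the modified score with step-halving;
  convergence requires max absolute score and step below $10^{-6}$, capped
  at 100 iterations. Slope SEs come from the inverse penalized information;
  the re-estimated intercept carries the SE of the one-parameter offset
  model, matching the estimation actually performed.
* REML maximizes the restricted likelihood on $\tau^2 \in [0,
  10\cdot\mathrm{var}(\text{values})]$ with a golden-section search and an
  explicit boundary comparison at 0; Paule–Mandel solves its moment
  equation by bisection to $10^{-8}$.
* Prediction intervals require at least three pooled estimates; with fewer
  they are reported as missing, not errors. Simulation (Q = 15 clusters,
  normal effects, heterogeneity dominating the within-cluster error) puts
  the empirical coverage of the approximate 95% interval near 94%; when
  within-cluster error dominates, the approximation is mildly
  anticonservative (coverage nearer 93%), a known property of the
  $t_{Q-2}$ plug-in formula.
* Problem sizes in the test-suite simulations (e.g. 10 clusters of 300 for
  selection-recovery runs, 100–500 replicates for calibration checks) are
  chosen so the full suite completes in a few minutes while keeping
  Monte-Carlo error well below the asserted margins.

## Worked example shipped with the package

The package ships the published per-cluster coefficient and hold-out
performance estimates of an 11-study deep-vein-thrombosis diagnostic model
(`dvt_cluster_coefficients()`, `dvt_iecv_performance()`), so the pooling
stage of the workflow can be reproduced without the restricted
participant-level data:

```{r dvt}
tab <- dvt_cluster_coefficients()
pool(tab$malignancy, tab$malignancy_se, method = "DL",
     labels = as.character(tab$cluster))
```

Because the shipped per-cluster inputs are rounded to two decimals, pooled
summaries can differ from summaries computed on unrounded estimates by up
to about one unit in the last printed digit.

## Known limitations

* Two-stage estimation requires every development cluster to support its
  own fit; very small clusters are excluded from development (with a
  warning) rather than stabilized by a one-stage mixed model, which is out
  of scope.
* Missing data must be handled upstream; the loader rejects incomplete
  tables outright.
* The heterogeneity estimate $\hat\tau$ — and every loss built on it — is
  imprecise with few clusters; with K < 10 treat the `re`, `sd` and `gini`
  losses as ordering heuristics rather than calibrated quantities.
* The greedy search is sequential and makes no claim of finding the
  globally optimal subset; forward and backward runs agree in
  clear-signal regimes but need not in general.
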