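---
title: "Calibrating mixed-format bifactor item response models from linked booklets"
author: "bifactorirt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating mixed-format bifactor item response models from linked booklets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifactorirt)
```

## The measurement problem

Large-scale educational assessments often conceive of an ability — here,
mathematical ability — as one broad construct expressed through several
content domains (computation, spatial reasoning, data analysis, logical
reasoning, problem solving). Domain subscores estimated with a between-item
multidimensional IRT (MIRT) model are invariably highly correlated, because
every domain shares the common core; a unidimensional (UIRT) model captures
that core but discards what is distinctive about each domain. The
full-information item bifactor (FIBF) model separates the two sources
explicitly: every item loads on a *general* factor $\theta_0$ and on exactly
one of $D$ mutually orthogonal *specific* factors $\theta_v$.

For a dichotomous item $j$ in domain $v$ the model is the bifactor extension
of the two-parameter logistic,
$$P(X_{ij}=1 \mid \theta_{0i}, \theta_{vi}) =
  \mathrm{logit}^{-1}(a_{0j}\theta_{0i} + a_{vj}\theta_{vi} + b_j),$$
and for a graded item with $K_j$ ordered categories the bifactor graded
response model,
$$P(X_{ij} \ge k \mid \theta_{0i}, \theta_{vi}) =
  \mathrm{logit}^{-1}(a_{0j}\theta_{0i} + a_{vj}\theta_{vi} + b_{kj}),
  \qquad k = 1, \dots, K_j - 1,$$
with $P(X \ge 0) = 1$ and $P(X \ge K_j) = 0$; category probabilities are
differences of adjacent cumulative curves. UIRT is the constrained case
$a_{vj} \equiv 0$; between-item MIRT is $a_{0j} \equiv 0$ with the $D$
factors allowed to correlate through a unit-diagonal matrix
$\Sigma_\theta$.

### Intercept orientation

Because the intercepts enter the cumulative logits with a *positive* sign,
validity (non-negative category probabilities) requires $b_{1j} > b_{2j} >
\dots$ — the canonical stored order in this package is strictly
*decreasing*. The simulator draws graded intercept pairs as $u_1 \sim
U(-2, 0)$, $u_2 \mid u_1 \sim U(u_1, u_1 + 2)$ and stores
$b_1 = \max(u_1, u_2)$, $b_2 = \min(u_1, u_2)$: the marginal distributions
of the pair are preserved and every simulated item is valid. (The opposite
sign convention, with increasing thresholds, generates identical data; only
the labelling differs.)

## Missing-by-design data

The test administration is an incomplete balanced block (linked booklet)
design: the 60-item pool is split into 6 blocks of 10 items (6 dichotomous
+ 4 three-category), booklet $i$ is the union of blocks $i$ and $i+1$
(cyclically), each item appears in exactly two booklets, adjacent booklets
share a full block, and the 2000 examinees are allocated round-robin, so
every booklet is answered by at least 300 persons and every item by at
least 600. Missingness is determined entirely by booklet assignment
(missing at random by design), so the observed-data likelihood simply
skips unadministered cells.

```{r design}
d <- build_design()
d
```

### Domain-to-item allocation

How the five domains are distributed over the item pool is a genuine design
choice; assessments state only that the pool is "divided into five
dimensions". Two natural layouts are provided:

* **blocked** (default): 12 consecutive items per domain, so each booklet
  concentrates on two domains and each person answers many items per domain
  they see;
* **cyclic**: domains rotate item by item, so each booklet covers all five
  domains with four items each.

The layout matters for how sharply the three models are distinguished:
with blocked allocation the specific factors are well measured within
persons, the bifactor model's deviance advantage over between-item MIRT
(roughly 430 on average at the default scale) approaches the BIC penalty
difference between the two models (about 380 at N = 2000), and AIC,
SABIC and HQ recover the bifactor generating model essentially always
while BIC does so in most replications. Cyclic allocation dilutes each
person's specific-factor information over five domains; the deviance
advantage shrinks to roughly 260 and BIC then prefers the simpler MIRT
structure even when the bifactor model is true. The blocked default was chosen
because domain-homogeneous blocks are how booklets for such assessments
are typically assembled, and because it separates the three measurement
models most sharply; `build_design(domain_layout = "cyclic")` switches
layouts.

## Estimation

`irt_fit()` maximises the marginal likelihood by EM with fixed
Gauss–Hermite quadrature.

**Dimension reduction (FIBF).** Conditional on the general factor the
specific factors are independent across item groups, so the
$(1+D)$-dimensional integral in each person's marginal likelihood factors
into nested one-dimensional integrals:
$$L_i = \int \phi(\theta_0) \prod_{v=1}^{D}
  \left[ \int \phi(\theta_v) \prod_{j \in v,\ \mathrm{obs}}
  P_j(x_{ij} \mid \theta_0, \theta_v)\, d\theta_v \right] d\theta_0 .$$
On the discrete grid this identity is exact, and the package's reduced
E-step is tested to $10^{-8}$ against a brute-force $(1+D)$-dimensional
tensor-grid evaluation.

**Quadrature sizes.** 21 nodes for the one-dimensional grids (UIRT, and
both the outer and inner bifactor grids) and 5 nodes per dimension for the
5-D MIRT tensor grid (3125 points). The MIRT grid is transformed by the
*symmetric* square root of the current $\Sigma_\theta$; a triangular
(Cholesky) factor would leave the first dimension supported on only the
five raw node values and measurably degrade dimension-1 slope recovery,
whereas the symmetric root treats all dimensions alike.

**M-step.** Each item's expected complete-data log-likelihood is maximised
by Fisher scoring with step-halving (at most 25 inner iterations, gradient
tolerance $10^{-8}$); all parameters are box-constrained to $[-10, 10]$,
and a step that violates the intercept ordering makes a category
probability negative and is rejected by the line search, so canonical order
is preserved throughout.

**Ascent safeguards.** With the latent grid fixed, the item-parameter EM
update cannot decrease the (discretised) marginal log-likelihood. Two
updates lack that guarantee and are treated as proposals, confirmed by the
next E-step and rolled back if they lower the log-likelihood: (i) a
Ramsay-type extrapolation along the EM direction applied every third cycle,
and (ii) the MIRT correlation update $\Sigma_\theta \leftarrow N^{-1}\sum_i
E[\theta\theta' \mid x_i]$ (rescaled to unit diagonal, with slopes
absorbing the scale), which moves the transformed grid itself — the exact
EM ascent property does not transfer to a 5-node-per-dimension quadrature
approximation, and unguarded iteration can drift downhill. After two
rejected correlation proposals the matrix is frozen. The recorded
log-likelihood trace is therefore non-decreasing by construction, and the
default stopping rule is $|\Delta \ell| < 10^{-4}$ (at most 500 cycles).
The replication-study driver uses $10^{-3}$ and 300 cycles: at
$N = 2000$ the parameter movement between $|\Delta\ell| = 10^{-3}$ and
$10^{-4}$ is orders of magnitude below the Monte Carlo noise the study
measures, and the looser rule keeps a three-model, multi-replication study
tractable on one CPU.

**Identification.** Latent scales are fixed by standard-normal priors
(unit-diagonal correlation matrix for MIRT); after convergence any factor
whose slopes sum to a negative value is reflected, removing the sign
indeterminacy deterministically. Starting values are slope 1, intercepts at
(clipped) logits of observed cumulative proportions. Parameter counts for
the information criteria are $\sum_j (2 + K_j - 1)$ for FIBF,
$\sum_j (1 + K_j - 1)$ for UIRT, and $\sum_j (1 + K_j - 1) + D(D-1)/2$ for
MIRT; latent means and variances are fixed and not counted.

```{r fit, eval = FALSE}
sim <- sim_study("FIBF", build_design(), seed = 1)
fit <- irt_fit(sim$responses, "FIBF", domains = sim$design$items$domain,
               K = sim$design$items$K)
summary(fit)
head(predict(fit))          # EAP scores: general + specific factors
fit_indices(fit)            # AIC, SABIC, HQ, BIC
```

## Model comparison

`fit_indices()` implements the four standard criteria,
$\mathrm{AIC} = -2\ell + 2p$,
$\mathrm{SABIC} = -2\ell + p\log\{(N+2)/24\}$,
$\mathrm{HQ} = -2\ell + 2p\log\log N$, and
$\mathrm{BIC} = -2\ell + p\log N$, with $N$ the number of *persons* (the
usual IRT convention; the criteria's source definitions are used because
the quantities themselves are standard). Note the four unit penalties are
not globally ordered in $N$: at $N = 2000$, $2\log\log N \approx 4.06$ is
*below* $\log\{(N+2)/24\} \approx 4.42$.

## What the simulator emulates — and what it does not

`sim_study()` implements the packaged study's generating conditions: FIBF truth with $a_0 \sim U(0.5, 2.5)$, $a_v \sim U(0, 1.5)$,
dichotomous $b \sim N(0,1)$, graded pairs as above, and
$\theta \sim MVN(0, I_6)$; MIRT truth with $a_v \sim U(0.5, 2.5)$ and
$\Sigma_\theta$ off-diagonals i.i.d. $U(0.4, 0.8)$ (redrawn whole until
positive definite, almost always immediately at $5 \times 5$); UIRT truth
with $a_0 \sim U(0.5, 2.5)$ and $\theta_0 \sim N(0,1)$. True item
parameters are redrawn every replication, so recovery summaries average
over parameter-sampling as well as estimation noise; a fixed-parameter mode
is available (`redraw_params = FALSE`).

The generator does *not* emulate several features of real assessment data:
guessing on multiple-choice items (no lower asymptote), differential item
functioning across subgroups, non-normal or multimodal ability
distributions, within-booklet position and fatigue effects, or
not-reached/omitted responses that are *not* missing at random. Passing
recovery and selection tests on the synthetic conditions therefore
demonstrates the estimator and the study pipeline, not robustness of the
model to those real-data complications.

## Recovery metrics

For each parameter class (general slope, each specific slope, pooled
intercepts), `armse()` averages the per-parameter RMSE across
replications, and `acor()` averages the per-replication Pearson
correlation between estimates and truths over the class. Both are checked
against naive double-loop implementations to $10^{-12}$. With specific
slopes drawn on $U(0, 1.5)$ (standard deviation $\approx 0.43$), a
replication-level truth–estimate correlation of $r$ implies an RMSE of
roughly $0.43\sqrt{1/r^2 - 1}$ for an unbiased estimator; the package's
slope recoveries are consistent with this relation.

## Problem sizes used by the test suite

The packaged study runs use the full data scale of the study
conditions ($N = 2000$, $M = 60$): the acceptance script fits the
correctly specified model with 10 replications for the bifactor and
unidimensional conditions and 5 for the MIRT condition; the test suite's
selection study fits all three models per replication (10 bifactor-truth
and 5 each of the other conditions) with the study stopping rule and an
EM cap of 150 cycles, ample for index comparisons whose model-to-model
gaps are two orders of magnitude larger than the remaining
log-likelihood movement. Smaller designs (`build_design()` is fully
configurable) are used for unit tests and smoke checks.

## Known limitations

* No item-parameter standard errors are produced.
* No guessing (3PL), nominal-response, or testlet structures.
* The MIRT estimator is deterministic quadrature EM; with many more
  dimensions a stochastic algorithm would be preferable.
* Quadrature grids are fixed (no adaptive recentering), trading a little
  efficiency for exact reproducibility.
* Domain-specific EAPs from the bifactor model measure what is *unique* to
  a domain; they are not domain scale scores (which would combine general
  and specific components).
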