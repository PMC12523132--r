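---
title: "Model and methods: Bayesian subgroup discovery for eGFR slope endpoints"
author: "slopehte"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopehte)
```

## The estimand and the longitudinal model

Chronic kidney disease trials increasingly use the 3-year *total eGFR slope*
as a surrogate endpoint: the average rate of eGFR change over a horizon
$T^\ast$ (3 years by default), combining a short *acute* phase right after
treatment initiation with the long-run *chronic* phase. eGFR trajectories are
modelled with a two-piece linear spline joined at a change point $t^\ast$
(default $1/3$ year, i.e. the fourth month, so that at least the baseline and
first follow-up visit inform the acute slope):

$$
Y_{ij} = (\alpha_0(x_i) + \alpha_i)
 + (\beta_0(x_i) + \beta_i)\,A_{ij}
 + (\gamma_0(x_i) + \gamma_i)\,C_{ij}
 + \tau_0(x_i)\,\mathrm{trt}_i\,\frac{C_{ij}}{1-w}
 + \zeta_0(x_i)\,\mathrm{trt}_i\!\left(t_{ij} - \frac{C_{ij}}{1-w}\right)
 + \varepsilon_{ij},
$$

with acute basis $A_{ij} = t_{ij} - d_{ij}(t_{ij}-t^\ast)$, chronic basis
$C_{ij} = d_{ij}(t_{ij}-t^\ast)$, $d_{ij} = 1(t_{ij} > t^\ast)$,
$\varepsilon_{ij} \sim N(0, \sigma^2)$ and subject random effects
$(\alpha_i,\beta_i,\gamma_i)^\top \sim N(0, \sigma^2\Sigma)$. Writing the
treatment terms this way makes $\tau_0(x)$ directly the *total* treatment
effect on the $T^\ast$-year slope,
$\tau_0 = w\,\zeta_0 + (1-w)\,\nu_0$ with weight $w = t^\ast/T^\ast$ and
$\nu_0$ the chronic treatment effect; `nu_from_tau()` / `tau_from_nu()`
convert between the two parameterizations and `test-acceptance.R` checks the
algebraic identity to $10^{-12}$. The indicator uses the strict convention
$1(t > t^\ast)$; at $t = t^\ast$ both conventions give the same mean because
the chronic basis vanishes there.

The scaling of the random-effect covariance by $\sigma^2$ is kept exactly as
written because it yields conjugate inverse-gamma/inverse-Wishart updates for
$(\sigma^2, \Sigma)$.

## Informative dropout: the shared-parameter link

Dialysis, transplantation and death censor the eGFR series informatively:
subjects with lower levels and faster decline leave earlier. Dropout times
get a piecewise-exponential hazard with $K = 5$ steps anchored at the
quantiles of the observed event times (linear-interpolation sample
quantiles; the last level extends beyond the final knot), scaled by the
frailty

$$
z_i = \exp\{\lambda_0\,\mathrm{trt}_i + \eta_1 \alpha_i + \eta_2 \gamma_i\}.
$$

The acute random effect $\beta_i$ is deliberately excluded: the one or two
acute-phase visits carry almost no information about it. No baseline
covariates enter $z_i$ either, for identifiability. $\lambda_0$ receives the
same vague $N(0, 1000^2)$ prior as the other hazard parameters (the prior
list in the source only names $\lambda_{1..K}, \eta_1, \eta_2$; symmetry is
our choice).

## Covariate-dependent surfaces and the tree prior

Three surfaces are tree-structured: the expected baseline eGFR
$\alpha_0(x) = x^\top \mu^{(0)}_{\mathcal{BT}_0(x)}$ and the control chronic
slope $\gamma_0(x) = x^\top \mu^{(1)}_{\mathcal{BT}_1(x)}$ are *within-leaf
linear*, while the total treatment effect
$\tau_0(x) = \theta^{(2)}_{\mathcal{BT}_2(x)}$ is *piecewise constant*, which
is what makes the discovered subgroups directly interpretable. The acute
slope and acute treatment effect stay globally linear ($x^\top\mu^{(3)}$,
$x^\top\mu^{(4)}$): trees on the acute phase collapse to the root anyway for
lack of signal. Modelling $\alpha_0$ and $\gamma_0$ flexibly is not optional
decoration — a heterogeneous control slope that the model cannot express
leaks into $\tau_0$ and fabricates treatment-effect heterogeneity.

Each tree follows the classic Bayesian CART generating prior: a node at
depth $d$ splits with probability $c_0 (1+d)^{-d_0}$ ($c_0 = 0.95$,
$d_0 = 2$), split variables uniform over the eligible set and cutpoints
uniform over a *frozen grid* (deciles of each continuous covariate, 0.5 for
binary ones). Frozen grids make the tree space finite, so trees can be
compared and counted across runs. Two occupancy constraints are imposed
during sampling: at least `max(25, 2% of n)` subjects per leaf and both
treatment arms present in every leaf — without both arms a leaf effect
$\theta_j$ is not estimable. Routing sends ties left (`x <= cut`).

Remaining priors: all regression/hazard coefficients $N(0, \tau_{pr}^2)$
with $\tau_{pr} = 1000$ (the symbol clash with the treatment effect
$\tau_0(x)$ is resolved in this package by calling the prior scale
`prior_scale`); $\sigma^{-2} \sim \mathrm{Gamma}(a_0, b_0)$,
$a_0 = b_0 = 0.01$. The source text puts a Wishart prior of dimension
$2\times 2$ on $\Sigma^{-1}$ although $\Sigma$ is the $3\times3$ covariance
of $(\alpha_i, \beta_i, \gamma_i)$; we read that as a typo and use
$\mathcal{W}(3 + a_0,\, b_0^{-1} I_3)$, the minimal proper choice of
matching dimension.

## The round-trip sampler

One round-trip alternates two conditional steps, keeping only each step's
final state; `B2` round-trips give `B2` retained posterior draws.

**Shared-parameter step** (`update_sp_params()`, C++ kernel): `B1` inner
iterations of (i) per-subject random effects from their conjugate Gaussian
conditional given the longitudinal data, corrected by a Metropolis step for
the frailty factor (an independence proposal; acceptance is 1 when
$\eta = 0$); (ii) all regression coefficients jointly from their conjugate
Gaussian conditional; (iii) $\sigma^2$ and $\Sigma^{-1}$ from conjugate
inverse-gamma/Wishart conditionals; (iv) hazard parameters by componentwise
adaptive random-walk Metropolis (scales adapted toward 0.44 acceptance in
the first half of the inner chain only). Any ergodic kernel targeting this
full conditional would do; this one needs no gradient tuning and mixes well
because the coefficient block is drawn jointly.

**Tree step** (`update_trees()`, C++ kernel): for each of the three trees in
turn, `B1` birth/death Metropolis–Hastings moves. Birth picks a leaf
uniformly, then an eligible (variable, cutpoint) pair uniformly; death
collapses a uniformly chosen internal node with two leaf children; the
Hastings ratio accounts for the reverse move.

Two design choices here deserve emphasis:

1. *Random effects are marginalized, not conditioned on.* Conditioning tree
   moves on sampled random effects buries subtle treatment effects in the
   subjects' own slopes. Instead, the survival-likelihood × random-effect
   prior factor of every subject is Gaussianized at its mode (found by a
   one-dimensional Newton iteration — the frailty depends on the random
   effects only through $\eta_1\alpha_i + \eta_2\gamma_i$), after which the
   Gaussian longitudinal likelihood integrates in closed form. This is the
   rough-but-effective approximation that makes collapsed tree moves
   tractable.
2. *All coefficient blocks are integrated out of the move ratio, jointly.*
   Integrating only the moving tree's leaf coefficients while conditioning
   on the other blocks lets the global linear terms (notably the acute
   treatment effect $\zeta_0(x)$ and the control chronic slope) absorb
   roughly half of a step-shaped treatment effect, attenuating the marginal
   gain of the correct split below the prior's parsimony penalty. The joint
   Gaussian marginal over *all* blocks is exact given the Laplace tilt, is
   assembled from nine per-subject basis Gram scalars, and was verified
   against a dense matrix oracle to $10^{-8}$ (`test-sampler.R`). After each
   sweep all coefficients are redrawn jointly from the same collapsed
   conditional — which also fixes the slow $\theta\,|\,b$ mixing of frozen-
   tree refits.

The standalone `laplace_subject_marginal()` refines the expansion point: the
factor is Gaussianized (value, gradient, curvature matched) at the *joint*
posterior mode of the random effects rather than at the factor's own mode.
That costs nothing (a three-dimensional concave Newton solve, tolerance
$10^{-8}$, 50-iteration cap with a prior-mode fallback) and reduces the log
error versus adaptive Gauss–Hermite quadrature from $\le 0.09$ to
$\le 0.014$ at the study's operating conditions; it is exact when
$\eta_1 = \eta_2 = 0$. A residual third-order error in the frailty direction
is intrinsic to any Gaussianization of $\exp(as - ce^{s})$; the test suite
pins the achieved accuracy honestly rather than an aspirational one. Inside
the tree sweep the expansion stays at the prior mode because only there are
the Laplace ingredients independent of the regression coefficients — the
prerequisite for integrating all blocks jointly.

Initialization: root trees, ordinary-least-squares coefficients, residual
moments for $(\sigma^2, \Sigma)$, a constant-hazard fit for the baseline
levels, $\eta_1 = \eta_2 = 0$.

## Honest subgroup estimation

Tree structure chosen and effects estimated on the same data are
overfit-biased, so the workflow splits subjects 60/40 (stratified by arm so
leaves keep both arms): trees are discovered on 60%, effects re-estimated on
the held-out 40% with the structures frozen. Per split, the *most
representative tree* is the retained draw whose effect surface is closest —
smallest sum of squared differences over discovery subjects, ties broken by
fewer leaves then canonical order — to the posterior-mean surface. Across
`B3` repeated splits, the *super-representative tree* is the modal
representative tree under canonical serialization; this is only meaningful
because cutpoint grids and design standardization are frozen once per run
from the covariate table (covariates only — no outcome information — so the
honesty guarantee is untouched). Validation refits run the shared-parameter
kernel with frozen trees, interleaved with collapsed coefficient redraws,
pooling posterior draws across the splits that produced the modal tree; the
report carries per-leaf expected sizes, uncensored proportions, control and
treatment total slopes, effect means with 95% credible intervals, pairwise
ordering probabilities, and a discovery/validation concordance table
(validation subjects grouped into tertiles of their discovery-tree
estimates).

The pipeline's point estimator $\hat\tau_0(x)$ is the super-representative
tree's surface with pooled honest leaf means. It is piecewise constant,
which makes the heterogeneity indicator below exact; the posterior-mean
surface over retained draws is available via the chain draws for users who
prefer a smoother estimator.

Remark: for subgroup-wise *conventional* model fits one should intersect the
leaves of all three trees (`intersection_tree()`), because a $\tau_0$ leaf
can straddle heterogeneous control slopes; the intersection partition
refines each tree's own partition.

## Simulation metrics

On the validation set of size $n_2 = 0.4n$: $\ell_1$ is the mean absolute
error of $\hat\tau_0$; $R_1$ the regret
$\tfrac{1}{n_2}\sum |\tau_0(x_i)|\,|1(\hat\tau_0(x_i)>0) - 1(\tau_0(x_i)>0)|$
of treating by estimated sign (with the treat-all rule as the naive
reference); $\mathrm{Htr}$ flags disagreement between estimated and true
constancy of the effect surface — with a tree estimator, "constant" is
exactly "the effect tree is root-only on the validation set". The oracle
Bayesian empirical power
$\mathrm{BEP} = \Pr(\hat\tau_0^+ - \hat\tau_0^- > 0 \mid \text{Data})$ fits
conventional root-tree models on the truly-benefiting and truly-harmed
subsets (the harmed-side estimate is fixed at 0 when that subset is empty).

## The trial simulator

`gen_trial()` emulates the study's data-generating processes: six
covariates ($x_{1..5} \sim \mathrm{Unif}(-2,2)$, $x_6 \sim
\mathrm{Bernoulli}(0.5)$), effect surfaces from step (ST), continuous (CON)
or constant (CST) families depending only on $(x_1, x_6)$ — the remaining
covariates are nuisance — 1:1 Bernoulli randomization, two-slope
trajectories, and dropout from the frailty-scaled piecewise-exponential
model with administrative censoring at 3 years. Informative censoring is
switched by $\eta_1 = \eta_2 \in \{0, -0.5\}$.

Quantities the source states are used verbatim: the covariate laws, the
surface families per setting, $\tau_0 \equiv 0.1$ for the null settings,
subtle contrasts $\tau_0^+ - \tau_0^- \in \{0.4, 0.2\}$, $\eta$ levels,
$t^\ast = 1/3$, $T^\ast = 3$. Magnitudes the source leaves to a
supplementary file are package choices, fixed once: residual SD
$\sigma = 3$ eGFR units; random-effect SDs $(2, 1.5, 1.5)$ for intercept
(units) and slopes (units/yr), diagonal $\Sigma$; visits every 4 months
(baseline plus 9 follow-ups to year 3); constant baseline hazard calibrated
so roughly 30% of control subjects reach the composite event by year 3; the
strong-heterogeneity settings use a $\tau_0$ contrast of 2 units/yr with a
harmed subgroup ($\pm 1$ split at $x_1 = 0$), step baseline
($40 + 5\cdot 1(x_1>0) - 5 x_6$) and step chronic slope
($-3 - 1(x_1>0) + 0.5 x_6$). These are realistic CKD-trial magnitudes; they
are not revisited per experiment.

What the generator does *not* emulate: irregular real-world visit patterns,
covariate-dependent visit compliance, measurement-error heteroscedasticity,
or eGFR-equation changes. Passing tests therefore demonstrate correctness of
the machinery and calibrated behaviour under the stated processes, not
performance guarantees on any particular trial.

`mdrd_like_fixture()` is a clearly-synthetic stand-in emulating the schema
of the blood-pressure trial reanalysis (the real data are access
restricted): the standard covariate panel with heavy-tailed UACR and
triglycerides (log-normal), `log(1+x)` transforms on continuous covariates,
roughly monthly visits, composite events, and a planted effect split on
baseline eGFR near 34 ml/min/1.73m² (benefit 1.5 vs 0.2 units/yr — a
contrast chosen so the plant is decisively detectable at the fixture's
size, since the fixture exists to smoke-test end-to-end recovery). The
pipeline recovering that planted split end-to-end is the package's smoke
test of the whole workflow.

## Problem sizes and numerical choices

Default chain lengths are $B_1 = B_2 = 100$ and $B_3 = 100$ splits. The
package's own simulation studies (tests and the acceptance script) run the
reduced protocol $B_1 = B_2 = 40$, $B_3 = 10$, 10 Monte-Carlo replicates,
with $n = 300$ for the null-control settings and $n = 800$ for the
strong-heterogeneity setting; at $n = 300$ (180 discovery subjects) a
contrast of 2 units/yr sits below the parsimony penalty of the tree prior,
which is the designed false-positive control, not a defect. Chains run in a
few seconds per split at these sizes (C++ kernels; R orchestration).

Numerical details: Newton tolerance $10^{-8}$ (max 50 iterations) for all
mode searches, with a prior-mode fallback on non-convergence; Cholesky-based
draws everywhere; the collapsed marginal's normal equations carry the prior
ridge $\tau_{pr}^{-2} I$, so they are well-posed even with empty leaves;
knot placement falls back to an equispaced grid when event times are too
few or degenerate; quantiles are always type-7 (linear interpolation).
Tie-breaks: routing ties go left; representative-tree ties prefer fewer
leaves, then lexicographic serialization; concordance tertiles break rank
ties randomly under the run seed.

## Known limitations

- The Laplace-collapsed tree moves inherit the approximation error discussed
  above; with strong frailty links and sparse follow-up the tree posterior
  is mildly perturbed (the null-control and detection experiments bound the
  practical consequence).
- The 60/40 split costs effective sample size in both stages; no selective-
  inference correction beyond honesty is attempted.
- Single trees per surface, birth/death moves only (no change/swap), no
  monotonicity constraints on trajectories, no time-varying covariates in
  the hazard.
- The reduced-protocol power results are specific to the documented
  generator magnitudes; detection thresholds scale with
  $\sqrt{n}\,/$(slope random-effect SD).
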