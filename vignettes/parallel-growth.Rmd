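---
title: "Linear-spline multilevel models for parallel growth processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-spline multilevel models for parallel growth processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallelgrowth)
```

## The problem

Many cohort analyses follow two change processes in the same individuals —
here, weight and mean arterial pressure (MAP) across pregnancy — and ask a
question a single correlation cannot answer: does change in one variable
*precede* change in the other, and in which periods? A bivariate linear
growth model (one slope per response) can correlate slopes, but it cannot
localise the association in time. Giving each response a piecewise-linear
trajectory whose slopes change at knot points turns "change" into a small
set of period-specific quantities that can be correlated, constrained and
regressed on one another.

## Model

For response $i$, occasion $j$, individual $k$:

$$ y^{(i)}_{jk} = (\beta^{(i)}_0 + u^{(i)}_{0k})
   + \sum_{l=1}^{m^{(i)}} (\beta^{(i)}_l + u^{(i)}_{lk})\, s^{(i)}_l(t_{jk})
   + \varepsilon^{(i)}_{jk}. $$

The spline basis $s_l(t)$ accrues the time spent inside period $l$:
$s_l(t) = \max\{0, \min(t, b_l) - b_{l-1}\}$ with boundaries
$b_0 = \text{baseline} < b_1 < \dots < b_m = \text{horizon}$ and the last
spline open-ended. Consequences used throughout: all components are
nonnegative, they sum to $t - b_0$ inside the window (so the mean
trajectory is continuous, kinked exactly at the knots), and period $l$ is
the *closed* interval $[b_{l-1}, b_l]$.

The stacked random-effect vector $\mathbf u_k$ (intercept then slopes for
response 1, then response 2, …; $M = \sum_i (m^{(i)}+1)$ effects) is
multivariate normal with covariance $G$. Occasion-level residuals are
normal with variance $\sigma^2_{e_i}$ per response, constant over time,
plus a covariance $\sigma_{e_{12}}$ *only when both responses are measured
at the same occasion* — occasions are matched on exact time equality, so
times should be rounded (e.g. `round_weeks()`) before fitting if the two
responses were not recorded on a shared clock. Covariates enter each
response's fixed part as intercept-shifting main effects only; we do not
fit covariate-by-spline interactions. Missing occasions are simply absent
rows (missing at random).

## Estimation

`fit_mlm()` maximises the exact marginal likelihood
$\sum_k \log N(\mathbf y_k;\, X_k\beta,\, Z_k G Z_k' + R_k)$ by Fisher
scoring on the free unique entries of $G$ and the occasion-level
parameters, with $\beta$ profiled out by generalised least squares at each
step. This design has three consequences that matter here:

- **Hard zeros.** Covariances named in a constraint set are removed from
  the parameter vector, not penalised, so restricted models have *exact*
  entry-wise zeros — something an unconstrained Cholesky parameterisation
  cannot represent.
- **An analytic $\Gamma$.** The sampling covariance of the $\hat G$
  entries is the $G$-block of the inverse *expected* (Fisher) information
  of all free (co)variance parameters at the optimum, on the raw
  covariance scale. We prefer the expected information to numerical
  differentiation of the score: the scoring iteration computes it exactly
  as a by-product, and it is symmetric and positive semi-definite by
  construction. Rows and columns of constrained entries are zero.
- **Positive definiteness by step-halving.** A scoring step that makes
  some individual's marginal covariance non-PD (or increases the deviance)
  is halved until it does neither; free entries of $G$ are otherwise
  unrestricted, so $G$ itself may pass through indefinite points while
  every per-individual covariance stays valid — the behaviour of classical
  MLM software. `mlm_loglik()` returns `-Inf` rather than an error at
  non-PD points so generic optimisers can recover.

Defaults (all overridable through `mlm_control()` and `init`): relative
deviance-change tolerance $10^{-8}$, iteration cap 200, starting values
from per-response OLS on the spline basis with a scaled-diagonal $G$
(intercept variance = OLS residual variance, slope variances = residual
variance divided by the squared window span) and half the residual
variance on the occasion level. For rich structures where one-shot
convergence is difficult, `fit_mlm_staged()` follows the practice of
adding random effects gradually: it fits each response univariately and
seeds the multivariate fit from those estimates. Estimation is straight
ML, not REML, because restricted models are compared by deviance
($-2\log L$) and REML deviances are not comparable across different fixed
parts; with thousands of individuals and a handful of fixed effects the
REML correction is negligible anyway.

## Temporal hypotheses as covariance constraints

With periods as closed intervals, two periods are *adjacent* when their
intervals intersect (overlap or share an endpoint), and period $B$ is
*subsequent* to period $A$ when $\mathrm{start}(B) \ge \mathrm{end}(A)$ —
the immediately following, boundary-sharing period counts as subsequent.
These two interval rules are what reproduce the published degrees of
freedom (8, 3, 5, 4) for the example's unequal knot sets, including the
overlap of weight's open-ended final period with MAP's last two periods:

```{r df}
specs <- pregnancy_example_specs()
c(
  same_adjacent = nrow(constrain_same_adjacent(specs)),
  map_not_before_weight = nrow(constrain_precedence(specs, "map", "weight")),
  weight_not_before_map = nrow(constrain_precedence(specs, "weight", "map")),
  early_map_blocked = nrow(constrain_block(specs, "map:slope1", "weight"))
)
```

`constrain_same_adjacent()` constrains within-response as well as
cross-response slope pairs by default (that is what the df count of 8
requires, and what "changes could only be correlated with change in the
same and adjacent periods" means); `include_within = FALSE` exposes the
cross-only reading (4 pairs). Intercepts are never constrained: baseline
levels may correlate with change anywhere. `constrain_lag()` measures its
lag in period *indices*, the natural reading when both responses share one
knot set; for unequal knot sets this is a documented choice, not an
asserted equivalence to a time-unit lag. The degrees of freedom of
`lrt()` equal the number of constrained covariances by construction, and
a negative statistic (possible only through failed convergence) warns and
reports $p = 1$.

## Regressions among random effects

All mutually adjusted associations derive from $G$ by solving
$\Sigma\beta = \sigma_0$ (`ranef_coefficients()`). The *model-estimated*
$G$ must be used rather than the covariance of predicted individual
effects: BLUPs are shrunken towards zero in proportion to each
individual's information, so their empirical covariance understates $G$
(`ranef_blup()` exists precisely to let you see this attenuation).

Three standard-error methods, in increasing order of honesty about where
the uncertainty lives:

1. **Moment-based** (`ranef_se_moment()`): pretends the $n$ random-effect
   vectors were observed; exactly reproduces `lm()` standard errors when
   fed empirical moments. Anti-conservative for estimated $G$.
2. **Delta method** (`ranef_se_delta()`): propagates $\Gamma$ through the
   analytic Jacobian $d\beta = \Sigma^{-1}(d\sigma_0 - d\Sigma\,\beta)$.
3. **Simulation** (`ranef_se_simulate()`): draws the relevant $G$ entries
   from $N(\hat\nu, \Gamma)$ (default $q = 10{,}000$), re-solves per draw,
   reports the mean and 2.5th/97.5th percentiles. Draws whose predictor
   block is singular or whose implied covariance is not PD are *skipped
   and counted*, not projected — projection would bias the percentiles,
   and the skip count is the user's gauge of approximation stress; more
   than 50% skipped is an error. A seed is mandatory.

Methods 2 and 3 agree to first order; at a fixed, large $\Gamma$ the
simulated distribution keeps second-order spread that the delta expansion
drops, so their agreement is asymptotic in sample size (both assume the
normal approximation for $\hat G$, a large-sample device). Reporting
scales (per 10 kg, per 0.4 kg/week) are presentation transforms applied
after estimation.

## The SEM view

On a balanced grid of occasions the same model is a latent growth curve:
intercept factors load 1 on every measurement, slope factors load the
spline basis at each grid time, factor covariance $= G$, per-occasion
residual structure $= R$ repeated down the grid. `sem_layout()` builds the
loadings (bit-identical to `spline_basis()`), `sem_implied_moments()`
computes $\Lambda G \Lambda' + R$-expansion, and
`sem_check_equivalence()` compares that against the multilevel marginal
moments for an individual observed on the grid — an algebraic identity, so
the discrepancy is reported at numerical precision ($<10^{-10}$). No
second SEM estimator is included: re-estimating by FIML would duplicate
the same likelihood, and the scientific content of the equivalence is the
shared parameterisation, which the moment check verifies directly.
Rescaling loadings (with inversely rescaled factors) leaves the implied
moments unchanged, as it must.

## What the generator emulates — and what it does not

`generator_spec()` defaults describe the motivating design: 9429
individuals; visit count $1 + \mathrm{Binomial}(17, 0.53)$ per woman
(median 10, range 1–18); visit times sampled without replacement from
integer weeks 8–43 with a mild linear enrichment (+2% weight per week)
towards late pregnancy, since antenatal visits densify near term; both
responses at every visit (per-response drop probabilities available to
exercise unmatched occasions); random effects from the published 9 × 9
covariance matrix, projected to positive definite only if rounding made it
indefinite (the printed matrix is in fact PD, smallest eigenvalue 0.018,
so the projection is a no-op). The visit-time *process* of the real cohort
is not recoverable from its summary statistics; only those statistics are
matched, and the schedule model is fully configurable.

Population curves default to plausible pregnancy shapes — weight ≈ 62 kg
at 8 weeks rising 0.3/0.5/0.4 kg/week across its periods; MAP ≈ 84 mmHg
falling 0.25 mmHg/week to 18 weeks then rising 0.1/0.6/0.9 mmHg/week —
and occasion-level noise to 1.2 kg² and 33 mmHg² with covariance 0.5.
These are round values chosen once for realism (mid-pregnancy blood
pressure dip, steepest weight gain in the second trimester, measurement
noise of roughly 1 kg and 5–6 mmHg); no published occasion-level values
exist to copy. Passing tests on these data shows the estimator recovers
the assumed data-generating process; it does not validate the model
against features real cohorts have and the generator lacks — informative
missingness, digit preference in clinic measurements, covariate-dependent
visit schedules, non-normal effects.

Two preparation utilities mirror common practice: `map_from_bp()`
($\mathrm{MAP} = \mathrm{SBP}/3 + 2\,\mathrm{DBP}/3$) and
`thin_to_window()` (at most one measurement per individual, response and
window — by default 2 time units — chosen at random under a seed, so that
frequently measured individuals do not dominate).

## Problem sizes used by the shipped experiments

The test suite runs its heavy experiments at sizes chosen to make their
statistical point at interactive cost: parameter recovery uses 20
replicates of $n = 500$ (each full 9-effect bivariate fit converges in
about 6 scoring iterations, a few seconds), where every unique $G$ entry
falls within 3 reported SEs of truth in at least 18 of 20 replicates; the
SE-method concordance experiment uses one fit at $n = 2000$, since
Methods 2 and 3 are large-sample approximations and their agreement is the
asymptotic statement above (≤ 5% relative interval width there, with the
moment intervals strictly narrower); likelihood correctness is checked
against a brute-force stacked-normal density on 100 random tiny instances
at $10^{-10}$.

## Known limitations

- Two nesting levels only (occasions in individuals), continuous
  responses, straight ML. No MCMC, no categorical outcomes, no
  missing-not-at-random sensitivity analysis.
- Knot locations are user-supplied; the package does not search for them.
- Covariates must be numeric (dummy-encode factors) and act on intercepts
  only.
- The occasion-level covariance is homogeneous over time; models where
  measurement noise changes across pregnancy need a different $R$
  structure.
- Fisher scoring is fast near the optimum but, like all covariance
  optimisation, can struggle when $G$ is large relative to the data;
  `fit_mlm_staged()` and explicit `init` are the remedies, and
  non-convergence is reported, never silently accepted.
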