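---
title: "Power and sample size for stepped wedge trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power and sample size for stepped wedge trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swtpower)
```

## The design problem

A stepped wedge trial (SWT) randomises intact clusters — wards, practices,
villages — to *sequences*: every cluster starts in the control condition and
switches to the intervention at one of several crossover points, so that by
the final measurement time all clusters are treated. Compared with a
parallel cluster-randomised trial (CRT), the design trades a longer study
for within-cluster before/after information, and its power depends on the
allocation structure in a way no single design effect fully captures.

`swtpower` provides the three closed-form routes in common use, plus a
simulation engine for everything the closed forms cannot represent:

1. the mixed-model (Hussey-Hughes-type) variance and power for
   cross-sectional SWTs;
2. design-effect routes that inflate a parallel-RCT sample size (the
   conventional CRT inflation factor, and the Woertman correction-factor
   design effect specific to SWTs);
3. a log-rank-based design effect for survival-type outcomes (Moulton
   route), comparing the statistic under SWT and CRT allocations;
4. Monte Carlo power for generalized linear mixed data-generating
   processes, cross-sectional or closed cohort, with time effects and
   random intervention effects.

## The model

Index clusters $i = 1, \dots, I$, measurement times $j = 1, \dots, J$
(time 1 is an all-control baseline; there are $J - 1$ crossover points) and
individuals $k = 1, \dots, K$ per cluster-period. The linear predictor on
the link scale is

$$\phi_{ij} = g(\mu_{ij}) = \mu + \alpha_i + \beta_j + X_{ij}(\theta + u_i)
  \;(+\, v_{ik}),$$

with cluster effects $\alpha_i \sim N(0, \sigma^2_\alpha)$, fixed or random
time effects $\beta_j$, the 0/1 treatment indicator $X_{ij}$, effect
$\theta$, optional cluster-specific intervention deviations
$u_i \sim N(0, \sigma^2_u)$, and — for closed cohorts, where the same $K$
individuals are measured at every time — individual effects
$v_{ik} \sim N(0, \sigma^2_v)$. Outcome families are normal (identity
link, residual variance $\sigma^2_e$), Bernoulli (logit) and Poisson
(log).

For the cross-sectional normal model, the GLS variance of $\hat\theta$ has
the closed form implemented in `hh_variance()`,

$$V(\theta) = \frac{I\sigma^2(\sigma^2 + J\sigma^2_\alpha)}
 {(IU - W)\sigma^2 + (U^2 + IJU - JW - IV)\sigma^2_\alpha},
 \qquad \sigma^2 = \sigma^2_e / K,$$

where $U = \sum_{ij} X_{ij}$, $W = \sum_j (\sum_i X_{ij})^2$ and
$V = \sum_i (\sum_j X_{ij})^2$ summarise the allocation matrix, and
two-sided power is $\Phi(|\theta|/\sqrt{V(\theta)} - z_{\alpha/2})$. A
property test verifies this expression against an independent GLS
information-matrix oracle on randomized small designs to $10^{-8}$
relative tolerance.

## Parameters that matter, and their conventions

**ICC and variance input mode.** The intracluster correlation is always
$\rho = \sigma^2_\alpha / (\sigma^2_\alpha + \sigma^2_e)$. Practitioners
quote variances two ways, and the package supports both explicitly:
*total* mode takes $\sigma^2_y$ and sets
$\sigma^2_\alpha = \rho\,\sigma^2_y$; *within* mode takes $\sigma^2_e$ and
sets $\sigma^2_\alpha = \sigma^2_e\,\rho/(1-\rho)$. Within mode is the
natural input for non-normal simulation, where the Bernoulli/Poisson
variance is not free; total mode matches how design-effect calculations
are usually parameterised. The two modes give different cluster counts at
the same nominal $\rho$, which is a real feature of practice, not a bug.

**Binary and count effects on two scales.** The analytic formulas operate
on the risk/rate-difference scale with a normal approximation
($\theta = p_1 - p_0$ or $\lambda_1 - \lambda_0$); the simulator operates
on the link scale (log-odds ratio, log rate ratio). For binary outcomes
the total-mode variance convention is $\bar p(1-\bar p)$ with
$\bar p = (p_0 + p_1)/2$, the within-mode convention is $p_0(1-p_0)$;
both appear in applied work without being named, so both are exposed. For
counts we use $(\lambda_0 + \lambda_1)/2$ in either mode.

**Allocation rule.** When $I$ is not a multiple of the number of
crossovers, the default `"even-earliest"` rule gives each crossover
$\lfloor I/(J-1)\rfloor$ clusters and assigns the remainder one each to
the *earliest* crossovers. This is a genuine choice (no published
convention exists); an explicit allocation override is provided, including
empty crossovers for sensitivity work. For the zero-ICC variance the rule
turns out not to matter much: reversing an allocation sequence leaves
$IU - W$ invariant (a tested property).

**Rounding.** Design-effect routes round *up* to whole clusters after
inflation; base RCT sizes round up per arm. Several published grid cells
sit within two-decimal rounding distance of the 80 % target at one fewer
cluster (e.g. the count outcome at $\rho = 0$, where 8 clusters give
power 0.7993); `reproduce_table()` annotates such cells rather than
silently matching either convention.

## The simulation engine

`simulate_trial()` follows the generative recipe directly: draw the random
effects, assemble $\phi_{ij}$, then draw outcomes from the family
distribution. `fit_swt()` fits the matching mixed model with `lme4` — maximum
likelihood (`REML = FALSE`) for normal outcomes, so the Wald statistic is
the likelihood-based one the power formula approximates, and the Laplace
approximation (`nAGQ = 1`) for Bernoulli and Poisson; these fitting
choices are fixed and documented rather than configurable, so Monte Carlo
results are comparable across runs. The Wald test compares $\hat\theta/\mathrm{SE}$ to a standard normal
(not a $t$), matching the analytic power formula; with few clusters this
is known to be slightly liberal, which the null-calibration test
quantifies rather than hides. Ties at the critical value count as
non-significant.

**Convergence policy.** Optimizer failures never raise during a power run:
the fit is returned flagged, counted as *non-significant*, and tallied in
`n_nonconverged`. Variance estimates on the zero boundary (common and
correct when the true $\sigma^2_\alpha$ is 0) are *converged* fits flagged
`singular`.

**Seeding.** One master seed drives everything: per-trial sub-seeds are
drawn once from the master stream and each simulated trial runs on its own
sub-stream. Estimates are therefore bit-reproducible and independent of
evaluation order, and a search re-uses a fixed sub-seed per candidate
size.

**Power search.** `find_min_clusters()` walks $I$ upward and accepts the
first candidate whose estimated power reaches the threshold, recording the
whole trajectory. Monte Carlo noise near the boundary is real: at
$S = 1000$ the standard error near 80 % power is about 0.013, so
boundary candidates can flip. There is no early stopping on noise; the
optional `refine = TRUE` re-runs any candidate landing within two MC
standard errors of the threshold (on either side) at $4S$ and lets the
refined estimate decide. This matters in practice: when the true
simulated power at the analytic optimum sits essentially *at* the
threshold — which is exactly the situation where the analytic and
simulation routes agree — the unrefined search outcome is close to a
coin flip. $S = 1000$ is the default (an MC error guideline, not a magic
number).

**Bayesian variant.** `bayesian_power()` draws designated parameters from
uniform priors before each simulated trial, estimating *expected power*
over the prior (assurance). Degenerate priors reproduce the fixed-parameter
estimate — a tested contract.

## What the generator emulates, and what it does not

The generator reproduces the features that drive SWT power: the staggered
allocation, exchangeable within-cluster correlation, secular time trends
(linear, categorical or random), closed-cohort repeat measurement and
cluster-varying intervention effects. It deliberately does **not** model
unequal cluster sizes, drop-out, lagged or learning intervention effects,
transition periods, incomplete designs or covariates beyond time and
treatment. Passing tests therefore demonstrate correct behaviour *under
the stated generative model*, not robustness of a real trial to features
the model excludes; for those, the engine's sensitivity-grid interface is
the intended tool once the user supplies a richer scenario.

## Numerical and design choices worth knowing

- **Degenerate designs.** If every cluster shares one sequence the
  treatment indicator is collinear with the time effects and
  `hh_variance()` raises a singular-design error rather than returning a
  misleading number.
- **Problem sizes in the test suite.** Monte Carlo assertions use
  $S$ between 300 and 2000 with 3-MC-SE tolerances, and large-sample
  distributional checks use around 2000 clusters; these sizes make the
  checks sharp enough to catch implementation errors while keeping a full
  run of the suite practical on a laptop.
- **Moulton route.** `moulton_de()` is a pure function of two incidence
  tables (SWT-allocated vs CRT-allocated), keeping the statistic
  deterministic and testable; scenario generation lives in
  `expected_incidence()` / `simulate_incidence()`, a discrete-time
  constant-hazard model in which expected (fractional) counts are allowed
  in tables. The final survival sample-size inflation step is out of
  scope.
- **Known limitation.** Published grids of this kind are not always
  recoverable to the last cell from stated conventions (rounding of power
  to two decimals, unstated allocation rules, unstated base-size
  formulas); `reproduce_table()` reports what the documented conventions
  actually give and annotates rounding-sensitive cells instead of forcing
  agreement.

## A worked example

```{r example, eval = FALSE}
# How many clusters for a continuous outcome, effect -0.3785, SD 1.55,
# ICC 0.1 (within mode), 6 times x 20 subjects, 80 % power?
vc <- variance_components(icc = 0.1, var = 1.55^2, mode = "within")
hh_min_clusters(vc, effect = -0.3785, n_times = 6, cluster_size = 20)

# The same question answered by simulation:
m <- outcome_model("normal", baseline = 0.3, effect = -0.3785, vc = vc)
find_min_clusters(m, analysis_spec("normal"), n_times = 6,
                  cluster_size = 20, threshold = 0.8, S = 1000, seed = 1)
```

The README shows the printed output of this example; the acceptance script
(`scripts/acceptance.R`) recomputes the package's headline numbers from
scratch.
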