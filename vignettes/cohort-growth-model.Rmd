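---
title: "A stochastic Von Bertalanffy model for cohort length-at-age distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic Von Bertalanffy model for cohort length-at-age distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbcohort)
```

## The model

`vbcohort` estimates growth and environmental growth limitation from
datasets with a single (age, length) observation per individual. Individual
growth follows the Von Bertalanffy equation
$d\ell/dt = r_B(f\,\ell_\infty - \ell)$, with the environmental limitation
$f$ treated as a Gaussian random quantity,
$f \sim N(\mu_t, \sigma_t^2)$, varying over time and between individuals.
Substituting the distribution gives a mean-reverting stochastic differential
equation with drift $r_B(\mu_t \ell_\infty - \ell)$ and diffusion
coefficient $r_B \sigma_t \ell_\infty$. Because the noise is Gaussian and
the drift linear, the length distribution of a *cohort* — all individuals
born in the same inter-sampling interval — remains Gaussian at all times,
and only its mean and variance need to be tracked.

Between consecutive survey occasions the limitation is summarised by its
interval averages $\bar\mu_T, \bar\sigma^2_T$, giving the discrete
recursions implemented in `propagate_mean()` and `propagate_var()`:

$$E[\ell_{T+1,a+1}] = E[\ell_{T,a}]\,e^{-r_B} +
  \bar\mu_T\ell_\infty\,(1 - e^{-r_B})$$

$$V[\ell_{T+1,a+1}] = V[\ell_{T,a}]\,e^{-2 r_B} +
  \frac{\bar\sigma^2_T\ell_\infty^2}{2 r_B}\,(1 - e^{-2 r_B})$$

Iterating the variance recursion under a constant environment converges to
the asymptotic within-cohort variance
$\bar\sigma^2_T \ell_\infty^2 / (2 r_B)$ (`asymptotic_variance()`), the
spread individuals would reach after unbounded exposure to that level of
environmental variability. Because the length of an individual integrates
environmental noise over time, $\bar\sigma^2_T$ carries units of time: a
cohort that experiences an environment for longer accumulates more spread.

Two parameterisation points deserve emphasis:

* **Only products are identifiable.** The limitation never appears except
  multiplied by $\ell_\infty$ (means) or $\ell_\infty^2$ (variances), so the
  package estimates the products `mu_linf` (mm) and `sigma2_linf2` (mm²·
  interval) and treats $\ell_\infty$ as an optional, externally supplied
  species constant used purely for reporting the dimensionless limitation.
* **The variance product absorbs the rate constant.** Carrying the Itô
  isometry through the interval integral multiplies the diffusion term by
  $r_B^2$; writing the variance gain as
  $\bar\sigma^2_T\ell_\infty^2 (1-e^{-2r_B})/(2r_B)$ therefore defines the
  estimated $\bar\sigma^2_T$ so that it absorbs that factor. The synthetic
  module is explicit about the mapping: a simulation with schedule standard
  deviation $\sigma_t$ implies an estimated variance product
  $(r_B \sigma_t \ell_\infty)^2$. (Printed inventories of this model family
  are inconsistent about one power of $\ell_\infty$ in the variance row; the
  package follows the recursion above throughout.)

## The lattice and its boundaries

Cohorts live on a discrete time × age lattice (`vb_grid()`): occasions
$T_{\min},\dots$ and integer age classes $a_{\min},\dots$. The recursion
needs a starting distribution for every cohort, which is exactly what the
data cannot supply for cohorts born before the survey window. The free
boundary parameters are therefore the length distribution of the *first age
class at every occasion* ($2 n_T$ parameters) and of *every older age class
at the first occasion* ($2(n_a - 1)$), giving the free-parameter count

$$k = 1 + 2 n_T + 2 (n_a - 1) + 2\,n_{\text{int}}\,n_{\text{groups}},$$

with $n_{\text{int}} = 1$ for the time-constant variant and $n_T - 1$ for
the year-varying one. This is the $k$ used in AIC; `glance()` and
`vb_compare()` surface it so the counting rule is always visible. Cells
outside the lattice are simply absent from the prediction tibble — they are
never extrapolated, because no boundary information exists for them.

## Fitting

All parameters are strictly positive, so optimisation works on their
logarithms (`vb_pack()`), which also evens out the scale difference between
$r_B$ (~0.3) and variance products (~10³–10⁴). The objective is the
negative weighted Gaussian log-likelihood; weights act as observation
multiplicities, which matches the convention of weighting survey
observations by inverse catch-per-unit-effort counts.

**Starting values** (`vb_initial_parameters()`): a single deterministic
growth curve is fitted to all weighted observations by least squares,
profiling $r_B$ (for fixed rate the curve is linear in its other two
parameters, so only a one-dimensional search is needed). Variances start at
the weighted variance of the youngest age class; the environmental variance
product starts so that its implied asymptote equals the oldest class's
variance.

**Optimizer.** The default is a derivative-free, subplex-style scheme built
on `stats::optim`: Nelder–Mead applied cyclically to small overlapping
blocks of the packed vector until a full cycle improves the objective by
less than the relative tolerance (default $10^{-10}$). Restricting each
simplex to a low-dimensional subspace keeps the method effective when the
parameter vector is long (73 parameters for a 15 × 8 varying-environment
fit), where a single full-space simplex stagnates; alternating block
offsets between cycles couples all coordinate pairs. A restarted full-space
Nelder–Mead and a numerical-gradient BFGS (for smooth variants only — the
non-shrink mean update is not differentiable) are available through
`vb_control()`. Optional seed-jittered multi-starts guard against local
optima; the default is a single start. The likelihood itself is evaluated
in compiled code from per-cell sufficient statistics, so each evaluation
costs microseconds and is independent of the number of observations; an R
reference implementation (`vb_predict()` + `vb_nll()`) defines the
semantics and the test suite holds the two routes together to $10^{-10}$.

**Numerical guards.** Cell variances are floored at $10^{-8}$ mm² inside
the likelihood (a collapsing cell would otherwise drive the log-density to
$\pm\infty$); floored evaluations are counted in `glance()$n_floored`.
Boundary cells that hold no data leave their two parameters weakly
identified; the fit warns and lists them rather than failing, because the
jackknife (below) depends on exactly this behaviour.

## Model variants

* **Constant vs varying environment.** Nested models compared by AIC and
  `vb_lr_test()`. When the generating environment truly varies, the
  constant fit must absorb between-year variation in the asymptote into its
  single variance product, inflating it relative to the mean of the
  varying fit's per-interval values — a diagnostic the acceptance checks
  exercise.
* **Non-shrink** (`non_shrink = TRUE`): the mean update becomes
  $\max(E, \text{update})$, the minimal restriction that prevents cohorts
  above the current asymptote from shrinking. Fit without it first; it
  inflates the influence of young cohorts.
* **Groups** (`vb_groups()`): separate environmental products per age or
  mean-length class. A cohort is classified as a whole — by its age or
  *predicted mean* length at the *start* of each interval (start-of-interval
  classification is the causal choice; the alternative, end-of-interval,
  would let the group assignment depend on the outcome of the update it
  selects). Classes are lower-closed and upper-open, so a cohort exactly on
  a boundary belongs to the upper class; with boundaries at ages 4 and 8
  the groups are "up to 3", "4–7" and "8 and older". Zero boundaries give a
  single all-encompassing class, which reproduces the ungrouped fit exactly
  (same $k$, same likelihood).

## The synthetic-data module

`vb_generate_dataset()` builds survey datasets with known truth: one cohort
born at every interval boundary, each simulated as an ensemble of
Euler–Maruyama paths of the stochastic growth equation
(`vb_simulate_individuals()`), then sampled by a survey design. Default
study conditions are 15 occasions × 8 age classes, 300 observations per
cell, $r_B = 0.3$ per interval, $\ell_\infty = 780$ mm, birth length
$N(50, 10^2)$ mm, schedule $\sigma = 0.5$ (equivalently an estimated
variance-of-limitation scale of $0.3^2 \times 0.5^2 = 0.0225$ per
interval), and limitation means between 0.5 and 0.9 — magnitudes chosen to
match a large flatfish survey. The integration step is $dt = 0.02$ interval
for bulk dataset generation and $0.01$ for the simulation-vs-recursion
checks; Euler–Maruyama has weak order one, and at these steps the
discretisation bias in interval-end means is several times smaller than the
Monte-Carlo standard error of a $10^5$-path ensemble.

Design choices worth knowing:

* Paths may transiently exceed the asymptote or dip below the birth length
  (occasionally below zero for small, variable age classes) — the Gaussian
  model permits this, and no reflecting boundary is imposed, so the
  simulated moments match the recursion exactly. File ingestion
  (`read_observations()`) rejects non-positive lengths, as real data would.
* All individuals are born exactly at interval boundaries and ages are
  whole intervals; there is no ageing error, mortality, or spatial
  structure. Passing tests on these data therefore demonstrates the
  estimator's correctness under its own assumptions, not robustness to the
  many ways real surveys violate them.
* **Catchability and CPUE weights.** Built-in biased designs make the catch
  probability exponential in length, i.e. a constant relative selection
  gradient across the whole size range. (A saturating curve — logistic,
  say — loses its gradient exactly where cohort variance is largest, which
  can reverse the direction of the induced bias; the exponential form keeps
  "contribution to the data increases with size" true for every age class.)
  Under uniform catchability nothing needs correcting and all weights are
  exactly 1. Under biased designs the sampler draws from each occasion's
  whole pool with probability proportional to catchability, and weights are
  the inverse empirical catch rate of each 5 mm length bin — caught over
  present, pooled across occasions (the catchability curve, not its annual
  realisation, is the estimand; per-occasion rates at realistic sample
  sizes are dominated by sparse-bin noise), using the nearly unbiased
  $(n+1)/(c+1)$ estimator of an inverse proportion, normalised to mean 1.

## Jackknife

`vb_jackknife()` refits the model once per omitted occasion. The lattice is
deliberately left unchanged: the omitted year's boundary cells become
zero-weight and their parameters weakly identified, but every interval
keeps its index, so per-interval limitation deltas against the full fit are
well defined. Starting values are recomputed from each reduced dataset (the
alternative — reusing full-data starts — would make each refit slightly
cheaper but risks anchoring the omitted year's weakly identified parameters
at values informed by the very data being omitted). Omitting a middle year
characteristically moves the limitation estimate most in an interval
adjacent to the omission, by an amount small relative to the within-cohort
spread — both properties are asserted in the acceptance suite.

## Problem sizes and runtime

The test suite runs the full study conditions where they are cheap (ten
recovery fits at 15 × 8 × 300 complete in under half a minute thanks to the
sufficient-statistic likelihood) and reduced lattices where replication
multiplies cost: the jackknife checks use 9 occasions × 6 ages × 150 per
cell with three middle-year omissions, and the CPUE experiment averages
three replicate surveys. These sizes are stated here as the package's
chosen experimental design; the same conditions are what
`scripts/acceptance.R` re-runs end to end.

## Known limitations

* Non-uniform sampling intervals are not supported; $r_B$ and
  $\bar\sigma^2_T$ are per-interval quantities.
* No standard errors or confidence intervals on parameters are produced;
  model comparison is by AIC and likelihood-ratio tests.
* $\ell_\infty$ cannot be estimated jointly — only its products with the
  limitation are identifiable.
* The Gaussian cell distribution is an assumption, not a diagnostic
  outcome; heavy selection or strongly size-dependent mortality that
  weights cannot express will bias the limitation estimates.
* Local, derivative-free optimisation from a single deterministic start: a
  severely mis-specified start (e.g. from data dominated by one cohort) can
  end in a local optimum. `vb_control(n_starts = )` enables jittered
  restarts.
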