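# vbcohort

Von Bertalanffy growth curves for populations of overlapping cohorts, fitted
to length-at-age data in which **every individual is measured only once** —
the typical output of a trawl survey with otolith ageing, and of analogous
surveys of amphibians, reptiles, mammals and insects aged from hard body
structures.

## The problem and the model

Individual growth toward an asymptotic length is well described by the Von
Bertalanffy equation dℓ/dt = r_B (f ℓ∞ − ℓ), where the asymptotic length is
a species maximum ℓ∞ scaled by a dimensionless *environmental limitation*
f ∈ (0, 1] (food, temperature, density). In real populations f varies over
time, between cohorts and between individuals, and those sources of
variation are entangled by the autoregressive nature of growth. With only
one (age, length) pair per fish, individual trajectories cannot be fitted —
but cohort *length distributions* can.

`vbcohort` models the limitation experienced by an individual during the
interval between survey occasions T and T+1 as Gaussian, f ~ N(μ̄_T, σ̄²_T).
Growth then follows a mean-reverting stochastic differential equation whose
cohort-level consequences are exactly Gaussian, with mean and variance
propagating across a discrete time × age lattice as

    E[ℓ_{T+1,a+1}] = E[ℓ_{T,a}] e^{−r_B} + μ̄_T ℓ∞ (1 − e^{−r_B})
    V[ℓ_{T+1,a+1}] = V[ℓ_{T,a}] e^{−2 r_B} + σ̄²_T ℓ∞² (1 − e^{−2 r_B}) / (2 r_B)

with the long-term within-cohort variance σ̄²_T ℓ∞² / (2 r_B). The free
parameters — r_B, the length distributions of the first age class at every
occasion and of all older ages at the first occasion, and the per-interval
environmental products μ̄_T ℓ∞ and σ̄²_T ℓ∞² — are estimated jointly by
weighted Gaussian maximum likelihood in log-transformed parameter space
(derivative-free local search). Only the *products* with ℓ∞ are
identifiable; supplying a species-specific ℓ∞ (e.g. 780 mm for North Sea
plaice) reports the dimensionless limitation alongside.

Variants: time-constant vs year-varying limitation (nested, comparable by
AIC and likelihood-ratio test), separate limitation per age or mean-length
group, and a non-shrink restriction for species that cannot shrink.
Observation weights (e.g. inverse catch-per-unit-effort of a length class)
correct size-selective sampling. A leave-one-year-out jackknife measures
robustness to missing survey years, and a synthetic-data module simulates
individual growth paths from the underlying stochastic equation and samples
them with survey designs of known (possibly length-biased) catchability.

## Worked example

A small synthetic survey (8 occasions × 5 age classes, time-varying
limitation) ships with the package:

```r
library(vbcohort)
obs <- read_observations(system.file("extdata", "synthetic_survey.csv",
                                     package = "vbcohort"))
attr(obs, "grid")
#> <vb_grid> 8 occasions (0..7) x 5 age classes (0..4); 7 intervals

fit_c <- vb_fit(obs, env = "constant", l_inf = 780)
fit_v <- vb_fit(obs, env = "varying",  l_inf = 780)
glance(fit_v)
#> # A tibble: 1 × 9
#>   variant   nll     k    aic weighted_n n_floored   r_b converged n_eval
#> 1 varying 5648.    39 11374.        992         0 0.270 TRUE      175973

vb_compare(constant = fit_c, varying = fit_v)
#> # A tibble: 2 × 10
#>   variant  env          k   nll    aic delta_aic lrt_vs    lrt_p lrt_stat lrt_df
#> 1 varying  varying     39 5648. 11374.       0   const…  2.09e-4     37.2     12
#> 2 constant constant    27 5666. 11387.      13.2 <NA>   NA           NA       NA
```

The year-varying model wins by 13 AIC points and a likelihood-ratio test at
p ≈ 2×10⁻⁴: the environmental limitation genuinely fluctuated in this
simulation. Its per-interval estimates (`scaled` = μ̄_T after division by
ℓ∞ = 780) track the sinusoidal limitation the data were generated with:

```r
library(dplyr)
tidy(fit_v) |> filter(term == "mu_linf") |> select(interval, estimate, scaled) |> head(4)
#> # A tibble: 4 × 3
#>   interval estimate scaled
#> 1        0     583.  0.747
#> 2        1     767.  0.984
#> 3        2     740.  0.949
#> 4        3     686.  0.879
```

`autoplot(fit_v)` draws the limitation trajectory with its ±2 SD asymptotic
band; `plot_cohort_curves(fit_v)` draws every cohort's predicted growth
curve; `augment(fit_v, obs)` attaches fitted cell distributions and
standardised residuals to the observations; `vb_jackknife()` refits with
single years omitted.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/vbcohort.R simulate --scenario trending-env --seed 1 --out sim/
Rscript inst/cli/vbcohort.R fit --input sim/observations.csv --env varying --linf 780 --out fit/
Rscript inst/cli/vbcohort.R compare --input sim/observations.csv --out cmp/
```

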