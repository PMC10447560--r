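# cogtraj

Bayesian restricted-cubic-spline modelling of age-related cognitive
trajectories in an autosomal dominant Alzheimer's disease (ADAD) kindred,
and of how *APOE* genotype and educational attainment modify them.

## The scientific problem

Carriers of fully penetrant ADAD mutations (here, the *PSEN1* E280A "Paisa"
variant) are genetically determined to develop dementia, yet their age of
cognitive decline varies. Two candidate modifiers are the common *APOE*
alleles — e4 (risk) and e2 (protective) — and educational attainment, a
proxy for cognitive reserve. With only cross-sectional MMSE scores (0–30,
higher = better) over a broad adult age range, the analytical questions
are:

1. At what age does the cognitive trajectory of one group *begin to
   differ* from another (carriers vs non-carriers; e4+ vs e4−; e2+ vs
   e2−)?
2. Does education attenuate the genotype effect on cognition?

`cogtraj` implements this analysis battery for participant-level cohort
tables, and — because kindred registry data are access-restricted — ships a
synthetic cohort generator with known ground truth so every stage is
testable.

## The model

For two comparison groups \(g \in \{A, B\}\) with shared noise scale,

&nbsp;&nbsp;&nbsp;&nbsp;MMSE_i ~ Normal( f_g(age_i), σ ),&nbsp;&nbsp;
f_g(age) = x(age)ᵀ β_g,

where x(age) is a restricted cubic spline basis (default 5 knots at
Harrell's quantiles of the pooled ages; linear beyond the boundary knots).
Priors are weakly informative Cauchy(0, 2.5) on the coefficients of the
orthonormalized basis and half-Cauchy(0, 5) on σ. The joint posterior is
sampled by Hamiltonian Monte Carlo (leapfrog integrator, dual-averaging
step size; full configuration: 8 chains × 10,000 iterations, half warmup,
thinned by 10).

The **divergence age** is the earliest grid age (0.1-year grid) from which
the equal-tailed 99% credible band of the posterior difference curve
f_A − f_B excludes zero for at least 5 consecutive years (or through the
end of the grid). Group comparisons by education use ordinary least
squares: `MMSE ~ genotype + education + genotype × education`, with the
genotype indicator coded in the risk orientation (e4: 1 = e4+; e2:
1 = e2−). Demographic tables use Mann–Whitney U and Pearson chi-square
tests.

## Worked example

```r
library(cogtraj)

sim <- simulate_cohort(cohort_params(n_carriers = 400, n_noncarriers = 300), seed = 7)
fit <- fit_trajectory(sim$cohort, group = "psen1", mcmc = mcmc_preset("desk", seed = 7))
fit
#> traj_fit: PSEN1 carriers vs PSEN1 non-carriers (2000 posterior draws, 5 knots)
#> max split R-hat: 1.004

divergence(fit, level = 0.99, direction = "lower")
#> Posterior difference: PSEN1 carriers - PSEN1 non-carriers
#> 99% band, direction 'lower': trajectories begin to differ at 38.4 years

education_model(sim$cohort, stratum = "carriers", allele = "e4")
#>                      term estimate     se       t         p
#>               (Intercept)  15.2300 1.4650 10.4000 1.504e-22
#>                  genotype  -3.3020 3.2560 -1.0140 3.112e-01
#>           education_years   0.1507 0.1762  0.8553 3.929e-01
#>  genotype:education_years   0.4006 0.3569  1.1220 2.624e-01
#> n = 400  residual SD = 13.27  R^2 = 0.009721
```

The divergence age (38.4 years here) is the model's estimate of when the
carrier trajectory separates from non-carriers in this simulated kindred.
The regression signs show the expected pattern built into the generator's
ground truth: an MMSE deficit for e4+ carriers (−3.3 points), a benefit of
education, and a positive interaction (education attenuating the e4
deficit); at 400 carriers with cross-sectional noise the individual
coefficients are not significant, which is the realistic small-cohort
behaviour.

`run_study()` runs the whole battery (demographic tables, five trajectory
comparisons with divergence summaries, four regressions) and writes CSVs
plus a JSON summary; `plot(fit)` and `plot(divergence(fit))` draw the
trajectory and difference-curve figures.

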