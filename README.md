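# opmsir

Bayesian inference for a stochastic SIR model with a time-varying
infestation rate, built for yearly nest-removal records of tree pests such
as the oak processionary moth (OPM). Park managers record, once a year, the
cumulative number of unique trees that have ever had nests removed; `opmsir`
treats that single series as noisy partial observation of a closed epidemic
among trees and recovers the removal rate, the (time-varying) infestation
rate, the latent susceptible/infested counts, forecasts of future removals,
and a yearly basic reproduction number.

## Model

A fixed population of `N` trees moves through susceptible, infested and
removed compartments via two reactions,

    S + I -> 2I   at hazard  exp(beta_log_t) * S * I
    I -> R        at hazard  gamma * I

with the log infestation rate following a Brownian motion,
`d beta_log_t = sigma dW_t`. The latent state
`X_t = (S_t, I_t, beta_log_t)` is modelled as an Ito diffusion; yearly
cumulative removals `R(t)` are observed through
`Y_t ~ N(P'X_t, sigma_e^2 P'X_t)` with `P = (1,1,0)'` (observing `R(t)`
with known `N` is equivalent to observing `S_t + I_t = N - R(t)`).
Inference uses a linear noise approximation (LNA): the mean follows the
rate ODE, the covariance a linear matrix ODE driven by the drift Jacobian,
and a Kalman-style forward filter yields the marginal likelihood
`pi(y | theta)` for `theta = (gamma, sigma, sigma_e)`. A random-walk
Metropolis sampler on log-parameters draws from the posterior; latent paths
come from forward-filter backward-sampling; forecasts push posterior draws
through the stochastic model itself; and the yearly reproduction number is
`R0(t) = exp(beta_log_t) * N / gamma`.

See `vignettes/opmsir-methods.Rmd` for the full model account, design
decisions, and an honest analysis of where the Gaussian approximation
strains.

## Worked example

Simulate a park-scale synthetic study (5000 trees, 8 yearly observations),
fit it, and summarise:

```r
library(opmsir)

fx <- generate_fixture("bushy-like", seed = 6)   # truth: gamma=1, sigma=0.75, sigma_e=1
fx$obs
#>   year t r_cumulative        y
#> 1 2013 0            4 4995.989
#> 2 2014 1           93 4906.501
#> 3 2015 2          228 4771.981
#> 4 2016 3          444 4555.550
#> 5 2017 4         1001 3998.727
#> 6 2018 5         1620 3379.823
#> 7 2019 6         2210 2789.663
#> 8 2020 7         2638 2362.296

cfg <- model_config(5e3, s0 = 4900, i0 = 100)
ch <- fit_mcmc(fx$obs, prior_spec(), cfg,
               mcmc_control(iterations = 4000, burn_in = 1000), seed = 11)
ch
#> <opm_chain: 3000 retained draws, acceptance rate 0.29>
#>          2.5%   50% 97.5%
#> gamma   0.268 0.684  1.11
#> sigma   0.214 0.548  1.52
#> sigma_e 0.126 0.421  1.56
```

The 95% credible intervals straddle the generating values. The yearly
reproduction number (draws of `exp(beta_log_t) N / gamma`, paired with each
draw's own `gamma`):

```r
r0_posterior(ch)
#> <r0_summary> yearly posterior of R0(t) = exp(beta_log_t) * N / gamma
#>   year   q25 median  q75
#> 1 2013 1.160   1.62 2.24
#> 2 2014 1.430   1.86 2.43
#> 3 2015 1.980   2.46 3.02
#> 4 2016 2.680   3.31 4.07
#> 5 2017 2.030   2.41 2.90
#> 6 2018 1.560   1.86 2.17
#> 7 2019 1.260   1.48 1.81
#> 8 2020 0.954   1.46 2.13
```

`R0(t)` staying above one means the infestation keeps spreading — the
epidemic only shrinks on average once `R0 < 1`. Forecasting three years
ahead (latent cumulative removals, medians with quartile and 95% bands):

```r
forward_simulate(ch, horizon_years = 3, seed = 13)
#>   year    q2.5      q25   median      q75    q97.5
#> 1 2021 2798.56 2908.691 2969.317 3047.305 3238.471
#> 2 2022 2902.79 3094.288 3222.507 3376.588 3952.192
#> 3 2023 2954.26 3219.985 3410.041 3641.159 4447.571
```

Removals keep rising and eventually saturate as susceptible trees run out.
A command-line wrapper covering
`simulate | fit | predict | r0 | report` lives at
`inst/scripts/opmsir-cli.R`.

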