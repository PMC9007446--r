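# recruitflow

Interim monitoring and forecasting of patient recruitment in multi-center
clinical trials.

Recruitment at a trial site is often fastest just after the site opens —
eligible patients are already waiting — and decays afterwards.
Time-homogeneous accrual models then produce optimistic, overly narrow
forecasts, because the steady initiation of new centers hides the
per-center decay (one reason trial timelines routinely stretch to nearly
twice the plan, the so-called Lasagna's Law).  `recruitflow` is aimed at
trial statisticians and operations teams doing interim analyses: it
detects rate decay, fits a family of decaying-intensity models, and
produces accrual and time-to-target forecasts whose intervals carry both
parameter and model uncertainty.

## The model

Center *c*, initiated on calendar day *s_c*, recruits on its local day *t*

&nbsp;&nbsp;&nbsp;&nbsp;*N_c(t) | λ_c ~ Pois( λ_c [G(t;θ) − G(t−1;θ)] )*,
&nbsp;&nbsp;&nbsp;&nbsp;*λ_c ~ Gamma(α, α/φ)*,

where *g_κ(t;θ) ∝ (1 + θt/κ)^(−κ)* is a monotonically decaying intensity
curve-shape and *G* its integral.  The tail parameter is restricted to the
grid *κ ∈ {0, 0.5, 1, 2, ∞}* — from the constant-rate Poisson-gamma model
(*κ = 0*) through power-law tails to exponential decay — and each shape is
normalized to integrate to the mean observation length, so *θ* controls
shape only while *(α, φ)* control magnitude (*E[λ] = φ*,
*V[λ] = φ²/α*).  The random effects marginalize in closed form, so the
likelihood, the per-center rate posteriors
*Gamma(α + n_c, α/φ + G(τ_c))*, and the one-interval negative-binomial
predictive are all exact.  Each *κ* model is fitted by importance sampling
(multivariate-t₄ proposal at the posterior mode); marginal likelihoods
weight the models in a Bayesian model average used for forecasting.

Two one-sided decay tests come first: a Poisson likelihood-ratio test on
the center-aligned half-period sums (null: ½δ₀ + ½χ²₁), and a
within-center bootstrap test that assumes only i.i.d. daily counts and is
robust to overdispersion.

## Worked example

Simulate the reference trial design (200 centers over 600 days, α = 1.4,
φ = 0.01, decay κ = 2.7 / θ = 0.02 — a tail deliberately *off* the model
grid), take an interim census at day 360, test for decay, fit, and
forecast:

```r
library(recruitflow)

sim <- simulate_trial(sim_config(seed = 360360,
                                 deterministic_first_recruitment = TRUE))
obs <- truncate_trial(sim, 360)

sp <- split_centers(obs)
lrt_decay(sp$x1, sp$x2)
#>    statistic      p_value
#> 2.575061e+02 2.999889e-58        # decay is unambiguous

fit <- fit_recruitment(obs, M = 10000, seed = 14)
fit
#> Bayesian model-averaged recruitment fit
#>   normalization horizon tau_norm = 176.4 days
#>
#>  kappa                alpha                  phi                theta post_prob  ESS
#>      0 0.874 (0.611, 1.217) 0.019 (0.015, 0.023)                    -  2.97e-48 9000
#>    0.5 1.059 (0.729, 1.508) 0.017 (0.014, 0.020) 0.245 (0.086, 0.642)  2.53e-10 8486
#>      1 1.085 (0.742, 1.555) 0.017 (0.014, 0.021) 0.048 (0.032, 0.068)  0.000651 8590
#>      2 1.088 (0.750, 1.550) 0.017 (0.014, 0.021) 0.024 (0.019, 0.030)     0.146 8668
#>    Inf 1.082 (0.748, 1.545) 0.018 (0.015, 0.021) 0.013 (0.011, 0.015)     0.853 8600

fc <- forecast_accrual(fit, obs, horizon = 600, n_paths = 2000,
                       target = 900, seed = 15)
fc
#> Accrual forecast: days 361-600, 2000 paths
#>   accrual at census: 546
#>   final accrual: median 874, 95% interval (807, 958)
#>   time to target 900: 73% of paths censored at horizon
#>     median completion day 562

totals(sim)$n_total
#> [1] 868                           # truth: inside the 95% band
```

The fit table reads like an interim report: the constant-rate model is
ruled out (posterior probability ~10⁻⁴⁸), essentially all mass sits on
the two fastest-decaying shapes (κ = 2 and ∞, jointly 0.999), the modal
model's credible intervals are consistent with the generating values, and
the ESS column confirms each importance sample is reliable.  The forecast
says a 900-patient target is unlikely (73% of paths never reach it) by
day 600 — the kind of early warning that motivates opening more centers,
which can be explored by passing an `initiation_schedule()` to
`forecast_accrual()`.

Model criticism before forecasting: `qq_random_effects()` and
`qq_initial_period()` return QQ pairings of the data against the fitted
hierarchy (see the vignette in `vignettes/recruitment-modeling.Rmd`).

A command-line wrapper with `simulate` / `test` / `fit` / `forecast` /
`diagnose` subcommands is installed at `inst/cli/recruitflow`; every
subcommand writes a JSON artifact embedding its seed and options.

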