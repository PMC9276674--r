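# mhode

Moving-horizon discovery of sparse governing differential equations from
noisy time-series data.

## The problem

Given noisy samples of the states `x(t)` of a dynamical system (optionally
with exogenous inputs `u(t)`), recover the governing ordinary differential
equations in sparse dictionary form

```
dx/dt = Ξᵀ Θ(xᵀ, uᵀ, c)ᵀ
```

where `Θ` is an ordered dictionary of candidate basis functions (monomials,
trigonometric terms, parametric terms such as an Arrhenius rate
`CA·exp(-c/T)`), `Ξ` is a coefficient matrix that is mostly zero in the true
model, and `c` are nonlinear parameters inside basis functions, estimated
jointly with the coefficients — which rules out methods requiring the model
to be linear in all unknowns.

`mhode` fits sliding data windows by simultaneous Lagrange–Radau collocation
(the dictionary is evaluated on decision-variable states, never on
noise-corrupted data, and no derivatives are estimated for the fit), and
prunes dictionary terms whose window-to-window coefficient estimates have a
coefficient of variation above a tolerance `ψ` (default 1): coefficients of
truly active terms are pinned by the data and vary little across windows,
while coefficients that only fit noise wander. Surviving coefficients are
aggregated over post-convergence windows with empirical intervals. The
intended users are researchers in systems biology, chemical engineering and
applied dynamics who want interpretable ODE models from experimental time
series.

## Worked example

Discover the Lotka–Volterra predator–prey equations from noisy simulated
measurements:

```r
library(mhode)

sys   <- make_system("lotka_volterra")   # dx1/dt = x1 - 0.1 x1 x2 ; dx2/dt = 0.075 x1 x2 - 1.5 x2
clean <- simulate_true(sys)              # 2001 samples over 40 time units
sigma <- 0.01 * apply(ts_states(clean), 2, function(v) diff(range(v)))
noisy <- add_noise(clean, sigma, seed = 13)

lib <- default_library(sys)              # monomials deg <= 3 plus sin/cos: 14 terms
pp  <- preprocess(noisy, lib)            # smooth, screen, initialize
fit <- run_mho(pp$ts, pp$lib, mho_config(seed = 1),
               screening = pp$screening, ts_raw = noisy)

fit$model
#> <mhode_model> discovered governing equations (data exhausted before convergence)
#>    dx1/dt = 1.0003976*x1 + -0.1000179*x1*x2
#>    dx2/dt = -1.4988752*x2 + 0.074987881*x1*x2
#>   aggregated over 5 window(s) by mean

glance(fit$model)
#> # A tibble: 1 x 5
#>   n_terms n_states n_params n_windows converged
#> 1       4        2        0         5 FALSE

tidy(fit$model)        # per-coefficient estimates with empirical intervals
autoplot(fit$history)  # active-term count across windows
```

The printed model has exactly the four true terms; the coefficients are
within a few hundredths of a percent of the values used to generate the
data (the `x1*x2` coefficients, 0.1 and 0.075, are an order of magnitude
smaller than the linear ones — the coefficient-of-variation rule is
scale-invariant, so no magnitude threshold had to be tuned). `trajectory_mse()`
and `simulate_model()` validate the discovered equations by integration.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/scripts/mhode discover --data measurements.csv --seed 1 --out results/
Rscript inst/scripts/mhode benchmark --system brusselator --noise 0.01 --replicates 3
```

## Further reading

The methods vignette (`vignettes/methods.Rmd`) documents the estimator —
the collocation discretization, the moving-horizon/variance-separation
mechanics, the preprocessing stack, every tunable parameter with its
default and rationale, and known limitations.
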