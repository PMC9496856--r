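# pead — coupled degradation–emotion modelling of Alzheimer's disease progression

`pead` models longitudinal cognitive scores (e.g. the 0–30 MMSE) of people
with Alzheimer's disease as the noisy read-out of two coupled latent
continuous-time processes:

- an **irreversible physiological degradation** path `D(t)` — a gamma
  process, so `D` is monotone non-decreasing, with per-interval shape
  `c_ga · sigmoid(M(t_{i-1})) · Δt` and rate `β`: a raised emotional state
  accelerates degradation;
- a **non-monotone emotional state** `M(t)` — a Wiener process with bounded
  drift `c_μ · tanh(ω_δᵀ δ(t_i) + ω_zᵀ z + ω_d D(t_{i-1}) + ω_0) · Δt` and
  diffusion `σ`, driven by compound-Poisson **emotional impacts** δ
  (Poisson counts with rates `k±`, exponential intensities with rates
  `λ±`), covariates `z` (e.g. APOE4), and the degradation level itself;
- an observed score `Y(t_i) = h_0 + h_d D(t_i) + h_m M(t_i) + ε`,
  `ε ~ N(0, σ_ε²)`.

Because `M` can recover while `D` cannot, the model reproduces the
non-monotone score trajectories seen in practice without discretizing the
disease into an arbitrary number of stages. The package provides the
simulator (with the five standard synthetic parameter settings), Bayesian
estimation by MCMC with latent-path augmentation, split-chain R-hat
diagnostics, sequential one-step-ahead forecasting with 5–95% prediction
intervals via a particle filter, MSE/coverage evaluation, plotting, and a
command-line interface. See the methods vignette
(`vignettes/pe-model.Rmd`) for the full model account, prior profiles and
identifiability discussion.

## Worked example

Simulate ten Setting-1 sequences (fast degradation, `c_ga = 10`), fit the
eight free parameters, and forecast a held-out subject:

```r
library(pead)

train <- pe_simulate(setting = 1, n_sequences = 10, seed = 1)
fit <- pe_fit(train, pe_priors_synthetic(),
              pe_control(n_chains = 3, n_adapt = 1000, n_warmup = 4000,
                         n_samples = 2000, thin = 2, seed = 2))
print(fit)
```

```
Coupled degradation-emotion model fit (3 chains, 2000 draws/chain)
 parameter   mean    sd    q05    q50    q95  rhat
      beta  8.672 0.817  7.364  8.637  9.933 1.143
      c_ga  9.239 1.105  7.602  9.109 11.229 1.201
      c_mu  2.486 0.334  1.944  2.485  3.036 1.077
       h_0 30.148 0.179 29.856 30.147 30.448 1.001
       h_d -0.889 0.089 -1.038 -0.890 -0.738 1.062
       h_m -0.654 0.112 -0.864 -0.644 -0.485 1.088
     sigma  0.310 0.118  0.128  0.303  0.509 1.007
 sigma_eps  1.049 0.057  0.957  1.047  1.146 1.001
max split R-hat: 1.201 (NOT converged)
```

At this interactive chain length the posterior means already sit near the
generating values (`c_ga = 10`, `β = 10`, `h_0 = 30`, `σ_ε = 1`…) but
several R-hats still exceed 1.05 — the acceptance-scale protocol in
`scripts/acceptance.R` (10000 warm-up, 20000 sampling iterations thinned
by 5) is what this dataset needs for full convergence. Forecasting a new
subject sequentially, with the fitted posterior as prior:

```r
test <- pe_simulate(setting = 1, n_sequences = 1, seed = 99)
fc <- pe_forecast(test, fit, i_min = 0, n_particles = 2000, seed = 3)
pe_evaluate(fc, test)
```

```
Forecast evaluation
  predictions:        20
  pooled MSE:         1.2192
  mean subject MSE:   1.2192
  5-95% coverage:     0.9500
```

Each row of `fc` carries the predictive mean and the 5% and 95% predictive
quantiles for one visit, conditioning only on the visits before it; the
MSE is the squared error of the predictive means against the realized
scores, and coverage is the fraction of realized scores inside the bands
(nominal 0.90).

A command-line pipeline wrapping the same functions lives in
`inst/cli/pead.R`:

```sh
Rscript inst/cli/pead.R simulate --setting 1 --seed 7 --out data.csv
Rscript inst/cli/pead.R fit --data data.csv --seed 8 --out fitdir
Rscript inst/cli/pead.R predict --data data.csv --fit fitdir --seed 9 --out fc.csv
Rscript inst/cli/pead.R evaluate --forecasts fc.csv --data data.csv --out report.txt
```

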