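---
title: "A coupled degradation-emotion model for Alzheimer's disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled degradation-emotion model for Alzheimer's disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pead)
```

## The model

Cognitive screening scores of people with Alzheimer's disease, such as the
0-30 MMSE, decline over the long run but fluctuate visit to visit: the
underlying neuropathology (amyloid accumulation, tau tangles, atrophy) is
irreversible, while the measured score also reflects reversible influences,
prominently the patient's emotional condition. `pead` implements a
continuous-time state-space model that separates these two channels.

Two latent processes evolve between the visit times $t_0 < t_1 < \dots < t_n$:

**Physiological degradation** $D(t) \ge 0$ is a gamma process, so its
increments are independent, non-negative, and the path is monotone
non-decreasing ($D = 0$ means degradation has not begun):

$$D(t_i) = D(t_{i-1}) + \mathrm{Ga}\!\big(\alpha_i,\ \beta\big), \qquad
\alpha_i = c_{ga}\, f_s\!\big(M(t_{i-1})\big)\, \Delta t_i,$$

where $f_s$ is the standard logistic function and $\Delta t_i = t_i -
t_{i-1}$. A higher emotional state at the start of an interval raises the
gamma shape and hence the expected degradation $\alpha_i/\beta$; the shape
is bounded by $c_{ga}\Delta t_i$.

**Emotional state** $M(t) \in \mathbb{R}$ is a Wiener process with a
bounded, saturating drift:

$$M(t_i) = M(t_{i-1}) + c_\mu \tanh\!\big(\omega_\delta^\top \delta(t_i) +
\omega_z^\top z(t_{i-1}) + \omega_d D(t_{i-1}) + \omega_0\big)\,\Delta t_i +
\sigma B(\Delta t_i),$$

where $\delta(t_i) = (\delta^{(-)}, \delta^{(+)})^\top$ are the cumulative
*emotional impacts* of the interval, $z$ are subject covariates (e.g. an
APOE4 indicator), and $B$ is standard Brownian motion. The per-unit-time
mean change of $M$ is confined to $[-c_\mu, c_\mu]$. Impacts arrive as two
independent compound-Poisson streams: counts with rates $k^{(+)}, k^{(-)}$
per unit time and exponential intensities with rates $\lambda^{(+)},
\lambda^{(-)}$. In this sign convention "positive" impacts raise $M$ and
thereby *accelerate* degradation, and "negative" impacts moderate it --
the labels follow the direction of the latent state, not colloquial usage.

**Observation.** The score is a noisy linear read-out of both processes,

$$Y(t_i) = h_0 + h_d D(t_i) + h_m M(t_i) + \epsilon_i, \qquad
\epsilon_i \sim N(0, \sigma_\epsilon^2),$$

with $h_d < 0$ (degradation lowers the score). Because $M$ is non-monotone,
observed scores can recover between visits even though $D$ never does --
the feature that distinguishes this model from purely monotone progression
models and from discrete-stage (CN/MCI/AD) Markov chains, which need an
arbitrary number of states fixed in advance.

The model is continuous-time throughout: all transition densities scale
with $\Delta t_i$, so irregular visit schedules need no special handling.

## Parameters, units, defaults

| Parameter | Meaning | Unit | Setting-1 default |
|---|---|---|---|
| $k^{(+)}, k^{(-)}$ | impact arrival rates | events / time | 5, 4 |
| $\lambda^{(+)}, \lambda^{(-)}$ | impact intensity rates | 1 / impact size | 3, 3 |
| $\omega_{\delta}^{(+)}, \omega_{\delta}^{(-)}$ | drift loadings on impacts | 1 / impact size | 0.1, -0.1 |
| $\omega_d$ | drift loading on degradation | 1 / degradation | 0.05 |
| $\omega_0$ | drift intercept | -- | 0 |
| $c_\mu$ | drift amplitude bound | emotion / time | 3 |
| $\sigma$ | Wiener diffusion | emotion / $\sqrt{\text{time}}$ | 0.5 |
| $c_{ga}$ | gamma shape amplitude | 1 / time | 10 |
| $\beta$ | gamma rate | 1 / degradation | 10 |
| $h_0$ | score intercept | score | 30 |
| $h_d, h_m$ | score loadings | score per unit $D$, $M$ | -1, -0.5 |
| $\sigma_\epsilon$ | observation noise sd | score | 1 |

$\sigma$ and $\sigma_\epsilon$ are standard deviations, not variances: both
appear as scale parameters of their normal densities. The five presets
returned by `pe_setting()` differ only in $(k^{(+)}, k^{(-)})$ and
$c_{ga}$; setting 5 switches the impact rates from negative-dominant (3/5)
to positive-dominant (5/3) after the tenth interval, producing the
slow-then-fast decline pattern. The coefficient-impact pairing is by sign
label -- $\omega_\delta^{(+)}$ multiplies $\delta^{(+)}$ -- so that
positive impacts push the emotional state up in every preset.

The impact *counts* are Poisson with mean $k\Delta t$, which is the law of
the stated Poisson arrival process; `logpmf_impact_count()` implements
exactly that pmf.

## What the simulator emulates, and what it does not

`pe_simulate()` draws from the full generative model: per interval it
samples the two impact streams, advances $M$ using $D(t_{i-1})$, advances
$D$ using $M(t_{i-1})$, and emits the score from the *new* latent pair.
Defaults reproduce the synthetic study design: 20 sequences of 21
observations at unit spacing per setting, initial latent state $(D, M) =
(0, 0)$ -- trajectories begin with degradation not yet started and a
neutral emotional state, which is what the model's $D=0$ anchor means; both
are overridable. The baseline score $Y(t_0)$ is emitted from the initial
state plus noise, giving 21 observations per sequence.

Scores are *not* clamped to $[0, 30]$ by default: the observation model is
an unbounded Gaussian and the inference assumes it; `clip_score()` (or
`clip = TRUE`) exists only for display-realistic fixtures. Each trajectory
consumes its own L'Ecuyer-CMRG substream derived from the root seed, so a
dataset is bit-reproducible and growing `n_sequences` never perturbs
earlier trajectories.

Passing synthetic-data tests shows the estimation and forecasting machinery
is correct *under the model's own assumptions*. Real cognitive-score series
differ in known ways: scores are bounded and discrete, emotional impacts
are not recorded (the clinical prior profile drops them by fixing
$\omega_\delta = 0$), visit schedules correlate with disease state, and the
Gaussian noise model ignores floor/ceiling compression.

## Inference

`pe_fit()` estimates the free parameters jointly with the latent paths by
MCMC. The latent paths are explicit augmented variables in a non-centered
parameterization: the emotional path is built from standard-normal
innovations scaled by $\sigma$, and each degradation increment from a
unit-rate gamma innovation scaled by $1/\beta$. Centered parameterizations
leave the scale parameters entangled with their paths (a classic funnel)
and in our prototypes left the drift and diffusion parameters unconverged
at any affordable chain length; the non-centered forms decouple them. The
model graph is sampled by JAGS (slice/Gibbs updates) with one RNG seed per
chain derived from `control$seed`, so fits are exactly reproducible.

Per-interval emotional impacts are conditioned on as recorded data when the
trajectories carry them (the simulator records them); otherwise the impact
coefficients must be fixed at zero so the compound-Poisson term vanishes
from the drift. Fully latent impacts are not supported. The impact-process
rates $k, \lambda$ are always fixed: given recorded impacts they are
likelihood-separated from every other parameter and would only ever
reproduce their own sufficient statistics.

**Identifiability and the prior profiles.** With the gamma shape given,
scaling every degradation increment by $c$ while mapping $(h_d, \beta) \to
(h_d / c,\ c\beta)$ leaves the likelihood exactly invariant: the data
identify only the ratio $h_d/\beta$ plus shape information. The analogous
(weaker, because the logistic link is nonlinear) trade-off ties the scale
of $M$ to $(h_m, \sigma, c_\mu)$. Informative priors are therefore not a
convenience but part of the model specification, as is usual for
latent-scale state-space models. The shipped synthetic profile
(`pe_priors_synthetic()`) pins the ridge directions with tight priors on
$h_d$ (sd 0.1) and $\beta$ (sd 1), uses moderately informative priors on
$c_\mu, \sigma, h_m, \sigma_\epsilon$, and deliberately leaves $c_{ga}$
loose (sd 2.5) because distinguishing degradation speeds is the question
the synthetic study asks. Every center sits at least one prior sd away from
every preset's generating value, so recovery is driven by the data, not by
prior centering. The clinical profile (`pe_priors_adni()`) follows the
registry-study reporting convention: a single covariate coefficient free,
$\omega_\delta = 0$ fixed, and tight (sd 0.05-0.10) priors throughout.
Diffuse priors are *not* expected to recover all parameters jointly, and
`pe_fit()` makes no attempt to hide that.

Convergence is judged by the split-chain potential scale reduction factor
(`split_rhat()`): each chain is halved, and between- and within-half
variances are compared; values below 1.05 are taken as mixed. Chains with
zero within-chain variance are reported as `NA` with a warning rather than
as a number. The default protocol (3 chains, 1000 warm-up, 1000 retained)
is sized for interactive use and smoke tests; the acceptance-scale protocol
used in `scripts/acceptance.R` and the test suite (3 chains, 2000
adaptation, 10000 warm-up, 20000 sampling iterations thinned by 5) is what
the 10-sequence Setting-1 fit needs to bring every split R-hat under 1.05.

## Forecasting

The task is strictly one-step-ahead: predict $Y(t_{i+1})$ given
$Y(t_0), \dots, Y(t_i)$, refreshed as each visit arrives. `pe_forecast()`
implements the sequential update as a particle filter: particles couple a
parameter draw (from a fitted posterior, or from the prior when no training
fit exists) with a latent $(D, M)$ state; each arriving observation
reweights and systematically resamples the cloud; a forecast propagates the
filtered cloud one interval forward -- drawing the coming interval's
impacts from their compound-Poisson law, since the future is not observed
-- and emits one predictive score draw per particle. The predictive mean
and the 5% and 95% quantiles of these draws are reported. This *is* the
Bayesian prior-to-posterior update applied at every visit, done by
filtering rather than by refitting; a full MCMC refit per step
(`method = "refit"`) is available but costs a fit per prediction event and
is reserved for spot checks. Forecasts are emitted before the observation
at the target time is assimilated, and the filter consumes randomness in a
data-independent order, so forecasts are invariant to any change in
observations at or after their target time (tested by fuzzing).

By default forecasting starts at `i_min = 1`, i.e. after two observations;
`i_min = 0` forecasts from the baseline visit alone and is used where a
full 20-forecast-per-sequence pass is wanted. `pe_evaluate()` reports the
pooled MSE over all prediction events (and, because conventions differ, the
mean of per-subject MSEs alongside) plus the empirical 5-95% interval
coverage.

## Numerical choices and degenerate modes

- $c_{ga} = 0$ switches the degradation increment off entirely. Simulation
  returns a flat path; density evaluation is an error (the gamma density
  does not exist at shape 0). Together with zero impact rates and zero
  noise scales (`allow_degenerate = TRUE`) this gives the all-noise-off
  mode used for exact tests: the forecast must then reproduce the previous
  score with a zero-width interval.
- Negative degradation increments are outside the gamma support:
  `logpdf_degradation_increment()` and `pe_joint_logdensity()` return
  $-\infty$, they do not raise.
- Particle weights that all vanish (possible only with degenerate
  observation noise and inconsistent data) fall back to uniform with a
  warning rather than aborting.
- MCMC initial values sit at the prior means, spread by $\pm 1$ prior sd
  across chains (clamped positive where the support requires it); latent
  innovations start at their prior centers.
- CSV writers print doubles with 17 significant digits so write-read
  round-trips are lossless.

## Problem sizes used in the checks

The shipped verification uses the synthetic-study geometry throughout: 10
training sequences of 21 observations for the recovery fits, 30 held-out
sequences (600 one-step prediction events at `i_min = 0`) for calibration —
at 200 events the between-dataset noise of a coverage estimate is about
$\pm 0.04$, so the larger evaluation set is needed for the band check to
measure the model rather than the draw — 20 sequences per setting for the
monotonicity sweep, $10^6$ draws for the compound-Poisson moment check and
4000 single-interval transitions for the increment moments, 1000 random
points at tolerance $10^{-10}$ for the density oracles, and 5 replicate
5-sequence datasets for the unbiasedness-across-replicates check (run with
a flattened amplitude prior, since the shipped profile's informative prior
shrinks deliberately).

## Known limitations

- $h_d$ and $\beta$ (and more weakly, the $M$-scale group) are identified
  only through their priors; reporting both separately inherits the
  prior's information.
- The emotional impacts must be recorded or excluded; there is no
  marginalization over latent impact histories.
- One-step-ahead only: no multi-step or time-to-conversion forecasting.
- The observation model ignores the instrument's floor and ceiling; scores
  near 0 or 30 will be mildly miscalibrated.
- The filter does not rejuvenate parameter particles; over very long series
  the parameter cloud can impoverish. With 21-visit series and a few
  thousand particles this is not material.
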