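## Independent textbook-formula density oracles: hand-coded expressions,
## never routed through the package's density functions.

oracle_norm_logpdf <- function(x, mean, sd)
  -0.5 * log(2 * pi) - log(sd) - (x - mean)^2 / (2 * sd^2)

oracle_gamma_logpdf <- function(x, shape, rate)
  shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x

oracle_pois_logpmf <- function(n, lam) -lam + n * log(lam) - lgamma(n + 1)

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

## random valid parameter sets for fuzzing
random_params <- function() {
  pe_params(k_pos = runif(1, 0.5, 8), k_neg = runif(1, 0.5, 8),
            lambda_pos = runif(1, 0.5, 5), lambda_neg = runif(1, 0.5, 5),
            w_delta_pos = runif(1, -0.5, 0.5), w_delta_neg = runif(1, -0.5, 0.5),
            w_d = runif(1, -0.2, 0.2), w_0 = runif(1, -1, 1),
            c_mu = runif(1, 0.5, 5), sigma = runif(1, 0.1, 2),
            c_ga = runif(1, 1, 15), beta = runif(1, 1, 15),
            h_0 = runif(1, 20, 32), h_d = runif(1, -2, -0.2),
            h_m = runif(1, -1.5, -0.1), sigma_eps = runif(1, 0.3, 2))
}

## noise-free parameter set for exact degeneracy checks
degenerate_params <- function(h_0 = 30, h_d = -1, h_m = -0.5)
  pe_params(k_pos = 0, k_neg = 0, sigma = 0, sigma_eps = 0, c_ga = 0,
            w_0 = 0, w_d = 0, h_0 = h_0, h_d = h_d, h_m = h_m,
            allow_degenerate = TRUE)

## tiny deterministic-protocol control for smoke fits
smoke_control <- function(seed = 1, n = 200)
  pe_control(n_chains = 2, n_adapt = n, n_warmup = n, n_samples = n, seed = seed)
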