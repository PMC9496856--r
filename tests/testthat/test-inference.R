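test_that("the joint log-density equals a brute-force term-by-term oracle", {
  set.seed(701)
  p <- random_params()
  mk_traj <- function(id) {
    times <- c(0, cumsum(runif(3, 0.5, 2)))
    m <- cumsum(c(0, rnorm(3)))
    d <- cumsum(c(0, rexp(3, 2)))
    imp <- data.frame(n_neg = rpois(3, 2), n_pos = rpois(3, 2))
    imp$delta_neg <- ifelse(imp$n_neg > 0, rgamma(3, imp$n_neg, 2), 0)
    imp$delta_pos <- ifelse(imp$n_pos > 0, rgamma(3, imp$n_pos, 2), 0)
    y <- rnorm(4, 28, 3)
    pe_trajectory(id, times, y, latent = data.frame(d = d, m = m),
                  impacts = imp)
  }
  data <- pe_data(list(mk_traj("a"), mk_traj("b")))

  oracle <- 0
  for (tr in data$trajectories) {
    d <- tr$latent$d; m <- tr$latent$m
    oracle <- oracle + oracle_norm_logpdf(tr$y[1],
                                          p$h_0 + p$h_d * d[1] + p$h_m * m[1],
                                          p$sigma_eps)
    for (j in 1:3) {
      dt <- tr$times[j + 1] - tr$times[j]
      x <- p$w_delta_pos * tr$impacts$delta_pos[j] +
        p$w_delta_neg * tr$impacts$delta_neg[j] + p$w_d * d[j] + p$w_0
      oracle <- oracle +
        oracle_norm_logpdf(m[j + 1] - m[j], p$c_mu * tanh(x) * dt,
                           p$sigma * sqrt(dt)) +
        oracle_gamma_logpdf(d[j + 1] - d[j],
                            p$c_ga * oracle_sigmoid(m[j]) * dt, p$beta) +
        oracle_norm_logpdf(tr$y[j + 1],
                           p$h_0 + p$h_d * d[j + 1] + p$h_m * m[j + 1],
                           p$sigma_eps) +
        oracle_pois_logpmf(tr$impacts$n_neg[j], p$k_neg * dt) +
        oracle_pois_logpmf(tr$impacts$n_pos[j], p$k_pos * dt)
      if (tr$impacts$n_neg[j] > 0)
        oracle <- oracle + oracle_gamma_logpdf(tr$impacts$delta_neg[j],
                                               tr$impacts$n_neg[j], p$lambda_neg)
      if (tr$impacts$n_pos[j] > 0)
        oracle <- oracle + oracle_gamma_logpdf(tr$impacts$delta_pos[j],
                                               tr$impacts$n_pos[j], p$lambda_pos)
    }
  }
  expect_equal(pe_joint_logdensity(p, data), oracle, tolerance = 1e-10)
})

test_that("a decreasing degradation step makes the joint density -Inf", {
  p <- pe_setting(1)$params
  tr <- pe_trajectory("a", 0:2, c(30, 29, 28),
                      latent = data.frame(d = c(0, 1, 1), m = c(0, 0.5, 0.2)),
                      impacts = data.frame(n_neg = 0L, n_pos = 0L,
                                           delta_neg = 0, delta_pos = 0)[c(1, 1), ])
  tr$latent$d <- c(0, 1, 0.5)  # bypass the constructor to hit the density guard
  expect_identical(pe_joint_logdensity(p, pe_data(list(tr))), -Inf)
})

test_that("split R-hat separates mixed, unmixed and degenerate chains", {
  set.seed(702)
  mixed <- matrix(rnorm(30000), 10000, 3)
  expect_lt(split_rhat(mixed), 1.01)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(split_rhat(apart), 3)
  ## exact copies of one iid stream: no between-chain variance
  stream <- rnorm(5000)
  expect_lt(split_rhat(cbind(stream, stream, stream)), 1.01)
  expect_warning(rh <- split_rhat(matrix(1, 100, 3)), "degenerate")
  expect_true(is.na(rh))
  ## trending (non-stationary) chains are flagged by the split halves
  expect_gt(split_rhat(cbind(seq_len(1000), seq_len(1000))), 1.5)
})

test_that("posterior summaries recompute exactly from the raw draws", {
  m1 <- coda::mcmc(cbind(a = c(1, 2), b = c(5, 5)))
  m2 <- coda::mcmc(cbind(a = c(3, 4), b = c(5, 5)))
  fit <- structure(list(draws = coda::as.mcmc.list(list(m1, m2)), rhat = NULL),
                   class = "pe_fit")
  s <- suppressWarnings(posterior_summary(fit))
  expect_equal(s$mean[s$parameter == "a"], 2.5, tolerance = 1e-12)
  expect_equal(s$sd[s$parameter == "b"], 0, tolerance = 1e-12)
  pooled <- rbind(as.matrix(m1), as.matrix(m2))
  expect_equal(s$mean, unname(colMeans(pooled)), tolerance = 1e-12)
  expect_equal(s$q50, unname(apply(pooled, 2, median)), tolerance = 1e-12)
})

test_that("a fully fixed model returns the point-mass posterior", {
  d <- pe_simulate(setting = 1, n_sequences = 2, n_obs = 4, seed = 21)
  p <- pe_setting(1)$params
  pri <- pe_priors(fixed = p[setdiff(names(p), "w_z")])
  fit <- pe_fit(d, pri, pe_control(n_samples = 50, seed = 1))
  s <- fit$summary
  expect_true(all(s$sd == 0))
  expect_equal(s$mean[s$parameter == "c_ga"], 10)
  expect_equal(unname(coef(fit)["beta"]), 10)
})

test_that("withholding the observations reproduces the prior (prior-sampling check)", {
  d <- pe_simulate(setting = 1, n_sequences = 2, n_obs = 5, seed = 22)
  pri <- pe_priors_synthetic()
  fit <- pe_fit(d, pri, pe_control(n_chains = 2, n_adapt = 300, n_warmup = 300,
                                   n_samples = 1500, seed = 3),
                use_observations = FALSE)
  draws <- pe_posterior_draws(fit)
  ## c_ga ~ N(7.5, 2.5) truncated at 0 (truncation mass ~ 0.13%)
  expect_lt(abs(mean(draws[, "c_ga"]) - 7.5), 0.4)
  expect_lt(abs(sd(draws[, "c_ga"]) - 2.5), 0.4)
  expect_lt(abs(mean(draws[, "h_d"]) - (-0.9)), 0.02)
  expect_lt(abs(quantile(draws[, "h_0"], 0.5) - 29), 0.25)
})

test_that("fits are deterministic given the seed and expose the fit surface", {
  d <- pe_simulate(setting = 1, n_sequences = 3, n_obs = 6, seed = 23)
  f1 <- pe_fit(d, pe_priors_synthetic(), smoke_control(seed = 5, n = 150))
  f2 <- pe_fit(d, pe_priors_synthetic(), smoke_control(seed = 5, n = 150))
  expect_identical(lapply(f1$draws, as.matrix), lapply(f2$draws, as.matrix))
  f3 <- pe_fit(d, pe_priors_synthetic(), smoke_control(seed = 6, n = 150))
  expect_false(identical(as.matrix(f1$draws[[1]]), as.matrix(f3$draws[[1]])))
  s <- summary(f1)
  expect_setequal(s$parameter, c("c_mu", "sigma", "c_ga", "beta", "h_0",
                                 "h_d", "h_m", "sigma_eps"))
  expect_true(all(is.finite(s$mean)))
  expect_true(all(c("chain", "iteration", "parameter", "value") %in%
                    names(pe_draws_table(f1))))
})

test_that("posterior means of the degradation amplitude are unbiased across replicates", {
  ## 5 replicate Setting-1 datasets (5 sequences each, short protocol). The
  ## amplitude prior is flattened (sd 10) so the check measures the sampler,
  ## not the deliberate shrinkage of the shipped informative profile.
  pri <- pe_priors_synthetic()
  pri$free$c_ga <- c(mean = 7.5, sd = 10)
  means <- vapply(1:5, function(r) {
    d <- pe_simulate(setting = 1, n_sequences = 5, n_obs = 21, seed = 800 + r)
    f <- pe_fit(d, pri,
                pe_control(n_chains = 3, n_adapt = 500, n_warmup = 1500,
                           n_samples = 1500, seed = 900 + r))
    coef(f)[["c_ga"]]
  }, numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 10), 2 * mc_se + 1e-12)
})

test_that("covariates enter the fit through the drift with a free coefficient", {
  ## one binary covariate, impact coefficients fixed at zero (registry-style)
  p <- pe_params(w_z = 0.6, w_delta_pos = 0, w_delta_neg = 0,
                 c_mu = 1.3, sigma = 1, c_ga = 5, beta = 6,
                 h_0 = 29.5, h_d = -0.5, h_m = -1, sigma_eps = 0.8)
  zs <- lapply(1:4, function(i) matrix(i %% 2, 6, 1))
  d <- pe_simulate(params = p, n_sequences = 4, n_obs = 6, seed = 24, z = zs)
  fit <- pe_fit(d, pe_priors_adni(), smoke_control(seed = 7, n = 150))
  s <- fit$summary
  expect_true("w_z[1]" %in% s$parameter)
  expect_true(all(is.finite(s$mean)))
  ## missing impacts with nonzero impact coefficients is an error
  d2 <- d
  d2$trajectories <- lapply(d2$trajectories, function(tr) { tr$impacts <- NULL; tr })
  expect_error(pe_fit(d2, pe_priors_synthetic(), smoke_control()),
               "impacts are not recorded")
})
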