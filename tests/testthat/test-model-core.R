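test_that("drift is the bounded tanh regression on impacts, covariates and degradation", {
  p1 <- pe_setting(1)$params
  expect_identical(drift_mu(pe_params(w_0 = 0), 0, 0, d_prev = 0, dt = 1), 0)
  ## Setting-1 coefficients: 3 * tanh(0.1*2 + 0.05*4)
  expect_equal(drift_mu(p1, delta_neg = 0, delta_pos = 2, d_prev = 4, dt = 1),
               3 * tanh(0.4), tolerance = 1e-12)
  ## saturation at the amplitude bound
  expect_equal(drift_mu(p1, 0, 0, d_prev = 1e8, dt = 1), 3, tolerance = 1e-12)
  ## covariates enter linearly inside the link
  pz <- pe_params(w_z = c(0.5, -0.25), c_mu = 2, w_0 = 0)
  expect_equal(drift_mu(pz, 0, 0, z = c(1, 2), d_prev = 0, dt = 2),
               2 * tanh(0.5 - 0.5) * 2, tolerance = 1e-12)
  expect_error(drift_mu(p1, 0, 0, z = c(1, 2), d_prev = 0, dt = 1),
               "covariate length mismatch")
  expect_error(drift_mu(p1, 0, 0, d_prev = 0, dt = 0), "dt")
})

test_that("drift never exceeds c_mu * dt on fuzzed inputs", {
  set.seed(401)
  for (i in seq_len(10000)) {
    p <- pe_params(c_mu = runif(1, 0.1, 10), w_delta_pos = rnorm(1),
                   w_delta_neg = rnorm(1), w_d = rnorm(1), w_0 = rnorm(1, 0, 3))
    dt <- runif(1, 0.01, 5)
    mu <- drift_mu(p, delta_neg = rexp(1, 0.2), delta_pos = rexp(1, 0.2),
                   d_prev = rexp(1, 0.1), dt = dt)
    expect_lte(abs(mu), p$c_mu * dt + 1e-12)
  }
})

test_that("gamma shape is the logistic link scaled by c_ga and dt, monotone in the emotion", {
  expect_equal(gamma_shape(pe_setting(1)$params, m_prev = 0, dt = 1), 5,
               tolerance = 1e-12)
  p2 <- pe_setting(2)$params
  expect_equal(gamma_shape(p2, m_prev = 2, dt = 1), 5 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_lt(gamma_shape(p2, m_prev = -40, dt = 1), 1e-12)
  m <- seq(-6, 6, length.out = 60)
  sh <- vapply(m, function(mm) gamma_shape(p2, mm, 1), numeric(1))
  expect_true(all(diff(sh) > 0))
  expect_true(all(sh > 0))
})

test_that("the three log-densities match independent textbook formulas", {
  set.seed(402)
  for (i in seq_len(1000)) {
    p <- random_params()
    dt <- runif(1, 0.1, 4)
    dneg <- rexp(1); dpos <- rexp(1); dprev <- rexp(1, 0.2); mprev <- rnorm(1, 0, 2)
    dm <- rnorm(1, 0, 3)
    x <- p$w_delta_pos * dpos + p$w_delta_neg * dneg + p$w_d * dprev + p$w_0
    expect_equal(
      logpdf_emotion_increment(p, dm, dneg, dpos, d_prev = dprev, dt = dt),
      oracle_norm_logpdf(dm, p$c_mu * tanh(x) * dt, p$sigma * sqrt(dt)),
      tolerance = 1e-10)
    dd <- rexp(1, 2)
    expect_equal(
      logpdf_degradation_increment(p, dd, m_prev = mprev, dt = dt),
      oracle_gamma_logpdf(dd, p$c_ga * oracle_sigmoid(mprev) * dt, p$beta),
      tolerance = 1e-10)
    y <- runif(1, 0, 30); d <- rexp(1, 0.2); m <- rnorm(1, 0, 2)
    expect_equal(
      logpdf_observation(p, y, d, m),
      oracle_norm_logpdf(y, p$h_0 + p$h_d * d + p$h_m * m, p$sigma_eps),
      tolerance = 1e-10)
  }
})

test_that("each conditional density integrates (or sums) to one", {
  p <- pe_setting(1)$params
  i1 <- integrate(function(dm) exp(logpdf_emotion_increment(
    p, dm, delta_neg = 1, delta_pos = 2, d_prev = 3, dt = 1.5)),
    -Inf, Inf, rel.tol = 1e-9)
  expect_equal(i1$value, 1, tolerance = 1e-6)
  i2 <- integrate(function(dd) exp(logpdf_degradation_increment(
    p, dd, m_prev = 0.7, dt = 1)), 0, Inf, rel.tol = 1e-9)
  expect_equal(i2$value, 1, tolerance = 1e-6)
  i3 <- integrate(function(y) exp(logpdf_observation(p, y, d = 5, m = 1)),
                  -Inf, Inf, rel.tol = 1e-9)
  expect_equal(i3$value, 1, tolerance = 1e-6)
  expect_equal(sum(exp(logpmf_impact_count(5, 0:60, dt = 1))), 1,
               tolerance = 1e-6)
})

test_that("degradation density rejects negative increments and the degenerate mode", {
  p <- pe_setting(1)$params
  expect_identical(logpdf_degradation_increment(p, -0.1, m_prev = 0), -Inf)
  ## exponential special case: shape 1 at zero has density beta
  p1 <- pe_params(c_ga = 2, beta = 10)
  expect_equal(logpdf_degradation_increment(p1, 0, m_prev = 0, dt = 1),
               log(10), tolerance = 1e-10)
  p0 <- pe_params(c_ga = 0)
  expect_error(logpdf_degradation_increment(p0, 0.5, m_prev = 0),
               "degenerate")
})

test_that("observation density peaks at the linear predictor", {
  p1 <- pe_setting(1)$params
  expect_equal(logpdf_observation(p1, 30, d = 0, m = 0), -0.5 * log(2 * pi),
               tolerance = 1e-10)
  ## mean 30 - 5 - 0.5 = 24.5: the peak argument
  ys <- seq(20, 30, by = 0.25)
  lp <- vapply(ys, function(y) logpdf_observation(p1, y, d = 5, m = 1),
               numeric(1))
  expect_equal(ys[which.max(lp)], 24.5)
  ## symmetry about the drift for the emotion increment
  mu <- drift_mu(p1, 1, 2, d_prev = 3, dt = 1)
  expect_equal(logpdf_emotion_increment(p1, mu + 0.37, 1, 2, d_prev = 3),
               logpdf_emotion_increment(p1, mu - 0.37, 1, 2, d_prev = 3),
               tolerance = 1e-12)
})

test_that("impact counts are Poisson with mean k*dt", {
  expect_equal(logpmf_impact_count(5, 0, dt = 1), -5, tolerance = 1e-12)
  set.seed(403)
  n <- sample(0:20, 200, replace = TRUE)
  k <- runif(200, 0.5, 8)
  expect_equal(logpmf_impact_count(k, n, dt = 1), oracle_pois_logpmf(n, k),
               tolerance = 1e-10)
  expect_error(logpmf_impact_count(5, -1), "non-negative integer")
  expect_error(logpmf_impact_count(5, 1.5), "non-negative integer")
  expect_error(logpmf_impact_count(5, 1, dt = 0), "dt")
})

test_that("parameter validation enforces positivity and finiteness", {
  expect_error(pe_params(sigma = 0), "strictly positive")
  expect_error(pe_params(beta = -1), "strictly positive")
  expect_error(pe_params(c_ga = -0.1), "non-negative")
  expect_error(pe_params(h_0 = Inf), "finite")
  expect_silent(pe_params(sigma = 0, k_pos = 0, allow_degenerate = TRUE))
  expect_error(pe_params(beta = 0, allow_degenerate = TRUE), "strictly positive")
})
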